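#' Run the full pooled-GWAS discovery and validation pipeline
#'
#' Simulates a cohort from `spec`, pools it, computes RAS, screens pools by
#' PC-based QC, scans each pool set with Welch t-tests plus Bonferroni
#' correction, selects candidate loci as blocks of tightly spaced associated
#' SNPs with index SNPs, merges the rounds, and validates the merged
#' candidates by individual genotyping on the same simulated cohort (allelic
#' Fisher exact tests, Woolf CIs, two-tier classification, direction
#' concordance). The Bonferroni denominator for the validation tier is the
#' number of merged candidates, passed explicitly to the classifier.
#'
#' @param spec a [sim_spec()] with at least one pool set.
#' @param criteria a [block_criteria()].
#' @param qc_threshold robust z threshold for [qc_pools()]; `NA` skips QC.
#' @param qc_groups optional group restriction for removals
#'   (see [qc_pools()]).
#' @param validate run the individual-genotyping stage (default `TRUE`).
#' @return A list of class `pooled_gwas_result` with elements `genotypes`,
#'   `membership`, `ras`, `qc`, `scan` (all sets, Bonferroni-adjusted),
#'   `blocks` (per set), `candidates` (merged `candidate_set`),
#'   `validation`, and `n_tests`.
#' @export
run_pooled_gwas <- function(spec, criteria = block_criteria(),
                            qc_threshold = 3.5, qc_groups = NULL,
                            validate = TRUE) {
  gt <- simulate_cohort(spec)
  membership <- assign_pools(gt, spec)
  intens <- simulate_intensities(gt, membership, spec)
  ras <- compute_ras(intens)
  qc <- NULL
  if (!is.na(qc_threshold)) {
    qc <- qc_pools(ras, threshold = qc_threshold,
                   restrict_to_groups = qc_groups)
    ras <- apply_qc(ras, qc)
  }
  scan <- bonferroni_adjust(welch_scan(ras, spec$case_label,
                                       spec$control_label))
  sets <- unique(scan$set_id)
  blocks <- list()
  cands <- NULL
  for (s in sets) {
    track <- scan[scan$set_id == s, c("chrom", "pos", "snp_id", "p_value")]
    bl <- select_index_snps(find_blocks(track, criteria), criteria)
    blocks[[s]] <- bl
    cs <- candidates_from_blocks(bl, disease = spec$case_label, round = s)
    cands <- if (is.null(cands)) cs else merge_rounds(cands, cs)
  }
  res <- list(genotypes = gt, membership = membership, ras = ras, qc = qc,
              scan = scan, blocks = blocks, candidates = cands,
              validation = NULL, n_tests = nrow(cands))
  if (validate && nrow(cands) > 0) {
    res$validation <- validate_candidates(
      gt, cands, spec$case_label, spec$control_label,
      n_tests = nrow(cands), scan = scan, orientation = "same")
  }
  class(res) <- "pooled_gwas_result"
  res
}

#' @export
#' @method print pooled_gwas_result
print.pooled_gwas_result <- function(x, ...) {
  cat("pooled-GWAS pipeline result\n")
  cat(sprintf("  scan: %d SNP tests over %d set(s)\n", nrow(x$scan),
              length(unique(x$scan$set_id))))
  cat(sprintf("  blocks: %s\n",
              paste(sprintf("%s=%d", names(x$blocks),
                            vapply(x$blocks, length, 0L)), collapse = ", ")))
  cat(sprintf("  candidates: %d", x$n_tests))
  if (!is.null(x$validation))
    cat(sprintf(" | corrected %d, suggestive %d, not validated %d",
                sum(x$validation$tier == "corrected"),
                sum(x$validation$tier == "suggestive"),
                sum(x$validation$tier == "not_validated")))
  cat("\n")
  invisible(x)
}
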