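#' Write the run report bundle
#'
#' Emits a machine-readable TSV bundle plus a human-readable markdown report
#' covering whatever stage outputs are supplied: QC removals, scan summary,
#' blocks, candidates, validation tiers, shared-locus summary and (when
#' given) the packaged-fixture bookkeeping. Missing stages are reported as
#' explicit gaps rather than silently dropped. The resolved configuration
#' (including the seed) is embedded in the report and written as YAML.
#'
#' @param dir output directory (created if needed).
#' @param config named list of resolved run parameters; should include
#'   `seed` and, for the validation stage, `n_tests`.
#' @param qc optional `qc_report`.
#' @param scan optional `scan_result`.
#' @param blocks optional `block_list`.
#' @param candidates optional `candidate_set`.
#' @param validation optional `validation_result`.
#' @param shared optional `shared_loci_summary`.
#' @param table2 optional `table2_summary`.
#' @return The report path, invisibly.
#' @export
write_report <- function(dir, config = list(), qc = NULL, scan = NULL,
                         blocks = NULL, candidates = NULL, validation = NULL,
                         shared = NULL, table2 = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(dir, "run_config.yaml"))
  lines <- c("# pooled-GWAS run report", "",
             "## Configuration", "```yaml",
             strsplit(yaml::as.yaml(config), "\n")[[1]], "```", "")
  gap <- function(stage) c(sprintf("## %s", stage),
                           "*not available for this run*", "")
  if (!is.null(qc)) {
    write_tsv0(qc$scores, file.path(dir, "qc_scores.tsv"))
    write_tsv0(qc$removed_pools, file.path(dir, "qc_removed.tsv"))
    lines <- c(lines, "## Pool QC",
               sprintf("- pools retained: %d", length(qc$retained_pools)),
               sprintf("- pools removed: %d (robust z > %.2f)",
                       nrow(qc$removed_pools), qc$threshold_used),
               if (length(qc$skipped_sets))
                 sprintf("- sets skipped (too few pools): %s",
                         paste(qc$skipped_sets, collapse = ", ")), "")
  } else lines <- c(lines, gap("Pool QC"))
  if (!is.null(scan)) {
    write_scan(scan, file.path(dir, "scan.tsv"))
    export_manhattan(scan, file.path(dir, "manhattan.tsv"))
    tested <- sum(!scan$skipped)
    lines <- c(lines, "## Pooled scan",
               sprintf("- SNP tests: %d (%d skipped)", nrow(scan),
                       sum(scan$skipped)),
               sprintf("- tested SNPs below p = 0.005: %d",
                       sum(scan$p_value < 0.005 & !scan$skipped)),
               sprintf("- minimum p: %.3g over %d tested",
                       suppressWarnings(min(scan$p_value[!scan$skipped])),
                       tested), "")
  } else lines <- c(lines, gap("Pooled scan"))
  if (!is.null(blocks)) {
    write_blocks(blocks, file.path(dir, "blocks.bed"),
                 file.path(dir, "block_members.tsv"))
    lines <- c(lines, "## Blocks",
               sprintf("- qualifying blocks: %d", length(blocks)), "")
  } else lines <- c(lines, gap("Blocks"))
  if (!is.null(candidates)) {
    write_candidates(candidates, file.path(dir, "candidates.tsv"))
    lines <- c(lines, "## Candidates",
               sprintf("- index-SNP candidates (%s): %d",
                       attr(candidates, "disease"), nrow(candidates)),
               sprintf("- rounds: %s",
                       paste(attr(candidates, "rounds"), collapse = ", ")),
               "")
  } else lines <- c(lines, gap("Candidates"))
  if (!is.null(validation)) {
    write_validation(validation, file.path(dir, "validation.tsv"))
    nt <- config$n_tests
    lines <- c(lines, "## Validation",
               if (!is.null(nt))
                 sprintf("- Bonferroni threshold: 0.05/%d = %.4g", nt,
                         bonferroni_threshold(nt)),
               sprintf("- corrected: %d | suggestive: %d | not validated: %d",
                       sum(validation$tier == "corrected"),
                       sum(validation$tier == "suggestive"),
                       sum(validation$tier == "not_validated")), "")
  } else lines <- c(lines, gap("Validation"))
  if (!is.null(shared)) {
    lines <- c(lines, "## Shared loci",
               sprintf("- unique to disease 1: %d | disease 2: %d",
                       shared$counts[["unique_disease1"]],
                       shared$counts[["unique_disease2"]]),
               sprintf("- shared: %d (same direction: %d)",
                       shared$counts[["shared"]],
                       shared$counts[["shared_same_direction"]]), "")
  } else lines <- c(lines, gap("Shared loci"))
  if (!is.null(table2)) {
    lines <- c(lines, "## Validated-loci fixture bookkeeping",
               sprintf("- total SNPs: %d across %d locus labels",
                       table2$total_snps, table2$distinct_loci),
               sprintf("- PBC only: %d | PSC only: %d | shared: %d",
                       table2$pbc_only, table2$psc_only, table2$shared), "")
  }
  path <- file.path(dir, "report.md")
  writeLines(lines[!vapply(lines, is.null, logical(1))], path)
  invisible(path)
}
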