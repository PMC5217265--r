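#' Allelic 2x2 contingency table
#'
#' Counts of minor (`a`, `c`) and major (`b`, `d`) alleles in cases and
#' controls; each genotyped individual contributes two alleles.
#'
#' @param a,b minor/major allele counts in cases.
#' @param c,d minor/major allele counts in controls.
#' @return A list of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(as.list(cells), monomorphic = (a + c == 0) || (b + d == 0),
            class = "contingency_table")
}

#' @export
#' @method print contingency_table
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("minor", "major")))
  print(m)
  invisible(x)
}

#' Build the allelic table for one SNP
#'
#' Minor-allele dosages are summed over genotyped individuals of each group;
#' missing genotypes (`NA`) are excluded from both margins.
#'
#' @param genotypes a `genotype_table`.
#' @param snp_id the marker.
#' @param case_group,control_group group labels.
#' @return A [contingency_table()].
#' @export
allele_table <- function(genotypes, snp_id, case_group, control_group) {
  if (!snp_id %in% colnames(genotypes$genotypes))
    stop("unknown snp_id: ", snp_id)
  g <- genotypes$genotypes[, snp_id]
  grp <- genotypes$individuals$group
  count <- function(label) {
    d <- g[grp == label]
    d <- d[!is.na(d)]
    if (!length(d))
      stop("all genotypes missing in group ", label, " at ", snp_id)
    c(minor = sum(d), total = 2L * length(d))
  }
  ca <- count(case_group); co <- count(control_group)
  contingency_table(ca["minor"], ca["total"] - ca["minor"],
                    co["minor"], co["total"] - co["minor"])
}

#' Two-sided Fisher exact test of an allelic table
#'
#' Two-sided p-value by the point-probability method (the sum of
#' hypergeometric probabilities no larger than that of the observed table),
#' i.e. the convention of R's `fisher.test`, which this wraps. Degenerate
#' margins (an empty row or column) give `p = 1`.
#'
#' @param table a [contingency_table()] (or vector `c(a, b, c, d)`).
#' @return The two-sided p-value.
#' @export
fisher_exact_test <- function(table) {
  x <- as_cells(table)
  if ((x[1] + x[2]) == 0 || (x[3] + x[4]) == 0 ||
      (x[1] + x[3]) == 0 || (x[2] + x[4]) == 0) return(1)
  stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
}

as_cells <- function(table) {
  if (inherits(table, "contingency_table"))
    c(table$a, table$b, table$c, table$d)
  else as.numeric(table)
}

#' Allelic odds ratio with Woolf (normal-approximation) confidence interval
#'
#' `OR = (a d) / (b c)`, with the Wald/Woolf interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied to the OR and
#' CI only — never to the Fisher p-value. Tables with an empty row or column
#' have no estimable OR and are returned flagged with `NA`s.
#'
#' @param table a [contingency_table()] or vector `c(a, b, c, d)`.
#' @param level confidence level (default 0.95).
#' @return List with `or_point`, `ci_low`, `ci_high`, `corrected` (logical,
#'   Haldane applied), `undefined` (logical).
#' @export
odds_ratio_ci <- function(table, level = 0.95) {
  x <- as_cells(table)
  if ((x[1] + x[2]) == 0 || (x[3] + x[4]) == 0 ||
      (x[1] + x[3]) == 0 || (x[2] + x[4]) == 0)
    return(list(or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                corrected = FALSE, undefined = TRUE))
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  or <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or_point = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       corrected = corrected, undefined = FALSE)
}

#' Per-test Bonferroni significance threshold
#'
#' @param n_tests number of validated candidates.
#' @param alpha family-wise level (default 0.05).
#' @return `alpha / n_tests` (e.g. 0.05/22 ~ 0.0023).
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Expected false positives among independent tests
#'
#' @param n_tests number of independent tests.
#' @param alpha per-test significance level.
#' @return `n_tests * alpha`.
#' @export
expected_false_positives <- function(n_tests, alpha = 0.05) n_tests * alpha

#' Two-tier significance classification of a validated candidate
#'
#' `"corrected"` if `p < alpha / n_tests` (Bonferroni); otherwise
#' `"suggestive"` if `p < alpha` with an odds ratio of at least 1.2 (risk) or
#' at most 0.83 (protective); otherwise `"not_validated"`. The OR bound is
#' inclusive by default because a published OR of exactly 0.83 counted as
#' validated; `strict_or = TRUE` uses strict inequalities.
#'
#' @param fisher_p validation p-value(s).
#' @param or_point odds ratio(s).
#' @param n_tests number of candidates validated for the disease (passed
#'   explicitly, never inferred from a filtered list).
#' @param alpha nominal level (default 0.05).
#' @param strict_or use `> 1.2` / `< 0.83` instead of `>=` / `<=`.
#' @return Character vector of tiers.
#' @export
classify_validation <- function(fisher_p, or_point, n_tests, alpha = 0.05,
                                strict_or = FALSE) {
  stopifnot(n_tests >= 1)
  thr <- bonferroni_threshold(n_tests, alpha)
  big_or <- if (strict_or) or_point > 1.2 | or_point < 0.83
            else or_point >= 1.2 | or_point <= 0.83
  big_or[is.na(big_or)] <- FALSE
  ifelse(fisher_p < thr, "corrected",
         ifelse(fisher_p < alpha & big_or, "suggestive", "not_validated"))
}

#' Direction-of-effect concordance between scan and validation
#'
#' `TRUE` when the pooled-scan frequency shift (sign of case minus control
#' mean RAS) and the validation odds ratio point the same way, after
#' harmonising allele orientation between platforms. A zero effect on either
#' side, or missing orientation metadata, yields `NA` (unknown) — orientation
#' is never silently assumed.
#'
#' @param scan_direction -1, 0 or +1 from the pooled scan.
#' @param or_point validation odds ratio (per the assay's minor allele).
#' @param orientation `"same"` if the scan's RAS allele is the assay's minor
#'   allele, `"flipped"` if it is the other allele, `NA` if unknown.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
direction_concordance <- function(scan_direction, or_point,
                                  orientation = "same") {
  n <- max(length(scan_direction), length(or_point), length(orientation))
  scan_direction <- rep_len(scan_direction, n)
  or_point <- rep_len(or_point, n)
  orientation <- rep_len(orientation, n)
  flip <- ifelse(orientation == "same", 1,
                 ifelse(orientation == "flipped", -1, NA))
  eff <- sign(log(or_point)) * flip
  out <- scan_direction * eff
  ifelse(is.na(out) | scan_direction == 0 | or_point == 1, NA, out > 0)
}

#' Validate a candidate set by individual genotyping
#'
#' For each candidate SNP, builds the allelic 2x2 table, runs the Fisher
#' exact test, estimates the Woolf OR/CI, classifies the two-tier
#' significance, and (when a scan is supplied) checks direction-of-effect
#' concordance. The minor allele is defined in controls: if the dosage-counted
#' allele exceeds 50% control frequency the table is flipped so the reported
#' OR and MAF refer to the control-minor allele, and the orientation handed to
#' the concordance check is flipped accordingly.
#'
#' @param genotypes a `genotype_table`.
#' @param candidates a `candidate_set` or character vector of SNP ids.
#' @param case_group,control_group group labels.
#' @param n_tests number of candidates tested for this disease (explicit).
#' @param scan optional `scan_result` for direction concordance.
#' @param orientation orientation of the scan's RAS allele relative to the
#'   dosage-counted allele: `"same"` (default for data simulated on one
#'   platform), `"flipped"`, or `NA` if unknown.
#' @param level CI level.
#' @param strict_or see [classify_validation()].
#' @return A `validation_result` data.frame: `snp_id`, `disease`, cell
#'   counts, `fisher_p`, `or_point`, `ci_low`, `ci_high`, `maf_controls`,
#'   `tier`, `direction_concordant`, `validated`.
#' @export
validate_candidates <- function(genotypes, candidates, case_group,
                                control_group, n_tests,
                                scan = NULL, orientation = "same",
                                level = 0.95, strict_or = FALSE) {
  snps <- if (is.data.frame(candidates)) candidates$snp_id
          else as.character(candidates)
  disease <- if (!is.null(attr(candidates, "disease")))
    attr(candidates, "disease") else case_group
  rows <- lapply(snps, function(s) {
    tab <- allele_table(genotypes, s, case_group, control_group)
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
    ornt <- orientation
    if (c / (c + d) > 0.5) {    # counted allele is major in controls: flip
      tmp <- a; a <- b; b <- tmp
      tmp <- c; c <- d; d <- tmp
      ornt <- if (is.na(ornt)) NA_character_
              else if (ornt == "same") "flipped" else "same"
    }
    tab <- contingency_table(a, b, c, d)
    orci <- odds_ratio_ci(tab, level = level)
    data.frame(snp_id = s, disease = disease, a = a, b = b, c = c, d = d,
               fisher_p = fisher_exact_test(tab),
               or_point = orci$or_point, ci_low = orci$ci_low,
               ci_high = orci$ci_high,
               maf_controls = c / (c + d),
               or_flipped_to_minor = !identical(ornt, orientation),
               orientation = as.character(ornt),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$tier <- classify_validation(res$fisher_p, res$or_point, n_tests,
                                  strict_or = strict_or)
  if (!is.null(scan)) {
    # direction from the best (smallest-p) scan row per SNP
    sc <- scan[order(scan$p_value), ]
    sc <- sc[!duplicated(sc$snp_id), ]
    dir <- sc$direction[match(res$snp_id, sc$snp_id)]
    res$direction_concordant <- direction_concordance(dir, res$or_point,
                                                      res$orientation)
  } else {
    res$direction_concordant <- NA
  }
  res$validated <- res$tier %in% c("corrected", "suggestive") &
    (is.na(res$direction_concordant) | res$direction_concordant)
  res$validated[res$tier %in% c("corrected", "suggestive") &
                  is.na(res$direction_concordant)] <- NA
  class(res) <- c("validation_result", "data.frame")
  res
}

#' Cross-disease shared-locus accounting
#'
#' A SNP counts for a disease when its tier is `corrected` or `suggestive`.
#' SNPs counting for both diseases are `shared`; among those,
#' `shared_same_direction` holds the SNPs whose ORs fall on the same side
#' of 1 in both diseases.
#'
#' @param recs1,recs2 `validation_result`s for the two diseases.
#' @return A `shared_loci_summary`: list of SNP-id sets `unique_disease1`,
#'   `unique_disease2`, `shared`, `shared_same_direction`, plus `counts`.
#' @export
shared_loci <- function(recs1, recs2) {
  hit <- function(r) r$snp_id[r$tier %in% c("corrected", "suggestive")]
  s1 <- hit(recs1); s2 <- hit(recs2)
  shared <- intersect(s1, s2)
  same <- shared[vapply(shared, function(s) {
    o1 <- recs1$or_point[match(s, recs1$snp_id)]
    o2 <- recs2$or_point[match(s, recs2$snp_id)]
    !is.na(o1) && !is.na(o2) && sign(log(o1)) == sign(log(o2)) &&
      o1 != 1 && o2 != 1
  }, logical(1))]
  structure(list(unique_disease1 = setdiff(s1, shared),
                 unique_disease2 = setdiff(s2, shared),
                 shared = shared,
                 shared_same_direction = same,
                 counts = c(unique_disease1 = length(setdiff(s1, shared)),
                            unique_disease2 = length(setdiff(s2, shared)),
                            shared = length(shared),
                            shared_same_direction = length(same))),
            class = "shared_loci_summary")
}

#' @export
#' @method print shared_loci_summary
print.shared_loci_summary <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Status of a known-association replication panel
#'
#' Pure reporting over validation records: for every SNP of an externally
#' defined panel (e.g. markers previously associated with related immune
#' diseases), report its association status per disease.
#'
#' @param recs a `validation_result` (possibly several diseases rbound).
#' @param panel character vector of panel SNP ids.
#' @return data.frame `snp_id`, `disease`, `status` (`tier` or
#'   `"not tested"`).
#' @export
summarize_known_panel <- function(recs, panel) {
  if (!length(panel))
    return(data.frame(snp_id = character(), disease = character(),
                      status = character(), stringsAsFactors = FALSE))
  diseases <- unique(recs$disease)
  if (!length(diseases)) diseases <- NA_character_
  out <- expand.grid(snp_id = panel, disease = diseases,
                     stringsAsFactors = FALSE)
  out$status <- vapply(seq_len(nrow(out)), function(i) {
    hit <- recs$snp_id == out$snp_id[i] & recs$disease == out$disease[i]
    if (any(hit)) recs$tier[which(hit)[1L]] else "not tested"
  }, character(1))
  out
}
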