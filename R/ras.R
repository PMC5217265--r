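#' Relative allele signal from two-channel intensities
#'
#' RAS is the per-SNP channel ratio `A / (A + B)`, an estimate of the pooled
#' minor-allele frequency. Entries with zero total signal are set to `NA`
#' (missing) and excluded from downstream tests; per-SNP missing counts are
#' kept in the `missing_by_snp` attribute.
#'
#' @param intensities an `intensity_table`.
#' @return A `ras_matrix`: list with `pools`, `values` (pools x SNPs in
#'   `[0, 1]`, `NA` = missing) and `snp_index` (the panel, when known).
#' @export
compute_ras <- function(intensities) {
  a <- intensities$channel_a
  b <- intensities$channel_b
  if (!identical(dim(a), dim(b)))
    stop("channel matrices have different shapes")
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("channel intensities must be non-negative")
  tot <- a + b
  ras <- a / tot
  ras[tot == 0] <- NA_real_
  structure(list(pools = intensities$pools,
                 values = ras,
                 snp_index = intensities$panel),
            missing_by_snp = colSums(is.na(ras)),
            class = "ras_matrix")
}

#' @export
#' @method print ras_matrix
print.ras_matrix <- function(x, ...) {
  cat(sprintf("ras_matrix: %d pools x %d SNPs, %d missing entries\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Principal-component quality control of pools
#'
#' Pooled arrays lack per-sample call rates, so outlying pools are flagged
#' from the leading principal components of the pool x SNP RAS matrix
#' (SNP-wise centred), separately per pool set. Each pool's Euclidean
#' distance from the coordinate-wise median in the first `n_components` PC
#' coordinates is converted to a robust z-score (centred on the median
#' distance, scaled by its MAD); pools with z above `threshold` are removed.
#' This is a reproducible surrogate for visual inspection of the first PCs,
#' with the scores retained for audit.
#'
#' Sets with fewer than `n_components + 1` pools are skipped with a recorded
#' warning. `NA` RAS entries are mean-imputed for the PCA only.
#'
#' @param ras a `ras_matrix`.
#' @param n_components PCs to use (default 4).
#' @param threshold robust z-score removal threshold (default 3.5).
#' @param restrict_to_groups if non-NULL, only pools in these groups may be
#'   removed (e.g. a controls-only policy).
#' @return A `qc_report`: list with `retained_pools`, `removed_pools`
#'   (data.frame `pool_id`, `reason`, `score`), `pc_coordinates`,
#'   `threshold_used`, `skipped_sets`.
#' @export
qc_pools <- function(ras, n_components = 4L, threshold = 3.5,
                     restrict_to_groups = NULL) {
  stopifnot(inherits(ras, "ras_matrix"))
  if (nrow(ras$values) < 3L) stop("QC needs at least 3 pools")
  pools <- ras$pools
  removed <- list()
  scores_all <- list()
  skipped <- character()
  zvec <- rep(NA_real_, nrow(pools))
  for (s in unique(pools$set_id)) {
    sel <- which(pools$set_id == s)
    if (length(sel) < n_components + 1L) {
      warning("set ", s, ": too few pools for ", n_components,
              "-component QC; skipped")
      skipped <- c(skipped, s)
      next
    }
    x <- ras$values[sel, , drop = FALSE]
    if (anyNA(x)) {
      mu <- colMeans(x, na.rm = TRUE)
      nafix <- which(is.na(x), arr.ind = TRUE)
      x[nafix] <- mu[nafix[, 2L]]
      x[is.na(x)] <- 0.5  # SNPs missing in every pool of the set
    }
    keep_col <- apply(x, 2L, stats::var) > 0
    k <- min(n_components, length(sel) - 1L, sum(keep_col))
    pc <- stats::prcomp(x[, keep_col, drop = FALSE],
                        center = TRUE, scale. = FALSE, rank. = k)
    sc <- pc$x[, seq_len(k), drop = FALSE]
    med <- apply(sc, 2L, stats::median)
    d <- sqrt(rowSums(sweep(sc, 2L, med)^2))
    s_mad <- stats::mad(d)
    z <- if (s_mad > 0) (d - stats::median(d)) / s_mad else rep(0, length(d))
    zvec[sel] <- z
    scores_all[[s]] <- cbind(pool_id = pools$pool_id[sel],
                             as.data.frame(sc))
    out <- z > threshold
    if (!is.null(restrict_to_groups))
      out <- out & pools$group[sel] %in% restrict_to_groups
    if (any(out))
      removed[[s]] <- data.frame(
        pool_id = pools$pool_id[sel][out],
        reason = sprintf("robust PC distance z > %.2f (set %s)", threshold, s),
        score = z[out],
        stringsAsFactors = FALSE)
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(pool_id = character(), reason = character(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  structure(list(retained_pools = setdiff(pools$pool_id, removed$pool_id),
                 removed_pools = removed,
                 pc_coordinates = scores_all,
                 scores = data.frame(pool_id = pools$pool_id,
                                     set_id = pools$set_id,
                                     group = pools$group,
                                     robust_z = zvec,
                                     stringsAsFactors = FALSE),
                 threshold_used = threshold,
                 skipped_sets = skipped),
            class = "qc_report")
}

#' Drop QC-removed pools from a RAS matrix
#'
#' @param ras a `ras_matrix`.
#' @param qc a `qc_report` from [qc_pools()].
#' @return The filtered `ras_matrix`.
#' @export
apply_qc <- function(ras, qc) {
  keep <- ras$pools$pool_id %in% qc$retained_pools
  ras$pools <- ras$pools[keep, , drop = FALSE]
  ras$values <- ras$values[keep, , drop = FALSE]
  ras
}

#' Per-SNP Welch t-test scan of pooled allele frequencies
#'
#' Two-sided Welch t-test comparing RAS between case and control pools,
#' run independently within each pool set (each hybridisation round is its
#' own scan). Every SNP appears in the output: SNPs with fewer than two
#' usable pools in a group, or zero variance in both groups, get `p = 1`
#' and `skipped = TRUE` rather than being dropped.
#'
#' @param ras a `ras_matrix` (typically after [apply_qc()]).
#' @param case_group,control_group group labels to compare.
#' @return A `scan_result` data.frame with one row per SNP per set:
#'   `snp_id`, `chrom`, `pos`, `set_id`, `mean_ras_case`, `mean_ras_control`,
#'   `t_stat`, `df` (Welch-Satterthwaite), `p_value`, `direction`
#'   (sign of case minus control mean), pool counts and `skipped`.
#'   `p_bonferroni` is added by [bonferroni_adjust()].
#' @export
welch_scan <- function(ras, case_group, control_group) {
  stopifnot(inherits(ras, "ras_matrix"))
  groups <- unique(ras$pools$group)
  for (g in c(case_group, control_group))
    if (!g %in% groups) stop("unknown group label: ", g)
  out <- list()
  for (s in unique(ras$pools$set_id)) {
    x <- ras$values[ras$pools$set_id == s & ras$pools$group == case_group, ,
                    drop = FALSE]
    y <- ras$values[ras$pools$set_id == s & ras$pools$group == control_group, ,
                    drop = FALSE]
    st <- welch_columns(x, y)
    snp <- if (!is.null(ras$snp_index)) ras$snp_index else
      data.frame(snp_id = colnames(ras$values),
                 chrom = NA_character_, pos = NA_integer_)
    out[[s]] <- data.frame(snp_id = snp$snp_id, chrom = snp$chrom,
                           pos = snp$pos, set_id = s,
                           mean_ras_case = st$m1, mean_ras_control = st$m2,
                           t_stat = st$t, df = st$df, p_value = st$p,
                           direction = st$direction,
                           n_case_pools = st$n1, n_control_pools = st$n2,
                           skipped = st$skipped,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("scan_result", "data.frame")
  res
}

# Vectorised two-sample Welch statistics over matrix columns (NAs excluded).
welch_columns <- function(x, y) {
  n1 <- colSums(!is.na(x)); n2 <- colSums(!is.na(y))
  m1 <- suppressWarnings(colMeans(x, na.rm = TRUE))
  m2 <- suppressWarnings(colMeans(y, na.rm = TRUE))
  v1 <- colSums(sweep(x, 2L, m1)^2, na.rm = TRUE) / pmax(n1 - 1L, 1L)
  v2 <- colSums(sweep(y, 2L, m2)^2, na.rm = TRUE) / pmax(n2 - 1L, 1L)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  skipped <- n1 < 2L | n2 < 2L | (v1 == 0 & v2 == 0)
  t[se2 == 0 & m1 == m2] <- 0
  p[skipped] <- 1
  list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, t = t, df = df, p = p,
       direction = sign(m1 - m2), skipped = skipped)
}

#' Bonferroni correction of a scan
#'
#' Adds `p_bonferroni = min(1, m * p)` where `m` counts the SNPs actually
#' tested (skip-flagged SNPs excluded from `m`), separately within each
#' `set_id` scan. The raw p-value is retained.
#'
#' @param results a `scan_result`.
#' @return The `scan_result` with a `p_bonferroni` column.
#' @export
bonferroni_adjust <- function(results) {
  stopifnot(is.data.frame(results), all(c("p_value", "skipped") %in%
                                          names(results)))
  set <- if ("set_id" %in% names(results)) results$set_id else "all"
  m <- stats::ave(!results$skipped, set, FUN = sum)
  results$p_bonferroni <- pmin(1, m * results$p_value)
  results
}

#' Export a Manhattan-plot table
#'
#' Writes (or returns) the scan as a genome-ordered table of `chrom`, `pos`,
#' `snp_id`, `p_value` and `-log10(p)`, ready for qqman-style plotting.
#'
#' @param results a `scan_result` (or anything with those columns).
#' @param path optional TSV output path.
#' @return The table, invisibly when `path` is given.
#' @export
export_manhattan <- function(results, path = NULL) {
  df <- data.frame(chrom = results$chrom, pos = results$pos,
                   snp_id = results$snp_id, p_value = results$p_value,
                   neg_log10_p = -log10(results$p_value),
                   stringsAsFactors = FALSE)
  df <- df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write_tsv0(df, path)
    return(invisible(df))
  }
  df
}

# numeric-aware chromosome ordering ("1" < "2" < "10" < "X")
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(is.na(num), Inf, num)
  order_alpha <- as.numeric(factor(chrom))
  r + order_alpha * 1e-9
}
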