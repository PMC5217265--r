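#' Simulate a case/control cohort with LD structure and seeded risk loci
#'
#' Genotypes are generated from a block-copy haplotype model: SNPs are grouped
#' into consecutive blocks of `ld_block_length`; each haplotype draws one
#' latent uniform per block, and every member SNP either thresholds that
#' shared uniform at its own MAF (probability `ld_r`, the "copy") or draws an
#' independent Bernoulli at its MAF. Control marginals therefore equal the
#' panel MAFs exactly in expectation while within-block alleles are
#' correlated.
#'
#' At each seeded risk locus the case haplotypes tilt the block's latent
#' uniform so that the locus reaches the case frequency implied by the
#' multiplicative allelic odds model, `p' = OR p / (1 - p + OR p)`; SNPs in LD
#' with the locus inherit an `ld_r`-scaled frequency shift through the shared
#' uniform.
#'
#' The global RNG seed is set from `spec$seed`, so identical specs give
#' byte-identical output.
#'
#' @param spec a [sim_spec()].
#' @return A `genotype_table`: list with `individuals` (data.frame `id`,
#'   `group`), `genotypes` (individuals x SNPs integer matrix of minor-allele
#'   dosages 0/1/2) and the `panel`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  panel <- spec$panel
  m <- nrow(panel)
  bidx <- block_index(panel, spec$ld_block_length)
  nb <- max(bidx)

  eff <- spec$effects
  # one tilt per block at most: first declared locus wins
  tilt <- NULL
  if (!is.null(eff) && nrow(eff)) {
    loc <- match(eff$snp_id, panel$snp_id)
    tilt <- data.frame(block = bidx[loc], col = loc,
                       p = panel$maf[loc],
                       p_case = case_maf(panel$maf[loc], eff$odds_ratio))
    tilt <- tilt[!duplicated(tilt$block), , drop = FALSE]
  }

  draw_group <- function(n, tilted) {
    n_hap <- 2L * n
    u <- matrix(stats::runif(n_hap * nb), n_hap, nb)
    forced <- NULL
    if (tilted && !is.null(tilt)) {
      for (k in seq_len(nrow(tilt))) {
        p_l <- tilt$p[k]
        a <- stats::runif(n_hap) < tilt$p_case[k]
        u[, tilt$block[k]] <- ifelse(a, stats::runif(n_hap) * p_l,
                                     p_l + stats::runif(n_hap) * (1 - p_l))
      }
      forced <- tilt$col
    }
    mafm <- matrix(panel$maf, n_hap, m, byrow = TRUE)
    tag <- u[, bidx, drop = FALSE] < mafm
    cop <- matrix(stats::runif(n_hap * m) < spec$ld_r, n_hap, m)
    if (!is.null(forced)) cop[, forced] <- TRUE   # locus itself always tracks
    ind <- matrix(stats::runif(n_hap * m), n_hap, m) < mafm
    hap <- (cop & tag) | (!cop & ind)
    odd <- seq(1L, n_hap, by = 2L)
    matrix(as.integer(hap[odd, , drop = FALSE]) +
             as.integer(hap[odd + 1L, , drop = FALSE]),
           n, m)
  }

  g_case <- draw_group(spec$n_cases, tilted = TRUE)
  g_ctrl <- draw_group(spec$n_controls, tilted = FALSE)
  geno <- rbind(g_case, g_ctrl)
  ids <- c(sprintf("%s_%05d", spec$case_label, seq_len(spec$n_cases)),
           sprintf("%s_%05d", spec$control_label, seq_len(spec$n_controls)))
  dimnames(geno) <- list(ids, panel$snp_id)
  structure(list(individuals = data.frame(
                   id = ids,
                   group = c(rep(spec$case_label, spec$n_cases),
                             rep(spec$control_label, spec$n_controls)),
                   stringsAsFactors = FALSE),
                 genotypes = geno,
                 panel = panel),
            class = "genotype_table")
}

#' @export
#' @method print genotype_table
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals (%s) x %d SNPs\n",
              nrow(x$genotypes),
              paste(sprintf("%d %s", table(x$individuals$group),
                            names(table(x$individuals$group))),
                    collapse = ", "),
              ncol(x$genotypes)))
  invisible(x)
}

#' Assign individuals to DNA pools
#'
#' Within each pool set, each group's individuals are shuffled (seeded from
#' `spec$seed + 1`) and packed into pools in order; individuals that do not
#' fill a complete pool are left out of that set. Pools are homogeneous in
#' group label and disjoint within a set; the same individual may recur in
#' pools of different sets, as when the same patients are re-pooled for a
#' second hybridisation.
#'
#' @param table a `genotype_table`.
#' @param spec the [sim_spec()] whose `pool_sets` describe the design.
#' @return A `pool_membership` data.frame with columns `set_id`, `pool_id`,
#'   `group`, `individual_id`.
#' @export
assign_pools <- function(table, spec) {
  stopifnot(inherits(table, "genotype_table"), inherits(spec, "sim_spec"))
  if (!length(spec$pool_sets)) stop("spec contains no pool sets")
  set.seed(spec$seed + 1L)
  out <- list()
  for (ps in spec$pool_sets) {
    for (g in names(ps$pools_per_group)) {
      ids <- table$individuals$id[table$individuals$group == g]
      size <- pool_size_for(ps, g)
      n_pools <- ps$pools_per_group[[g]]
      need <- size * n_pools
      if (length(ids) < need)
        stop(sprintf(
          "group %s has %d individuals but set %s needs %d (%d pools of %d)",
          g, length(ids), ps$set_id, need, n_pools, size))
      ids <- ids[sample.int(length(ids))][seq_len(need)]
      out[[length(out) + 1L]] <- data.frame(
        set_id = ps$set_id,
        pool_id = sprintf("%s_%s_p%02d", ps$set_id, g,
                          rep(seq_len(n_pools), each = size)),
        group = g,
        individual_id = ids,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("pool_membership", "data.frame")
  res
}

#' Simulate two-channel pooled array intensities
#'
#' For every pool and SNP the true pooled minor-allele fraction
#' `f = sum(dosages) / (2 * pool_size)` is perturbed with additive Gaussian
#' noise (SD `spec$noise_sd`) clipped to `[0, 1]`, then split over two
#' channels: `A = f_noisy * total_signal`, `B = (1 - f_noisy) * total_signal`.
#' The RNG is seeded from `spec$seed + 2`.
#'
#' A systematic batch artefact can be planted for QC testing: pools named in
#' `batch_shift_pools` get `batch_shift` added to their noisy fraction on a
#' seeded random subset (`batch_shift_frac`) of SNPs, the same subset for all
#' shifted pools.
#'
#' @param table a `genotype_table`.
#' @param membership a `pool_membership` from [assign_pools()].
#' @param spec the governing [sim_spec()].
#' @param total_signal positive per-entry total channel signal.
#' @param batch_shift,batch_shift_pools,batch_shift_frac optional planted
#'   batch artefact (see above).
#' @return An `intensity_table`: list with `pools` (data.frame `pool_id`,
#'   `group`, `set_id`), matrices `channel_a`, `channel_b`, and the `panel`.
#' @export
simulate_intensities <- function(table, membership, spec, total_signal = 1,
                                 batch_shift = 0, batch_shift_pools = NULL,
                                 batch_shift_frac = 0.2) {
  stopifnot(inherits(table, "genotype_table"),
            inherits(membership, "data.frame"), total_signal > 0)
  if (!all(membership$individual_id %in% table$individuals$id))
    stop("membership references individuals absent from the genotype table")
  set.seed(spec$seed + 2L)
  key <- paste(membership$set_id, membership$pool_id, sep = "\r")
  upool <- !duplicated(key)
  pools <- data.frame(pool_id = membership$pool_id[upool],
                      group = membership$group[upool],
                      set_id = membership$set_id[upool],
                      stringsAsFactors = FALSE)
  rows <- match(membership$individual_id, table$individuals$id)
  fac <- match(key, key[upool])
  sums <- rowsum(table$genotypes[rows, , drop = FALSE], group = fac,
                 reorder = FALSE)
  sizes <- tabulate(fac, nbins = nrow(pools))
  f <- sums / (2 * sizes)
  if (spec$noise_sd > 0)
    f <- f + matrix(stats::rnorm(length(f), 0, spec$noise_sd),
                    nrow(f), ncol(f))
  if (batch_shift != 0 && length(batch_shift_pools)) {
    hit <- which(pools$pool_id %in% batch_shift_pools)
    cols <- sample.int(ncol(f), size = max(1L, round(batch_shift_frac * ncol(f))))
    f[hit, cols] <- f[hit, cols] + batch_shift
  }
  f <- pmin(pmax(f, 0), 1)
  dimnames(f) <- list(pools$pool_id, table$panel$snp_id)
  structure(list(pools = pools,
                 channel_a = f * total_signal,
                 channel_b = (1 - f) * total_signal,
                 panel = table$panel),
            class = "intensity_table")
}

#' @export
#' @method print intensity_table
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d pools x %d SNPs (sets: %s)\n",
              nrow(x$channel_a), ncol(x$channel_a),
              paste(unique(x$pools$set_id), collapse = ", ")))
  invisible(x)
}
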