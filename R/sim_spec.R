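#' Define a SNP panel
#'
#' A SNP panel is the ordered set of markers a study interrogates. Rows must
#' be sorted by `(chrom, pos)`; `allele_a` is the reference (major) allele and
#' `allele_b` the minor allele whose dosage is counted throughout the package.
#' `maf` is the population minor-allele frequency used by the simulator.
#'
#' @param snp_id character, unique marker names.
#' @param chrom character, chromosome labels.
#' @param pos integer, 1-based base-pair positions, strictly increasing within
#'   a chromosome.
#' @param allele_a,allele_b allele labels, unequal per SNP.
#' @param maf minor-allele frequencies in `[0, 0.5]`.
#' @return A `data.frame` of class `snp_panel`.
#' @seealso [random_panel()] for a quick synthetic panel.
#' @export
snp_panel <- function(snp_id, chrom, pos, allele_a = "A", allele_b = "B",
                      maf = 0.2) {
  df <- data.frame(snp_id = as.character(snp_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   allele_a = rep_len(as.character(allele_a), length(snp_id)),
                   allele_b = rep_len(as.character(allele_b), length(snp_id)),
                   maf = rep_len(as.numeric(maf), length(snp_id)),
                   stringsAsFactors = FALSE)
  validate_snp_panel(df)
}

validate_snp_panel <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("snp_id", "chrom", "pos", "allele_a", "allele_b", "maf")
                %in% names(df)))
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$allele_a <- as.character(df$allele_a)
  df$allele_b <- as.character(df$allele_b)
  df$maf <- as.numeric(df$maf)
  if (anyDuplicated(df$snp_id))
    stop("snp_id values must be unique within a panel")
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  if (any(df$maf < 0 | df$maf > 0.5))
    stop("maf must lie in [0, 0.5]")
  if (any(df$allele_a == df$allele_b))
    stop("allele_a and allele_b must differ")
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Generate a synthetic SNP panel
#'
#' Evenly spaced markers with minor-allele frequencies drawn uniformly from
#' `maf_range`. Handy for simulations and tests.
#'
#' @param n_snps number of SNPs.
#' @param chrom chromosome label(s); SNPs are split evenly across them.
#' @param spacing_bp distance between adjacent SNPs in bp (default 5000).
#' @param maf_range range the per-SNP MAF is drawn from.
#' @param seed integer seed for the MAF draw.
#' @return A [snp_panel()].
#' @export
random_panel <- function(n_snps, chrom = "1", spacing_bp = 5000L,
                         maf_range = c(0.05, 0.5), seed = 1L) {
  set.seed(seed)
  chrom <- as.character(chrom)
  per <- rep(n_snps %/% length(chrom), length(chrom))
  per[seq_len(n_snps %% length(chrom))] <- per[seq_len(n_snps %% length(chrom))] + 1L
  chr <- rep(chrom, per)
  pos <- unlist(lapply(per, function(k) seq_len(k) * as.integer(spacing_bp)),
                use.names = FALSE)
  snp_panel(snp_id = sprintf("snp%06d", seq_len(n_snps)),
            chrom = chr, pos = pos,
            maf = stats::runif(n_snps, maf_range[1], maf_range[2]))
}

#' Describe one set of DNA pools
#'
#' A pool set mirrors one hybridisation round: every group contributes
#' `pools_per_group[[g]]` pools of `pool_size` individuals each (pool size may
#' also be a named vector giving one size per group, as when cases and
#' controls were pooled at different depths).
#'
#' @param set_id label of the set (e.g. `"I"`, `"II"`).
#' @param pool_size individuals per pool; scalar or named by group.
#' @param pools_per_group named integer vector, group label -> pool count.
#' @return A list of class `pool_set_spec`.
#' @export
pool_set <- function(set_id, pool_size, pools_per_group) {
  stopifnot(length(set_id) == 1L, is.numeric(pool_size),
            !is.null(names(pools_per_group)))
  if (any(pool_size < 2)) stop("pool_size must be >= 2")
  if (!is.null(names(pool_size)) &&
      !all(names(pools_per_group) %in% names(pool_size)))
    stop("named pool_size must cover every pooled group")
  structure(list(set_id = as.character(set_id),
                 pool_size = as.integer(pool_size),
                 pools_per_group = as.integer(pools_per_group) |>
                   stats::setNames(names(pools_per_group))),
            names = c("set_id", "pool_size", "pools_per_group"),
            class = "pool_set_spec")
}

pool_size_for <- function(ps, group) {
  sz <- ps$pool_size
  if (is.null(names(sz))) sz[1L] else sz[[group]]
}

#' Declare seeded risk loci
#'
#' Each locus shifts the case minor-allele frequency according to a
#' multiplicative allelic odds model: with control MAF `p` and odds ratio
#' `OR`, the case MAF is `p' = OR * p / (1 - p + OR * p)`. Odds ratios are per
#' minor allele, as in validation reporting.
#'
#' @param snp_id marker names (must exist in the panel).
#' @param odds_ratio positive allelic odds ratios.
#' @param disease group label the effect applies to.
#' @return A `data.frame` of class `effect_loci`.
#' @export
effect_loci <- function(snp_id, odds_ratio, disease = "CASE") {
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0")
  df <- data.frame(snp_id = as.character(snp_id),
                   odds_ratio = as.numeric(odds_ratio),
                   disease = rep_len(as.character(disease), length(snp_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("effect_loci", "data.frame")
  df
}

#' Case minor-allele frequency under a multiplicative allelic odds model
#'
#' @param p control minor-allele frequency.
#' @param or allelic odds ratio per minor allele.
#' @return The implied case minor-allele frequency
#'   `OR * p / (1 - p + OR * p)`.
#' @export
case_maf <- function(p, or) or * p / (1 - p + or * p)

#' Full description of a synthetic pooled-GWAS study
#'
#' Bundles cohort sizes, the SNP panel, LD structure, seeded risk loci, the
#' pooling design, array noise and the master seed. The seed fully determines
#' every downstream output ([simulate_cohort()], [assign_pools()],
#' [simulate_intensities()]).
#'
#' @param n_cases,n_controls cohort sizes (>= 1).
#' @param panel a [snp_panel()].
#' @param ld_block_length SNPs per LD block (1 = independent SNPs).
#' @param ld_r within-block copy probability in `[0, 1)`; see the methods
#'   vignette for the implied allelic correlation.
#' @param effects an [effect_loci()] table, or `NULL` for a null study.
#' @param pool_sets list of [pool_set()] specs.
#' @param noise_sd SD of additive array noise on pooled allele fractions.
#' @param seed integer master seed (< 2^31 - 3).
#' @param case_label,control_label group labels.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_cases, n_controls, panel,
                     ld_block_length = 1L, ld_r = 0,
                     effects = NULL, pool_sets = list(),
                     noise_sd = 0.02, seed = 1L,
                     case_label = "CASE", control_label = "CTRL") {
  panel <- validate_snp_panel(panel)
  stopifnot(n_cases >= 1, n_controls >= 1, noise_sd >= 0,
            ld_block_length >= 1, ld_r >= 0, ld_r < 1)
  seed <- as.integer(seed)
  if (is.na(seed) || seed > .Machine$integer.max - 3L)
    stop("seed must be an integer below 2^31 - 3")
  if (!is.null(effects)) {
    unknown <- setdiff(effects$snp_id, panel$snp_id)
    if (length(unknown))
      stop("effect locus references unknown snp_id: ",
           paste(unknown, collapse = ", "))
    bad <- setdiff(effects$disease, case_label)
    if (length(bad))
      stop("effect loci declared for unknown group: ",
           paste(bad, collapse = ", "))
  }
  for (ps in pool_sets) {
    stopifnot(inherits(ps, "pool_set_spec"))
    bad <- setdiff(names(ps$pools_per_group), c(case_label, control_label))
    if (length(bad))
      stop("pool set ", ps$set_id, " pools unknown group: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 panel = panel,
                 ld_block_length = as.integer(ld_block_length),
                 ld_r = ld_r,
                 effects = effects,
                 pool_sets = pool_sets,
                 noise_sd = noise_sd,
                 seed = seed,
                 case_label = case_label,
                 control_label = control_label),
            class = "sim_spec")
}

#' @export
#' @method print sim_spec
print.sim_spec <- function(x, ...) {
  cat("Pooled-GWAS simulation spec\n")
  cat(sprintf("  cohorts: %d %s / %d %s\n", x$n_cases, x$case_label,
              x$n_controls, x$control_label))
  cat(sprintf("  panel: %d SNPs on %d chromosome(s)\n", nrow(x$panel),
              length(unique(x$panel$chrom))))
  cat(sprintf("  LD: blocks of %d, copy prob %.2f\n",
              x$ld_block_length, x$ld_r))
  cat(sprintf("  effect loci: %d; pool sets: %d; noise_sd: %.3f; seed: %d\n",
              if (is.null(x$effects)) 0L else nrow(x$effects),
              length(x$pool_sets), x$noise_sd, x$seed))
  invisible(x)
}

# LD block index per SNP: consecutive runs of ld_block_length within a chrom.
block_index <- function(panel, ld_block_length) {
  idx <- integer(nrow(panel))
  offset <- 0L
  for (ch in unique(panel$chrom)) {
    sel <- which(panel$chrom == ch)
    idx[sel] <- offset + (seq_along(sel) - 1L) %/% ld_block_length + 1L
    idx_max <- idx[sel[length(sel)]]
    offset <- idx_max
  }
  idx
}
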