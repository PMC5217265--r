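# Independent oracles and small fixture builders shared across tests.

# Welch two-sample t statistics transcribed directly from the textbook
# formulas (scalar, no shortcuts) — the reference the vectorised scan is
# checked against.
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1); v2 <- sum((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins (point-probability rule with fisher.test's
# relative tolerance).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # cases margin
  n <- c + d          # controls margin
  k <- a + c          # minor-allele margin
  lo <- max(0L, k - n); hi <- min(k, m)
  if (lo > hi || m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  supp <- lo:hi
  pr <- stats::dhyper(supp, m, n, k)
  sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
}

# Brute-force block finder: grow a run from every start SNP while the
# criteria hold, then keep only maximal qualifying runs.
oracle_find_blocks <- function(track, criteria) {
  if (!"p_value" %in% names(track)) track$p_value <- track$p
  out <- list()
  for (cc in unique(track$chrom)) {
    tr <- track[track$chrom == cc, ]
    n <- nrow(tr)
    qual <- tr$p_value < criteria$p_block
    runs <- list()
    for (s in seq_len(n)) {
      if (!qual[s]) next
      e <- s
      while (e < n && qual[e + 1L] &&
             (tr$pos[e + 1L] - tr$pos[e]) < criteria$max_gap_bp) e <- e + 1L
      runs[[length(runs) + 1L]] <- c(s, e)
    }
    if (!length(runs)) next
    runs <- unique(runs)
    maximal <- Filter(function(r) {
      !any(vapply(runs, function(o)
        (o[1] < r[1] && o[2] >= r[2]) || (o[1] <= r[1] && o[2] > r[2]),
        logical(1)))
    }, runs)
    for (r in maximal) {
      if (r[2] - r[1] + 1L < criteria$min_snps) next
      out[[length(out) + 1L]] <- list(chrom = cc,
                                      start_pos = tr$pos[r[1]],
                                      end_pos = tr$pos[r[2]],
                                      snp_id = tr$snp_id[r[1]:r[2]])
    }
  }
  out
}

random_track <- function(n, frac_low = 0.3, chrom = "1",
                         gap_range = c(1000L, 40000L)) {
  gaps <- sample(seq(gap_range[1], gap_range[2], by = 1000L), n,
                 replace = TRUE)
  p <- ifelse(stats::runif(n) < frac_low,
              stats::runif(n, 0, 0.01), stats::runif(n))
  data.frame(chrom = chrom, pos = cumsum(gaps),
             snp_id = sprintf("s%04d", seq_len(n)), p_value = p,
             stringsAsFactors = FALSE)
}

# Small study spec used by several files; one seeded locus mid-panel.
small_spec <- function(n_snps = 150, n_cases = 200, n_controls = 200,
                       or = 1, maf_range = c(0.1, 0.4),
                       ld_block_length = 15L, ld_r = 0.9,
                       noise_sd = 0.02, seed = 11L,
                       pool_sets = list(pool_set("I", 20L,
                                                 c(CASE = 5L, CTRL = 5L)))) {
  panel <- random_panel(n_snps, maf_range = maf_range, seed = seed + 1L)
  eff <- if (or != 1)
    effect_loci(panel$snp_id[ceiling(n_snps / 2)], or) else NULL
  sim_spec(n_cases, n_controls, panel, ld_block_length = ld_block_length,
           ld_r = ld_r, effects = eff, pool_sets = pool_sets,
           noise_sd = noise_sd, seed = seed)
}

read_tsv0_for_test <- function(path)
  utils::read.delim(path, na.strings = ".", check.names = FALSE,
                    stringsAsFactors = FALSE)
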