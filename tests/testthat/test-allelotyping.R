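make_ras <- function(values, group, set_id = "I") {
  pools <- data.frame(pool_id = sprintf("p%02d", seq_along(group)),
                      group = group, set_id = set_id,
                      stringsAsFactors = FALSE)
  rownames(values) <- pools$pool_id
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  structure(list(pools = pools, values = values, snp_index = NULL),
            class = "ras_matrix")
}

test_that("RAS is the channel ratio, complement under swap, missing when signal is zero", {
  pools <- data.frame(pool_id = c("p1", "p2"), group = c("CASE", "CTRL"),
                      set_id = "I", stringsAsFactors = FALSE)
  a <- matrix(c(1, 3, 0, 2), 2, 2)
  b <- matrix(c(1, 1, 0, 6), 2, 2)
  it <- structure(list(pools = pools, channel_a = a, channel_b = b,
                       panel = NULL), class = "intensity_table")
  ras <- compute_ras(it)
  expect_equal(ras$values[1, 1], 0.5)
  expect_equal(ras$values[2, 1], 0.75)
  expect_equal(ras$values[2, 2], 0.25)
  expect_true(is.na(ras$values[1, 2]))          # A = B = 0 -> missing
  expect_equal(attr(ras, "missing_by_snp"), c(0, 1), ignore_attr = TRUE)
  # complement: swapped channels give 1 - RAS wherever defined
  swapped <- compute_ras(structure(list(pools = pools, channel_a = b,
                                        channel_b = a, panel = NULL),
                                   class = "intensity_table"))
  ok <- !is.na(ras$values)
  expect_equal(swapped$values[ok], 1 - ras$values[ok], tolerance = 1e-12)
  # shape mismatch errors
  it$channel_b <- b[, 1, drop = FALSE]
  expect_error(compute_ras(it), "shape")
})

test_that("welch_scan matches a direct formula transcription on random instances", {
  set.seed(202)
  for (rep in 1:200) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- runif(n1); y <- runif(n2)
    ras <- make_ras(rbind(matrix(x, n1, 1), matrix(y, n2, 1)),
                    c(rep("CASE", n1), rep("CTRL", n2)))
    got <- welch_scan(ras, "CASE", "CTRL")
    ref <- oracle_welch(x, y)
    expect_equal(got$t_stat, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
  }
})

test_that("welch_scan agrees with the frozen hand-computed example", {
  ras <- make_ras(cbind(c(0.60, 0.62, 0.58, 0.50, 0.52, 0.48)),
                  c(rep("CASE", 3), rep("CTRL", 3)))
  got <- welch_scan(ras, "CASE", "CTRL")
  expect_equal(got$t_stat, 6.123724, tolerance = 1e-6)
  expect_equal(got$df, 4.0, tolerance = 1e-12)
  expect_equal(got$p_value, 0.0036022, tolerance = 1e-4)
  expect_equal(got$direction, 1)
  # cross-check against R's own Welch test as a second, independent route
  tt <- t.test(c(0.60, 0.62, 0.58), c(0.50, 0.52, 0.48))
  expect_equal(got$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate scans are flagged, identical groups give t = 0, p = 1", {
  v <- c(0.4, 0.5, 0.6)
  ras <- make_ras(cbind(c(v, v)), c(rep("CASE", 3), rep("CTRL", 3)))
  # same values in both groups: t = 0, p = 1 (not an error, still reported)
  got <- welch_scan(ras, "CASE", "CTRL")
  expect_equal(got$t_stat, 0)
  expect_equal(got$p_value, 1)
  # zero variance in both groups -> skipped with p = 1
  ras2 <- make_ras(cbind(rep(c(0.3, 0.7), each = 3)),
                   c(rep("CASE", 3), rep("CTRL", 3)))
  got2 <- welch_scan(ras2, "CASE", "CTRL")
  expect_true(got2$skipped)
  expect_equal(got2$p_value, 1)
  # single case pool -> skipped
  ras3 <- make_ras(cbind(c(0.5, 0.4, 0.45, 0.5)),
                   c("CASE", rep("CTRL", 3)))
  expect_true(welch_scan(ras3, "CASE", "CTRL")$skipped)
  # unknown group label errors
  expect_error(welch_scan(ras, "CASE", "NOPE"), "unknown group")
  # permuting pool order within groups changes nothing
  set.seed(1)
  vals <- matrix(runif(8 * 5), 8, 5)
  grp <- rep(c("CASE", "CTRL"), each = 4)
  r1 <- welch_scan(make_ras(vals, grp), "CASE", "CTRL")
  perm <- c(sample(1:4), sample(5:8))
  r2 <- welch_scan(make_ras(vals[perm, ], grp[perm]), "CASE", "CTRL")
  expect_equal(r1$t_stat, r2$t_stat, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("Bonferroni adjustment multiplies by the per-set tested count and caps at 1", {
  res <- data.frame(set_id = c("I", "I", "I", "II", "II"),
                    p_value = c(0.001, 0.9, 0.5, 0.02, 0.3),
                    skipped = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  adj <- bonferroni_adjust(res)
  expect_equal(adj$p_bonferroni[1], 0.002)   # m = 2 tested in set I
  expect_equal(adj$p_bonferroni[2], 1)       # capped
  expect_equal(adj$p_bonferroni[4], 0.04)    # m = 2 in set II
  # m = 22 worth of tests: p = 0.001 -> 0.022
  res22 <- data.frame(set_id = "I", p_value = c(0.001, rep(0.5, 21)),
                      skipped = FALSE)
  expect_equal(bonferroni_adjust(res22)$p_bonferroni[1], 0.022)
})

test_that("QC keeps homogeneous pools and removes a planted batch of outliers", {
  # homogeneous: 30 pools, same noise regime -> at most one chance removal
  spec <- small_spec(n_snps = 400, n_cases = 300, n_controls = 720,
                     seed = 101L,
                     pool_sets = list(pool_set("I", 24L, c(CTRL = 30L))))
  gt <- simulate_cohort(spec)
  mem <- assign_pools(gt, spec)
  ras <- compute_ras(simulate_intensities(gt, mem, spec))
  qc <- qc_pools(ras)
  expect_lte(nrow(qc$removed_pools), 1L)

  # planted: 6 pools get a systematic +0.05 shift on 20% of SNPs, on
  # replicate pools of identical composition (array noise is then the only
  # pool-to-pool variation, the regime the batch-shift artefact models)
  set.seed(102)
  shared <- rbinom(400, 2, spec$panel$maf)
  gt$genotypes[] <- matrix(shared, nrow(gt$genotypes), 400, byrow = TRUE)
  shifted <- sprintf("I_CTRL_p%02d", 1:6)
  it2 <- simulate_intensities(gt, mem, spec, batch_shift = 0.05,
                              batch_shift_pools = shifted,
                              batch_shift_frac = 0.2)
  ras2 <- compute_ras(it2)
  qc2 <- qc_pools(ras2)
  z <- qc2$scores
  worst6 <- z$pool_id[order(-z$robust_z)][1:6]
  expect_setequal(worst6, shifted)
  expect_setequal(qc2$removed_pools$pool_id, shifted)
  expect_setequal(c(qc2$retained_pools, qc2$removed_pools$pool_id),
                  ras2$pools$pool_id)
  # and apply_qc drops exactly those rows
  expect_equal(nrow(apply_qc(ras2, qc2)$values), 24L)
})

test_that("zero-variance SNP columns do not change QC distances", {
  spec <- small_spec(n_snps = 100, n_cases = 60, n_controls = 120,
                     seed = 111L,
                     pool_sets = list(pool_set("I", 20L, c(CTRL = 6L))))
  gt <- simulate_cohort(spec)
  mem <- assign_pools(gt, spec)
  ras <- compute_ras(simulate_intensities(gt, mem, spec))
  qc1 <- qc_pools(ras)
  ras_aug <- ras
  ras_aug$values <- cbind(ras$values,
                          matrix(0.5, nrow(ras$values), 20,
                                 dimnames = list(NULL, sprintf("const%02d", 1:20))))
  qc2 <- qc_pools(ras_aug)
  expect_equal(qc1$scores$robust_z, qc2$scores$robust_z, tolerance = 1e-8)
})

test_that("QC is skipped with a recorded warning when a set has too few pools", {
  vals <- matrix(runif(3 * 50), 3, 50)
  ras <- make_ras(vals, rep("CTRL", 3))
  expect_warning(qc <- qc_pools(ras, n_components = 4L), "skipped")
  expect_equal(qc$skipped_sets, "I")
  expect_length(qc$retained_pools, 3L)
})

test_that("scan power at a seeded locus is non-decreasing in the odds ratio", {
  ors <- c(1.0, 1.3, 1.6, 2.0)
  n_rep <- 200
  panel <- snp_panel("s1", "1", 1000, maf = 0.25)
  power <- vapply(seq_along(ors), function(k) {
    hits <- 0L
    for (r in seq_len(n_rep)) {
      eff <- if (ors[k] > 1) effect_loci("s1", ors[k]) else NULL
      spec <- sim_spec(400, 400, panel, effects = eff,
                       pool_sets = list(pool_set("I", 20L,
                                                 c(CASE = 20L, CTRL = 20L))),
                       noise_sd = 0.02, seed = 7000L + 17L * r + k)
      gt <- simulate_cohort(spec)
      mem <- assign_pools(gt, spec)
      ras <- compute_ras(simulate_intensities(gt, mem, spec))
      sc <- welch_scan(ras, "CASE", "CTRL")
      hits <- hits + (sc$p_value < 0.005)
    }
    hits / n_rep
  }, numeric(1))
  inversions <- sum(diff(power) < 0)
  expect_lte(inversions, 1L)
  expect_gt(power[4], power[1])   # OR 2.0 clearly beats the null
})

test_that("Manhattan export is genome-ordered, complete, and on the -log10 scale", {
  res <- data.frame(chrom = c("2", "2", "1", "10"),
                    pos = c(500, 100, 50, 7),
                    snp_id = c("a", "b", "c", "d"),
                    p_value = c(0.001, 0.5, 0.01, 1))
  out <- export_manhattan(res)
  expect_equal(nrow(out), nrow(res))
  expect_equal(out$snp_id, c("c", "b", "a", "d"))   # 1 < 2 < 10
  expect_equal(out$neg_log10_p[out$snp_id == "a"], 3)
  path <- tempfile(fileext = ".tsv")
  export_manhattan(res, path)
  back <- read.delim(path)
  expect_equal(back$snp_id, out$snp_id)
})
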