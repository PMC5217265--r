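test_that("allele tables count two alleles per genotyped individual", {
  gt <- structure(list(
    individuals = data.frame(id = sprintf("i%d", 1:6),
                             group = rep(c("PBC", "CTRL"), each = 3)),
    genotypes = matrix(c(2L, 1L, 0L, 0L, 0L, 1L), 6, 1,
                       dimnames = list(sprintf("i%d", 1:6), "s1"))),
    class = "genotype_table")
  tab <- allele_table(gt, "s1", "PBC", "CTRL")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 3, b = 3, c = 1, d = 5))
  # boundary: {2,2} vs {0,0}
  gt$genotypes[, 1] <- c(2L, 2L, NA, 0L, 0L, NA)
  tab2 <- allele_table(gt, "s1", "PBC", "CTRL")
  expect_equal(unlist(tab2[c("a", "b", "c", "d")]),
               c(a = 4, b = 0, c = 0, d = 4))
  # monomorphic flag when the minor allele is absent everywhere
  gt$genotypes[, 1] <- 0L
  expect_true(attr(allele_table(gt, "s1", "PBC", "CTRL"), "monomorphic"))
  # all-missing group errors with the group named
  gt$genotypes[1:3, 1] <- NA
  expect_error(allele_table(gt, "s1", "PBC", "CTRL"), "PBC")
  expect_error(allele_table(gt, "s2", "PBC", "CTRL"), "unknown snp_id")
})

test_that("Fisher p equals the hypergeometric enumeration oracle on 500 random tables", {
  set.seed(303)
  for (i in 1:500) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c <- sample(0:30, 1); d <- sample(0:30, 1)
    expect_equal(fisher_exact_test(c(a, b, c, d)),
                 oracle_fisher(a, b, c, d), tolerance = 1e-12)
  }
})

test_that("Fisher test honours its frozen example, symmetry and degenerate margins", {
  expect_equal(fisher_exact_test(contingency_table(5, 5, 1, 9)),
               0.1408669, tolerance = 1e-6)
  # proportional rows: no association
  expect_equal(fisher_exact_test(c(4, 4, 4, 4)), 1)
  # transposition and case/control swap leave p unchanged
  expect_equal(fisher_exact_test(c(5, 5, 1, 9)),
               fisher_exact_test(c(1, 9, 5, 5)), tolerance = 1e-12)
  expect_equal(fisher_exact_test(c(5, 5, 1, 9)),
               fisher_exact_test(c(5, 1, 5, 9)), tolerance = 1e-12)
  # degenerate margins give p = 1
  expect_equal(fisher_exact_test(c(0, 0, 3, 7)), 1)
  expect_equal(fisher_exact_test(c(0, 5, 0, 7)), 1)
})

test_that("Woolf OR/CI matches the closed form, with Haldane correction only at zero cells", {
  # frozen example: a=5 b=5 c=1 d=9 -> OR 9, CI from the Woolf formula
  got <- odds_ratio_ci(contingency_table(5, 5, 1, 9))
  expect_equal(got$or_point, 9)
  expect_equal(got$ci_low, 0.8088794, tolerance = 1e-6)
  expect_equal(got$ci_high, 100.1385, tolerance = 1e-6)
  expect_false(got$corrected)
  # null table: OR 1, CI straddles 1
  nul <- odds_ratio_ci(c(4, 4, 4, 4))
  expect_equal(nul$or_point, 1)
  expect_lt(nul$ci_low, 1); expect_gt(nul$ci_high, 1)
  # closed form on random tables
  set.seed(404)
  for (i in 1:100) {
    x <- sample(1:40, 4, replace = TRUE)
    g <- odds_ratio_ci(x)
    expect_equal(g$or_point, x[1] * x[4] / (x[2] * x[3]), tolerance = 1e-12)
    se <- sqrt(sum(1 / x))
    expect_equal(g$ci_low, exp(log(g$or_point) - qnorm(0.975) * se),
                 tolerance = 1e-12)
  }
  # single zero cell: +0.5 everywhere, estimable
  z <- odds_ratio_ci(c(0, 10, 5, 5))
  expect_true(z$corrected)
  expect_equal(z$or_point, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  # empty margin: undefined and flagged
  u <- odds_ratio_ci(c(0, 10, 0, 10))
  expect_true(u$undefined)
  expect_true(is.na(u$or_point))
})

test_that("Woolf CI covers the true allelic OR at its nominal rate", {
  set.seed(505)
  true_or <- 1.5
  p0 <- 0.3
  p1 <- case_maf(p0, true_or)
  n_rep <- 1000
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rbinom(1, 2 * 400, p1); b <- 2 * 400 - a
    c <- rbinom(1, 2 * 900, p0); d <- 2 * 900 - c
    ci <- odds_ratio_ci(c(a, b, c, d))
    covered[i] <- ci$ci_low <= true_or && true_or <= ci$ci_high
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("two-tier classification reproduces the published decision rule", {
  # corrected tier at the 0.05/22 threshold
  expect_equal(classify_validation(1.2e-5, 0.39, 22), "corrected")
  # suggestive: nominal p with a large-enough effect
  expect_equal(classify_validation(0.028, 1.24, 22), "suggestive")
  # nominal p but a negligible effect: not validated
  expect_equal(classify_validation(0.04, 1.05, 22), "not_validated")
  # OR exactly 0.83 counts by default (inclusive), not under strict_or
  expect_equal(classify_validation(0.033, 0.83, 22), "suggestive")
  expect_equal(classify_validation(0.033, 0.83, 22, strict_or = TRUE),
               "not_validated")
  # threshold arithmetic
  expect_equal(signif(bonferroni_threshold(22), 2), 0.0023)
  expect_equal(signif(bonferroni_threshold(29), 2), 0.0017)
  # boundary: p just under / at the corrected threshold
  expect_equal(classify_validation(0.05 / 22 - 1e-12, 5, 22), "corrected")
  expect_equal(classify_validation(0.05 / 22, 1.5, 22), "suggestive")
  # every record lands in exactly one tier
  set.seed(6)
  tiers <- classify_validation(runif(200), exp(rnorm(200)), 22)
  expect_true(all(tiers %in% c("corrected", "suggestive", "not_validated")))
})

test_that("direction concordance respects sign and allele orientation", {
  expect_true(direction_concordance(+1, 1.5, "same"))
  expect_false(direction_concordance(+1, 0.6, "same"))
  expect_true(direction_concordance(+1, 0.6, "flipped"))
  expect_false(direction_concordance(-1, 1.5, "same"))
  expect_true(is.na(direction_concordance(0, 1.5, "same")))
  expect_true(is.na(direction_concordance(+1, 1.0, "same")))
  expect_true(is.na(direction_concordance(+1, 1.5, NA)))
})

test_that("shared-locus accounting partitions validated SNPs across diseases", {
  mk_rec <- function(ids, ors, tiers, disease)
    structure(data.frame(snp_id = ids, disease = disease, or_point = ors,
                         tier = tiers, stringsAsFactors = FALSE),
              class = c("validation_result", "data.frame"))
  r1 <- mk_rec(c("rs1", "rs2", "rs3", "rs4"), c(0.7, 1.3, 0.73, 1.4),
               c("suggestive", "corrected", "suggestive", "not_validated"),
               "PBC")
  r2 <- mk_rec(c("rs1", "rs3", "rs5"), c(0.7, 2.47, 1.5),
               c("suggestive", "corrected", "suggestive"), "PSC")
  s <- shared_loci(r1, r2)
  expect_setequal(s$shared, c("rs1", "rs3"))
  expect_setequal(s$unique_disease1, "rs2")       # rs4 not validated
  expect_setequal(s$unique_disease2, "rs5")
  # rs1: 0.7 and 0.7 -> same direction; rs3: 0.73 vs 2.47 -> opposite
  expect_equal(s$shared_same_direction, "rs1")
  # the three primary sets are disjoint
  expect_length(intersect(s$shared, c(s$unique_disease1,
                                      s$unique_disease2)), 0L)
  # no overlap at all
  s0 <- shared_loci(mk_rec("rsA", 1.5, "corrected", "PBC"),
                    mk_rec("rsB", 1.5, "corrected", "PSC"))
  expect_length(s0$shared, 0L)

  # known-panel reporting
  recs <- rbind(r1, r2)
  pan <- summarize_known_panel(recs, c("rs1", "rs999"))
  expect_equal(pan$status[pan$snp_id == "rs999" & pan$disease == "PBC"],
               "not tested")
  expect_equal(pan$status[pan$snp_id == "rs1" & pan$disease == "PSC"],
               "suggestive")
  expect_equal(nrow(summarize_known_panel(recs, character(0))), 0L)
})

test_that("validate_candidates ties the stages together on simulated data", {
  panel <- snp_panel(c("s1", "s2"), "1", c(1000, 2000), maf = c(0.2, 0.3))
  spec <- sim_spec(400, 900, panel,
                   effects = effect_loci("s1", 2.0, disease = "PBC"),
                   pool_sets = list(pool_set("I", 20L,
                                             c(PBC = 5L, CTRL = 5L))),
                   seed = 606L, case_label = "PBC")
  gt <- simulate_cohort(spec)
  mem <- assign_pools(gt, spec)
  scan <- welch_scan(compute_ras(simulate_intensities(gt, mem, spec)),
                     "PBC", "CTRL")
  recs <- validate_candidates(gt, c("s1", "s2"), "PBC", "CTRL",
                              n_tests = 2, scan = scan)
  expect_equal(nrow(recs), 2L)
  r1 <- recs[recs$snp_id == "s1", ]
  expect_equal(r1$tier, "corrected")      # OR 2 at n=400/900 is unmissable
  expect_gt(r1$or_point, 1.4)
  expect_true(r1$direction_concordant)
  expect_true(r1$validated)
  expect_true(all(recs$ci_low <= recs$or_point &
                    recs$or_point <= recs$ci_high))
  expect_lte(recs$maf_controls[1], 0.5)
  # reported MAF is the control-minor-allele frequency by construction
  expect_equal(r1$a + r1$b, 2 * 400)
  expect_equal(r1$c + r1$d, 2 * 900)
})

test_that("validation flips to the control-minor allele when the counted allele is major", {
  # counted allele at 70% in controls: must be flipped, OR inverted
  gt <- structure(list(
    individuals = data.frame(id = sprintf("i%d", 1:40),
                             group = rep(c("PBC", "CTRL"), each = 20)),
    genotypes = matrix(c(rep(2L, 12), rep(1L, 8),      # cases: freq 0.8
                         rep(2L, 9), rep(1L, 10), 0L), # controls: freq 0.7
                       40, 1, dimnames = list(sprintf("i%d", 1:40), "s1"))),
    class = "genotype_table")
  rec <- validate_candidates(gt, "s1", "PBC", "CTRL", n_tests = 1)
  expect_true(rec$or_flipped_to_minor)
  expect_lte(rec$maf_controls, 0.5)
  # flipped OR equals the reciprocal structure: minor allele is protective
  tab_minor <- allele_table(gt, "s1", "PBC", "CTRL")
  or_counted <- (tab_minor$a * tab_minor$d) / (tab_minor$b * tab_minor$c)
  expect_equal(rec$or_point, 1 / or_counted, tolerance = 1e-12)
})

test_that("expected false positives follow n * alpha", {
  expect_equal(expected_false_positives(50, 0.05), 2.5)
  expect_equal(expected_false_positives(22), 1.1)
})
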