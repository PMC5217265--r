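# pooledscan

Case/control association discovery for studies that allelotype **pooled
DNA** instead of genotyping individuals — the design used when a disease is
too rare to assemble the thousands of patients a conventional GWAS needs.
DNA from many same-phenotype individuals is combined into pools, each pool
is hybridised to a SNP array, and allele frequencies are compared between
case and control pools; only a short list of candidate SNPs is then
genotyped individually.

The package implements the full workflow:

1. **Allelotyping** — relative allele signal `RAS = A/(A+B)` from
   two-channel intensities; principal-component pool QC (robust z-score of
   each pool's distance in the first four PCs, an auditable surrogate for
   visual inspection); per-SNP two-sided **Welch t-tests** between case and
   control pools, per pool set, with Bonferroni correction over the tested
   SNPs. No probe filtering: untestable SNPs are reported with `p = 1` and
   a skip flag.
2. **Candidate selection** — loci are *blocks*: maximal runs of ≥ 10
   consecutive SNPs, each associated at `p < 0.005`, with < 30 kb between
   adjacent members (a proxy for a disease-associated strong-LD region).
   Block members with `p < 1e-4` become **index SNPs**, the candidates
   carried to validation; candidate sets from two scan rounds are merged as
   a provenance-keyed union.
3. **Validation** — allelic 2×2 Fisher exact tests on individual
   genotypes; odds ratios with Woolf (normal-approximation) 95% CIs,
   `exp(log OR ± z·√(1/a + 1/b + 1/c + 1/d))`, Haldane-corrected at zero
   cells; a two-tier classification (**corrected**: `p < 0.05/n_tests`;
   **suggestive**: `p < 0.05` with OR ≥ 1.2 or ≤ 0.83); direction-of-effect
   concordance with the pooled scan; and cross-disease shared-locus
   accounting.
4. **Synthetic cohorts** — a seedable generator (block-copy LD haplotypes,
   a multiplicative allelic odds model `p' = OR·p/(1−p+OR·p)` at seeded
   risk loci, two-set pooling designs with leftover exclusion, additive
   array noise) so the entire pipeline runs end to end with no external
   data. See the methods vignette (`vignettes/pooled-gwas-methods.Rmd`)
   for the models and every design decision.

## Worked example

Simulate a 400-case / 800-control study on a 2,000-SNP panel with one
seeded risk locus (OR 1.8, MAF 0.25) inside a strong-LD block, pool it into
two sets, and run the whole pipeline:

```r
library(pooledscan)

panel <- random_panel(2000, spacing_bp = 5000, maf_range = c(0.1, 0.4), seed = 7)
panel$maf[991:1005] <- 0.25                     # strong-LD block shares its MAF
spec <- sim_spec(n_cases = 400, n_controls = 800, panel,
                 ld_block_length = 15, ld_r = 0.95,
                 effects = effect_loci("snp000998", odds_ratio = 1.8),
                 pool_sets = list(
                   pool_set("I", 20, c(CASE = 20L, CTRL = 20L)),
                   pool_set("II", 37, c(CASE = 10L, CTRL = 10L))),
                 noise_sd = 0.02, seed = 42)
res <- run_pooled_gwas(spec)
res
#> pooled-GWAS pipeline result
#>   scan: 4000 SNP tests over 2 set(s)
#>   blocks: I=1, II=1
#>   candidates: 15 | corrected 15, suggestive 0, not validated 0

as.data.frame(res$blocks$I)
#>   block chrom start_pos end_pos n_snps        min_p n_index
#> 1     1     1   4955000 5025000     15 9.810864e-07      15
```

The scan found exactly one block per set — the 15 SNPs around the seeded
locus (positions 4,955,000–5,025,000), every member below the 0.005 block
threshold and 15 of them below the 1e-4 index threshold. Validation on the
individual genotypes confirms the locus; the seeded SNP's row:

```r
res$validation[res$validation$snp_id == "snp000998",
               c("snp_id", "fisher_p", "or_point", "ci_low", "ci_high", "tier")]
#>      snp_id fisher_p or_point ci_low ci_high      tier
#> 8 snp000998 8.93e-12     1.88   1.57    2.25 corrected
```

The Fisher p-value is far below the Bonferroni tier threshold
`0.05/15 = 0.0033` and the allelic OR estimate 1.88 (95% CI 1.57–2.25)
brackets the simulated OR of 1.8 — the pipeline recovers both the locus and
its effect size. A null run of the same design (`effects = NULL`) returns
zero blocks and zero candidates.

The package also ships a transcription of a published table of
validated/replicated loci for bookkeeping checks:

```r
summarize_table2(load_table2())
#> validated/replicated loci: 57 SNPs, 38 locus labels
#>   PBC only 28 | PSC only 18 | shared 11 (same direction 5)
```

A thin command-line wrapper over the same functions is provided in
`inst/cli/pooledscan.R`
(`pooledscan {simulate, scan, blocks, validate, table2-summary}`).

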