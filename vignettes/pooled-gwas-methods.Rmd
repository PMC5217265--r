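---
title: "Pooled-DNA GWAS discovery and validation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-DNA GWAS discovery and validation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooledscan)
```

## The problem

Genome-wide association studies of uncommon diseases are often stuck with
cohorts of a few hundred patients — far too small to reach the conventional
genome-wide threshold of $5 \times 10^{-8}$. One cost-effective response is
*pooled-DNA allelotyping*: rather than genotyping every individual, DNA from
many same-phenotype individuals is combined into pools, each pool is
hybridised to a SNP array, and case and control pools are compared on their
estimated allele frequencies. Individual genotyping is then spent only on a
short list of candidate SNPs.

`pooledscan` implements that whole workflow — pooled scan, candidate
selection, and individual-genotyping validation — together with a synthetic
cohort generator, so every stage can be exercised and its statistical
behaviour measured without access to patient data.

## Relative allele signal and the pooled scan

A two-channel array reports intensities $A$ and $B$ for the two alleles of
each SNP. The *relative allele signal*

$$\mathrm{RAS} = \frac{A}{A + B}$$

estimates the pool's frequency of the $A$-counted allele. Entries with
$A + B = 0$ are flagged missing and excluded from testing (they are counted
in a per-SNP missingness tally, never propagated as `NaN`).

Each pool-array is treated as one observation. For every SNP, case pools and
control pools are compared with a two-sided Welch $t$-test
($t = (\bar x_1 - \bar x_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}$ with
Welch–Satterthwaite degrees of freedom), separately within each pool set,
because the two sets are separate hybridisations. No probe filtering is
performed: every SNP appears in the output, and SNPs that cannot be tested
(fewer than two usable pools in a group, or zero variance in both groups)
are reported with $p = 1$ and a skip flag rather than dropped. Bonferroni
correction multiplies by the number of SNPs actually tested in that scan,
excluding skip-flagged SNPs.

## Pool quality control

Pooled samples have no per-sample call rate, so outlying arrays must be
found from the data. The package automates the usual visual inspection of
leading principal components: per pool set, the pool × SNP RAS matrix is
SNP-wise centred and decomposed; each pool's Euclidean distance from the
coordinate-wise median in the first four PC coordinates is turned into a
robust z-score (centred on the median distance, scaled by its MAD), and
pools above a threshold (default 3.5, a conventional robust-outlier cutoff)
are removed. The threshold is exposed because any automated surrogate for a
by-eye decision is a convention; all scores are retained for audit. Removal
can be restricted to selected groups (e.g. a controls-only policy) without
changing the scores.

With fewer than five pools in a set the four-component decomposition is not
meaningful; QC is skipped for that set and the skip is recorded.

## Candidate selection: blocks and index SNPs

With small cohorts no single SNP is expected to reach genome-wide
significance, so candidate loci are defined by *co-significance in physical
proximity*: a block is a maximal run of at least 10 consecutive SNPs, each
associated at $p < 0.005$, with strictly less than 30 kb between adjacent
members. Within qualifying blocks, *index SNPs* — members with
$p < 10^{-4}$ — are carried forward to individual genotyping. A block may
contribute more than one index SNP; all sub-threshold members are reported
ranked by $p$, and a `max_per_block` cap is available because no principled
per-block choice rule exists.

Three readings of the rule deserve comment:

* All inequalities are strict; an inclusive index threshold
  ($p \le 10^{-4}$) is available by flag since both readings appear
  plausible.
* A non-qualifying SNP terminates a run even if the next qualifying SNP is
  physically close. A `bridge` mode that chains qualifying SNPs by distance
  alone is provided for sensitivity analysis, off by default.
* Blocks never span chromosomes, and unsorted tracks are rejected rather
  than silently reordered.

On an LD-free null track the criterion is extremely conservative: the
chance that 10 consecutive independent SNPs all reach $p < 0.005$ is
$\sim 10^{-23}$ per start, so a 10,000-SNP null genome essentially never
produces a block (the test suite verifies this over 1,000 replicates).
The criterion's power comes entirely from LD: a true risk locus drags its
correlated neighbours below the block threshold together.

Scans from the two pool sets are processed independently and their
candidate sets merged as a union keyed by SNP, with per-round provenance —
mirroring a two-round discovery design.

## Validation by individual genotyping

Each candidate is tested on individually genotyped samples with an allelic
$2 \times 2$ table (each individual contributes two alleles; missing
genotypes leave both margins). The test is the two-sided Fisher exact test
in R's point-probability convention. The allelic model, rather than a
genotypic $2 \times 3$ one, is used because effect sizes are reported as
per-minor-allele odds ratios.

The odds ratio and its 95% CI use the Woolf (normal-approximation) form
$\exp(\log \mathrm{OR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d})$. When a single
cell is zero, the Haldane–Anscombe correction (+0.5 to every cell) is
applied to the OR and CI only — never to the exact test, which needs no
correction. Tables with an empty row or column have no estimable OR and are
flagged. The minor allele is defined in controls; if the dosage-counted
allele is the control-major allele the table is flipped so reported ORs and
MAFs always refer to the control-minor allele.

Validated candidates fall into two tiers: **corrected**
($p < 0.05/n_\text{tests}$, Bonferroni over the candidates actually
genotyped for that disease — $n_\text{tests}$ is always passed explicitly,
never inferred from a filtered list), and **suggestive** ($p < 0.05$ with
OR $\ge 1.2$ or $\le 0.83$). The OR bound is inclusive by default because a
published table counts an OR of exactly 0.83 as validated; a strict mode is
available. A candidate is only *reported* validated if its direction of
effect agrees with the pooled scan after allele-orientation harmonisation;
missing orientation metadata yields "unknown", never a silent assumption.

When two diseases are validated over a common SNP set, shared-locus
accounting partitions the validated SNPs into disease-unique and shared
sets, and counts how many shared SNPs have ORs on the same side of 1. The
shared-direction count is reported but not asserted against any external
figure: recomputing it from a published table of per-disease ORs is known
to be sensitive to which rows one treats as shared.

## The synthetic cohort generator

The generator exists to emulate the *shape* of a pooled-DNA study — not
human population genetics. Its components:

* **Panel**: SNPs with positions (1-based; gaps in bp) and control MAFs,
  by default drawn uniformly from a configurable range.
* **LD**: a block-copy haplotype model. SNPs are grouped into consecutive
  blocks of `ld_block_length`; each haplotype draws one latent uniform
  $U$ per block, and each member SNP either thresholds that shared $U$ at
  its own MAF (probability `ld_r`) or draws independently. Marginal control
  frequencies equal the panel MAFs exactly; within-block alleles are
  correlated. For two copying SNPs with equal MAF the allelic correlation
  is 1, so adjacent-SNP correlation is approximately `ld_r`$^2$ for
  equal-MAF members and lower for unequal MAFs — `ld_r` is a dial, not a
  literal $r$. This is deliberately simple: the block-selection algorithm
  only needs correlated p-value runs, not realistic recombination maps.
* **Disease model**: a multiplicative allelic odds model. With control MAF
  $p$ and odds ratio $\mathrm{OR}$ the case MAF is
  $p' = \mathrm{OR}\,p / (1 - p + \mathrm{OR}\,p)$. In case haplotypes the
  affected block's latent uniform is *tilted* — drawn from the two-piece
  density that gives the effect locus exactly the marginal $p'$ — so
  correlated neighbours inherit an `ld_r`-scaled frequency shift through
  the shared uniform, exactly as a causal allele drags its LD partners.
  This matches the allelic 2 × 2 OR used at validation; no liability-scale
  model is involved.
* **Pooling**: pool sets mirror a two-hybridisation design; within a set
  each group's individuals are shuffled (seeded) and packed into equal
  pools, with leftovers excluded from that set (so 443 enrolled cases pool
  to 407 in an 11 × 37 design). The same individuals may be re-pooled in a
  different set. Pool sizes may differ by group within a set.
* **Array noise**: the true pooled minor-allele fraction is perturbed with
  additive Gaussian noise clipped to $[0,1]$, default SD 0.02 — a single
  interpretable parameter standing in for all array-level error, chosen as
  a realistic magnitude for pooled-array frequency estimates; no published
  quantification exists to calibrate against. An optional systematic batch
  shift on a subset of SNPs supports QC testing.

Everything is a deterministic function of the spec's seed (the generator,
pooling and intensity stages use `seed`, `seed + 1`, `seed + 2`), so a
study is reproducible from its YAML spec alone, and every simulation run
can write its resolved spec next to its outputs.

What the generator does *not* emulate: realistic recombination and
coalescent structure, allele-frequency spectra, genotyping-platform
artefacts beyond additive noise, population stratification, or
X-chromosome dosage. Passing tests therefore demonstrate the pipeline's
internal correctness and its statistical calibration under the stated
noise model — not performance on real arrays.

## Study-scale experiments

Two packaged experiments measure the pipeline's behaviour at the scale of
the emulated study design (sizes chosen to keep a full run in minutes on one
CPU):

* `null_scan_calibration()`: 10,000 independent SNPs, 20 + 20 pools of 20,
  noise SD 0.02, no effect loci; the fraction of SNPs with $p < 0.005$
  should sit in the binomial 99% band [0.0035, 0.0065].
* `locus_recovery_rate()`: 50 replicates of the full pipeline at study
  scale — 443 cases vs 934 controls, 10,000 SNPs, the two-set pool design
  (21 × 20 cases + 30 × 24 controls; 11 × 37 + 10 × 37) — with one seeded
  locus (OR 2.0, MAF 0.2) inside a strong-LD block (`ld_r` 0.95, 15 SNPs,
  5 kb spacing). A replicate counts as a success when a corrected-tier
  validated candidate lies in the recovered block containing the locus.
  All members of the seeded block share the locus MAF: strong allelic LD
  mathematically forces near-equal allele frequencies ($r^2$ between SNPs
  with very different MAFs cannot approach 1), so an equal-MAF block is the
  faithful rendering of "strong LD" in this model.

## Numerical and degenerate-input conventions

* Welch statistics are computed in a centred two-pass form to avoid
  cancellation; identical case and control values give $t = 0$, $p = 1$.
* Fisher p-values follow `fisher.test`'s point-probability convention and
  its relative tolerance; degenerate margins give $p = 1$.
* Positions are 1-based; BED output converts to 0-based half-open
  intervals (`start = start_pos - 1`, `end = end_pos`).
* TSVs are UTF-8, tab-separated, `.` for missing, headers mandatory, no
  quoting. The packaged validated-loci fixture is checksum-guarded and its
  loader additionally accepts typeset scientific notation ("1.5 × 10−7").
* Ties in index-SNP ranking are broken by position after p-value.

## Known limitations

* The QC threshold automates a judgement the original workflow made by
  eye; different thresholds can retain or drop borderline pools.
* The block criterion is tuned to arrays dense enough that adjacent SNPs
  in an LD region sit within 30 kb; on sparser panels it loses power by
  construction.
* The Woolf CI is a normal approximation; its coverage is verified at
  moderate counts but degrades for very sparse tables even with the
  Haldane correction.
* One case group per simulation spec: cross-disease analyses are built by
  running the validation stage twice and combining with `shared_loci()`.
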