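---
title: "Cross-population haplotype fine-mapping with haplofine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population haplotype fine-mapping with haplofine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplofine)
```

## The problem

A genome-wide significant case/control signal usually points at a
linkage-disequilibrium (LD) block tens of kilobases wide, not at a variant.
When the same disease has been genotyped in several populations, the
differing LD patterns can be exploited: each population's most-associated
haplotype covers the causal variant, so the *shared* portion of those
haplotypes — the core haplotype — is a smaller credible region than any
single cohort provides. Comparing the allelic make-up of the frequent
protective (odds ratio < 1) and risk (odds ratio > 1) haplotypes then
narrows the region further: only SNPs whose minor allele rides exclusively
on the protective haplotype can explain a protective signal. haplofine
implements this strategy end to end for biallelic SNP panels, together with
a synthetic multi-population cohort generator used to validate every stage
by parameter recovery.

## Models and procedure

**Single-SNP association.** Case status is modelled by logistic regression
on the additive minor-allele dosage (0/1/2), by maximum likelihood (IRLS,
log-likelihood tolerance 1e-8, at most 50 iterations), reporting the Wald
z-test and a 95% CI with the multiplier fixed at 1.959964 for
reproducibility. Sex enters as a 0/1 covariate (`unknown` = missing, the
sample is dropped); in the pooled ("meta") analysis the population label
enters as indicator variables with the alphabetically first label as the
reference. The pooled fit — a mega-analysis with country as covariate — is
the primary combiner because that is what per-country-covariate logistic
tooling computes; an inverse-variance combiner
(`metaInverseVariance()`) is provided as a cross-check. Conditional scans
add the lead SNP's dosage as a covariate; a test SNP whose dosage is
exactly collinear with a lead SNP (r² = 1) is flagged `collinear` with
p = NA rather than silently absorbing the lead effect.

**QC.** Variants are kept when the folded pooled minor-allele frequency
exceeds `mafMin` (default 0.01) and the exact Hardy–Weinberg test in
controls exceeds `hweMinP` (default 1e-4). The HWE test conditions on the
allele counts and sums the probabilities of all heterozygote counts no more
likely than the one observed (computed by the standard recurrence;
monomorphic sites return p = 1).

**Phasing and LD.** Haplotype frequencies are estimated from unphased
genotypes by EM, with deterministic initialization at the product of
single-SNP allele frequencies. Small windows (≤ 8 SNPs) enumerate all 2^m
haplotypes; larger windows are phased progressively — SNPs are appended one
at a time, each candidate splits in two, candidates below the frequency
floor (default 0.01) are pruned between iterations and the mass
renormalized — followed by a full EM pass to a 1e-10 frequency tolerance.
With the floor at 0 the progressive path reproduces exhaustive EM, which is
asserted against an independent brute-force implementation in the tests.
Two-locus r², D and D′ come from the analogous four-haplotype EM. Haplotype
blocks use the confidence-interval method: a pair is in strong LD when the
likelihood-profile 5th/95th percentile bounds on |D′| reach 0.70 and 0.98,
shows recombination when the upper bound is below 0.90, and a candidate
span is accepted when its outermost pair is strong and ≥ 95% of its
informative pairs are strong (greedy, longest span first). The block
algorithm and thresholds are declared defaults, not values inferred from
any particular dataset.

**Haplotype association.** Each haplotype at or above the frequency floor
is tested one-vs-rest by logistic regression on its expected dosage (the
posterior expected copy count, which is robust to phase uncertainty and
sums to 2 across haplotypes for every individual). Case/control
frequencies are re-estimated by running the EM inside each stratum. In the
joint analysis each population is phased separately — haplotype frequencies
are population-specific — haplotypes are matched by allele string, and one
pooled regression with sex and population indicators is fitted per
haplotype.

**Fine-mapping.** A population enters the haplotype stage when its p-value
at the anchor SNP (the pooled top SNP) is below `round(alpha/k, 3)` — for
six populations 0.05/6 → 0.008, rounded to three decimals so the gate
matches the conventional printed threshold. The strict core is
`[max(block starts), min(block ends)]` with the SNPs present in every
population's top block; consensus mode extends the strict core outward
SNP-by-SNP while every population whose top haplotype covers the flanking
SNP carries the same allele there. Strict is the default; consensus
documents how a core larger than the smallest block can arise and is
clearly labelled in its output. Among the two most frequent core
haplotypes, the one with OR < 1 is designated protective and the one with
OR > 1 risk; if they do not disagree in direction the pipeline stops with
an error rather than guessing. A SNP is *differentiating* when the
protective haplotype carries its minor allele and the risk haplotype its
major allele; the refined interval spans the flagged SNPs. Interval sizes
in kb are truncated (not rounded) to one decimal, the convention under
which a 53,780 bp block prints as 53.7 kb.

**Regulatory prioritization.** BED features are converted to 1-based
inclusive coordinates at the boundary; a SNP overlaps a feature when
`start ≤ pos ≤ end`. Motif disruption scores every placement of a
position-weight matrix covering the SNP on both strands with
`sum(log2(p/background))`, taking the best placement independently for the
reference and alternative allele (sum-aggregation is available); PWMs are
loaded from JASPAR-style text with a pseudo-count of 1e-3 so no entry is
zero — the standard log-likelihood-ratio convention, adopted because
motif-break services do not publish their exact formulas. Ranking is by
distinct feature classes hit (label prefix before the first colon), then
largest |delta|, then position — a total, deterministic order.

## The synthetic generator

`defaultStudyScenario(scale)` emulates the study conditions: six
case/control cohorts (UK 7728/8274, Italy 1486/1270, Netherlands
1150/1173, Spain 1131/662, Poland 521/541, India 497/736, scaled and
rounded with a floor of 1), 14 SNPs in a single LD block, and a pool of
four haplotypes whose per-population frequencies are the published control
frequencies renormalized to the simplex. The common protective haplotype
`CCGATCTGGCGCAT` is causal with per-copy odds ratio 0.75 in the four
European cohorts that share the signal; Poland and India carry the same
pool with no effect, emulating populations whose association at the anchor
SNP is null (their published top SNPs trend in the opposite direction, so
they are modelled as null rather than asserted to match any particular
effect). Five SNP positions are genuine GRCh37 coordinates
(rs7634898, rs6790260, rs4686484, rs2030519, rs12634152); the other nine
are synthetic, interpolated monotonically between those anchors.

Individuals draw two haplotypes i.i.d. from their population pool
(Hardy–Weinberg at the haplotype level, no recombination — the region is a
single block by construction), disease probability is
`plogis(alpha + beta*copies + sexBeta*sex)` with `alpha = qlogis(0.01)`
(~1% prevalence, keeping rejection sampling efficient and realistic), and
sampling proceeds by rejection until the case/control quotas are met — a
retrospective design, so the odds ratio (not the risk ratio) is the
recoverable quantity. Sex is Bernoulli(0.5) with `sexBeta = 0` by default;
genotypes can be masked to missing uniformly. Everything is reproducible
from the seed.

What the generator does **not** model: the residual haplotype diversity of
real cohorts (the four modelled haplotypes carry all the mass, so
panel-derived minor alleles can differ from array-wide ones at a few
sites), genotyping error beyond uniform missingness, recombination within
the region, imputation uncertainty, and population substructure within a
labelled cohort. Passing recovery tests therefore demonstrate that the
pipeline's inference machinery is correct under its own assumptions, not
that those assumptions hold in any particular real dataset.

## Numerical choices and degenerate inputs

* EM: convergence at max frequency change < 1e-10 (two-locus and final
  multi-locus pass), 1e-4 during progressive extension; log-likelihood is
  non-decreasing by construction and asserted in tests. No random
  restarts — initialization is deterministic, so results are reproducible.
* Haplotype report ordering: frequency descending, ties broken
  lexicographically by allele string; top-haplotype selection breaks p-value
  ties by larger |log OR|, then lexicographically.
* Separation in logistic fits (non-convergence or diverging |beta|) yields a
  flagged result with p = NA instead of a spurious estimate.
* Minor alleles are defined on the pooled sample per panel (ties broken by
  the alphabetically later allele) and re-derived after pooling
  populations; population-stratified frequencies may exceed 0.5 and are
  reported unclamped.
* Missing genotypes are excluded pairwise from frequencies, LD and
  regressions, and marginalized in phasing; no imputation is performed.
* When the Bonferroni gate passes a single population, the pipeline uses
  that population's top block as the core region (the intersection operator
  itself requires at least two populations); the mode is recorded as
  `single-population` in the output.
* When the gate passes no population, or the region holds no variants, the
  pipeline terminates cleanly with a status message instead of erroring.

## Problem sizes used by the test-suite

Recovery checks run the full pipeline on 50 scenario replicates at
scale 0.25 (~6,300 individuals each), chosen so that the UK cohort retains
essentially full power at the anchor SNP while the suite stays fast;
type-I calibration uses 600 null replicates of 500 individuals; EM oracle
comparisons use 100 random windows of 2–5 SNPs over 20 individuals, where
exhaustive enumeration is feasible. The acceptance script repeats the
end-to-end recovery on 10 seeded replicates.

## Limitations

Biallelic SNPs only; no indels, dosage genotypes or binary PLINK files.
The EM phaser is windowed (≤ 25 SNPs) and intended for a fine-mapping
region, not chromosome-scale phasing. The block-definition parameters are
conventions, and the consensus core mode is a documented construction, not
an inference. Bayesian credible sets and trans-ethnic random-effects
models are out of scope.
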