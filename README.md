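# haplofine

Cross-population haplotype fine-mapping of case/control association
regions, for statistical geneticists who have a genome-wide-significant
signal inside a linkage-disequilibrium (LD) block and genotypes from
several cohorts, and want to shrink the credible region before functional
follow-up.

## What it computes

Given per-population biallelic SNP panels (VCF or PLINK-style text plus a
phenotype table), haplofine runs:

1. **QC**: pooled MAF > 0.01 and exact Hardy–Weinberg test in controls
   (p > 1e-4).
2. **Association**: per-SNP logistic regression of case status on the
   additive minor-allele dosage *g*,
   `logit P(case) = α + β g + covariates`, per population (sex-adjusted)
   and pooled across populations with sex and country indicators; Wald
   tests, OR = exp(β) with 95% CI. A stepwise conditional scan on the lead
   SNP checks for independent signals.
3. **Phasing/LD**: EM haplotype-frequency estimation from unphased
   genotypes with per-individual phase posteriors; two-locus r² and D′;
   confidence-interval haplotype blocks (strong-LD pair: |D′| bounds
   ≥ 0.70 / ≥ 0.98; block: ≥ 95% of informative pairs strong).
4. **Haplotype association**: one-vs-rest logistic regression on expected
   haplotype dosages, per population and jointly (populations gated by the
   Bonferroni threshold `round(α/k, 3)`, e.g. 0.05/6 → 0.008 at the anchor
   SNP).
5. **Fine-mapping**: the core haplotype — the intersection of each gated
   population's most-associated block — and the *differentiating SNPs*,
   whose minor allele is carried by the protective haplotype (OR < 1) but
   not by the risk haplotype (OR > 1). Their span is the refined region.
6. **Prioritization**: overlap of refined SNPs with regulatory BED
   features and PWM motif-disruption scoring
   (`Δ = best alt log₂-odds − best ref log₂-odds`).

A bundled generator (`defaultStudyScenario()`) simulates six case/control
cohorts (~25,000 individuals at full scale) from a four-haplotype pool
with a shared protective haplotype (per-copy OR 0.75), and writes truth
records so every stage is validated by parameter recovery.

## Worked example

```r
library(haplofine)

cfg    <- defaultStudyScenario(scale = 0.25, seed = 7)
sim    <- simulatePanel(cfg)
panels <- splitByPopulation(sim$panel)
b      <- runPipeline(panels, pipelineConfig())
str(b$summary)
#> $ anchor              : chr "rs6790260"
#> $ anchor_p            : num 3.5e-13
#> $ conditional_min_p   : num 0.257
#> $ gate_threshold      : num 0.008
#> $ gated_populations   : chr "UK"
#> $ core_mode           : chr "single-population"
#> $ core_interval       : chr "chr3:188116907-188121019"
#> $ core_span_kb        : num 4.1
#> $ differentiating_snps: chr [1:7] "rs6790260" "rs6444285" "rs4686483" ...
#> $ refined_interval    : chr "chr3:188117070-188119901"
#> $ refined_span_kb     : num 2.8
```

At a quarter of the full cohort sizes only the UK passes the 0.008 gate on
this seed, so the core is its top block; the protective/risk comparison
still flags the 7 differentiating SNPs and narrows the region to 2.8 kb,
which contains the simulated causal variant. The joint haplotype test on
the core SNPs reads:

```r
b$coreHapAssoc$meta[, c("haplotype", "freq_cases", "freq_controls", "or", "p")]
#>        haplotype freq_cases freq_controls    or        p
#> 3 CCGATCTGGCGCAT     0.4053        0.4906 0.705 2.31e-14   # protective
#> 2 CCCTCTAAATATTC     0.4645        0.3936 1.334 2.16e-10   # risk
#> 1 CACATTAAATACAT     0.0784        0.0687 1.152 9.82e-02
#> 4 TACATTAAATACAC     0.0518        0.0471 1.103 3.40e-01
```

i.e. the protective haplotype sits at 49% in controls vs 41% in cases
(true generating OR 0.75). Stage tables and a machine-readable
`summary.json` are written when `outDir` is given.

See `vignette("haplotype-fine-mapping")` for the models, the generator's
assumptions and the numerical conventions (including why interval sizes
are truncated, not rounded, to one decimal kb).

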