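# poolrfi

Pooled-sequencing screens and pedigree validation of genomic variants
for **residual feed intake (RFI)** in poultry.

Feed is ~70% of the cost of raising a meat chicken, and RFI — the
difference between what a bird eats and what its maintenance and growth
predict — is the accepted efficiency phenotype for selection. This
package reimplements, as tested reusable R code, the full analysis
chain of a pool-seq selection screen for RFI variants:

1. **Phenotype** — fit `FI = b0 + b1·BW^0.75 + b2·WG + rfi` by least
   squares, derive RFI/FCR per bird, select the phenotypic extremes and
   build replicate DNA pools (`fit_rfi`, `select_extremes`,
   `build_pools`, `group_summary`).
2. **Screen** — per-SNP pooled allele frequencies from sync-format
   counts; replicate one-way ANOVA with Benjamini–Hochberg adjustment,
   pairwise pooled F_ST (π-based estimator with the
   min(coverage, chromosomes) correction), and an
   allele-frequency-divergence cutoff; candidates are the conjunction
   (`read_sync`, `screen_sites`, `filter_cascade`).
3. **Annotation** — assign candidates to genes within ±50 kb
   (inclusive, many-to-many) and categorize each SNP down to
   synonymous/missense by strand-aware codon substitution
   (`assign_genes`, `categorize_snp`, `annotation_summary`).
4. **Validation** — in an independent pedigreed population: numerator
   relationship matrix (tabular method), animal-model BLUP breeding
   values `y = Xb + Za + e`, REML variance components, per-SNP Wald
   tests of EBV on dosage, and genotype least-squares means decomposed
   into additive and dominance effects
   `a = (LSM_hom1 − LSM_hom2)/2`, `d = LSM_het − (LSM_hom1 + LSM_hom2)/2`
   (`build_a_matrix`, `solve_blup`, `estimate_variance_components`,
   `wald_snp_test`, `genotype_lsm`, `additive_dominance`).
5. **Expression** — two-group 2^−ΔΔCt comparison with Student's t on
   ΔCt (`ddct`, `group_ttest`).

A first-class **synthetic-data module** (`sim_config`, `simulate_*`)
generates every input with known ground truth — phenotypes with a
pedigree-structured additive model, two-stage pool counts
(chromosomes, then reads), Hardy–Weinberg validation genotypes with
planted additive/dominance effects, and Ct tables — so the whole
pipeline is testable without any sequencing data. `run_pipeline()`
drives everything end to end from one JSON config;
`vignettes/poolrfi-methods.Rmd` documents the models, defaults and
honest limitations.

## Worked example

```r
library(poolrfi)

# the published decomposition convention, verified to printed precision
additive_dominance(35.02, 9.91, 6.20)
#> $a_eff
#> [1] 14.41
#> $d_eff
#> [1] -10.7

# a synthetic discovery flock of 400 birds
cfg <- sim_config(seed = 42, n_birds = 400, n_snps = 2000,
                  n_divergent = 40, delta_p_planted = 0.8)
r <- fit_rfi(simulate_phenotypes(cfg)$phenotypes)
r$fit
#> RFI regression (n = 400): FI = 560.586 + 9.5092 * BW^0.75 + 1.4336 * WG
#>   residual SD = 152.98 g, R^2 = 0.715

ex <- select_extremes(r$records, 48)
group_summary(ex$low, ex$high)[, c(1, 2, 4, 6)]
#>        trait low_mean high_mean  p_value
#> 1        rfi  -255.63     250.7 1.12e-54
#> 2        dfi    91.20     110.4 2.43e-19
#> 3 initial_bw   826.47     826.5 1.00e+00
#> 4   final_bw  1373.82    1396.4 4.81e-01
#> 5        adg    19.55      20.4 4.30e-01
#> 6        fcr     4.82       5.7 4.41e-05
```

The extremes differ strongly in RFI, intake and FCR but not in body
weight or gain — the signature of a well-formed RFI contrast (eating
less at equal growth). Screening the pooled counts:

```r
sc <- screen_sites(simulate_pool_counts(cfg)$sync,
                   screen_config(delta_mode = "fixed"))
sc
#> pooled screen: 2000 sites in, 1900 scored
#>   excluded: 0 triallelic/invalid-ref, 0 low-coverage, 100 high-coverage
#>   q < cutoff: 42; + F_ST top set: 38; + delta_p > 0.350: 38 candidates
```

38 of the 40 planted divergent loci survive all three filters. The
bundled published reference table of genotype least-squares means
recomputes every printed additive/dominance effect:

```r
head(decompose_lsm_table()[, c("snp", "hom1", "het", "hom2",
                               "a_eff", "d_eff")], 4)
#>              snp hom1 het hom2   a_eff   d_eff
#> 1     rs15213482   AA  AG   GG  14.410 -10.700
#> 2    rs318069175   AA  AG   GG -12.950  -8.310
#> 3 chr2_145118378   CC  TC   TT -12.645   0.175
#> 4    rs315791208   AA  AG   GG  -8.815  12.435
```

End to end, from a config:

```r
r <- run_pipeline(system.file("extdata", "demo_config.json",
                              package = "poolrfi"),
                  out_dir = "demo_out")
# or from a shell:
#   Rscript -e 'poolrfi::poolrfi_cli()' run --config cfg.json --out out/
#   Rscript -e 'poolrfi::poolrfi_cli()' simulate --config cfg.json --out data/
```

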