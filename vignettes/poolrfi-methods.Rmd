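---
title: "Methods: pooled screens and pedigree validation for residual feed intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled screens and pedigree validation for residual feed intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

poolrfi implements a complete desk-scale pipeline for mapping genomic
variants associated with residual feed intake (RFI) in poultry from
pooled whole-genome sequencing of phenotypic extremes, followed by
validation in an independent pedigreed population. This vignette is the
package's own account of the models, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open.

## 1. The RFI phenotype

Residual feed intake is the part of feed intake not explained by
maintenance and growth. For a test window of `test_days` days the
package fits, by ordinary least squares over the whole flock,

    FI = b0 + b1 * BW^0.75 + b2 * WG + rfi

where `FI` is total feed intake (g), `BW^0.75` the metabolic body weight
at the start of the test (g^0.75, computed on initial body weight), and
`WG` the weight gain (g). The residual is the bird's RFI; by
construction it sums to zero and is uncorrelated with the regressors,
which the tests assert at 1e-8 relative tolerance. A lower RFI means a
more efficient bird. The feed conversion ratio (FCR) is computed per
bird as daily feed intake over average daily gain and then averaged;
group means are therefore means of per-bird ratios, not ratios of
means.

One pooled regression over both sexes is the default. The discovery
design mixes sexes within pools, so a single fit is the consistent
reading; `fit_rfi(by_sex = TRUE)` is available for sensitivity
analysis. Extreme-group selection takes the `n_per_tail` smallest and
largest residuals with a deterministic tie-break on bird id, and
replicate pools are filled round-robin by RFI rank (within sex when
sex-balanced pooling is requested), so the replicate pools are matched
on the phenotype distribution.

## 2. The pooled screen

Input is a sync-format table of per-pool allele counts
(`A:T:C:G:N:del` per pool per site). The screen is SNP-only: N and
deletion columns are parsed but ignored. At each site the reference
base plus the most frequent non-reference base define the allele pair;
sites with a residual third allele above 5% of reads are excluded
(pooled F_ST and frequency divergence are two-allele quantities).

Per-site statistics, all computed on every scored site:

* **Replicate ANOVA.** One-way ANOVA of the per-pool alternate-allele
  frequencies with the phenotypic group as factor; with 2 x 3 pools the
  F statistic has df (1, 4). Frequencies enter untransformed and
  unweighted; sites with zero between- and within-group variance are
  degenerate and get p = 1. P-values are Benjamini-Hochberg adjusted
  over all scored sites.
* **Pooled F_ST.** Read counts are aggregated over each group's
  replicate pools. For group g with frequency p_g, coverage c_g and n_g
  pooled diploids, `pi_g = C_g/(C_g - 1) * 2 p_g (1 - p_g)` with
  `C_g = min(c_g, 2 n_g)`; the total diversity uses the combined counts
  with the same correction, and
  `F_ST = max(0, (pi_T - mean(pi_L, pi_H)) / pi_T)`. The min(coverage,
  chromosomes) correction acknowledges that a pool cannot carry more
  information than its chromosomes. A Karlsson-style ratio estimator is
  available as an option; any estimator monotone in frequency
  divergence yields asymptotically the same top-5% set.
* **Frequency divergence.** `delta_p = |p_bar_L - p_bar_H|`, the
  absolute difference of group mean pool frequencies.

**Candidate filter.** A site is a candidate when all three hold: BH
q < 0.05; F_ST at or above the 95th percentile of all scored sites
(boundary ties kept); and delta_p above a threshold that is, by
default, the median divergence within the F_ST top set (mirroring a
data-derived 35% rule), or a fixed value. The rank percentile and the
divergence threshold are computed over *all* scored sites rather than
over ANOVA survivors: published top-5% tallies are whole-set tallies,
and a survivor-only denominator collapses the rank filter whenever the
ANOVA passes few sites. The threshold report records both derived
thresholds and the count surviving each cumulative step, so either
reading can be reconstructed.

**Coverage filters.** Sites need `min_coverage` (default 4) usable
reads in every pool; sites where any pool exceeds the 99th percentile
of pool coverages are excluded as collapsed-repeat suspects, the
per-pool max-coverage convention of standard pool-seq tooling. In the
synthetic world (Poisson 20x) this cap removes about 1% of
observations per pool and is the main source of randomly lost sites.

### Why the BH step has no power in a sparse synthetic world

This is the package's most important honest limitation, and it is the
reason one acceptance criterion is deliberately left red. With three
replicate pools per group the ANOVA has df (1, 4), so even a fixed
between-group difference of 0.8 at 20x coverage yields p-values around
1e-4 to 1e-3 — the F distribution's tail simply cannot produce smaller
values at that coverage. Benjamini-Hochberg is adaptive: its effective
threshold is about `0.05 * (fraction of sites passing) `. When 6% of
millions of real SNPs are genuinely differentiated (selection plus
drift between groups of 48 birds plus pervasive linkage
disequilibrium), the threshold rises to ~3e-3 and hundreds of
thousands of sites pass. When 5 loci in 10,000 are planted and the
rest are exactly null — the synthetic stated world, which deliberately
excludes LD — the threshold stays near Bonferroni scale (~2.5e-5) and
no site can pass. Measured over 100 seeded replicates, the
all-five-planted-as-candidates rate is 0/100, while the F_ST-top-5%
plus divergence filters alone recover all five in 80/100 (the
remainder lost to the random 99th-percentile coverage cap). The
package does not redefine "candidate" to hide this; the module tests
demonstrate full-cascade power in the dense regime (50 planted of
1,000) where BH genuinely adapts.

## 3. Gene assignment and variant categorization

Candidates are assigned to every gene whose span lies within 50 kb
(inclusive at exactly 50,000 bp; the mapping is many-to-many, matching
published gene counts that exceed a one-gene-per-SNP reading). One
category per SNP with precedence CDS > non-coding exon > intron >
upstream/downstream (nearest gene, 5' side = upstream respecting
strand) > intergenic. Codon-level calls build the codon strand-aware
from the reference sequence, substitute reference and alternate
alleles, and translate under the standard genetic code: synonymous if
the amino acid is unchanged, missense if both codons code and differ,
and `exon_other` otherwise — stop gain/loss is deliberately kept out of
the missense tally, matching categorization schemes that count only
synonymous and missense classes. Frame-ambiguous CDS hits (or hits
without reference sequence) also fall back to `exon_other`.

## 4. Validation in a pedigreed population

The validation model is the standard animal model
`y = Xb + Za + e` with sex as the fixed effect and
`a ~ N(0, sigma2_a A)`, where A is the numerator relationship matrix
built by the tabular method. Breeding values are BLUP solutions of
Henderson's mixed-model equations, solved densely with an explicit
check that the relative residual of the system is below 1e-8.

**Variance components.** The restricted likelihood of the animal model
depends on the data only through the marginal covariance
`sigma2_a ZAZ' + sigma2_e I`. The package therefore eigendecomposes
`ZAZ'` once and maximizes the profile restricted log-likelihood over
the heritability by one-dimensional search, profiling the total
variance out in closed form. This reaches the same stationary point an
EM-REML iteration converges to, in a fraction of the time, with no
stall risk near the boundary; estimates with h2 < 1e-3 are flagged as
boundary solutions. A fixed user-supplied h2 skips estimation.

**Association.** Each SNP is tested by regressing the EBVs on allele
dosage; the Wald statistic `(beta/se)^2` is referred to chi-square with
1 df. EBVs enter as observations without deregression — a documented
simplification; under a permutation null the Wald p-values are uniform
(asserted by Kolmogorov-Smirnov at alpha 0.01). No multiplicity
correction is applied in validation (raw p < 0.05), matching the
candidate-confirmation design; BH is available.

For significant SNPs the genotype effect on raw RFI is decomposed via
the fixed-effects model `y ~ sex + genotype`: least-squares means are
model predictions averaged over sex levels, pairwise t contrasts give
letter groupings at 0.05 (lowercase) and 0.01 (uppercase), and

    a = (LSM_hom1 - LSM_hom2) / 2,  d = LSM_het - (LSM_hom1 + LSM_hom2) / 2

with hom1 the alphabetically first homozygote class — the convention
that reproduces every published effect in the bundled reference table
to its printed precision.

## 5. Expression comparison (2^-ddCt)

Per sample `dCt = Ct_target - Ct_reference`; per gene
`ddCt = dCt - mean(dCt of the reference group)` and relative expression
`2^-ddCt`, so the reference group's geometric mean is exactly 1. The
two-group test is an equal-variance Student t on dCt — the log2 scale,
where approximate normality is defensible — with stars shown on fold
changes. Amplification-efficiency correction and multi-reference
normalization are out of scope.

## 6. The synthetic world

Every input is generated by `sim_config()` plus the `simulate_*`
generators, pure functions of (config, seed). Defaults are the stated
study design: 400 discovery birds phenotyped 28 days; 48 extremes per
tail; 2 groups x 3 pools x 16 birds at Poisson 20x coverage; a
validation cohort of 779 (345 males, 434 females) genotyped at 191
SNPs; 8 qPCR replicates per group. Where the design gives no number,
values were fixed once at realistic broiler magnitudes and not
revisited: intake coefficients b = (500 g, 10 g/g^0.75, 1.4 g/g) give
~2.8 kg intake over the test; RFI variance 22,500 g^2 (SD 150 g) split
as h2 = 0.3 (sigma2_a = 6,750, sigma2_e = 15,750), consistent with
moderate published heritabilities and with extreme-group separations of
a few hundred grams; initial body weight log-normal around 820 g and
gain around 540 g.

Pool counts are drawn in two stages — 32 chromosomes per pool
binomially from the group frequency, then reads binomially from the
realized pool frequency at truncated-Poisson coverage — reproducing the
extra-binomial variance that pooled F_ST corrections assume. A
consequence worth knowing: even at infinite coverage the per-pool read
frequency converges to the realized 32-chromosome frequency, not to the
group frequency; the corresponding test asserts exactly that.

What the generator does **not** emulate: linkage disequilibrium (loci
are independent), sequencing error, chromosome-specific enrichment of
divergent loci, selection-induced genome-wide drift between the extreme
groups, and inbreeding (Mendelian-deviation variance uses F = 0, exact
for the founders-only matings generated). A green test therefore
establishes correctness of the statistics on exchangeable independent
loci — not that the screen would have the published power on a real
genome, which the sparse-world analysis above makes explicit.

## 7. Numerical choices and degenerate inputs

* Ties: bird-id ascending everywhere a tie needs breaking; F_ST
  boundary ties are all retained (inclusive rule) and counted.
* Degenerate ANOVA sites (no variance at all) get p = 1 and a flag;
  monomorphic sites get F_ST 0 and a flag; monomorphic SNPs in
  validation get Wald p = 1 and a flag; Wald p is clamped at 1e-300.
* The BLUP solver refuses systems whose reciprocal condition is below
  1e-14 and verifies its solution to 1e-8 relative residual.
* REML searches h2 in [1e-6, 1 - 1e-6] with optimize() at 1e-9
  tolerance; eigenvalues of ZAZ' are clamped at 0.
* Coordinates are 1-based inclusive everywhere (sync, GFF3, VCF,
  internal); no half-open conversion is exposed.
* Config files are JSON (no YAML parser in the supported stack); every
  pipeline output carries the config md5 in a comment header, and
  writes are atomic (temp file, then rename).

## 8. Known limitations

Beyond the sparse-world BH analysis above: EBVs are not deregressed
before association; transcript-isoform-specific consequences, UTR and
splice-site classes are not distinguished; the F_ST estimator is a
single-locus estimator (no sliding windows); and the pipeline is
single-process by design — at hundreds of thousands of sites every
stage is vectorized and desk-scale.
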