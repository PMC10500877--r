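---
title: "Mapping polygenic selection with a generation proxy: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polygenic selection with a generation proxy: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Commercial breeding programs apply index selection to quantitative traits.
Over a decade this moves allele frequencies by small, consistent amounts at
many loci — polygenic selection — without the hard-sweep signatures that
classical selection scans look for. Generation proxy selection mapping
(GPSM) turns the problem into a genome-wide association study in which the
*dependent* variable is the animal's birth date: a SNP whose genotype
predicts when an animal was born is a SNP whose frequency has been moving
through time. The central difficulty is confounding: animals are related,
populations are structured, and genotyping effort changed over the years.
All three are absorbed by a genomic relationship matrix (GRM) in a mixed
linear model, so that only frequency change in excess of what
relatedness/drift explains is declared significant.

`gpsmr` implements the whole chain: genotype input and QC, the GRM,
variance components by AI-REML, the per-SNP mixed-model scan with Storey
q-values, a gene-drop simulation null, and a synthetic breeding-program
generator that makes every stage testable without proprietary data.

## The generation proxy (AGE)

`AGE = 12 (birth_year - 2006) + (birth_month - 1)`: whole months between
the birth month and a January 2006 epoch (`compute_age()`); animals born
earlier get negative values. Day-of-month is ignored because breeding
records carry birth month. Shifting all birth dates by k months shifts AGE
by k and changes nothing downstream (the intercept absorbs it).

## Models

**Variance components.** The null model is

    y = 1 mu + g + e,   g ~ N(0, G sigma_g^2),  e ~ N(0, I sigma_e^2)

with y the AGE vector and G the Yang et al. GRM (off-diagonals
`mean[(x_j - 2p)(x_k - 2p) / 2p(1-p)]`, diagonals
`1 + mean[(x^2 - (1+2p)x + 2p^2) / 2p(1-p)]`, allele frequencies estimated
in the analyzed subset, per-pair deletion for missing genotypes). The
quantity of interest is PVE = sigma_g^2 / (sigma_g^2 + sigma_e^2): the
share of variance in birth date tracked by genome-wide genotype. It is a
demography/pedigree readout, *not* a trait heritability — a deep, closed
pedigree with temporally clustered genotyping produces PVE above 0.8 even
under pure drift, which the gene-drop experiments reproduce.

Estimation is average-information REML. Because V = G sigma_g^2 +
I sigma_e^2 shares eigenvectors with G, the univariate fit performs one
eigendecomposition of G and then O(n) work per iteration. The AI step is
guarded by step-halving on the restricted likelihood with an EM-REML
fallback, so accepted iterations never decrease the likelihood. The
likelihood-ratio test of sigma_g^2 = 0 uses the 50:50 mixture of a point
mass and chi-squared(1), the correct reference for a variance component on
its boundary.

**Bivariate model.** For two populations with no animal recorded in both,
the stacked covariance is

    V = | G11 s_g1 + I s_e1      G12 s_g12        |
        | G21 s_g12              G22 s_g2 + I s_e2 |

with residual covariance structurally zero. The genetic correlation of AGE,
r_G = s_g12 / sqrt(s_g1 s_g2), measures whether the same loci move in the
same direction over time in both populations. The fit is dense AI-REML with
step-halving (positive-definiteness checked by Cholesky); r_G = 0 is tested
by a 1-df likelihood ratio against the constrained fit (an interior null,
so no boundary mixture). r_G is reported clamped to [-1, 1] with a warning
if the unconstrained ratio falls outside.

**The scan.** For each SNP,

    y = mu + x_s b_s + g + e

is fitted by generalized least squares under the *fixed* covariance
V-hat = G sigma_g2-hat + I sigma_e2-hat taken from the null fit
(EMMAX-style): the per-SNP variance components are not of interest and
re-estimating them would multiply the cost by orders of magnitude while
moving p-values in the third decimal. The candidate SNP stays in the GRM
(no leave-one-chromosome-out), matching standard mixed-linear-model
association behaviour. One rotation of the genotype matrix into the
eigenbasis of G makes each SNP an O(n) weighted regression; p-values are
Wald chi-squared(1). Missing genotypes are mean-imputed per SNP (post-QC
missingness is at most 10%), keeping the single decomposition valid for
every SNP. A SNP with zero variance after imputation is reported with
b = 0, p = 1 and a flag.

**Multiple testing.** Storey q-values with the smoother pi0 estimate
(lambda grid 0.05–0.95 in steps of 0.05, cubic smoothing spline with 3 df,
evaluated at lambda = 0.95, clamped to (0, 1]), monotonized from the
largest p-value down; tied p-values get equal q-values. Below 100 p-values
the smoother is unstable, so pi0 = 1 (Benjamini–Hochberg) is used with a
warning. Selection is called at q < 0.10.

**Descriptive rate of change.** `af_change_per_year()` reports the
absolute OLS slope of per-sample allele frequency (dosage/2) on birth year
(AGE/12). No formula for this quantity is standard; plain OLS was chosen
as the most transparent definition, and it is deliberately *not* adjusted
for relatedness — the contrast with the mixed-model effect is informative.
Effect-size summaries report the SD of SNP effects both over all SNPs and
over significant SNPs, since "SDs above the mean" statements depend on
that choice.

## The gene-drop null

The null hypothesis behind every significance call is genetic drift
through the actual pedigree. `simulate_founder_pool()` draws site
frequencies i.i.d. from a U-shaped Beta(0.5, 0.5) truncated to
[0.01, 0.99] and founder haplotypes as independent Bernoulli draws (the
pool is in linkage equilibrium); fixed sites are redrawn. The coalescent
founder simulation used with commercial data is intentionally replaced by
this i.i.d.-site generator: the drift-null contract needs a realistic
frequency spectrum, not realistic founder LD. Consequences are discussed
under Limitations.

Pedigree founders (and every unknown-parent slot, which is treated as a
new founder) receive distinct pool diplotypes sampled without replacement
(`assign_pedigree_founders()`); two founder schemes span the extremes of
population divergence — one shared pool ("method 1", recent divergence)
versus independently seeded pools per population ("method 2", unrelated
populations). `gene_drop()` then transmits haplotypes down the pedigree:
per meiosis and chromosome the crossover count is Poisson with mean equal
to the chromosome map length (1 Morgan per autosome, uniform — the site
map specifies only physical evenness), breakpoints uniform, no
interference and no obligate chiasma, and recombination is resampled for
every meiosis. Mendelian consistency is asserted in the tests (zero trio
violations), heterozygosity decays at the pedigree inbreeding rate on a
full-sib-mating test pedigree, and per-site frequency-on-generation slopes
are centred at zero over replicates.

`extract_array()` mimics array genotyping: the genotyped animals' dosages
at a uniform random subset of sites segregating in the extracted sample,
with a MAF >= 0.01 re-qualification applied by default (`requalify`),
since a real array analysis would re-run QC on the extracted sample.

## The synthetic breeding program

`generate_pedigree()`/`simulate_selection()` emulate a closed nucleus
line: discrete generations, truncation selection of the top fractions of
boars and gilts on a criterion = TBV + noise with
cor(criterion, TBV) = `index_accuracy`, where TBV is the sum of causal
dosages times N(0, `causal_effect_sd`^2) effects at `n_causal_loci` loci.
The multi-trait selection indices of real programs are collapsed into this
single accuracy knob — it is the lever that distinguishes a hard-driven
terminal line from a maternal line spreading pressure over many traits.
Defaults (chosen once, as plausible for a desk-scale pig nucleus):

| parameter | default | rationale |
|---|---|---|
| `n_generations` | 10 | a decade-scale program at pig turnover |
| `n_founder_sires` / `n_founder_dams` | 25 / 150 | small closed nucleus |
| `litter_size`, `litters_per_dam` | 7, 1 | pig litters, one per cycle |
| `sires_selected_frac` / `dams_selected_frac` | 0.10 / 0.30 | strong male, moderate female truncation |
| `generation_interval_months` | 27 | pigs turn over in 2–2.5 years |
| `birth_jitter_sd` | 3 months | farrowing spread; approximates overlap |
| `n_causal_loci`, `causal_effect_sd` | 50, 1 | polygenic index target |
| `index_accuracy` | 0.7 | realistic evaluation accuracy; 0 = drift |
| genotyping scheme | left-skewed | platform volume grew over the years |

With `index_accuracy = 0` the ranking is pure noise and the generator is
the same code path as drift-mode pedigree construction. Genotyped animals
are sampled with weights increasing in birth year (squared year rank), so
the AGE distribution is left-skewed like commercial SNP platforms; a
uniform scheme is available for calibration contrasts. Founder birth is
placed in mid-1997 so that a 10-generation run puts genotyped cohorts in
the 2010s relative to the January 2006 epoch.

What the generator does **not** emulate: founder linkage disequilibrium
(the pool is in LE; early-generation LD is therefore entirely
pedigree-generated), truly overlapping generations (approximated by birth
jitter), multi-trait economic indices, BLUP evaluation inside the
generator, mutation, and sex chromosomes. Passing tests therefore
demonstrate correct behaviour under drift + pedigree structure + single
index truncation selection, not under every feature of commercial data.

## Numerical choices

- QC order: SNP call rate >= 0.90, then sample call rate >= 0.90, then
  MAF >= 0.01 (recomputed after sample removal). The order is not forced
  by anything; it is fixed and the report is stepwise so other orders can
  be audited. QC is idempotent. When several population subsets are
  analyzed, QC is per subset (each subset re-filters its own data).
- Purity filter: purebred animals with own-breed ancestry below 0.95 are
  removed; exactly 0.95 is retained ("less than" semantics); crossbreds
  are never removed.
- GRM eigenvalues below 1e-8 are clipped to 1e-8 (deep pedigrees produce
  numerically singular GRMs); the clip count is reported.
- REML: start at sigma_g^2 = sigma_e^2 = var(y)/2; converge when the
  restricted log-likelihood changes by less than 1e-8; cap at 100
  iterations; variances floored at 1e-6 var(y). The floor means a
  boundary fit can sit within ~1e-5 log-likelihood units of the exact
  sigma_g^2 = 0 optimum.
- Wald (not score) tests in the scan; p-values floored at the smallest
  positive double so they stay in (0, 1].
- Annotation windows are symmetric +/-100 kb, boundary inclusive,
  strand-agnostic, measured to the feature body (not the TSS).
- All generators are pure functions of (configuration, seed); derived
  sub-seeds stay below 2^31.

## Problem sizes used by the test suite

The package's reference experiment (also run by `scripts/acceptance.R`) is
sized for a single desktop core: a drift pedigree of about 13,700 animals
(10 generations), 3,000 genotyped, and per replicate a 1,000-founder pool
at 36,000 sites from which a 20,000-SNP array is extracted; five
replicates. Under these conditions the pooled false-positive rate at
q < 0.10 is at or below 0.02%, the PVE of AGE falls in the mid-0.8s to
low-0.9s from pedigree structure alone, and the Kolmogorov–Smirnov
statistic of null p-values against the uniform stays below 0.02 for both
left-skewed and uniform genotype sampling. Parameter-recovery checks use
n = 1000 (univariate, PVE 0.9) and n = 400 (bivariate, r_G 0.8); the
power check uses the default selection scenario at 7,200 sites with 2,000
genotyped animals and a 5,000-SNP array, where significant SNPs concentrate
within 1 Mb of the 50 causal loci (Fisher p < 0.01 per replicate). Full
commercial scale (tens of thousands of animals, 38k–46k SNPs, 90,000-site
pools of 5,000 founders) is the function-default configuration and runs
the same code paths.

## Limitations

- The founder pool has no LD, so the drift null may be slightly
  optimistic about long-range allele-frequency covariance among founders;
  with array-density SNP sets and pedigree-dominated structure this is a
  second-order effect, but it is the first thing to revisit with real
  data.
- EMMAX-style fixed variance components understate per-SNP uncertainty by
  a hair for SNPs with very large effects; exact per-SNP REML would change
  p-values in the third decimal at two orders of magnitude more cost.
- The bivariate genetic covariance is weakly identified when the two
  populations share almost no genomic relationship (independent founder
  pools at small n): estimates are then noisy with honest, large standard
  errors.
- PVE standard errors come from the inverse AI matrix via the delta
  method; they are asymptotic and can be optimistic in small samples.
- `af_change_per_year` is an unadjusted regression; it is descriptive and
  should not be used for inference.
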