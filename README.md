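# gpsmr — generation proxy selection mapping

Breeding programs move allele frequencies a little, at many loci, every
generation. `gpsmr` detects this *polygenic selection* in genotyped,
pedigreed populations (its defaults are shaped around commercial pig
lines) by running a genome-wide association study in which the dependent
variable is the animal's **birth date**: SNPs whose genotypes predict when
an animal was born are SNPs whose frequencies have been changing over
time. It is aimed at quantitative geneticists working with livestock SNP
array data who want a self-contained, tested R implementation of the whole
pipeline — including the simulation machinery needed to ask "would I have
seen this under drift alone?"

## The model

With `y` the vector of AGE values (months between each animal's birth
month and a January 2006 epoch), the per-SNP model is

```
y = mu + x_s b_s + Z g + e,   g ~ N(0, G sigma_g^2),  e ~ N(0, I sigma_e^2)
```

where `x_s` is the SNP-s dosage vector and `G` the Yang et al. genomic
relationship matrix. The GRM soaks up relatedness, population structure
and uneven genotype sampling over time, so `b_s` (months per allele copy)
captures only excess association of genotype with birth date. Variance
components come from one null AI-REML fit and are then held fixed for the
scan (EMMAX-style GLS via a single eigendecomposition of `G`); Wald
p-values are converted to Storey q-values and SNPs with `q < 0.10` are
called as responding to selection. The null fit's
`PVE = sigma_g^2 / (sigma_g^2 + sigma_e^2)` summarizes how strongly
genotype tracks time — a readout of demography and pedigree structure, not
a trait heritability. A bivariate version estimates the genetic
correlation of AGE between two populations,
`r_G = sigma_g12 / sqrt(sigma_g1^2 sigma_g2^2)` (shared selection
objectives push `r_G` above 0).

The null model is explicit: founder haplotypes simulated from a U-shaped
site-frequency spectrum are *gene-dropped* through the pedigree by
Mendelian segregation with Poisson recombination, an array is extracted,
and the full pipeline is re-run. Genotypes built this way carry drift and
pedigree structure but no selection, so every significant call there is a
false positive.

## Worked example (synthetic breeding program)

```r
library(gpsmr)

# a 10-generation nucleus line under truncation selection on a
# 50-locus polygenic index (accuracy 0.7), then array genotyping
cfg <- breeding_config()
sim <- simulate_selection(cfg, n_sites = 7200, seed = 201)
gt  <- assign_genotyping(sim$pedigree, "left_skewed", 2000, seed = 202)
ds  <- extract_array(sim, sim$pedigree, gt$id, n_array_snps = 5000,
                     seed = 203)

fit <- gpsm(ds)       # GRM + null REML + per-SNP scan + q-values
print(fit)
```

```
GPSM scan: 2000 samples, 5000 SNPs
  PVE of AGE = 0.825 (SE 0.016)
  significant SNPs (q < 0.10): 11 (0.220% of loci)
  mean |SNP effect| among significant: 13.28 months/allele
```

PVE of 0.83 says genotype tracks birth date strongly — expected in a deep
closed pedigree even without selection. The 11 significant SNPs (0.22% of
loci) are the selection signal; in this simulation the truth is known, and
they cluster near the 50 causal loci (`sim$causal`). Effects are in months
per allele copy: a SNP with effect +13 months has its counted allele
enriched in later-born animals. `plot(fit, "manhattan")`,
`plot(fit, "qq")` and `summary(fit)` give the usual views;
`run_genedrop_null()` reruns everything on drift-only genotypes for the
same pedigree, where the significant count drops to (essentially) zero.

Real PLINK data follow the same path: `read_plink()` → `qc_filter()` →
(optionally `purity_filter()`) → `gpsm()`; `annotate_windows()` reports
features within ±100 kb of significant SNPs, and `reml_bivariate()` /
`run_bivariate()` handle two-population genetic correlations.

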