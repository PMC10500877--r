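Package: gpsmr
Title: Generation Proxy Selection Mapping in Pedigreed Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects polygenic selection in genotyped breeding populations by
    regressing SNP genotype on birth date (generation proxy selection mapping,
    GPSM). Provides PLINK binary genotype input/output with quality control,
    genomic relationship matrices (Yang et al. estimator) and their principal
    components, average-information REML for univariate (proportion of
    variance in birth date explained by SNPs) and bivariate (cross-population
    genetic correlation) mixed linear models, an EMMAX-style single-SNP scan
    with Storey q-value false-discovery-rate control, gene-drop pedigree
    simulation as the genetic-drift null model, a synthetic multi-generation
    breeding-program generator with truncation selection on a polygenic index,
    and window-based annotation of significant SNPs against GFF feature
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
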