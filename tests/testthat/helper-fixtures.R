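# shared fixtures and a per-run cache so expensive simulations are built
# once and reused across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# random genotype dataset in linkage equilibrium
make_geno <- function(n, m, seed = 1, miss_rate = 0, population = "P",
                      age_months = NULL, maf_range = c(0.05, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  repeat {   # keep every SNP polymorphic in the finite sample
    f <- colMeans(X) / 2
    bad <- which(f == 0 | f == 1)
    if (!length(bad)) break
    X[, bad] <- rbinom(n * length(bad), 2L, rep(p[bad], each = n))
  }
  if (miss_rate > 0) X[sample(length(X), round(miss_rate * length(X)))] <- NA
  if (is.null(age_months)) age_months <- sample(0:170, n, replace = TRUE)
  chrom <- sort(rep_len(1:18, m))
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     chrom = chrom,
                     pos_bp = as.integer(unlist(lapply(
                       table(chrom), function(k) seq_len(k) * 1000L))),
                     allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("id%05d", seq_len(n)),
                        population = rep_len(population, n),
                        birth_month = age_to_month_chr(age_months),
                        age_months = as.integer(age_months),
                        stringsAsFactors = FALSE)
  geno_data(X, snps, samples)
}

# "YYYY-MM" for an AGE offset (test-side mirror of the epoch arithmetic)
age_to_month_chr <- function(age) {
  tot <- 2006L * 12L + as.integer(age)
  sprintf("%04d-%02d", tot %/% 12L, tot %% 12L + 1L)
}

# minimal reml_fit stand-in with fixed variance components, for scan tests
fake_vc <- function(G, sigma_g2, sigma_e2) {
  Gm <- if (inherits(G, "grm")) G$values else as.matrix(G)
  eg <- eigen(Gm, symmetric = TRUE)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 n = nrow(Gm), eigen_U = eg$vectors,
                 eigen_values = pmax(eg$values, 1e-8)),
            class = "reml_fit")
}

# dense GLS oracle: per-SNP mixed-model solve with an explicit V inverse
dense_gls_oracle <- function(x, y, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  b <- solve(XtViX, crossprod(X, Vi %*% y))
  se <- sqrt(solve(XtViX)[2, 2])
  c(beta = b[2], se = se)
}

# brute-force Benjamini-Hochberg (pi0 = 1) oracle
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i)
    min(1, min((m * p / r)[p >= p[i]])), 0)
}

# the acceptance-scale drift-null experiment (shared across tests)
acceptance_null_run <- function() cached("null_run", {
  cfg <- breeding_config()
  ped <- generate_pedigree(cfg, seed = 101)
  gt <- assign_genotyping(ped, "left_skewed", 3000, seed = 102)
  run_genedrop_null(ped, gt$id, n_replicates = 5, pool_founders = 1000,
                    n_sites = 36000, n_array_snps = 20000, seed = 103)
})

# one uniform-sampling drift replicate for the calibration contrast
# (only the association table is cached; the fit itself is large)
uniform_null_fit <- function() cached("uniform_null", {
  cfg <- breeding_config()
  ped <- generate_pedigree(cfg, seed = 101)
  gt <- assign_genotyping(ped, "uniform", 3000, seed = 104)
  pool <- simulate_founder_pool(1000, 36000, seed = 105)
  asg <- assign_pedigree_founders(pool, ped, "method1_shared", seed = 106)
  dr <- gene_drop(asg, ped, seed = 107, keep = gt$id)
  ds <- extract_array(dr, ped, gt$id, 20000, seed = 108)
  rm(pool, asg, dr); gc(verbose = FALSE)
  fit <- gpsm(ds)
  out <- list(assoc = fit$assoc, pve = fit$vc$pve)
  rm(fit, ds); gc(verbose = FALSE)
  out
})

# 10,000 full-sib trios from one mating, for segregation checks
trio_drop <- function() cached("trio_drop", {
  n_off <- 10000
  ped <- data.frame(
    id = c("sire", "dam", sprintf("off%05d", seq_len(n_off))),
    sire = c(NA, NA, rep("sire", n_off)),
    dam = c(NA, NA, rep("dam", n_off)),
    birth_month = c("2008-01", "2008-01", rep("2010-06", n_off)),
    population = "P", generation = c(0L, 0L, rep(1L, n_off)),
    stringsAsFactors = FALSE)
  pool <- simulate_founder_pool(10, 90, seed = 111)
  asg <- assign_pedigree_founders(pool, ped, "method1_shared", seed = 112)
  list(drop = gene_drop(asg, ped, seed = 113), ped = ped, pool = pool,
       assignment = asg)
})

# one selection-scenario replicate at the default synthetic scale
power_replicate <- function(seed) {
  cfg <- breeding_config()
  sim <- simulate_selection(cfg, n_sites = 7200, seed = seed)
  gt <- assign_genotyping(sim$pedigree, "left_skewed", 2000, seed = seed + 1)
  ds <- extract_array(sim, sim$pedigree, gt$id, 5000, seed = seed + 2)
  causal <- sim$causal
  rm(sim); gc(verbose = FALSE)
  fit <- gpsm(ds)
  near <- mapply(function(ch, pos) {
    cs <- causal[causal$chrom == ch, ]
    nrow(cs) > 0 && min(abs(cs$pos_bp - pos)) <= 1e6
  }, fit$assoc$chrom, fit$assoc$pos_bp)
  out <- list(assoc = fit$assoc, near = near, causal = causal)
  rm(fit, ds); gc(verbose = FALSE)
  out
}
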