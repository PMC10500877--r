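test_that("drift pedigrees are well-formed and deterministic", {
  cfg <- breeding_config(n_generations = 3, n_founder_sires = 5,
                         n_founder_dams = 10, litter_size = 4)
  ped <- generate_pedigree(cfg, seed = 100)
  expect_identical(ped, generate_pedigree(cfg, seed = 100))
  expect_false(identical(ped, generate_pedigree(cfg, seed = 101)))
  founders <- ped[ped$generation == 0, ]
  expect_true(all(is.na(founders$sire) & is.na(founders$dam)))
  expect_identical(nrow(founders), 15L)
  for (g in 1:3) {
    off <- ped[ped$generation == g, ]
    prev <- ped$id[ped$generation == g - 1]
    expect_true(all(off$sire %in% prev))
    expect_true(all(off$dam %in% prev))
    # parents born before offspring
    pb <- compute_age(ped$birth_month[match(off$sire, ped$id)])
    expect_true(all(pb < compute_age(off$birth_month)))
  }
  expect_silent(validate_pedigree(ped))
})

test_that("pedigree validation sorts unordered rows and rejects cycles", {
  cfg <- breeding_config(n_generations = 2, n_founder_sires = 3,
                         n_founder_dams = 6, litter_size = 3)
  ped <- generate_pedigree(cfg, seed = 102)
  shuffled <- ped[sample(nrow(ped)), ]
  sorted <- validate_pedigree(shuffled)
  pos <- seq_len(nrow(sorted)); names(pos) <- sorted$id
  expect_true(all(pos[sorted$sire] < pos, na.rm = TRUE))
  bad <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = NA_character_, birth_month = "2010-01",
                    population = "P", generation = 1L)
  expect_error(validate_pedigree(bad), "cycle")
})

test_that("genotyping schemes weight birth years as documented", {
  cfg <- breeding_config(n_generations = 6, n_founder_sires = 8,
                         n_founder_dams = 50, litter_size = 6,
                         dams_selected_frac = 1 / 3)
  ped <- generate_pedigree(cfg, seed = 103)
  g1 <- assign_genotyping(ped, "left_skewed", 600, seed = 104)
  expect_identical(g1, assign_genotyping(ped, "left_skewed", 600,
                                         seed = 104))
  yr_all <- as.integer(substr(ped$birth_month, 1, 4))
  yr_pick <- as.integer(substr(g1$birth_month, 1, 4))
  counts <- table(factor(yr_pick, levels = sort(unique(yr_all))))
  sp <- cor(as.integer(names(counts)), as.integer(counts),
            method = "spearman")
  expect_gt(sp, 0)
  # uniform scheme: sampling fractions even across generations
  g2 <- assign_genotyping(ped, "uniform", 600, seed = 105)
  gen_pick <- ped$generation[match(g2$id, ped$id)]
  frac <- table(gen_pick) / table(ped$generation)[names(table(gen_pick))]
  expect_gt(chisq.test(table(gen_pick),
                       p = table(ped$generation) / nrow(ped))$p.value,
            1e-3)
  expect_error(assign_genotyping(ped, "uniform", nrow(ped) + 1, seed = 1),
               "exceeds")
  # AGE metadata matches the epoch arithmetic
  expect_identical(g1$age_months, compute_age(g1$birth_month))
})

test_that("selection shifts causal allele frequencies faster than matched
           neutral loci", {
  mean_c <- mean_n <- numeric(5)
  for (r in 1:5) {
    cfg <- breeding_config(n_generations = 5, n_founder_sires = 8,
                           n_founder_dams = 50, litter_size = 5,
                           n_causal_loci = 30, index_accuracy = 0.9)
    sim <- simulate_selection(cfg, n_sites = 900, seed = 110 + r)
    ped <- sim$pedigree
    dos <- sim$drop$hap1 + sim$drop$hap2
    gen <- ped$generation[match(sim$drop$ids, ped$id)]
    f0 <- colMeans(dos[gen == 0, , drop = FALSE]) / 2
    fT <- colMeans(dos[gen == max(gen), , drop = FALSE]) / 2
    dpg <- abs(fT - f0) / max(gen)
    causal <- sim$causal$site
    # match each causal locus to the neutral locus closest in initial MAF
    neutral <- setdiff(seq_len(ncol(dos)), causal)
    match_n <- vapply(causal, function(s)
      neutral[which.min(abs(pmin(f0[neutral], 1 - f0[neutral]) -
                              min(f0[s], 1 - f0[s])))], 0L)
    mean_c[r] <- mean(dpg[causal])
    mean_n[r] <- mean(dpg[match_n])
    expect_gt(mean_c[r], mean_n[r])   # holds in every replicate
  }
  # paired comparison over replicates
  expect_lt(t.test(mean_c, mean_n, paired = TRUE,
                   alternative = "greater")$p.value, 0.05)
})

test_that("zero index accuracy reduces the program to random mating", {
  cfg <- breeding_config(n_generations = 3, n_founder_sires = 5,
                         n_founder_dams = 20, litter_size = 4,
                         index_accuracy = 0)
  sim <- simulate_selection(cfg, n_sites = 360, seed = 120)
  expect_s3_class(sim, "breeding_sim")
  expect_identical(mendelian_violations(sim$drop, sim$pedigree), 0L)
  # same generator, same seed: pure function of (config, seed)
  sim2 <- simulate_selection(cfg, n_sites = 360, seed = 120)
  expect_identical(sim$drop$hap1, sim2$drop$hap1)
  expect_identical(sim$pedigree, sim2$pedigree)
})

test_that("two populations selected on shared causal loci develop a
           positive genetic correlation of AGE", {
  pool <- simulate_founder_pool(300, 5400, seed = 301)
  mk <- function(p) breeding_config(
    n_generations = 8, n_founder_sires = 12, n_founder_dams = 80,
    litter_size = 6, index_accuracy = 1, sires_selected_frac = 0.05,
    population = p)
  set.seed(302)
  causal <- data.frame(site = sort(sample.int(5400, 50)),
                       effect = rnorm(50))
  simA <- simulate_selection(mk("PopA"), pool = pool, causal = causal,
                             seed = 303)
  simB <- simulate_selection(mk("PopB"), pool = pool, causal = causal,
                             seed = 304)
  gA <- assign_genotyping(simA$pedigree, n_genotyped = 500, seed = 305)
  gB <- assign_genotyping(simB$pedigree, n_genotyped = 500, seed = 306)
  dr <- combine_drops(simA, simB)
  ped <- rbind(simA$pedigree, simB$pedigree)
  ds <- extract_array(dr, ped, c(gA$id, gB$id), 3000, seed = 307)
  G <- make_grm(ds)
  memb <- ds$samples$population
  fit <- reml_bivariate(ds$samples$age_months[memb == "PopA"],
                        ds$samples$age_months[memb == "PopB"], G, memb,
                        pops = c("PopA", "PopB"))
  expect_gt(fit$r_g, 0)
  expect_lt(fit$lrt_p_rg0, 0.05)
})

test_that("terminal crossing records only the sire side and transmits
           Mendelian genotypes", {
  pool <- simulate_founder_pool(200, 360, seed = 130)
  mk <- function(p) breeding_config(n_generations = 2, n_founder_sires = 5,
                                    n_founder_dams = 25, litter_size = 4,
                                    population = p)
  simA <- simulate_selection(mk("Duroc"), pool = pool, seed = 131)
  simB <- simulate_selection(mk("LW"), pool = pool, seed = 132)
  tc <- terminal_cross(simA, simB, n_offspring = 50, seed = 133)
  expect_true(all(is.na(tc$pedigree$dam)))
  expect_true(all(tc$pedigree$sire %in% simA$pedigree$id))
  expect_identical(tc$pedigree$population, rep("Crossbred", 50))
  # offspring carry one allele from the recorded sire at every site
  dosS <- simA$drop$hap1 + simA$drop$hap2
  si <- match(tc$pedigree$sire, simA$drop$ids)
  kid <- tc$drop$hap1   # sire-derived gamete
  for (i in 1:5) {
    s <- dosS[si[i], ]
    expect_true(all(kid[i, s == 0L] == 0L))
    expect_true(all(kid[i, s == 2L] == 1L))
  }
})
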