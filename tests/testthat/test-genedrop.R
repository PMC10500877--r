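test_that("founder pools are deterministic, segregating, evenly laid out", {
  p1 <- simulate_founder_pool(40, 360, seed = 30)
  p2 <- simulate_founder_pool(40, 360, seed = 30)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$map, p2$map)
  cs <- colSums(p1$haplotypes != as.raw(0))
  expect_true(all(cs > 0 & cs < 80))
  expect_identical(as.integer(table(p1$map$chrom)), rep(20L, 18))
  for (ch in c(1, 18)) {
    pos <- p1$map$pos_bp[p1$map$chrom == ch]
    expect_true(all(diff(pos) == diff(pos)[1]))   # even spacing
  }
  expect_error(simulate_founder_pool(10, 100, seed = 1), "divisible")
})

test_that("a point-mass SFS yields pool frequencies within binomial
           bounds", {
  pool <- simulate_founder_pool(200, 180, seed = 31,
                                sfs = function(k) rep(0.5, k))
  f <- colMeans(pool$haplotypes != as.raw(0))
  half_w <- qnorm(0.995) * sqrt(0.25 / 400)
  # 99% bounds per site; allow the expected handful of exceedances
  expect_lt(mean(f < 0.5 - half_w | f > 0.5 + half_w), 0.05)
})

test_that("founder assignment is distinct within pool capacity and
           schemes behave as specified", {
  cfg <- breeding_config(n_generations = 2, n_founder_sires = 5,
                         n_founder_dams = 20, litter_size = 4)
  ped <- generate_pedigree(cfg, seed = 32)
  pool <- simulate_founder_pool(60, 90, seed = 33)
  asg <- assign_pedigree_founders(pool, ped, "method1_shared", seed = 34)
  expect_length(asg$founder_index, 25)
  expect_false(anyDuplicated(asg$founder_index) > 0)
  # two populations, one shared pool
  cfg2 <- breeding_config(n_generations = 2, n_founder_sires = 5,
                          n_founder_dams = 20, litter_size = 4,
                          population = "Pop2")
  ped2 <- rbind(ped, generate_pedigree(cfg2, seed = 35))
  asg2 <- assign_pedigree_founders(pool, ped2, "method1_shared", seed = 36)
  expect_identical(unique(asg2$pool_name), "shared")
  expect_false(anyDuplicated(asg2$founder_index) > 0)
  # method 2 with identical seeds must fail
  pools_bad <- list(SimPop = pool, Pop2 = pool)
  expect_error(
    assign_pedigree_founders(pools_bad, ped2, "method2_independent",
                             seed = 37),
    "distinct seeds")
  pools_ok <- list(SimPop = pool,
                   Pop2 = simulate_founder_pool(40, 90, seed = 38))
  asg3 <- assign_pedigree_founders(pools_ok, ped2, "method2_independent",
                                   seed = 39)
  expect_setequal(unique(asg3$pool_name), c("SimPop", "Pop2"))
  # over-capacity falls back to replacement with a warning
  tiny <- simulate_founder_pool(20, 90, seed = 40)
  expect_warning(
    assign_pedigree_founders(tiny, ped, "method1_shared", seed = 41),
    "with replacement")
})

test_that("gene drop is deterministic and Mendelian-consistent", {
  cfg <- breeding_config(n_generations = 3, n_founder_sires = 4,
                         n_founder_dams = 16, litter_size = 4)
  ped <- generate_pedigree(cfg, seed = 42)
  pool <- simulate_founder_pool(30, 180, seed = 43)
  asg <- assign_pedigree_founders(pool, ped, "method1_shared", seed = 44)
  d1 <- gene_drop(asg, ped, seed = 45)
  d2 <- gene_drop(asg, ped, seed = 45)
  expect_identical(d1$hap1, d2$hap1)
  expect_identical(d1$hap2, d2$hap2)
  expect_identical(mendelian_violations(d1, ped), 0L)
  d3 <- gene_drop(asg, ped, seed = 46)
  expect_false(identical(d3$hap1, d1$hap1))
  # unordered rows are re-sorted; a true cycle is rejected
  d4 <- gene_drop(asg, ped[rev(seq_len(nrow(ped))), ], seed = 45)
  expect_identical(mendelian_violations(d4, ped), 0L)
  cyc <- ped
  kid <- ped$id[!is.na(ped$sire)][1]       # a child of some parent
  par <- ped$sire[ped$id == kid]
  cyc$sire[cyc$id == par] <- kid           # parent descended from its child
  expect_error(gene_drop(asg, cyc, seed = 1), "cycle")
})

test_that("homozygous crosses are invariant and het x hom segregates 1:1
           over 10,000 trios", {
  td <- trio_drop()
  dr <- td$drop
  dos <- dr$hap1 + dr$hap2
  sire <- dos[1, ]; dam <- dos[2, ]
  kids <- dos[-(1:2), , drop = FALSE]
  hom_alt <- which(sire == 2L & dam == 2L)
  if (length(hom_alt))
    expect_true(all(kids[, hom_alt] == 2L))
  hom_ref <- which(sire == 0L & dam == 0L)
  if (length(hom_ref))
    expect_true(all(kids[, hom_ref] == 0L))
  seg <- which((sire == 1L & dam == 0L) | (sire == 0L & dam == 1L))
  expect_gt(length(seg), 5)
  frac_het <- mean(kids[, seg] == 1L)
  n_draw <- length(seg) * nrow(kids)
  expect_lt(abs(frac_het - 0.5), 3 * sqrt(0.25 / n_draw))
  expect_identical(mendelian_violations(dr, td$ped), 0L)
})

test_that("allele frequencies show no systematic trend across generations
           under drift", {
  cfg <- breeding_config(n_generations = 6, n_founder_sires = 8,
                         n_founder_dams = 40, litter_size = 5)
  slopes <- numeric(5)
  for (r in 1:5) {
    ped <- generate_pedigree(cfg, seed = 50 + r)
    pool <- simulate_founder_pool(48, 360, seed = 60 + r)
    asg <- assign_pedigree_founders(pool, ped, "method1_shared",
                                    seed = 70 + r)
    dr <- gene_drop(asg, ped, seed = 80 + r)
    dos <- dr$hap1 + dr$hap2
    gen <- ped$generation[match(dr$ids, ped$id)]
    freq_by_gen <- apply(dos, 2, tapply, gen, mean) / 2
    gens <- as.numeric(rownames(freq_by_gen))
    site_slopes <- apply(freq_by_gen, 2, function(f)
      coef(lm(f ~ gens))[2])
    slopes[r] <- mean(site_slopes)
  }
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("repeated full-sib mating loses heterozygosity at the pedigree
           inbreeding rate", {
  # 150 independent lines of 5 generations of full-sib matings;
  # F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4 -> F_5 = 0.59375
  nl <- 150
  rows <- list(data.frame(
    id = c(sprintf("L%03d_f1", 1:nl), sprintf("L%03d_f2", 1:nl)),
    sire = NA_character_, dam = NA_character_, birth_month = "2000-01",
    population = "P", generation = 0L, stringsAsFactors = FALSE))
  for (g in 1:5) {
    sire <- if (g == 1) sprintf("L%03d_f1", 1:nl) else
      sprintf("L%03d_g%d_a", 1:nl, g - 1)
    dam <- if (g == 1) sprintf("L%03d_f2", 1:nl) else
      sprintf("L%03d_g%d_b", 1:nl, g - 1)
    rows[[g + 1]] <- data.frame(
      id = c(sprintf("L%03d_g%d_a", 1:nl, g), sprintf("L%03d_g%d_b", 1:nl, g)),
      sire = rep(sire, 2), dam = rep(dam, 2),
      birth_month = sprintf("20%02d-01", g), population = "P",
      generation = g, stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  pool <- simulate_founder_pool(2 * nl, 720, seed = 90)
  asg <- assign_pedigree_founders(pool, ped, "method1_shared", seed = 91)
  dr <- gene_drop(asg, ped, seed = 92)
  dos <- dr$hap1 + dr$hap2
  f_exp <- c(0, 0, 0.25, 0.375, 0.5, 0.59375)
  gen <- ped$generation[match(dr$ids, ped$id)]
  # founder heterozygosity expectation from the realized founder draws
  h0 <- mean(dos[gen == 0, ] == 1L)
  for (g in c(3L, 5L)) {
    hg <- rowMeans(dos[gen == g, , drop = FALSE] == 1L)
    ratio <- hg / h0
    expect_lt(abs(mean(ratio) - (1 - f_exp[g + 1])),
              3 * sd(ratio) / sqrt(length(ratio)))
  }
})

test_that("array extraction is reproducible, respects counts and MAF, and
           returns founder diplotypes untouched", {
  cfg <- breeding_config(n_generations = 3, n_founder_sires = 5,
                         n_founder_dams = 25, litter_size = 4)
  ped <- generate_pedigree(cfg, seed = 93)
  pool <- simulate_founder_pool(30, 720, seed = 94)
  asg <- assign_pedigree_founders(pool, ped, "method1_shared", seed = 95)
  dr <- gene_drop(asg, ped, seed = 96)
  gids <- ped$id[ped$generation >= 1][1:100]
  e1 <- extract_array(dr, ped, gids, 300, seed = 97)
  e2 <- extract_array(dr, ped, gids, 300, seed = 97)
  expect_identical(e1$dosages, e2$dosages)
  expect_identical(dim(e1$dosages), c(100L, 300L))
  f <- colMeans(e1$dosages) / 2
  expect_true(all(pmin(f, 1 - f) >= 0.01))
  expect_identical(e1$samples$age_months,
                   compute_age(ped$birth_month[match(gids, ped$id)]))
  # founders only: no meioses, dosages equal the assigned pool diplotypes
  fids <- ped$id[ped$generation == 0]
  ef <- extract_array(dr, ped, fids, 200, seed = 98, requalify = FALSE)
  slot <- match(fids, asg$slots)
  fi <- asg$founder_index[slot]
  site <- match(ef$snps$snp_id,
                sprintf("s%d_%d", dr$map$chrom, dr$map$pos_bp))
  pool_dos <- (matrix(as.integer(pool$haplotypes[2 * fi - 1, ] != as.raw(0)),
                      length(fi)) +
               matrix(as.integer(pool$haplotypes[2 * fi, ] != as.raw(0)),
                      length(fi)))[, site]
  expect_identical(unname(ef$dosages), unname(pool_dos))
  expect_error(extract_array(dr, ped, gids, 1e6, seed = 1), "segregating")
})
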