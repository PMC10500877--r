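test_that("GRM closed forms hold for a single SNP", {
  # genotypes (2, 1, 0): p = 0.5, 2p(1-p) = 0.5
  ds <- make_geno(3, 1, seed = 1)
  ds$dosages[, 1] <- c(2L, 1L, 0L)
  G <- make_grm(ds)
  expect_equal(G$values[1, 3], (2 - 1) * (0 - 1) / 0.5)  # -2
  expect_equal(G$values[2, 2], 1 + (1 - 2 * 1 + 0.5) / 0.5)  # 0
})

test_that("GRM equals the naive double-loop oracle with missingness", {
  ds <- make_geno(20, 200, seed = 2, miss_rate = 0.02)
  G <- make_grm(ds)
  X <- ds$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  n <- nrow(X); m <- ncol(X)
  Go <- matrix(0, n, n)
  No <- matrix(0L, n, n)
  for (j in 1:n) for (k in j:n) {
    s <- 0; cnt <- 0L
    for (i in 1:m) {
      xj <- X[j, i]; xk <- X[k, i]
      if (is.na(xj) || is.na(xk)) next
      cnt <- cnt + 1L
      den <- 2 * p[i] * (1 - p[i])
      s <- s + if (j == k)
        (xj^2 - (1 + 2 * p[i]) * xj + 2 * p[i]^2) / den
      else (xj - 2 * p[i]) * (xk - 2 * p[i]) / den
    }
    Go[j, k] <- Go[k, j] <- if (j == k) 1 + s / cnt else s / cnt
    No[j, k] <- No[k, j] <- cnt
  }
  expect_lt(max(abs(G$values - Go)), 1e-12)
  expect_identical(G$n_snps_used, No)
})

test_that("GRM is invariant to allele relabeling and symmetric", {
  ds <- make_geno(15, 300, seed = 3)
  G1 <- make_grm(ds)
  ds2 <- ds
  ds2$dosages <- 2L - ds$dosages
  G2 <- make_grm(ds2)
  expect_lt(max(abs(G1$values - G2$values)), 1e-10)
  expect_lt(max(abs(G1$values - t(G1$values))), 1e-10)
})

test_that("unrelated samples in linkage equilibrium give mean diagonal 1
           and mean off-diagonal 0", {
  n <- 60
  ds <- make_geno(n, 5000, seed = 4)
  G <- make_grm(ds)
  d <- diag(G$values)
  off <- G$values[upper.tri(G$values)]
  expect_lt(abs(mean(d) - 1), 3 * stats::sd(d) / sqrt(length(d)))
  # in-sample allele frequencies centre each SNP over the sample, which
  # pins the mean off-diagonal at -mean(diag)/(n - 1); beyond that
  # structural term the off-diagonals are noise around zero
  expect_lt(abs(mean(off)),
            1 / (n - 1) + 3 * stats::sd(off) / sqrt(length(off)))
  expect_error(make_grm({
    dsm <- ds; dsm$dosages[, 1] <- 0L; dsm
  }), "monomorphic")
})

test_that("full-sib pairs average G near 0.5 in a gene-drop pedigree", {
  # 80 unrelated founder pairs, two full sibs each
  np <- 80
  ped <- data.frame(
    id = c(sprintf("f%03da", 1:np), sprintf("f%03db", 1:np),
           sprintf("s%03da", 1:np), sprintf("s%03db", 1:np)),
    sire = c(rep(NA, 2 * np), rep(sprintf("f%03da", 1:np), 2)),
    dam = c(rep(NA, 2 * np), rep(sprintf("f%03db", 1:np), 2)),
    birth_month = c(rep("2008-01", 2 * np), rep("2010-06", 2 * np)),
    population = "P",
    generation = rep(c(0L, 1L), each = 2 * np),
    stringsAsFactors = FALSE)
  pool <- simulate_founder_pool(2 * np, 1800, seed = 5)
  asg <- assign_pedigree_founders(pool, ped, "method1_shared", seed = 6)
  dr <- gene_drop(asg, ped, seed = 7,
                  keep = c(sprintf("s%03da", 1:np), sprintf("s%03db", 1:np)))
  dos <- dr$hap1 + dr$hap2
  ds <- geno_data(dos,
                  data.frame(snp_id = paste0("x", seq_len(ncol(dos))),
                             chrom = dr$map$chrom, pos_bp = dr$map$pos_bp,
                             allele_a = "A", allele_b = "B"),
                  data.frame(sample_id = dr$ids, population = "P",
                             birth_month = "2010-06", age_months = 53L))
  keep_poly <- colMeans(dos) / 2
  ds <- ds[, which(keep_poly > 0 & keep_poly < 1)]
  G <- make_grm(ds)
  sib_g <- vapply(1:np, function(i)
    G$values[i, np + i], 0)
  expect_lt(abs(mean(sib_g) - 0.5),
            3 * stats::sd(sib_g) / sqrt(np))
})

test_that("PCA separates equal blocks, scores carry sqrt(eigenvalue)", {
  n <- 10
  B <- matrix(0.5, n / 2, n / 2)
  Gm <- rbind(cbind(B, -B), cbind(-B, B))
  diag(Gm) <- 1
  G <- structure(list(values = Gm, sample_ids = paste0("s", 1:n),
                      n_snps_used = matrix(100L, n, n), n_snps = 100L),
                 class = "grm")
  pc <- grm_pca(G, 2)
  s1 <- pc$components[, 1]
  expect_true(all(sign(s1[1:(n / 2)]) == sign(s1[1])))
  expect_true(all(sign(s1[(n / 2 + 1):n]) == -sign(s1[1])))
  expect_equal(unname(abs(s1)), rep(abs(s1[[1]]), n), tolerance = 1e-8)
  expect_equal(sum(pc$components[, 1]^2), pc$eigenvalues[1],
               tolerance = 1e-8)
  expect_error(grm_pca(G, 0), "positive")
  expect_error(grm_pca(G, n), "smaller")
})

test_that("an admixed population sits between its sources on the leading
           PCs", {
  set.seed(8)
  m <- 2000
  # three source populations with divergent frequencies, one 50/25/25 mix
  p0 <- runif(m, 0.2, 0.8)
  shift <- function(p, s) pmin(pmax(p + rnorm(m, 0, s), 0.02), 0.98)
  pA <- shift(p0, 0.18); pB <- shift(p0, 0.18); pC <- shift(p0, 0.18)
  pX <- 0.5 * pA + 0.25 * pB + 0.25 * pC
  draw <- function(p, n) matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  n <- 25
  X <- rbind(draw(pA, n), draw(pB, n), draw(pC, n), draw(pX, n))
  pop <- rep(c("A", "B", "C", "X"), each = n)
  ds <- geno_data(X,
                  data.frame(snp_id = paste0("x", 1:m),
                             chrom = rep_len(1:18, m), pos_bp = seq_len(m),
                             allele_a = "A", allele_b = "B"),
                  data.frame(sample_id = paste0("s", seq_len(4 * n)),
                             population = pop, birth_month = "2015-01",
                             age_months = 108L))
  ds <- qc_filter(ds)
  pc <- grm_pca(make_grm(ds), 2)
  cent <- apply(pc$components, 2, tapply, ds$samples$population, mean)
  # X must lie strictly between A and the B/C side on the axis that
  # separates A from B and C
  sepA <- which.max(abs(cent["A", ] - (cent["B", ] + cent["C", ]) / 2))
  a <- cent["A", sepA]; bc <- (cent["B", sepA] + cent["C", sepA]) / 2
  x <- cent["X", sepA]
  expect_true((x - a) * (x - bc) < 0)   # strictly between
  expect_lt(abs(x - (0.5 * a + 0.5 * bc)), 0.35 * abs(a - bc))
})

test_that("GRM persists through the binary triple and text formats", {
  ds <- make_geno(12, 150, seed = 9, miss_rate = 0.03)
  G <- make_grm(ds)
  tmp <- tempfile()
  write_grm(G, tmp)
  G2 <- read_grm(tmp)
  expect_identical(G2$sample_ids, G$sample_ids)
  expect_lt(max(abs(G2$values - G$values)), 1e-6)  # single precision
  expect_identical(G2$n_snps_used, G$n_snps_used)
  txt <- tempfile()
  write_grm(G, txt, format = "text")
  tab <- read.table(paste0(txt, ".grm.txt"), header = TRUE)
  expect_equal(nrow(tab), 12 * 13 / 2)
})
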