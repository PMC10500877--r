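#' Storey q-values
#'
#' Converts p-values to false-discovery-rate q-values using Storey's
#' estimator of the null proportion pi0. pi0 is estimated on the lambda
#' grid 0.05, 0.10, ..., 0.95 as mean(p > lambda)/(1 - lambda), smoothed
#' with a cubic smoothing spline (3 df) and read off at the largest lambda,
#' then clamped to (0, 1]. q-values are monotonized from the largest
#' p-value down; tied p-values receive equal q-values. With fewer than 100
#' p-values pi0 estimation is unstable, so pi0 = 1 is used (equivalent to
#' Benjamini-Hochberg) with a warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param pi0 optional fixed null proportion, bypassing estimation.
#' @return Numeric vector of q-values, with the estimated pi0 as attribute
#'   \code{"pi0"}.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      warning("fewer than 100 p-values; using pi0 = 1 (Benjamini-Hochberg)")
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      sp <- stats::smooth.spline(lambda, pi0l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  i <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[i] <- cummin(pi0 * m * p[i] / (m - seq_len(m) + 1))
  q <- pmin(q, 1)
  # equal p-values share a q-value
  stats::ave(q, p, FUN = min) -> q
  attr(q, "pi0") <- pi0
  q
}

#' Allele-frequency change per year
#'
#' The absolute slope of an ordinary least-squares regression of per-sample
#' allele frequency (dosage / 2) on birth year (AGE / 12), in frequency
#' units per year — a descriptive companion to the mixed-model scan.
#'
#' @param ds a [geno_data()] with AGE metadata spanning at least two
#'   distinct birth years.
#' @param snp_id optional SNP id(s); default all SNPs.
#' @return Named numeric vector of |slope| per SNP.
#' @export
af_change_per_year <- function(ds, snp_id = NULL) {
  stopifnot(inherits(ds, "geno_data"))
  yr <- ds$samples$age_months / 12
  if (length(unique(floor(yr))) < 2)
    stop("at least two distinct birth years are required")
  X <- ds$dosages
  if (!is.null(snp_id)) X <- X[, snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  yc <- yr - mean(yr)
  syy <- sum(yc^2)
  obs <- !is.na(X)
  if (all(obs)) {
    slope <- drop(crossprod(X / 2, yc)) / syy
  } else {
    # per-SNP complete-case slope
    slope <- apply(X, 2, function(x) {
      ok <- !is.na(x)
      ybar <- yr[ok] - mean(yr[ok])
      s <- sum(ybar^2)
      if (s == 0) return(0)
      sum((x[ok] / 2) * ybar) / s
    })
  }
  abs(slope)
}

# per-SNP GLS scan under fixed V-hat, in the eigenbasis of G
scan_engine <- function(dos, U, lam, y, sigma_g2, sigma_e2,
                        block = 2000L) {
  n <- nrow(dos); m <- ncol(dos)
  w <- 1 / (sigma_g2 * lam + sigma_e2)
  yr <- drop(crossprod(U, y))
  onesr <- drop(crossprod(U, rep(1, n)))
  S11 <- sum(w * onesr^2)
  S1y <- sum(w * onesr * yr)
  beta <- se <- numeric(m)
  mono <- logical(m)
  for (s0 in seq(1, m, by = block)) {
    s1 <- min(s0 + block - 1L, m)
    B <- dos[, s0:s1, drop = FALSE]
    storage.mode(B) <- "double"
    if (anyNA(B)) {            # mean-impute per SNP
      mu <- colMeans(B, na.rm = TRUE)
      idx <- which(is.na(B), arr.ind = TRUE)
      B[idx] <- mu[idx[, 2]]
    }
    sds <- col_sds(B)
    Br <- crossprod(U, B)
    Sxx <- colSums(w * Br^2)
    Sx1 <- colSums(w * Br * onesr)
    Sxy <- colSums(w * Br * yr)
    den <- S11 * Sxx - Sx1^2
    b <- (S11 * Sxy - Sx1 * S1y) / den
    v <- S11 / den
    z <- sds == 0 | den <= 0
    b[z] <- 0; v[z] <- NA_real_
    beta[s0:s1] <- b
    se[s0:s1] <- sqrt(v)
    mono[s0:s1] <- z
  }
  chisq <- ifelse(mono, 0, (beta / se)^2)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  p[mono] <- 1
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  list(beta = beta, se = se, p = p, monomorphic = mono)
}

# colSds without extra deps
col_sds <- function(B) {
  n <- nrow(B)
  mu <- colMeans(B)
  sqrt(pmax(colSums(B^2) / n - mu^2, 0))
}

#' Single-SNP mixed-model scan of genotype on the generation proxy
#'
#' For each SNP s, fits y = mu + x_s b_s + g + e by generalized least
#' squares under the fixed covariance V-hat = G sigma_g^2 + I sigma_e^2,
#' with the variance components taken from the null REML fit and not
#' re-estimated per SNP (EMMAX-style). A single eigendecomposition of G
#' makes the scan one matrix rotation plus O(n) per SNP. P-values are Wald
#' chi-squared with 1 df; missing genotypes are mean-imputed per SNP; SNPs
#' with zero variance after imputation get beta = 0, p = 1 and a flag.
#'
#' @param ds a post-QC [geno_data()] with AGE metadata.
#' @param G a [make_grm()] object over the same samples.
#' @param vc a [reml_univariate()] fit on the same samples (its stored
#'   eigendecomposition is reused).
#' @param fdr q-value significance threshold (default 0.10).
#' @return A data.frame (the association table) with columns \code{snp_id},
#'   \code{chrom}, \code{pos_bp}, \code{maf}, \code{beta} (months per
#'   allele), \code{se}, \code{p}, \code{q}, \code{significant},
#'   \code{af_change_per_year}, \code{monomorphic}; attribute \code{"pi0"}.
#' @seealso [gpsm()] for the one-call interface with methods.
#' @export
gpsm_scan <- function(ds, G, vc, fdr = 0.10) {
  stopifnot(inherits(ds, "geno_data"), inherits(vc, "reml_fit"))
  y <- ds$samples$age_months
  if (anyNA(y)) stop("all samples need AGE metadata for the scan")
  if (length(y) != vc$n) stop("vc was fitted on a different sample size")
  U <- vc$eigen_U; lam <- vc$eigen_values
  if (is.null(U)) {
    Gm <- if (inherits(G, "grm")) G$values else as.matrix(G)
    eg <- eigen(Gm, symmetric = TRUE)
    U <- eg$vectors; lam <- pmax(eg$values, 1e-8)
  }
  sc <- scan_engine(ds$dosages, U, lam, y, vc$sigma_g2, vc$sigma_e2)
  q <- qvalues(sc$p)
  pobs <- colMeans(ds$dosages, na.rm = TRUE) / 2
  afc <- tryCatch(af_change_per_year(ds), error = function(e)
    rep(NA_real_, ncol(ds$dosages)))
  tab <- data.frame(
    snp_id = ds$snps$snp_id, chrom = ds$snps$chrom, pos_bp = ds$snps$pos_bp,
    maf = pmin(pobs, 1 - pobs),
    beta = sc$beta, se = sc$se, p = sc$p, q = as.numeric(q),
    significant = as.numeric(q) < fdr,
    af_change_per_year = afc, monomorphic = sc$monomorphic,
    stringsAsFactors = FALSE)
  attr(tab, "pi0") <- attr(q, "pi0")
  attr(tab, "fdr") <- fdr
  tab
}

#' Generation proxy selection mapping
#'
#' The one-call interface: builds (or accepts) the genomic relationship
#' matrix, fits the null variance-component model for AGE, runs the
#' per-SNP mixed-model scan, converts p-values to Storey q-values, and
#' returns a fitted object with print, summary and plot methods. SNPs whose
#' genotypes associate with birth date at q below \code{fdr} are candidates
#' for directional (polygenic) selection.
#'
#' @param ds a post-QC [geno_data()] with AGE metadata.
#' @param G optional [make_grm()] result (computed from \code{ds} if
#'   missing).
#' @param vc optional [reml_univariate()] fit (fitted if missing).
#' @param fdr q-value threshold for calling selection (default 0.10).
#' @return Object of class \code{"gpsm"}: list with \code{assoc} (the
#'   association table), \code{vc}, \code{fdr}, \code{n}, \code{n_snps}.
#' @examples
#' sim <- simulate_selection(breeding_config(n_generations = 4,
#'   n_founder_sires = 5, n_founder_dams = 30, litter_size = 4),
#'   n_sites = 360, seed = 1)
#' ids <- assign_genotyping(sim$pedigree, n_genotyped = 80, seed = 2)
#' ds <- extract_array(sim, sim$pedigree, ids$id, n_array_snps = 200,
#'                     seed = 3)
#' fit <- gpsm(ds)
#' print(fit)
#' @export
gpsm <- function(ds, G = NULL, vc = NULL, fdr = 0.10) {
  stopifnot(inherits(ds, "geno_data"))
  if (is.null(G)) G <- make_grm(ds)
  if (is.null(vc)) vc <- reml_univariate(ds$samples$age_months, G)
  assoc <- gpsm_scan(ds, G, vc, fdr = fdr)
  structure(list(assoc = assoc, vc = vc, fdr = fdr,
                 n = nrow(ds$dosages), n_snps = ncol(ds$dosages)),
            class = "gpsm")
}

#' Summaries of estimated SNP effects
#'
#' Counts and effect-size summaries over significant SNPs: mean and range
#' of |beta| (months per allele), the proportion of autosomal loci called
#' significant, the mean allele-frequency change per year among significant
#' SNPs, and the SD of SNP effects computed both over all SNPs and over
#' significant SNPs only.
#'
#' @param tab an association table from [gpsm_scan()], or a \code{gpsm}
#'   fit.
#' @return A list of summary statistics.
#' @export
effect_summaries <- function(tab) {
  if (inherits(tab, "gpsm")) tab <- tab$assoc
  if (!nrow(tab)) stop("empty association table")
  sig <- tab[tab$significant, , drop = FALSE]
  nsig <- nrow(sig)
  list(
    n_snps = nrow(tab),
    n_significant = nsig,
    prop_significant = nsig / nrow(tab),
    mean_abs_beta = if (nsig) mean(abs(sig$beta)) else NA_real_,
    range_abs_beta = if (nsig) range(abs(sig$beta)) else c(NA_real_, NA_real_),
    mean_af_change = if (nsig) mean(sig$af_change_per_year) else NA_real_,
    range_af_change = if (nsig) range(sig$af_change_per_year)
                      else c(NA_real_, NA_real_),
    sd_beta_all = stats::sd(tab$beta),
    sd_beta_significant = if (nsig > 1) stats::sd(sig$beta) else NA_real_)
}

#' @export
print.gpsm <- function(x, ...) {
  es <- effect_summaries(x$assoc)
  cat("GPSM scan:", x$n, "samples,", x$n_snps, "SNPs\n")
  cat(sprintf("  PVE of AGE = %.3f (SE %.3f)\n", x$vc$pve, x$vc$se_pve))
  cat(sprintf("  significant SNPs (q < %.2f): %d (%.3f%% of loci)\n",
              x$fdr, es$n_significant, 100 * es$prop_significant))
  if (es$n_significant > 0)
    cat(sprintf("  mean |SNP effect| among significant: %.2f months/allele\n",
                es$mean_abs_beta))
  invisible(x)
}

#' @export
summary.gpsm <- function(object, ...) effect_summaries(object$assoc)

#' @export
coef.gpsm <- function(object, ...) {
  stats::setNames(object$assoc$beta, object$assoc$snp_id)
}

#' Manhattan and Q-Q plots of a GPSM scan
#'
#' @param x a \code{gpsm} fit.
#' @param type \code{"manhattan"} (-log10 q against genome position) or
#'   \code{"qq"} (observed vs expected -log10 p).
#' @param truncate_at optional cap on the -log10(q) axis (e.g. 10).
#' @param ... passed to the underlying plot call.
#' @return Invisibly, \code{x}.
#' @export
plot.gpsm <- function(x, type = c("manhattan", "qq"), truncate_at = NULL,
                      ...) {
  type <- match.arg(type)
  a <- x$assoc
  if (type == "manhattan") {
    ord <- order(a$chrom, a$pos_bp)
    a <- a[ord, ]
    off <- c(0, cumsum(tapply(a$pos_bp, a$chrom, max)))
    xs <- a$pos_bp + off[match(a$chrom, sort(unique(a$chrom)))]
    ly <- -log10(pmax(a$q, 1e-300))
    if (!is.null(truncate_at)) ly <- pmin(ly, truncate_at)
    graphics::plot(xs, ly, pch = 16, cex = 0.4,
                   col = c("grey40", "steelblue")[a$chrom %% 2 + 1],
                   xlab = "genome position", ylab = "-log10(q)", ...)
    graphics::abline(h = -log10(x$fdr), col = "red", lty = 2)
  } else {
    p <- sort(a$p)
    exp_p <- stats::ppoints(length(p))
    graphics::plot(-log10(exp_p), -log10(p), pch = 16, cex = 0.4,
                   xlab = "expected -log10(p)", ylab = "observed -log10(p)",
                   ...)
    graphics::abline(0, 1, col = "red")
  }
  invisible(x)
}
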