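#' Univariate AI-REML for the generation-proxy mixed model
#'
#' Fits y = Xb + g + e with g ~ N(0, G sigma_g^2), e ~ N(0, I sigma_e^2) by
#' average-information restricted maximum likelihood, and reports the
#' proportion of variance in y explained by genome-wide SNPs,
#' PVE = sigma_g^2 / (sigma_g^2 + sigma_e^2). With y the birth-date proxy
#' (AGE, months) this PVE reflects how strongly genotype tracks time, i.e.
#' demographic and pedigree structure rather than a trait heritability.
#'
#' Because V = G sigma_g^2 + I sigma_e^2 shares eigenvectors with G, the
#' model is fitted in the eigenbasis of G: one O(n^3) eigendecomposition,
#' then O(n) per iteration. Eigenvalues of G below 1e-8 are clipped to 1e-8
#' (near-singular GRMs arise from dense pedigrees). An EM-REML step is taken
#' whenever an AI step would leave the parameter space or decrease the
#' restricted likelihood; variances are floored at 1e-6 var(y).
#'
#' The likelihood-ratio p-value tests sigma_g^2 = 0 against a 50:50 mixture
#' of a point mass at zero and chi-squared with 1 df, the appropriate null
#' for a variance component on the boundary.
#'
#' @param y numeric response (AGE in months), length n.
#' @param G a [make_grm()] object or an n x n relationship matrix.
#' @param X fixed-effect design matrix (default intercept only).
#' @param max_iter maximum REML iterations (default 100).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-8).
#' @return An object of class \code{"reml_fit"} with components
#'   \code{sigma_g2}, \code{sigma_e2}, \code{pve}, \code{se_pve},
#'   \code{se_sigma} (2 x 2 sampling covariance of the variance components),
#'   \code{loglik}, \code{loglik_null}, \code{lrt_p}, \code{beta},
#'   \code{n_iter}, \code{converged}, and the eigendecomposition of G
#'   (reused by [gpsm()] for the per-SNP scan).
#' @export
reml_univariate <- function(y, G, X = NULL, max_iter = 100, tol = 1e-8) {
  Gm <- if (inherits(G, "grm")) G$values else as.matrix(G)
  n <- length(y)
  if (nrow(Gm) != n) stop("length(y) must equal the GRM dimension")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)

  eg <- eigen(Gm, symmetric = TRUE)
  lam <- eg$values
  n_clip <- sum(lam < 1e-8)
  if (n_clip > 0) {
    message("reml_univariate: clipped ", n_clip,
            " GRM eigenvalue(s) below 1e-8")
    lam <- pmax(lam, 1e-8)
  }
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)

  vy <- stats::var(y)
  floor_v <- 1e-6 * vy

  eval_point <- function(th) {
    d <- th[1] * lam + th[2]
    w <- 1 / d
    XtViX <- crossprod(Xr, Xr * w)
    cXtViX <- chol(XtViX)
    beta <- backsolve(cXtViX, forwardsolve(t(cXtViX), crossprod(Xr, w * yr)))
    r <- yr - drop(Xr %*% beta)
    Py <- w * r
    yPy <- sum(r * Py)
    ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(cXtViX))) + yPy)
    list(ll = ll, w = w, Py = Py, yPy = yPy, beta = beta, XtViX = XtViX)
  }
  proj <- function(z, w, XtViX) {
    # apply P to a rotated vector
    w * z - (w * Xr) %*% solve(XtViX, crossprod(Xr, w * z))
  }
  tr_PV <- function(vk, w, XtViX) {
    A <- Xr * w
    sum(w * vk) - sum(diag(solve(XtViX, crossprod(A, vk * A))))
  }

  th <- c(vy / 2, vy / 2)
  st <- eval_point(th)
  AI <- NULL
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    Py <- st$Py
    qg <- lam * Py
    qe <- Py
    yPVgPy <- sum(Py * qg)
    yPVePy <- sum(Py * qe)
    grad <- -0.5 * c(tr_PV(lam, st$w, st$XtViX) - yPVgPy,
                     tr_PV(rep(1, n), st$w, st$XtViX) - yPVePy)
    Pqg <- drop(proj(qg, st$w, st$XtViX))
    Pqe <- drop(proj(qe, st$w, st$XtViX))
    AI <- 0.5 * matrix(c(sum(qg * Pqg), sum(qg * Pqe),
                         sum(qe * Pqg), sum(qe * Pqe)), 2, 2)
    AI <- (AI + t(AI)) / 2

    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    ok <- FALSE
    if (!is.null(step)) {
      sc <- 1
      for (h in 1:20) {
        cand <- pmax(th + sc * step, floor_v)
        stc <- eval_point(cand)
        if (stc$ll >= st$ll - 1e-12) {
          th <- cand; new <- stc; ok <- TRUE; break
        }
        sc <- sc / 2
      }
    }
    if (!ok) {
      # EM-REML fallback: monotone but slow
      em <- th + th^2 * c(yPVgPy - tr_PV(lam, st$w, st$XtViX),
                          yPVePy - tr_PV(rep(1, n), st$w, st$XtViX)) / n
      th <- pmax(em, floor_v)
      new <- eval_point(th)
    }
    dll <- new$ll - st$ll
    st <- new
    if (abs(dll) < tol) { converged <- TRUE; break }
  }

  sg <- th[1]; se <- th[2]
  cov_th <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  pve <- sg / (sg + se)
  gvec <- c(se, -sg) / (sg + se)^2
  se_pve <- sqrt(max(drop(t(gvec) %*% cov_th %*% gvec), 0))

  # null model sigma_g^2 = 0: closed-form REML
  rss0_fit <- stats::lm.fit(X, y)
  rss0 <- sum(rss0_fit$residuals^2)
  se0 <- rss0 / (n - p)
  XtX <- crossprod(X)
  ll0 <- -0.5 * (n * log(se0) + determinant(XtX)$modulus[1] - p * log(se0) +
                   rss0 / se0)
  lrt <- max(2 * (st$ll - ll0), 0)
  lrt_p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  structure(list(sigma_g2 = sg, sigma_e2 = se, pve = pve, se_pve = se_pve,
                 se_sigma = cov_th, loglik = st$ll, loglik_null = ll0,
                 lrt_p = lrt_p, beta = drop(st$beta), n_iter = it,
                 converged = converged, n = n, n_clipped = n_clip,
                 eigen_U = U, eigen_values = lam, y = y, X = X),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("Univariate AI-REML fit (n =", x$n, ")\n")
  cat(sprintf("  sigma_g^2 = %.4f, sigma_e^2 = %.4f\n",
              x$sigma_g2, x$sigma_e2))
  cat(sprintf("  PVE = %.4f (SE %.4f), logLik = %.3f, LRT p = %.3g\n",
              x$pve, x$se_pve, x$loglik, x$lrt_p))
  if (!x$converged) cat("  WARNING: did not converge in", x$n_iter,
                        "iterations\n")
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) {
  c(sigma_g2 = object$sigma_g2, sigma_e2 = object$sigma_e2,
    pve = object$pve)
}

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = 2 + ncol(object$X), class = "logLik")
}

#' @export
summary.reml_fit <- function(object, ...) {
  out <- data.frame(
    component = c("sigma_g2", "sigma_e2", "pve"),
    estimate = c(object$sigma_g2, object$sigma_e2, object$pve),
    se = c(sqrt(diag(object$se_sigma)), object$se_pve))
  attr(out, "lrt_p") <- object$lrt_p
  out
}
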