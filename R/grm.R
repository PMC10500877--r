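#' Genomic relationship matrix (Yang et al. estimator)
#'
#' Builds the additive genomic relationship matrix from a post-QC dosage
#' matrix. For samples j, k and SNP i with dosage x and sample allele
#' frequency p_i:
#' off-diagonals are mean over shared non-missing SNPs of
#' \eqn{(x_{ij} - 2p_i)(x_{ik} - 2p_i) / (2 p_i (1 - p_i))};
#' diagonals use the Yang et al. estimator
#' \eqn{1 + mean[x^2 - (1 + 2p) x + 2 p^2] / (2 p (1 - p))}.
#' Missing genotypes are handled by per-pair deletion with per-pair SNP
#' counts (the GCTA convention), not mean imputation.
#'
#' @param ds a [geno_data()] after QC; every SNP must be polymorphic.
#' @param block SNPs per accumulation block; bounds memory at
#'   O(n x block) beyond the n x n output.
#' @return An object of class \code{"grm"}: list with \code{values}
#'   (symmetric matrix), \code{sample_ids}, \code{n_snps_used} (per-pair
#'   non-missing SNP counts) and \code{n_snps} (SNPs supplied).
#' @export
make_grm <- function(ds, block = 2000L) {
  stopifnot(inherits(ds, "geno_data"))
  X <- ds$dosages
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP reached make_grm (QC contract violated): ",
         ds$snps$snp_id[which(p <= 0 | p >= 1)[1]])
  het <- 2 * p * (1 - p)

  any_na <- anyNA(X)
  G <- matrix(0, n, n)
  dterm <- numeric(n)        # Yang diagonal accumulator
  Nmat <- NULL
  if (any_na) Nmat <- matrix(0, n, n)
  for (j0 in seq(1, m, by = block)) {
    jj <- j0:min(j0 + block - 1L, m)
    B <- X[, jj, drop = FALSE]
    storage.mode(B) <- "double"
    pj <- p[jj]; hj <- het[jj]
    W <- sweep(sweep(B, 2, 2 * pj), 2, sqrt(hj), "/")
    # Yang diagonal: (x^2 - (1+2p)x + 2p^2) / (2p(1-p)) per sample x SNP
    D <- sweep(sweep(B * B - sweep(B, 2, 1 + 2 * pj, "*"),
                     2, 2 * pj * pj, "+"), 2, hj, "/")
    if (any_na) {
      o <- !is.na(B)
      W[!o] <- 0
      Nmat <- Nmat + tcrossprod(o * 1)
      dterm <- dterm + rowSums(D, na.rm = TRUE)
    } else {
      dterm <- dterm + rowSums(D)
    }
    G <- G + tcrossprod(W)
  }
  if (any_na) {
    if (any(Nmat == 0)) stop("a sample pair shares no non-missing SNPs")
    G <- G / Nmat
    diag(G) <- 1 + dterm / diag(Nmat)
  } else {
    G <- G / m
    diag(G) <- 1 + dterm / m
    Nmat <- matrix(m, n, n)
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- NULL
  dimnames(Nmat) <- NULL
  storage.mode(Nmat) <- "integer"
  structure(list(values = G, sample_ids = ds$samples$sample_id,
                 n_snps_used = Nmat, n_snps = m),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- length(x$sample_ids)
  off <- x$values[upper.tri(x$values)]
  cat("grm:", n, "samples,", x$n_snps, "SNPs\n")
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x$values)), mean(off)))
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Top-k eigenpairs of the GRM; scores are eigenvectors scaled by the square
#' root of their eigenvalue, so squared score norms equal eigenvalues. A
#' deterministic sign convention is applied: within each component the
#' largest-magnitude loading is positive.
#'
#' @param G a [make_grm()] result.
#' @param k number of components (0 < k < number of samples).
#' @return List of class \code{"grm_pca"} with \code{eigenvalues} (descending)
#'   and \code{components} (samples x k score matrix).
#' @export
grm_pca <- function(G, k = 2) {
  stopifnot(inherits(G, "grm"))
  n <- length(G$sample_ids)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of samples")
  eg <- eigen(G$values, symmetric = TRUE)
  val <- eg$values[seq_len(k)]
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(pmax(val, 0)), "*")
  rownames(scores) <- G$sample_ids
  structure(list(eigenvalues = val, components = scores),
            class = "grm_pca")
}

#' Write a GRM in the GCTA binary triple format
#'
#' Writes \code{prefix.grm.bin} (lower triangle including the diagonal,
#' row-wise, single precision), \code{prefix.grm.N.bin} (matching per-pair
#' SNP counts) and \code{prefix.grm.id}.
#'
#' @param G a \code{grm} object.
#' @param prefix output path prefix.
#' @param format \code{"bin"} (GCTA triple) or \code{"text"} (one
#'   \code{id1 id2 n value} row per pair).
#' @return Invisibly, the paths written.
#' @export
write_grm <- function(G, prefix, format = c("bin", "text")) {
  stopifnot(inherits(G, "grm"))
  format <- match.arg(format)
  n <- length(G$sample_ids)
  lt <- which(lower.tri(G$values, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  vals <- G$values[lt]
  cnts <- G$n_snps_used[lt]
  if (format == "bin") {
    paths <- paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id"))
    con <- file(paths[1], "wb"); writeBin(vals, con, size = 4); close(con)
    con <- file(paths[2], "wb"); writeBin(as.numeric(cnts), con, size = 4)
    close(con)
    utils::write.table(data.frame(G$sample_ids, G$sample_ids), paths[3],
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    paths <- paste0(prefix, ".grm.txt")
    utils::write.table(
      data.frame(id1 = G$sample_ids[lt[, 1]], id2 = G$sample_ids[lt[, 2]],
                 n_snps = cnts, value = vals),
      paths, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a GRM written by [write_grm()]
#'
#' @param prefix path prefix of the \code{.grm.bin/.grm.N.bin/.grm.id}
#'   triple.
#' @return A \code{grm} object (values in single precision as stored).
#' @export
read_grm <- function(prefix) {
  paths <- paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id"))
  for (p in paths) if (!file.exists(p)) stop("missing GRM file: ", p)
  ids <- utils::read.table(paths[3], colClasses = "character")[[2]]
  n <- length(ids)
  np <- n * (n + 1) / 2
  vals <- readBin(paths[1], "numeric", n = np, size = 4)
  cnts <- readBin(paths[2], "numeric", n = np, size = 4)
  G <- matrix(0, n, n); Nm <- matrix(0, n, n)
  lt <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  G[lt] <- vals; Nm[lt] <- cnts
  G <- G + t(G) - diag(diag(G))
  Nm <- Nm + t(Nm) - diag(diag(Nm))
  storage.mode(Nm) <- "integer"
  structure(list(values = G, sample_ids = ids, n_snps_used = Nm,
                 n_snps = max(Nm)),
            class = "grm")
}
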