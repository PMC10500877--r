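#' Genotype quality control
#'
#' Applies the standard array QC used before selection mapping, in a fixed
#' order: (1) SNPs with call rate below \code{snp_call_rate} are removed,
#' (2) samples with call rate below \code{sample_call_rate} are removed,
#' (3) SNPs with minor allele frequency below \code{maf} (computed after the
#' sample filter) are removed. The order is reported stepwise so alternative
#' orders can be audited. QC is idempotent.
#'
#' @param ds a [geno_data()] object.
#' @param snp_call_rate minimum per-SNP call rate (default 0.90).
#' @param maf minimum minor allele frequency (default 0.01).
#' @param sample_call_rate minimum per-sample call rate (default 0.90).
#' @return The filtered \code{geno_data}, with a data.frame attribute
#'   \code{"qc_report"} listing counts removed at each step.
#' @export
qc_filter <- function(ds, snp_call_rate = 0.90, maf = 0.01,
                      sample_call_rate = 0.90) {
  stopifnot(inherits(ds, "geno_data"))
  for (th in c(snp_call_rate, maf, sample_call_rate))
    if (!(th > 0 && th <= 1)) stop("QC thresholds must be in (0, 1]")
  X <- ds$dosages
  obs <- !is.na(X)

  cr_snp <- colMeans(obs)
  keep_snp <- cr_snp >= snp_call_rate
  n_snp_cr <- sum(!keep_snp)
  X <- X[, keep_snp, drop = FALSE]; obs <- obs[, keep_snp, drop = FALSE]

  cr_samp <- rowMeans(obs)
  keep_samp <- if (ncol(obs)) cr_samp >= sample_call_rate else rep(TRUE, nrow(obs))
  n_samp_cr <- sum(!keep_samp)
  X <- X[keep_samp, , drop = FALSE]; obs <- obs[keep_samp, , drop = FALSE]

  p <- colMeans(X, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  keep_maf <- !is.na(mafs) & mafs >= maf
  n_maf <- sum(!keep_maf)

  report <- data.frame(
    step = c("snp_call_rate", "sample_call_rate", "maf"),
    threshold = c(snp_call_rate, sample_call_rate, maf),
    removed = c(n_snp_cr, n_samp_cr, n_maf),
    remaining = c(sum(keep_snp), sum(keep_samp), sum(keep_maf)))

  out <- ds[keep_samp, which(keep_snp)[keep_maf]]
  if (nrow(out$dosages) == 0L || ncol(out$dosages) == 0L)
    stop("no samples or SNPs survive QC")
  attr(out, "qc_report") <- report
  out
}

#' Remove impure purebred samples
#'
#' Drops purebred samples whose estimated ancestry proportion for their own
#' assigned population falls below \code{min_prop} (possible sample swaps).
#' The boundary is inclusive: exactly \code{min_prop} is retained, matching
#' a "less than 95\%" removal rule. Crossbred samples are never removed,
#' since their deviations from expected breed composition cannot be told
#' apart from Mendelian sampling.
#'
#' @param ds a [geno_data()] whose \code{ancestry} matrix covers every
#'   purebred sample (columns named by population).
#' @param min_prop minimum own-population ancestry (default 0.95).
#' @param crossbred population labels exempt from the filter.
#' @return The filtered \code{geno_data}.
#' @export
purity_filter <- function(ds, min_prop = 0.95, crossbred = "Crossbred") {
  stopifnot(inherits(ds, "geno_data"))
  pop <- ds$samples$population
  pure <- !(pop %in% crossbred)
  if (!any(pure)) return(ds)
  if (is.null(ds$ancestry))
    stop("purebred samples lack ancestry proportions: ",
         ds$samples$sample_id[pure][1])
  own <- rep(NA_real_, length(pop))
  idx <- match(pop, colnames(ds$ancestry))
  has <- !is.na(idx)
  own[has] <- ds$ancestry[cbind(seq_along(pop)[has], idx[has])]
  if (any(pure & !has))
    stop("purebred sample lacks an ancestry column for its population: ",
         ds$samples$sample_id[pure & !has][1])
  keep <- !pure | own >= min_prop
  ds[keep, ]
}
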