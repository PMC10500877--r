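#' Genotype dataset container
#'
#' Bundles a sample-by-SNP dosage matrix with its SNP map and per-sample
#' metadata. Dosages count copies of \code{allele_b} (the PLINK A1 allele)
#' and are integers in \{0, 1, 2\} with \code{NA} for missing calls.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns. Entries
#'   must be 0, 1, 2 or \code{NA}.
#' @param snps data.frame with columns \code{snp_id}, \code{chrom} (integer,
#'   autosomes 1--18 after filtering), \code{pos_bp} (1-based physical
#'   position), \code{allele_a}, \code{allele_b}.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{population}, \code{birth_month} (\code{"YYYY-MM"} character or
#'   \code{NA}) and \code{age_months} (months since the January 2006 epoch;
#'   may be \code{NA} when birth dates are unknown).
#' @param ancestry optional numeric matrix of ancestry proportions (samples
#'   by population); each row must sum to 1 within 1e-6.
#'
#' @return An object of class \code{"geno_data"}.
#' @seealso [read_plink()], [qc_filter()], [compute_age()]
#' @export
geno_data <- function(dosages, snps, samples, ancestry = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(is.data.frame(snps), is.data.frame(samples))
  need_snp <- c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b")
  if (!all(need_snp %in% names(snps)))
    stop("snps must have columns: ", paste(need_snp, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("samples must have columns sample_id and population")
  if (is.null(samples$birth_month)) samples$birth_month <- NA_character_
  if (is.null(samples$age_months)) samples$age_months <- NA_integer_
  if (nrow(dosages) != nrow(samples))
    stop("dosage rows (", nrow(dosages), ") != samples (", nrow(samples), ")")
  if (ncol(dosages) != nrow(snps))
    stop("dosage columns (", ncol(dosages), ") != snps (", nrow(snps), ")")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- snps$snp_id
  if (!is.null(ancestry)) {
    ancestry <- as.matrix(ancestry)
    if (nrow(ancestry) != nrow(samples))
      stop("ancestry rows must match samples")
    rs <- rowSums(ancestry)
    if (any(abs(rs - 1) > 1e-6))
      stop("ancestry proportions must sum to 1 (tolerance 1e-6)")
    rownames(ancestry) <- samples$sample_id
  }
  structure(
    list(dosages = dosages, snps = snps, samples = samples,
         ancestry = ancestry),
    class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("geno_data:", nrow(x$dosages), "samples x", ncol(x$dosages), "SNPs\n")
  pops <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  if (any(!is.na(x$samples$age_months)))
    cat(sprintf("  AGE range (months since Jan 2006): %d..%d\n",
                min(x$samples$age_months, na.rm = TRUE),
                max(x$samples$age_months, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.geno_data <- function(x) dim(x$dosages)

#' Subset a genotype dataset
#'
#' @param x a \code{geno_data} object.
#' @param i sample index (logical, integer or sample ids).
#' @param j SNP index (logical, integer or SNP ids).
#' @param ... unused.
#' @return A \code{geno_data} with the selected samples and SNPs.
#' @export
`[.geno_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  geno_data(x$dosages[i, j, drop = FALSE],
            x$snps[j, , drop = FALSE],
            x$samples[i, , drop = FALSE],
            if (!is.null(x$ancestry)) x$ancestry[i, , drop = FALSE])
}

#' Months between a birth month and the analysis epoch
#'
#' The generation proxy used throughout the package ("AGE") is the signed
#' number of whole months between an animal's birth month and a fixed epoch,
#' January 2006 by default. Animals born before the epoch get negative
#' values; day-of-month is ignored.
#'
#' @param birth_month character vector \code{"YYYY-MM"} (a trailing
#'   \code{"-DD"} is tolerated and ignored).
#' @param epoch epoch month, same format. Default \code{"2006-01"}.
#' @return Integer vector of month differences.
#' @examples
#' compute_age("2016-01")  # 120
#' compute_age("2006-01")  # 0
#' compute_age("2005-12")  # -1
#' @export
compute_age <- function(birth_month, epoch = "2006-01") {
  parse_ym <- function(s) {
    m <- regmatches(s, regexec("^([0-9]{4})-([0-9]{2})", s))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad & !is.na(s)))
      stop("birth_month must be 'YYYY-MM': ", s[bad & !is.na(s)][1])
    yr <- vapply(m, function(p) if (length(p) == 3L) as.integer(p[2]) else NA_integer_, 1L)
    mo <- vapply(m, function(p) if (length(p) == 3L) as.integer(p[3]) else NA_integer_, 1L)
    if (any(!is.na(mo) & (mo < 1L | mo > 12L))) stop("month out of range 1-12")
    list(yr = yr, mo = mo)
  }
  b <- parse_ym(birth_month)
  e <- parse_ym(epoch)
  as.integer(12L * (b$yr - e$yr) + (b$mo - e$mo))
}

# inverse of compute_age: month string for an offset from the epoch
age_to_month <- function(age_months, epoch = "2006-01") {
  e <- as.integer(c(substr(epoch, 1, 4), substr(epoch, 6, 7)))
  tot <- (e[1] * 12L + (e[2] - 1L)) + as.integer(round(age_months))
  sprintf("%04d-%02d", tot %/% 12L, tot %% 12L + 1L)
}
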