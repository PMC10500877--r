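#' Read a PLINK v1 binary genotype triple
#'
#' Decodes \code{prefix.bed} (v1 magic bytes, SNP-major), \code{prefix.bim}
#' and \code{prefix.fam}. Dosages count copies of the .bim A1 allele
#' (stored as \code{allele_b}); the PLINK two-bit codes are 00 = A1/A1
#' (dosage 2), 01 = missing, 10 = heterozygous, 11 = A2/A2 (dosage 0).
#' Non-autosomal rows (chromosome outside 1--18) are dropped with a message.
#'
#' The .fam family ID is taken as the population label. If a sixth .fam
#' column holds a parseable \code{"YYYY-MM"} string it is used as the birth
#' month and AGE is computed; otherwise birth metadata are \code{NA}.
#'
#' @param prefix path prefix of the .bed/.bim/.fam triple.
#' @param autosomes integer chromosomes retained (default \code{1:18}, the
#'   pig autosomes).
#' @return A [geno_data()] object.
#' @export
read_plink <- function(prefix, autosomes = 1:18) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing PLINK file: ", p)

  bim <- utils::read.table(paths[2], header = FALSE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "pos_bp", "a1", "a2")
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bad PLINK .bed magic bytes in ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop(".bed is not in SNP-major (v1) mode: ", paths[1])
  bps <- ceiling(n / 4)                       # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop(".bed size inconsistent with .bim/.fam dimensions")
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = m)

  # expand each byte into 4 two-bit codes (sample index runs low bits first)
  codes <- matrix(NA_integer_, nrow = 4L * bps, ncol = m)
  q <- body
  for (k in 1:4) {
    codes[seq.int(k, by = 4L, length.out = bps), ] <- q %% 4L
    q <- q %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # code -> A1 dosage: 0 -> 2, 1 -> NA, 2 -> 1, 3 -> 0
  lut <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(lut[codes + 1L], nrow = n, ncol = m)

  chrom_num <- suppressWarnings(as.integer(bim$chrom))
  keep <- !is.na(chrom_num) & chrom_num %in% autosomes
  if (any(!keep))
    message("read_plink: dropped ", sum(!keep),
            " non-autosomal SNP(s); kept ", sum(keep))
  snps <- data.frame(snp_id = bim$snp_id[keep], chrom = chrom_num[keep],
                     pos_bp = bim$pos_bp[keep], allele_a = bim$a2[keep],
                     allele_b = bim$a1[keep], stringsAsFactors = FALSE)
  ord <- order(snps$chrom, snps$pos_bp)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  dos <- dos[, which(keep)[ord], drop = FALSE]

  birth <- rep(NA_character_, n)
  if (ncol(fam) >= 6) {
    ok <- grepl("^[0-9]{4}-[0-9]{2}$", fam[[6]])
    birth[ok] <- fam[[6]][ok]
  }
  samples <- data.frame(sample_id = fam[[2]], population = fam[[1]],
                        birth_month = birth,
                        age_months = ifelse(is.na(birth), NA_integer_,
                                            compute_age(birth)),
                        stringsAsFactors = FALSE)
  geno_data(dos, snps, samples)
}

#' Write a genotype dataset as a PLINK v1 binary triple
#'
#' Inverse of [read_plink()]: dosages, SNP map and sample ids round-trip
#' losslessly, including missing genotypes. The birth month (when known) is
#' written into the sixth .fam column so AGE survives the round trip.
#'
#' @param ds a [geno_data()] object with at least one SNP and one sample.
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(ds, prefix) {
  stopifnot(inherits(ds, "geno_data"))
  n <- nrow(ds$dosages); m <- ncol(ds$dosages)
  if (n == 0L || m == 0L) stop("cannot write an empty dataset")
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))

  bim <- data.frame(ds$snps$chrom, ds$snps$snp_id, 0, ds$snps$pos_bp,
                    ds$snps$allele_b, ds$snps$allele_a)
  utils::write.table(bim, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  birth <- ds$samples$birth_month
  fam <- data.frame(ds$samples$population, ds$samples$sample_id, 0, 0, 0,
                    ifelse(is.na(birth), "-9", birth))
  utils::write.table(fam, paths[3], sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # dosage -> code: 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  codes <- matrix(3L, nrow = n, ncol = m)
  codes[which(ds$dosages == 1L)] <- 2L
  codes[which(ds$dosages == 2L)] <- 0L
  codes[which(is.na(ds$dosages))] <- 1L
  bps <- ceiling(n / 4)
  pad <- 4L * bps - n
  if (pad > 0L) codes <- rbind(codes, matrix(0L, pad, m))
  w <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, nrow = bps, ncol = m)
  for (k in 1:4)
    bytes <- bytes + w[k] * codes[seq.int(k, by = 4L, length.out = bps), ,
                                  drop = FALSE]
  con <- file(paths[1], "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paths)
}
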