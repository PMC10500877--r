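#' Read a GFF/GTF-like feature table
#'
#' Minimal tab-delimited GFF reader for window annotation: keeps seqid,
#' feature type, 1-based inclusive start/end and a feature identifier
#' pulled from the attribute column (first of \code{ID=}, \code{gene_id},
#' \code{Name=}, \code{QTL_ID=}, else the raw attribute string). Lines that
#' do not have nine tab-separated fields or have non-numeric coordinates
#' are skipped with a warning naming the line number. Comment lines
#' (\code{#}) are ignored.
#'
#' @param path GFF/GTF file path (uncompressed text).
#' @param source label stored on every row (e.g. "gene_gff", "qtl_gff").
#' @return data.frame(feature_id, chrom, start, end, type, source).
#' @export
read_features <- function(path, source = "gene_gff") {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  skipped <- integer(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    st <- if (length(p) == 9L) suppressWarnings(as.integer(p[4])) else NA
    en <- if (length(p) == 9L) suppressWarnings(as.integer(p[5])) else NA
    if (length(p) != 9L || is.na(st) || is.na(en)) {
      skipped <- c(skipped, lineno[i])
      next
    }
    attr_s <- p[9]
    idm <- regmatches(attr_s,
      regexec('(?:ID=|gene_id[ ="]+|Name=|QTL_ID=)"?([^";]+)', attr_s))[[1]]
    fid <- if (length(idm) == 2) idm[2] else attr_s
    rows[[i]] <- data.frame(feature_id = fid, chrom = p[1], start = st,
                            end = en, type = p[3], source = source,
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " malformed GFF line(s), e.g. line ",
            skipped[1])
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(feature_id = character(), chrom = character(),
                      start = integer(), end = integer(), type = character(),
                      source = character(), stringsAsFactors = FALSE)
  out
}

#' Annotate significant SNPs with nearby features
#'
#' Reports every feature whose span intersects the symmetric window
#' [pos - window_bp, pos + window_bp] around each SNP (boundary inclusive;
#' strand is ignored, the window being a physical distance). Distance is 0
#' when the SNP lies inside the feature, otherwise the gap between the SNP
#' and the nearest feature end.
#'
#' @param sig_snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp} (e.g. significant rows of a [gpsm_scan()] table).
#' @param features data.frame from [read_features()] (or with columns
#'   \code{feature_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{source}).
#' @param window_bp half-window in bp (default 100000).
#' @return data.frame(snp_id, feature_id, chrom, start, end, distance_bp,
#'   source), one row per (SNP, feature) hit.
#' @export
annotate_windows <- function(sig_snps, features, window_bp = 100000) {
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(sig_snps)),
            all(c("feature_id", "chrom", "start", "end") %in%
                  names(features)))
  if (is.null(features$source)) features$source <- "gene_gff"
  hits <- lapply(seq_len(nrow(sig_snps)), function(i) {
    ch <- as.character(sig_snps$chrom[i]); pos <- sig_snps$pos_bp[i]
    f <- features[as.character(features$chrom) == ch, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    ok <- f$end >= pos - window_bp & f$start <= pos + window_bp
    f <- f[ok, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    d <- pmax(f$start - pos, pos - f$end, 0L)
    data.frame(snp_id = sig_snps$snp_id[i], feature_id = f$feature_id,
               chrom = ch, start = f$start, end = f$end, distance_bp = d,
               source = f$source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(snp_id = character(), feature_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), distance_bp = integer(),
                      source = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exclusive overlap counts of significant SNP sets
#'
#' For each non-empty subset S of populations, counts the SNPs significant
#' in exactly the populations of S (the bars of an upset plot), plus the
#' "significant in at least k populations" marginals. Exclusive counts sum
#' to the size of the union.
#'
#' @param sig_sets named list mapping population to a vector of significant
#'   SNP ids (at least two populations).
#' @return List with \code{exclusive} (data.frame: populations, a
#'   "+"-joined subset label; n) and \code{at_least} (data.frame: k, n).
#' @export
exclusive_overlaps <- function(sig_sets) {
  if (length(sig_sets) < 2) stop("need at least two populations")
  pops <- names(sig_sets)
  if (is.null(pops) || any(!nzchar(pops))) stop("sig_sets must be named")
  all_ids <- unique(unlist(sig_sets))
  member <- vapply(sig_sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, pops))
  key <- apply(member, 1, function(r) paste(pops[r], collapse = "+"))
  npop <- rowSums(member)
  subsets <- unlist(lapply(seq_along(pops), function(k)
    utils::combn(pops, k, paste, collapse = "+")))
  cnt <- table(factor(key, levels = subsets))
  exclusive <- data.frame(populations = subsets, n = as.integer(cnt),
                          stringsAsFactors = FALSE)
  exclusive <- exclusive[exclusive$n > 0, , drop = FALSE]
  rownames(exclusive) <- NULL
  at_least <- data.frame(
    k = seq_along(pops),
    n = vapply(seq_along(pops), function(k) sum(npop >= k), 0L))
  list(exclusive = exclusive, at_least = at_least,
       union_size = length(all_ids))
}
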