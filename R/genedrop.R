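#' Simulate a founder haplotype pool
#'
#' Draws site frequencies i.i.d. from a site-frequency spectrum (default a
#' U-shaped Beta(0.5, 0.5) truncated to [0.01, 0.99]) and founder haplotype
#' alleles as independent Bernoulli draws at those frequencies, so the pool
#' is in linkage equilibrium. Sites are evenly spaced along the 18
#' autosomes; any site fixed in the finite pool is redrawn so every site
#' segregates. Haplotypes are stored one byte per allele.
#'
#' @param n_founders number of founder individuals (2 haplotypes each).
#' @param n_sites total number of sites; must be divisible by the number of
#'   autosomes (default 18).
#' @param seed integer seed; the pool is a pure function of its arguments.
#' @param sfs function(k) returning k allele frequencies in (0, 1), or NULL
#'   for the truncated Beta(0.5, 0.5) default.
#' @param n_autosomes number of chromosomes (default 18).
#' @param chrom_bp physical chromosome length in bp (default 150e6).
#' @param morgans_per_chrom genetic map length per chromosome (default 1.0).
#' @return Object of class \code{"founder_pool"}: \code{haplotypes} (raw
#'   matrix, 2 n_founders x n_sites), \code{map} (chrom, pos_bp, gpos in
#'   Morgans), \code{freq}, \code{n_founders}, \code{seed}.
#' @export
simulate_founder_pool <- function(n_founders = 5000, n_sites = 90000,
                                  seed = 1, sfs = NULL, n_autosomes = 18,
                                  chrom_bp = 150e6,
                                  morgans_per_chrom = 1.0) {
  if (n_sites %% n_autosomes != 0)
    stop("n_sites must be divisible by the number of autosomes (",
         n_autosomes, ")")
  set.seed(seed)
  if (is.null(sfs))
    sfs <- function(k) {
      f <- stats::rbeta(k, 0.5, 0.5)
      pmin(pmax(f, 0.01), 0.99)
    }
  spc <- n_sites %/% n_autosomes
  nh <- 2L * n_founders
  freq <- sfs(n_sites)
  H <- matrix(as.raw(stats::rbinom(nh * n_sites, 1L, rep(freq, each = nh))),
              nrow = nh, ncol = n_sites)
  # redraw sites fixed in the finite pool
  repeat {
    cs <- colSums(H != as.raw(0))
    bad <- which(cs == 0L | cs == nh)
    if (!length(bad)) break
    freq[bad] <- sfs(length(bad))
    H[, bad] <- as.raw(stats::rbinom(nh * length(bad), 1L,
                                     rep(freq[bad], each = nh)))
  }
  map <- data.frame(
    chrom = rep(seq_len(n_autosomes), each = spc),
    pos_bp = rep(round(seq_len(spc) * (chrom_bp / spc)), n_autosomes),
    gpos = rep((seq_len(spc) - 0.5) / spc * morgans_per_chrom, n_autosomes))
  structure(list(haplotypes = H, map = map, freq = freq,
                 n_founders = n_founders, seed = seed),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat("founder_pool:", x$n_founders, "founders,", nrow(x$map), "sites on",
      length(unique(x$map$chrom)), "chromosomes (seed", x$seed, ")\n")
  invisible(x)
}

# founder slots of a pedigree: individuals with both parents unknown get one
# diplotype; an individual with exactly one unknown parent gets a phantom
# founder for the unknown side (its gamete is a meiosis of that phantom)
founder_slots <- function(ped) {
  no_sire <- is.na(ped$sire); no_dam <- is.na(ped$dam)
  slots <- ped$id[no_sire & no_dam]
  phant_s <- ped$id[!no_sire & no_dam]     # dam unknown
  phant_d <- ped$id[no_sire & !no_dam]     # sire unknown
  c(slots,
    if (length(phant_s)) paste0(phant_s, "@dam"),
    if (length(phant_d)) paste0(phant_d, "@sire"))
}

#' Assign pool founders to pedigree founders
#'
#' Each pedigree founder (and each unknown-parent slot, which is treated as
#' a new founder) receives the diplotype of a distinct pool individual,
#' sampled without replacement. Under \code{"method1_shared"} all
#' populations draw from one shared pool (recent-divergence extreme); under
#' \code{"method2_independent"} each population draws from its own
#' independently simulated pool (unrelated-populations extreme), and the
#' pools must have been simulated with distinct seeds.
#'
#' @param pool a [simulate_founder_pool()] result (method 1), or a named
#'   list of pools keyed by population (method 2).
#' @param ped a pedigree data.frame (see [generate_pedigree()]).
#' @param scheme \code{"method1_shared"} or \code{"method2_independent"}.
#' @param seed integer seed for the random assignment.
#' @return Object of class \code{"founder_assignment"}: \code{slots}
#'   (slot id), \code{pool_name}, \code{founder_index}, plus the pools and
#'   scheme.
#' @export
assign_pedigree_founders <- function(pool, ped,
                                     scheme = c("method1_shared",
                                                "method2_independent"),
                                     seed = 1) {
  scheme <- match.arg(scheme)
  ped <- validate_pedigree(ped)
  set.seed(seed)
  slots <- founder_slots(ped)
  base_id <- sub("@(sire|dam)$", "", slots)
  slot_pop <- ped$population[match(base_id, ped$id)]
  if (scheme == "method1_shared") {
    if (!inherits(pool, "founder_pool"))
      stop("method1_shared needs a single founder_pool")
    pools <- list(shared = pool)
    pool_name <- rep("shared", length(slots))
  } else {
    if (inherits(pool, "founder_pool") || is.null(names(pool)))
      stop("method2_independent needs a named list of pools per population")
    pops <- unique(slot_pop)
    if (!all(pops %in% names(pool)))
      stop("missing pool for population(s): ",
           paste(setdiff(pops, names(pool)), collapse = ", "))
    seeds <- vapply(pool, function(p) p$seed, 0)
    if (anyDuplicated(seeds))
      stop("method2_independent pools must be simulated with distinct seeds")
    maps <- lapply(pool, function(p) p$map)
    if (!all(vapply(maps[-1], identical, TRUE, maps[[1]])))
      stop("all pools must share the same site map")
    pools <- pool
    pool_name <- slot_pop
  }
  founder_index <- integer(length(slots))
  for (pn in unique(pool_name)) {
    idx <- which(pool_name == pn)
    nf <- pools[[pn]]$n_founders
    if (length(idx) > nf) {
      warning("more founder slots (", length(idx), ") than pool founders (",
              nf, ") for pool '", pn, "'; sampling with replacement")
      founder_index[idx] <- sample.int(nf, length(idx), replace = TRUE)
    } else {
      founder_index[idx] <- sample.int(nf, length(idx))
    }
  }
  structure(list(slots = slots, pool_name = pool_name,
                 founder_index = founder_index, pools = pools,
                 scheme = scheme, seed = seed),
            class = "founder_assignment")
}

# one gamete: recombine two parental haplotype vectors on one chromosome
meiose <- function(h1, h2, gpos, map_len) {
  k <- stats::rpois(1L, map_len)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(if (start == 1L) h1 else h2)
  bps <- sort(stats::runif(k, 0, map_len))
  seg <- findInterval(gpos, bps)
  pick <- (start + seg) %% 2L
  out <- h2
  sel <- pick == 1L
  out[sel] <- h1[sel]
  out
}

#' Drop founder haplotypes through a pedigree
#'
#' Transmits the assigned founder haplotypes through the pedigree by
#' Mendelian segregation with recombination: per meiosis and chromosome the
#' crossover count is Poisson with mean equal to the chromosome map length
#' in Morgans, breakpoints are uniform on the map, and there is no
#' interference. Genotypes produced this way reflect drift and pedigree
#' structure only — the drift null for selection mapping. Unknown parents
#' are treated as new founders (handled by the assignment).
#'
#' @param assignment a [assign_pedigree_founders()] result.
#' @param ped pedigree data.frame, topologically ordered (parents before
#'   offspring; an error is raised otherwise).
#' @param seed integer seed for all meioses.
#' @param keep optional character vector of ids to retain haplotypes for
#'   (default: every pedigree member). Restricting this bounds memory for
#'   large pedigrees.
#' @return Object of class \code{"gene_drop"}: \code{ids}, \code{hap1} and
#'   \code{hap2} (ids x sites integer 0/1 matrices), \code{map},
#'   \code{provenance} (the assignment).
#' @export
gene_drop <- function(assignment, ped, seed = 1, keep = NULL) {
  stopifnot(inherits(assignment, "founder_assignment"))
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  row_of <- seq_len(n); names(row_of) <- ped$id
  sire_r <- row_of[ped$sire]; dam_r <- row_of[ped$dam]
  if (any(!is.na(ped$sire) & is.na(sire_r)) ||
      any(!is.na(ped$dam) & is.na(dam_r)))
    stop("pedigree refers to parents absent from the id column")
  if (any(sire_r >= row_of, na.rm = TRUE) ||
      any(dam_r >= row_of, na.rm = TRUE))
    stop("pedigree is not topologically ordered (parent after offspring)")

  if (is.null(keep)) keep <- ped$id
  krow <- match(keep, ped$id)
  if (anyNA(krow)) stop("keep contains ids absent from the pedigree")
  slot_of_id <- match(ped$id, assignment$slots)
  phantom_sire <- match(paste0(ped$id, "@sire"), assignment$slots)
  phantom_dam <- match(paste0(ped$id, "@dam"), assignment$slots)

  map <- assignment$pools[[1]]$map
  chroms <- unique(map$chrom)
  S <- nrow(map)
  K <- length(keep)
  hap1 <- matrix(0L, K, S); hap2 <- matrix(0L, K, S)

  set.seed(seed)
  for (ch in chroms) {
    cidx <- which(map$chrom == ch)
    gpos <- map$gpos[cidx]
    map_len <- max(gpos) + min(gpos)   # sites at (i - 0.5)/spc * L
    H1 <- matrix(0L, n, length(cidx))
    H2 <- matrix(0L, n, length(cidx))
    pool_hap <- function(slot_i, which_h) {
      p <- assignment$pools[[assignment$pool_name[slot_i]]]
      fi <- assignment$founder_index[slot_i]
      as.integer(p$haplotypes[2L * fi - 2L + which_h, cidx] != as.raw(0))
    }
    for (i in seq_len(n)) {
      si <- slot_of_id[i]
      if (!is.na(si)) {                        # pedigree founder
        H1[i, ] <- pool_hap(si, 1L)
        H2[i, ] <- pool_hap(si, 2L)
        next
      }
      sr <- sire_r[i]
      if (!is.na(sr)) {
        H1[i, ] <- meiose(H1[sr, ], H2[sr, ], gpos, map_len)
      } else {
        ps <- phantom_sire[i]
        H1[i, ] <- meiose(pool_hap(ps, 1L), pool_hap(ps, 2L), gpos, map_len)
      }
      dr <- dam_r[i]
      if (!is.na(dr)) {
        H2[i, ] <- meiose(H1[dr, ], H2[dr, ], gpos, map_len)
      } else {
        pd <- phantom_dam[i]
        H2[i, ] <- meiose(pool_hap(pd, 1L), pool_hap(pd, 2L), gpos, map_len)
      }
    }
    hap1[, cidx] <- H1[krow, , drop = FALSE]
    hap2[, cidx] <- H2[krow, , drop = FALSE]
  }
  structure(list(ids = keep, hap1 = hap1, hap2 = hap2, map = map,
                 provenance = assignment, seed = seed),
            class = "gene_drop")
}

#' @export
print.gene_drop <- function(x, ...) {
  cat("gene_drop:", length(x$ids), "individuals,", nrow(x$map), "sites\n")
  invisible(x)
}

#' Count Mendelian violations in dropped genotypes
#'
#' For every trio fully contained in the drop, counts genotype combinations
#' impossible under Mendelian transmission (e.g. homozygous parents with an
#' offspring carrying an allele neither parent has). A correct gene-drop
#' yields zero.
#'
#' @param dropped a [gene_drop()] result covering offspring and parents.
#' @param ped the pedigree it was dropped through.
#' @return Integer count of violating (trio, site) pairs.
#' @export
mendelian_violations <- function(dropped, ped) {
  ped <- validate_pedigree(ped)
  idx <- match(ped$id, dropped$ids)
  si <- match(ped$sire, dropped$ids)
  di <- match(ped$dam, dropped$ids)
  trio <- which(!is.na(idx) & !is.na(si) & !is.na(di))
  if (!length(trio)) return(0L)
  dos <- dropped$hap1 + dropped$hap2
  viol <- 0L
  for (i in trio) {
    o <- dos[idx[i], ]; s <- dos[si[i], ]; d <- dos[di[i], ]
    # offspring must receive one allele from each parent
    bad <- (s == 0L & o == 2L) | (s == 2L & o == 0L) |
           (d == 0L & o == 2L) | (d == 2L & o == 0L) |
           (s == 0L & d == 0L & o != 0L) | (s == 2L & d == 2L & o != 2L) |
           (s == 0L & d == 2L & o != 1L) | (s == 2L & d == 0L & o != 1L)
    viol <- viol + sum(bad)
  }
  viol
}

#' Extract a SNP-array sample from dropped genotypes
#'
#' Builds a genotype dataset for the genotyped individuals: their dosages
#' at a uniform random subset of sites that segregate in the extracted
#' sample, mimicking array genotyping of the real animals. Sites
#' monomorphic among the extracted individuals are excluded before
#' sampling; when \code{requalify} is TRUE (default) sites below
#' \code{min_maf} are also excluded, mirroring array QC. Birth metadata
#' (AGE) are copied from the pedigree.
#'
#' @param dropped a [gene_drop()] result (or a [simulate_selection()]
#'   result, whose \code{$drop} element is used).
#' @param ped the pedigree providing birth months and population labels.
#' @param genotyped_ids ids to extract; must be present in \code{dropped}.
#' @param n_array_snps number of array SNPs to sample.
#' @param seed integer seed for the site subset.
#' @param requalify apply the MAF filter before sampling (default TRUE).
#' @param min_maf minimum MAF when requalifying (default 0.01).
#' @return A [geno_data()] object.
#' @export
extract_array <- function(dropped, ped, genotyped_ids, n_array_snps,
                          seed = 1, requalify = TRUE, min_maf = 0.01) {
  if (!inherits(dropped, "gene_drop") && !is.null(dropped$drop))
    dropped <- dropped$drop
  stopifnot(inherits(dropped, "gene_drop"))
  ped <- validate_pedigree(ped)
  rows <- match(genotyped_ids, dropped$ids)
  if (anyNA(rows))
    stop("genotyped_ids absent from the drop: ",
         genotyped_ids[is.na(rows)][1])
  all_rows <- identical(rows, seq_len(nrow(dropped$hap1)))
  h1 <- if (all_rows) dropped$hap1 else dropped$hap1[rows, , drop = FALSE]
  h2 <- if (all_rows) dropped$hap2 else dropped$hap2[rows, , drop = FALSE]
  S <- ncol(h1)
  f <- numeric(S)
  for (j0 in seq(1, S, by = 4000L)) {   # blockwise: bounds peak memory
    jj <- j0:min(j0 + 3999L, S)
    f[jj] <- colMeans(h1[, jj, drop = FALSE] + h2[, jj, drop = FALSE]) / 2
  }
  ok <- f > 0 & f < 1
  if (requalify) ok <- ok & pmin(f, 1 - f) >= min_maf
  if (sum(ok) < n_array_snps)
    stop("only ", sum(ok), " segregating sites available; ",
         n_array_snps, " requested")
  set.seed(seed)
  pick <- sort(sample(which(ok), n_array_snps))
  dos <- h1[, pick, drop = FALSE] + h2[, pick, drop = FALSE]
  snps <- data.frame(
    snp_id = sprintf("s%d_%d", dropped$map$chrom[pick],
                     dropped$map$pos_bp[pick]),
    chrom = dropped$map$chrom[pick], pos_bp = dropped$map$pos_bp[pick],
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  pr <- match(genotyped_ids, ped$id)
  if (anyNA(pr)) stop("genotyped_ids absent from the pedigree")
  samples <- data.frame(
    sample_id = genotyped_ids,
    population = ped$population[pr],
    birth_month = ped$birth_month[pr],
    age_months = compute_age(ped$birth_month[pr]),
    stringsAsFactors = FALSE)
  geno_data(dos, snps, samples)
}
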