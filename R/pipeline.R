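#' Run configuration
#'
#' Flat configuration record driving the pipeline wrappers: QC thresholds,
#' FDR threshold, annotation window, simulation sizes and seeds. Round-trips
#' losslessly through [save_run_config()] / [load_run_config()].
#'
#' @param ... overrides of the defaults.
#' @return A named list of class \code{"run_config"}.
#' @export
run_config <- function(...) {
  cfg <- list(
    snp_call_rate = 0.90, sample_call_rate = 0.90, maf = 0.01,
    purity_min_prop = 0.95, fdr = 0.10, window_bp = 100000,
    pool_founders = 5000, n_sites = 90000, n_array_snps = 20000,
    n_replicates = 5, seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a \code{run_config}.
#' @param path file path (DCF, one field per line).
#' @export
save_run_config <- function(cfg, path) {
  m <- matrix(vapply(cfg, function(v) format(v, digits = 17), ""),
              nrow = 1, dimnames = list(NULL, names(cfg)))
  write.dcf(m, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  m <- read.dcf(path)
  vals <- as.list(as.numeric(m[1, ]))
  names(vals) <- colnames(m)
  do.call(run_config, vals)
}

#' End-to-end selection scan
#'
#' The full analysis on one dataset: quality control, genomic relationship
#' matrix, null variance-component REML, per-SNP scan, q-values, effect
#' summaries, and (optionally) window annotation of significant SNPs.
#'
#' @param input a [geno_data()] object or a PLINK file prefix.
#' @param config a [run_config()].
#' @param features optional feature table ([read_features()]) for
#'   annotation.
#' @param out_dir optional directory; when given, the association table,
#'   QC report and a manifest are written as tab-separated text.
#' @return List of class \code{"gpsm_run"}: \code{fit} (a [gpsm()]
#'   object), \code{qc_report}, \code{summaries}, \code{annotation}
#'   (or NULL), \code{manifest}.
#' @export
run_gpsm <- function(input, config = run_config(), features = NULL,
                     out_dir = NULL) {
  ds <- if (inherits(input, "geno_data")) input else read_plink(input)
  n0 <- dim(ds)
  ds <- qc_filter(ds, snp_call_rate = config$snp_call_rate,
                  maf = config$maf,
                  sample_call_rate = config$sample_call_rate)
  qc_rep <- attr(ds, "qc_report")
  fit <- gpsm(ds, fdr = config$fdr)
  summaries <- effect_summaries(fit$assoc)
  ann <- NULL
  if (!is.null(features)) {
    sig <- fit$assoc[fit$assoc$significant, c("snp_id", "chrom", "pos_bp")]
    ann <- annotate_windows(sig, features, window_bp = config$window_bp)
  }
  manifest <- list(
    stage_counts = c(input_samples = n0[1], input_snps = n0[2],
                     qc_samples = fit$n, qc_snps = fit$n_snps,
                     significant = summaries$n_significant),
    pve = fit$vc$pve, pi0 = attr(fit$assoc, "pi0"),
    fdr = config$fdr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fit$assoc, file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qc_rep, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ann))
      utils::write.table(ann, file.path(out_dir, "annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = "\t"),
               file.path(out_dir, "manifest.tsv"))
  }
  structure(list(fit = fit, qc_report = qc_rep, summaries = summaries,
                 annotation = ann, manifest = manifest),
            class = "gpsm_run")
}

#' @export
print.gpsm_run <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

# deterministic per-replicate sub-seeds from a base seed (kept < 2^31)
derive_seed <- function(seed, r, k) {
  (as.integer(seed) %% 100000L) * 10000L + r * 100L + k
}

#' Gene-drop false-positive-rate study
#'
#' The drift-null experiment: for each replicate, simulate a founder pool,
#' assign pool founders to the pedigree founders, gene-drop through the
#' pedigree, extract an array for the genotyped animals (with their real
#' AGE values), run the full scan, and count SNPs called significant. The
#' error rate is 100 x significant / tested, pooled over replicates. Since
#' the dropped genotypes contain no selection, every significant call is a
#' false positive.
#'
#' @param ped pedigree data.frame.
#' @param genotyped_ids ids of the genotyped animals (their AGE comes from
#'   the pedigree's birth months).
#' @param n_replicates number of gene-drop replicates (default 5).
#' @param pool_founders founder pool size per replicate (default 5000).
#' @param n_sites pool sites (default 90000).
#' @param n_array_snps array SNPs extracted per replicate (default 20000).
#' @param fdr significance threshold on q (default 0.10).
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param keep_pvalues store each replicate's p-values (for calibration
#'   diagnostics; default TRUE).
#' @return Object of class \code{"genedrop_null"}: \code{replicates}
#'   (data.frame: replicate, n_snps, n_significant, error_rate_pct, pve),
#'   \code{pooled_error_rate_pct}, \code{pvalues} (list), \code{failed}.
#' @export
run_genedrop_null <- function(ped, genotyped_ids, n_replicates = 5,
                              pool_founders = 5000, n_sites = 90000,
                              n_array_snps = 20000, fdr = 0.10, seed = 1,
                              keep_pvalues = TRUE) {
  ped <- validate_pedigree(ped)
  reps <- vector("list", n_replicates)
  pvals <- vector("list", n_replicates)
  failed <- integer(0)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      pool <- simulate_founder_pool(pool_founders, n_sites,
                                    seed = derive_seed(seed, r, 1L))
      asg <- assign_pedigree_founders(pool, ped, "method1_shared",
                                      seed = derive_seed(seed, r, 2L))
      dropped <- gene_drop(asg, ped, seed = derive_seed(seed, r, 3L),
                           keep = genotyped_ids)
      ds <- extract_array(dropped, ped, genotyped_ids, n_array_snps,
                          seed = derive_seed(seed, r, 4L))
      rm(pool, asg, dropped)            # free the drop before the scan
      gc(verbose = FALSE)
      fit <- gpsm(ds, fdr = fdr)
      list(assoc = fit$assoc, pve = fit$vc$pve)
    }, error = function(e) e)
    gc(verbose = FALSE)
    if (inherits(res, "error")) {
      warning("replicate ", r, " failed: ", conditionMessage(res))
      failed <- c(failed, r)
      next
    }
    a <- res$assoc
    reps[[r]] <- data.frame(
      replicate = r, n_snps = nrow(a), n_significant = sum(a$significant),
      error_rate_pct = 100 * sum(a$significant) / nrow(a),
      pve = res$pve)
    if (keep_pvalues) pvals[[r]] <- a$p
  }
  rep_df <- do.call(rbind, reps)
  pooled <- if (is.null(rep_df)) NA_real_ else
    100 * sum(rep_df$n_significant) / sum(rep_df$n_snps)
  structure(list(replicates = rep_df, pooled_error_rate_pct = pooled,
                 pvalues = if (keep_pvalues) pvals else NULL,
                 failed = failed, fdr = fdr, seed = seed),
            class = "genedrop_null")
}

#' @export
print.genedrop_null <- function(x, ...) {
  cat("Gene-drop drift null:", nrow(x$replicates), "replicate(s)\n")
  print(x$replicates, row.names = FALSE)
  cat(sprintf("  pooled false-positive rate at q < %.2f: %.4f%%\n",
              x$fdr, x$pooled_error_rate_pct))
  if (length(x$failed)) cat("  failed replicates:",
                            paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Bivariate drift-null or cross-population analysis on simulated genotypes
#'
#' Drops founder genotypes through two population pedigrees — from one
#' shared pool (method 1, recent divergence) or two independently seeded
#' pools (method 2, unrelated populations) — extracts a union SNP array,
#' and fits the bivariate model for AGE. Under drift the genetic
#' correlation between populations is expected to be 0.
#'
#' @param ped1,ped2 pedigrees of the two populations (distinct population
#'   labels and ids).
#' @param genotyped1,genotyped2 genotyped ids per population.
#' @param method \code{"method1_shared"} or \code{"method2_independent"}.
#' @param pool_founders pool size per population (method 1 uses one pool of
#'   \code{2 * pool_founders}).
#' @param n_sites,n_array_snps pool sites and extracted array size.
#' @param seed base seed.
#' @return List of class \code{"bivar_run"}: \code{fit} (a
#'   [reml_bivariate()] object), \code{method}, \code{n_snps}.
#' @export
run_bivariate <- function(ped1, ped2, genotyped1, genotyped2,
                          method = c("method1_shared",
                                     "method2_independent"),
                          pool_founders = 5000, n_sites = 90000,
                          n_array_snps = 20000, seed = 1) {
  method <- match.arg(method)
  ped1 <- validate_pedigree(ped1); ped2 <- validate_pedigree(ped2)
  pop1 <- unique(ped1$population); pop2 <- unique(ped2$population)
  if (length(pop1) != 1 || length(pop2) != 1)
    stop("each pedigree must carry a single population label")
  if (identical(pop1, pop2))
    stop("the two pedigrees must be different populations")
  if (any(ped1$id %in% ped2$id)) stop("pedigree ids overlap")
  ped <- rbind(ped1, ped2)
  if (method == "method1_shared") {
    pool <- simulate_founder_pool(2L * pool_founders, n_sites,
                                  seed = derive_seed(seed, 1L, 1L))
    asg <- assign_pedigree_founders(pool, ped, "method1_shared",
                                    seed = derive_seed(seed, 1L, 2L))
  } else {
    pools <- list(
      simulate_founder_pool(pool_founders, n_sites,
                            seed = derive_seed(seed, 1L, 1L)),
      simulate_founder_pool(pool_founders, n_sites,
                            seed = derive_seed(seed, 2L, 1L)))
    names(pools) <- c(pop1, pop2)
    asg <- assign_pedigree_founders(pools, ped, "method2_independent",
                                    seed = derive_seed(seed, 1L, 2L))
  }
  gids <- c(genotyped1, genotyped2)
  dropped <- gene_drop(asg, ped, seed = derive_seed(seed, 1L, 3L),
                       keep = gids)
  ds <- extract_array(dropped, ped, gids, n_array_snps,
                      seed = derive_seed(seed, 1L, 4L))
  G <- make_grm(ds)
  memb <- ds$samples$population
  y1 <- ds$samples$age_months[memb == pop1]
  y2 <- ds$samples$age_months[memb == pop2]
  fit <- reml_bivariate(y1, y2, G, memb, pops = c(pop1, pop2))
  structure(list(fit = fit, method = method, n_snps = ncol(ds$dosages),
                 seed = seed),
            class = "bivar_run")
}

#' @export
print.bivar_run <- function(x, ...) {
  cat("Simulated bivariate run (", x$method, ", ", x$n_snps, " SNPs)\n",
      sep = "")
  print(x$fit)
  invisible(x)
}
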