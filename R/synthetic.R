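#' Validate (and topologically order) a pedigree table
#'
#' A pedigree is a data.frame with columns \code{id}, \code{sire},
#' \code{dam} (NA for unknown), \code{birth_month} ("YYYY-MM"),
#' \code{population} and \code{generation}. Ids must be unique and the
#' parent-offspring graph acyclic; rows are reordered so parents precede
#' offspring (an error is raised on a cycle).
#'
#' @param ped pedigree data.frame.
#' @return The validated pedigree, topologically ordered.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "sire", "dam", "birth_month", "population", "generation")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("pedigree ids must be unique")
  for (col in c("sire", "dam")) {
    v <- as.character(ped[[col]])
    v[v %in% c("", "0", "NA")] <- NA_character_
    ped[[col]] <- v
  }
  ped$id <- as.character(ped$id)
  n <- nrow(ped)
  pos <- seq_len(n); names(pos) <- ped$id
  sp <- pos[ped$sire]; dp <- pos[ped$dam]
  ordered <- !any(sp >= pos, na.rm = TRUE) && !any(dp >= pos, na.rm = TRUE)
  if (!ordered) {
    # Kahn topological sort on the parent -> offspring DAG
    parents <- cbind(sp, dp)
    indeg <- rowSums(!is.na(parents))
    out <- integer(0)
    ready <- which(indeg == 0)
    child_of <- split(rep(seq_len(n), 2), c(sp, dp))
    indeg_left <- indeg
    while (length(ready)) {
      out <- c(out, ready)
      nxt <- integer(0)
      for (r in ready) {
        kids <- child_of[[as.character(r)]]
        for (k in kids) {
          indeg_left[k] <- indeg_left[k] - 1L
          if (indeg_left[k] == 0L) nxt <- c(nxt, k)
        }
      }
      ready <- nxt
    }
    if (length(out) != n) stop("pedigree contains a cycle")
    ped <- ped[out, , drop = FALSE]
  }
  rownames(ped) <- NULL
  ped
}

#' Breeding-program configuration
#'
#' Parameters of the synthetic multi-generation breeding program. Defaults
#' describe a desk-scale nucleus line: 10 discrete generations, a
#' generation interval of 27 months (pigs turn over in 2--2.5 years),
#' litters of 7, truncation selection keeping the top 10\% of boars and 30\%
#' of gilts on a selection index whose correlation with the true polygenic
#' breeding value is \code{index_accuracy} (0 reduces the program to random
#' mating, i.e. pure drift). Birth months get Gaussian jitter
#' (\code{birth_jitter_sd} months) to mimic overlapping farrowing groups.
#'
#' @param n_generations number of bred generations (default 10).
#' @param n_founder_sires,n_founder_dams founder counts (default 25 / 150).
#' @param litters_per_dam,litter_size litters per dam per generation and
#'   piglets per litter (defaults 1 and 7).
#' @param sires_selected_frac,dams_selected_frac fraction of male / female
#'   candidates kept as parents (defaults 0.10 and 0.30).
#' @param generation_interval_months months between successive generations
#'   (default 27).
#' @param birth_jitter_sd SD of the birth-month jitter (default 3).
#' @param n_causal_loci,causal_effect_sd polygenic architecture of the
#'   selection index (defaults 50 loci, effect SD 1).
#' @param index_accuracy correlation between the ranking criterion and the
#'   true breeding value (default 0.7).
#' @param genotyping_scheme \code{"left_skewed"} (genotyping volume grows
#'   with birth year, as in commercial SNP platforms) or \code{"uniform"}.
#' @param population population label (default "SimPop").
#' @param start_month founder birth month (default "1997-06", placing the
#'   final generations in the late 2010s relative to the January 2006 AGE
#'   epoch).
#' @return A list of class \code{"breeding_config"}.
#' @export
breeding_config <- function(n_generations = 10, n_founder_sires = 25,
                            n_founder_dams = 150, litters_per_dam = 1,
                            litter_size = 7, sires_selected_frac = 0.10,
                            dams_selected_frac = 0.30,
                            generation_interval_months = 27,
                            birth_jitter_sd = 3, n_causal_loci = 50,
                            causal_effect_sd = 1, index_accuracy = 0.7,
                            genotyping_scheme = c("left_skewed", "uniform"),
                            population = "SimPop",
                            start_month = "1997-06") {
  genotyping_scheme <- match.arg(genotyping_scheme)
  stopifnot(litter_size >= 1, litters_per_dam >= 1, n_generations >= 1)
  for (f in c(sires_selected_frac, dams_selected_frac))
    if (!(f > 0 && f <= 1)) stop("selected fractions must be in (0, 1]")
  if (index_accuracy < 0 || index_accuracy > 1)
    stop("index_accuracy must be in [0, 1]")
  structure(as.list(environment()), class = "breeding_config")
}

# birth month for generation g with jitter, as "YYYY-MM"
gen_birth_month <- function(cfg, g, k) {
  off <- compute_age(cfg$start_month) + g * cfg$generation_interval_months +
    round(stats::rnorm(k, 0, cfg$birth_jitter_sd))
  age_to_month(off)
}

#' Generate a drift-mode breeding pedigree
#'
#' Builds the pedigree of a closed breeding program in which parents of
#' each generation are chosen at random (no selection): founders mate to
#' form generation 1, and each generation a random subset of males and
#' females becomes the next parents. Birth months advance by the
#' generation interval with jitter. Use [simulate_selection()] when the
#' parent choice should depend on genotype.
#'
#' @param cfg a [breeding_config()].
#' @param seed integer seed; the pedigree is a pure function of (cfg, seed).
#' @return A pedigree data.frame with columns \code{id}, \code{sire},
#'   \code{dam}, \code{birth_month}, \code{population}, \code{generation},
#'   \code{sex}.
#' @export
generate_pedigree <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "breeding_config"))
  set.seed(seed)
  build_pedigree(cfg, ranker = NULL)
}

# shared pedigree constructor; `ranker(ids)` returns the selection
# criterion for candidate ids (NULL = random ranking, i.e. drift)
build_pedigree <- function(cfg, ranker = NULL, on_new = NULL) {
  pop <- cfg$population
  ns <- cfg$n_founder_sires; nd <- cfg$n_founder_dams
  ids <- function(g, k) sprintf("%s_g%d_%04d", pop, g, seq_len(k))
  sires <- ids(0, ns)
  dams <- paste0(ids(0, nd), "d")
  founders <- data.frame(
    id = c(sires, dams), sire = NA_character_, dam = NA_character_,
    birth_month = gen_birth_month(cfg, 0, ns + nd), population = pop,
    generation = 0L, sex = c(rep("M", ns), rep("F", nd)),
    stringsAsFactors = FALSE)
  if (!is.null(on_new)) on_new(founders)
  rows <- list(founders)
  for (g in seq_len(cfg$n_generations)) {
    n_lit <- length(dams) * cfg$litters_per_dam
    lit_dam <- rep(dams, each = cfg$litters_per_dam)
    lit_sire <- sample(sires, n_lit, replace = TRUE)
    k <- n_lit * cfg$litter_size
    off <- data.frame(
      id = sprintf("%s_g%d_%05d", pop, g, seq_len(k)),
      sire = rep(lit_sire, each = cfg$litter_size),
      dam = rep(lit_dam, each = cfg$litter_size),
      birth_month = gen_birth_month(cfg, g, k), population = pop,
      generation = g, sex = sample(c("M", "F"), k, replace = TRUE),
      stringsAsFactors = FALSE)
    if (!is.null(on_new)) on_new(off)
    rows[[g + 1L]] <- off
    if (g == cfg$n_generations) break
    males <- off$id[off$sex == "M"]; females <- off$id[off$sex == "F"]
    n_s <- max(1L, round(cfg$sires_selected_frac * length(males)))
    n_d <- max(1L, round(cfg$dams_selected_frac * length(females)))
    if (!length(males) || !length(females))
      stop("no candidates of one sex in generation ", g)
    if (is.null(ranker)) {
      sires <- sample(males, n_s)
      dams <- sample(females, n_d)
    } else {
      crit_m <- ranker(males); crit_f <- ranker(females)
      sires <- males[order(crit_m, decreasing = TRUE)[seq_len(n_s)]]
      dams <- females[order(crit_f, decreasing = TRUE)[seq_len(n_d)]]
    }
  }
  do.call(rbind, rows)
}

#' Simulate a breeding program with truncation selection on a polygenic
#' index
#'
#' Couples pedigree construction to a gene-drop: founders receive pool
#' diplotypes, every candidate's true breeding value (TBV) is the sum of
#' causal dosages times effects drawn N(0, causal_effect_sd^2), and parents
#' are the top fractions on a ranking criterion = TBV + noise scaled so
#' that cor(criterion, TBV) = \code{index_accuracy}. With accuracy 0 the
#' program reduces to drift. Causal loci and effects are returned as truth
#' for power evaluation.
#'
#' @param cfg a [breeding_config()].
#' @param pool optional [simulate_founder_pool()]; by default a pool of
#'   \code{n_founder_sires + n_founder_dams} founders at \code{n_sites}
#'   sites is simulated from \code{seed + 1}.
#' @param n_sites sites when simulating the default pool (default 5400).
#' @param causal optional data.frame(site, effect) to reuse causal
#'   architecture across populations (shared selection objectives).
#' @param seed integer seed.
#' @return Object of class \code{"breeding_sim"}: \code{pedigree},
#'   \code{drop} (a [gene_drop()]-compatible object over every pedigree
#'   member), \code{causal} (site, chrom, pos_bp, effect), \code{config}.
#' @export
simulate_selection <- function(cfg, pool = NULL, n_sites = 5400,
                               causal = NULL, seed = 1) {
  stopifnot(inherits(cfg, "breeding_config"))
  if (is.null(pool))
    pool <- simulate_founder_pool(
      n_founders = cfg$n_founder_sires + cfg$n_founder_dams,
      n_sites = n_sites, seed = seed + 1L)
  set.seed(seed)
  S <- nrow(pool$map)
  if (is.null(causal)) {
    if (cfg$n_causal_loci > S)
      stop("n_causal_loci exceeds the number of pool sites")
    causal <- data.frame(
      site = sort(sample.int(S, cfg$n_causal_loci)),
      effect = stats::rnorm(cfg$n_causal_loci, 0, cfg$causal_effect_sd))
  }

  # grow haplotype store as generations are appended
  env <- new.env()
  env$ids <- character(0)
  env$hap1 <- NULL; env$hap2 <- NULL
  env$free_founders <- sample.int(pool$n_founders)
  chroms <- unique(pool$map$chrom)
  cidx <- split(seq_len(S), pool$map$chrom)
  gl <- lapply(cidx, function(ii) pool$map$gpos[ii])
  glen <- vapply(gl, function(g) max(g) + min(g), 0)

  on_new <- function(df) {
    k <- nrow(df)
    h1 <- matrix(0L, k, S); h2 <- matrix(0L, k, S)
    if (all(is.na(df$sire)) && all(is.na(df$dam))) {
      if (k > length(env$free_founders))
        stop("founder pool too small for the pedigree founders")
      fi <- env$free_founders[seq_len(k)]
      env$free_founders <- env$free_founders[-seq_len(k)]
      h1[] <- as.integer(pool$haplotypes[2L * fi - 1L, , drop = FALSE] !=
                           as.raw(0))
      h2[] <- as.integer(pool$haplotypes[2L * fi, , drop = FALSE] !=
                           as.raw(0))
    } else {
      sr <- match(df$sire, env$ids); dr <- match(df$dam, env$ids)
      for (i in seq_len(k)) {
        for (ci in seq_along(chroms)) {
          ii <- cidx[[ci]]
          h1[i, ii] <- meiose(env$hap1[sr[i], ii], env$hap2[sr[i], ii],
                              gl[[ci]], glen[ci])
          h2[i, ii] <- meiose(env$hap1[dr[i], ii], env$hap2[dr[i], ii],
                              gl[[ci]], glen[ci])
        }
      }
    }
    env$ids <- c(env$ids, df$id)
    env$hap1 <- rbind(env$hap1, h1)
    env$hap2 <- rbind(env$hap2, h2)
  }
  ranker <- if (cfg$index_accuracy == 0) NULL else function(cand) {
    rows <- match(cand, env$ids)
    tbv <- drop((env$hap1[rows, causal$site, drop = FALSE] +
                   env$hap2[rows, causal$site, drop = FALSE]) %*%
                  causal$effect)
    acc <- cfg$index_accuracy
    if (acc >= 1) return(tbv)
    s <- stats::sd(tbv)
    if (s == 0) s <- 1
    tbv + stats::rnorm(length(tbv), 0, s * sqrt(1 / acc^2 - 1))
  }
  ped <- build_pedigree(cfg, ranker = ranker, on_new = on_new)
  drop_obj <- structure(
    list(ids = env$ids, hap1 = env$hap1, hap2 = env$hap2, map = pool$map,
         provenance = NULL, seed = seed),
    class = "gene_drop")
  structure(list(pedigree = ped, drop = drop_obj,
                 causal = data.frame(site = causal$site,
                                     chrom = pool$map$chrom[causal$site],
                                     pos_bp = pool$map$pos_bp[causal$site],
                                     effect = causal$effect),
                 config = cfg, seed = seed),
            class = "breeding_sim")
}

#' Choose which animals are genotyped
#'
#' Samples \code{n_genotyped} animals from the pedigree. Under the default
#' left-skewed scheme the sampling weight grows with birth year (squared
#' rank of birth year), emulating a genotyping platform whose volume grew
#' over the program; the uniform scheme samples evenly.
#'
#' @param ped a pedigree data.frame.
#' @param scheme \code{"left_skewed"} or \code{"uniform"}.
#' @param n_genotyped number of animals to genotype.
#' @param seed integer seed.
#' @return data.frame(id, birth_month, age_months, population).
#' @export
assign_genotyping <- function(ped, scheme = c("left_skewed", "uniform"),
                              n_genotyped, seed = 1) {
  scheme <- match.arg(scheme)
  ped <- validate_pedigree(ped)
  if (n_genotyped > nrow(ped))
    stop("n_genotyped exceeds the pedigree size")
  set.seed(seed)
  yr <- as.integer(substr(ped$birth_month, 1, 4))
  w <- if (scheme == "uniform") rep(1, nrow(ped)) else {
    r <- match(yr, sort(unique(yr)))
    r^2
  }
  pick <- sort(sample.int(nrow(ped), n_genotyped, prob = w))
  out <- ped[pick, c("id", "birth_month", "population")]
  out$age_months <- compute_age(out$birth_month)
  rownames(out) <- NULL
  out
}

#' Terminal cross between two simulated populations
#'
#' Produces crossbred offspring of sires from one simulated population and
#' dams from another, recording only the sire side of the pedigree (dam
#' unknown), as is typical for commercial crossbred animals. Offspring
#' genotypes are built by one meiosis from each true parent.
#'
#' @param sire_sim,dam_sim [simulate_selection()] results sharing a site
#'   map.
#' @param n_offspring number of crossbred offspring.
#' @param population label for the offspring (default "Crossbred").
#' @param seed integer seed.
#' @return A list with \code{pedigree} (sire known, dam NA) and \code{drop}
#'   covering the offspring only.
#' @export
terminal_cross <- function(sire_sim, dam_sim, n_offspring,
                           population = "Crossbred", seed = 1) {
  stopifnot(inherits(sire_sim, "breeding_sim"),
            inherits(dam_sim, "breeding_sim"))
  if (!identical(sire_sim$drop$map, dam_sim$drop$map))
    stop("the two populations must share a site map")
  set.seed(seed)
  map <- sire_sim$drop$map
  S <- nrow(map)
  cidx <- split(seq_len(S), map$chrom)
  gl <- lapply(cidx, function(ii) map$gpos[ii])
  glen <- vapply(gl, function(g) max(g) + min(g), 0)
  last_gen <- function(sim, sex) {
    p <- sim$pedigree
    p$id[p$generation == max(p$generation) & p$sex == sex]
  }
  sires <- sample(last_gen(sire_sim, "M"), n_offspring, replace = TRUE)
  dams <- sample(last_gen(dam_sim, "F"), n_offspring, replace = TRUE)
  born <- max(c(sire_sim$pedigree$birth_month, dam_sim$pedigree$birth_month))
  h1 <- matrix(0L, n_offspring, S); h2 <- matrix(0L, n_offspring, S)
  si <- match(sires, sire_sim$drop$ids); di <- match(dams, dam_sim$drop$ids)
  for (i in seq_len(n_offspring)) {
    for (ci in seq_along(cidx)) {
      ii <- cidx[[ci]]
      h1[i, ii] <- meiose(sire_sim$drop$hap1[si[i], ii],
                          sire_sim$drop$hap2[si[i], ii], gl[[ci]], glen[ci])
      h2[i, ii] <- meiose(dam_sim$drop$hap1[di[i], ii],
                          dam_sim$drop$hap2[di[i], ii], gl[[ci]], glen[ci])
    }
  }
  ids <- sprintf("%s_%05d", population, seq_len(n_offspring))
  age0 <- compute_age(born) + 27L
  ped <- data.frame(
    id = ids, sire = sires, dam = NA_character_,
    birth_month = age_to_month(age0 + round(stats::rnorm(n_offspring, 0, 3))),
    population = population, generation = 1L, sex = sample(c("M", "F"),
    n_offspring, replace = TRUE), stringsAsFactors = FALSE)
  drop_obj <- structure(
    list(ids = ids, hap1 = h1, hap2 = h2, map = map, provenance = NULL,
         seed = seed),
    class = "gene_drop")
  list(pedigree = ped, drop = drop_obj)
}

#' Stack two gene-drops over the same site map
#'
#' Utility for building union samples (e.g. two populations ahead of a
#' bivariate analysis): row-binds the haplotypes of two drops that share a
#' site map.
#'
#' @param d1,d2 [gene_drop()] results (or \code{$drop} of a
#'   [simulate_selection()]).
#' @return A \code{gene_drop} over the concatenated ids.
#' @export
combine_drops <- function(d1, d2) {
  if (!inherits(d1, "gene_drop") && !is.null(d1$drop)) d1 <- d1$drop
  if (!inherits(d2, "gene_drop") && !is.null(d2$drop)) d2 <- d2$drop
  stopifnot(inherits(d1, "gene_drop"), inherits(d2, "gene_drop"))
  if (!identical(d1$map, d2$map)) stop("drops must share a site map")
  if (any(d1$ids %in% d2$ids)) stop("drops contain overlapping ids")
  structure(list(ids = c(d1$ids, d2$ids),
                 hap1 = rbind(d1$hap1, d2$hap1),
                 hap2 = rbind(d1$hap2, d2$hap2),
                 map = d1$map, provenance = NULL, seed = NA_integer_),
            class = "gene_drop")
}
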