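# Structured-coalescent simulation of two populations descended from a split.

.MODEL_KINDS <- c("SI", "IM", "AM", "SC")

#' Demographic configuration for the two-population split models
#'
#' Describes one member of the SI/IM/AM/SC family: an ancestral population of
#' diploid effective size `N_anc` splits `T_split` (in units of `2 * N_anc`
#' generations) ago into two daughters of relative sizes `nu1` and `nu2`.
#' Depending on `model_kind` the daughters exchange no migrants (SI), migrants
#' throughout (IM), migrants only between the split and `T_change` ago
#' ("ancient migration", AM), or migrants only from `T_change` ago to the
#' present ("secondary contact", SC). `T_change` is measured backward from the
#' present in the same units as `T_split`.
#'
#' @param model_kind one of `"SI"`, `"IM"`, `"AM"`, `"SC"`
#' @param N_anc ancestral diploid effective size
#' @param nu1,nu2 daughter sizes relative to `N_anc`
#' @param T_split split time, units of `2 * N_anc` generations
#' @param T_change migration cessation (AM) or onset (SC) time, backward from
#'   the present, same units; unused for SI and IM
#' @param m12,m21 scaled migration rates (`2 * N_anc` times the per-generation
#'   migration fraction); `m12` is migration into population 1 from
#'   population 2
#' @param mu per-site per-generation mutation rate (default `1e-8`, i.e.
#'   `2e-9` per year at a 5-year generation time)
#' @param L sequence length in bp
#' @param g generation time in years (default 5)
#' @return an object of class `demography_config`
#' @export
demography_config <- function(model_kind = c("SI", "IM", "AM", "SC"),
                              N_anc = 1e4, nu1 = 1, nu2 = 1,
                              T_split = 1, T_change = 0, m12 = 0, m21 = 0,
                              mu = 1e-8, L = 1e6, g = 5) {
  model_kind <- match.arg(model_kind)
  for (nm in c("N_anc", "nu1", "nu2", "T_split", "T_change",
               "m12", "m21", "mu", "L", "g"))
    .chk_nonneg(get(nm), nm)
  if (model_kind == "SI" && (m12 != 0 || m21 != 0))
    stop("SI requires m12 = m21 = 0", call. = FALSE)
  if (model_kind %in% c("SI", "IM")) T_change <- NA_real_
  if (!is.na(T_change) && T_change > T_split)
    stop("T_change must satisfy 0 <= T_change <= T_split", call. = FALSE)
  structure(list(model_kind = model_kind, N_anc = N_anc, nu1 = nu1,
                 nu2 = nu2, T_split = T_split, T_change = T_change,
                 m12 = m12, m21 = m21, mu = mu, L = L, g = g),
            class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat(sprintf("Two-population %s model: N_anc=%g, nu=(%g, %g), Ts=%g",
              x$model_kind, x$N_anc, x$nu1, x$nu2, x$T_split))
  if (!is.na(x$T_change)) cat(sprintf(", Tc=%g", x$T_change))
  cat(sprintf(", m=(%g, %g), mu=%g, L=%g bp, g=%g y\n",
              x$m12, x$m21, x$mu, x$L, x$g))
  invisible(x)
}

.model_code <- function(kind) match(kind, .MODEL_KINDS) - 1L

#' Simulate a two-population cohort under the structured coalescent
#'
#' Draws genealogies under the configured split model (continuous-time
#' event-driven structured coalescent), places infinite-sites mutations on
#' branches (Poisson, positions uniform without replacement on a discrete
#' 1..L grid), and forms diploid genotypes by pairing consecutive sampled
#' chromosomes within each population. The genome can be split into `n_loci`
#' independently segregating loci (free recombination between loci, none
#' within); mutation positions stay within each locus' span.
#'
#' @param config a [demography_config()]
#' @param n1,n2 diploid sample sizes for populations 1 and 2
#' @param seed integer seed; the simulation is fully reproducible
#' @param n_loci number of independent non-recombining loci (default 1)
#' @return an object of class `simulated_cohort`: genotype matrix `genotypes`
#'   (sites x individuals, values 0/1/2), strictly increasing 1-based
#'   `positions`, `chrom`, `site_class` (all `"other"` until annotated),
#'   `pop` (population of each individual) and a `truth` record
#' @export
simulate_two_pop_coalescent <- function(config, n1, n2, seed, n_loci = 1) {
  stopifnot(inherits(config, "demography_config"))
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be >= 1", call. = FALSE)
  stopifnot(n_loci >= 1, config$L >= n_loci)
  locus_len <- floor(config$L / n_loci)
  lens <- rep(locus_len, n_loci)
  lens[n_loci] <- config$L - locus_len * (n_loci - 1)
  theta_locus <- 4 * config$N_anc * config$mu * lens
  tc <- if (is.na(config$T_change)) 0 else config$T_change
  haps <- cpp_sim_haplotypes(.model_code(config$model_kind),
                             config$nu1, config$nu2, config$T_split, tc,
                             config$m12, config$m21,
                             2L * n1, 2L * n2, theta_locus,
                             as.double(substream_seed(seed, "coalescent")))
  n_ind <- n1 + n2
  pos_rng_seed <- substream_seed(seed, "positions")
  gt_list <- vector("list", n_loci)
  pos_list <- vector("list", n_loci)
  offset <- 0L
  old <- .set_local_seed(pos_rng_seed)
  on.exit(.restore_seed(old), add = TRUE)
  for (l in seq_len(n_loci)) {
    h <- haps[[l]]
    ns <- nrow(h)
    if (ns > lens[l]) {  # more mutations than grid sites: collapse extras
      h <- h[seq_len(lens[l]), , drop = FALSE]
      ns <- nrow(h)
    }
    pos <- sort(sample.int(lens[l], ns)) + offset
    gt <- h[, seq(1, 2 * n_ind, by = 2), drop = FALSE] +
      h[, seq(2, 2 * n_ind, by = 2), drop = FALSE]
    gt_list[[l]] <- gt
    pos_list[[l]] <- pos
    offset <- offset + lens[l]
  }
  gt <- do.call(rbind, gt_list)
  positions <- unlist(pos_list)
  storage.mode(gt) <- "integer"
  colnames(gt) <- sprintf("ind%02d", seq_len(n_ind))
  structure(list(
    genotypes = gt,
    positions = as.integer(positions),
    chrom = rep("1", length(positions)),
    site_class = rep("other", length(positions)),
    gene_id = rep(NA_character_, length(positions)),
    pop = rep(1:2, c(n1, n2)),
    L = config$L,
    truth = list(config = config, seed = seed, n_loci = n_loci,
                 fp_positions = integer(0), fp_windows = integer(0),
                 roh_tracts = NULL)
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d segregating sites, %d individuals (%d + %d), L = %g bp\n",
    nrow(x$genotypes), ncol(x$genotypes), sum(x$pop == 1), sum(x$pop == 2), x$L))
  invisible(x)
}

# Run code under a local RNG seed, restoring R's global stream afterwards.
.set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Label simulated variant sites as synonymous / nonsynonymous / other
#'
#' Assigns each segregating site a coding class independently (synonymous
#' with probability `syn_fraction`, otherwise nonsynonymous unless
#' `other_fraction` reserves mass for non-coding sites), and groups sites
#' into consecutive "genes" of `gene_span` bp for per-gene spectra.
#'
#' @param cohort a `simulated_cohort`
#' @param syn_fraction probability a site is synonymous
#' @param seed integer seed
#' @param other_fraction probability a site is non-coding (`"other"`)
#' @param gene_span gene block length in bp (default 10 kb)
#' @return the cohort with `site_class` and `gene_id` filled in
#' @export
annotate_site_classes <- function(cohort, syn_fraction, seed,
                                  other_fraction = 0, gene_span = 10000) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  .chk_prob(syn_fraction, "syn_fraction")
  .chk_prob(other_fraction, "other_fraction")
  if (syn_fraction + other_fraction > 1)
    stop("syn_fraction + other_fraction must be <= 1", call. = FALSE)
  old <- .set_local_seed(substream_seed(seed, "site_classes"))
  on.exit(.restore_seed(old), add = TRUE)
  u <- runif(length(cohort$positions))
  cls <- ifelse(u < syn_fraction, "synonymous",
                ifelse(u < syn_fraction + other_fraction, "other",
                       "nonsynonymous"))
  cohort$site_class <- cls
  cohort$gene_id <- sprintf("gene%05d", window_index(cohort$positions, gene_span))
  cohort
}

#' Poisson-sample an observed SFS from an expected SFS
#'
#' Independent Poisson draws per cell of a non-negative expected spectrum
#' (1D vector or 2D matrix; masked cells of a folded joint SFS are left at
#' zero). Reproducible by seed.
#'
#' @param expected_sfs non-negative numeric vector/matrix, or a
#'   `folded_joint_sfs`
#' @param seed integer seed
#' @return object of the same shape with integer counts
#' @export
sample_sfs_counts <- function(expected_sfs, seed) {
  old <- .set_local_seed(substream_seed(seed, "sfs_sampling"))
  on.exit(.restore_seed(old), add = TRUE)
  if (inherits(expected_sfs, "folded_joint_sfs")) {
    x <- expected_sfs$counts
    if (any(!is.finite(x[!expected_sfs$mask])) || any(x[!expected_sfs$mask] < 0))
      stop("expected SFS entries must be finite and non-negative", call. = FALSE)
    drawn <- x
    drawn[!expected_sfs$mask] <- rpois(sum(!expected_sfs$mask), x[!expected_sfs$mask])
    drawn[expected_sfs$mask] <- 0
    out <- expected_sfs
    out$counts <- drawn
    return(out)
  }
  if (any(!is.finite(expected_sfs)) || any(expected_sfs < 0))
    stop("expected SFS entries must be finite and non-negative", call. = FALSE)
  out <- expected_sfs
  out[] <- rpois(length(expected_sfs), as.vector(expected_sfs))
  out
}
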