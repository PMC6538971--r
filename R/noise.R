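# Sequencing-noise layer: turn true simulated genotypes into VCF-like calls
# with per-genotype DP/AD/GQ, per-site QC annotations, and two replicate
# callsets of one individual carrying injected clustered false-positive SNPs
# in designated 5-kb windows (emulating mapping errors in duplicated regions).

#' Sequencing-noise configuration
#'
#' @param mean_depth mean read depth per genotype
#' @param depth_dispersion negative-binomial overdispersion; 0 gives a
#'   deterministic depth equal to `mean_depth` (variance
#'   `mu + dispersion * mu^2` otherwise)
#' @param balance_noise probability that a heterozygous genotype's allele
#'   ratio is distorted (drawn uniformly in (0.05, 0.95) instead of binomial
#'   around 1/2); 0 splits reads deterministically half/half
#' @param gq_floor,gq_ceiling Phred bounds for reported genotype quality
#' @param fp_window_count number of designated 5-kb artifact windows
#' @param fp_per_window injected artifact SNPs per designated window
#' @param info_fail_fraction probability a site's QC annotations are drawn
#'   from the failing side of the hard-filter thresholds
#' @param seed integer seed for the noise substreams
#' @return object of class `noise_config`
#' @export
noise_config <- function(mean_depth = 20, depth_dispersion = 0,
                         balance_noise = 0, gq_floor = 0, gq_ceiling = 99,
                         fp_window_count = 0, fp_per_window = 0,
                         info_fail_fraction = 0, seed = 1) {
  .chk_nonneg(mean_depth, "mean_depth")
  .chk_nonneg(depth_dispersion, "depth_dispersion")
  .chk_prob(balance_noise, "balance_noise")
  .chk_prob(info_fail_fraction, "info_fail_fraction")
  .chk_nonneg(fp_window_count, "fp_window_count")
  .chk_nonneg(fp_per_window, "fp_per_window")
  stopifnot(gq_floor <= gq_ceiling)
  structure(list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 balance_noise = balance_noise, gq_floor = gq_floor,
                 gq_ceiling = gq_ceiling, fp_window_count = fp_window_count,
                 fp_per_window = fp_per_window,
                 info_fail_fraction = info_fail_fraction, seed = seed),
            class = "noise_config")
}

# Draw DP/AD/GQ for a genotype matrix. Deterministic when both depth
# dispersion and balance noise are zero.
.noise_genotype_layers <- function(gt, noise) {
  n <- length(gt)
  if (noise$depth_dispersion > 0) {
    dp <- rnbinom(n, mu = noise$mean_depth, size = 1 / noise$depth_dispersion)
  } else dp <- rep(round(noise$mean_depth), n)
  dp <- matrix(as.integer(dp), nrow(gt), ncol(gt))
  alt <- matrix(0L, nrow(gt), ncol(gt))
  hom_alt <- !is.na(gt) & gt == 2L
  alt[hom_alt] <- dp[hom_alt]
  het <- which(!is.na(gt) & gt == 1L)
  if (length(het)) {
    if (noise$balance_noise > 0) {
      p <- rep(0.5, length(het))
      distort <- runif(length(het)) < noise$balance_noise
      p[distort] <- runif(sum(distort), 0.05, 0.95)
      alt[het] <- rbinom(length(het), dp[het], p)
    } else alt[het] <- as.integer(round(dp[het] / 2))
  }
  ref <- dp - alt
  gq <- .gq_from_likelihoods(gt, dp, alt)
  gq <- pmin(pmax(gq, noise$gq_floor), noise$gq_ceiling)
  list(dp = dp, ad_ref = ref, ad_alt = alt, gq = matrix(as.integer(gq), nrow(gt)))
}

# Phred-scaled margin between the called genotype's likelihood and the best
# competing genotype, under a symmetric 1% base-error model.
.gq_from_likelihoods <- function(gt, dp, alt, err = 0.01) {
  p <- c(err, 0.5, 1 - err)  # P(alt read | genotype 0, 1, 2)
  a <- as.vector(alt); d <- as.vector(dp)
  ll <- vapply(p, function(pg) a * log10(pg) + (d - a) * log10(1 - pg),
               numeric(length(a)))
  ll <- matrix(ll, ncol = 3)
  idx <- as.vector(gt) + 1L
  ok <- !is.na(idx)
  called <- rep(NA_real_, length(idx))
  called[ok] <- ll[cbind(which(ok), idx[ok])]
  masked <- ll
  masked[cbind(which(ok), idx[ok])] <- -Inf
  other <- pmax(masked[, 1], masked[, 2], masked[, 3])
  gq <- round(10 * (called - other))
  gq[!ok] <- 0
  matrix(as.integer(pmax(gq, 0)), nrow(gt))
}

# Per-site QC annotations, passing or failing the GATK-style hard filters.
.draw_info <- function(ns, fail_frac) {
  fail <- runif(ns) < fail_frac
  draw <- function(lo, hi, flo, fhi) {
    x <- runif(ns, lo, hi)
    x[fail] <- runif(sum(fail), flo, fhi)
    round(x, 3)
  }
  data.frame(
    QD = draw(5, 30, 0, 1.9),
    SOR = draw(0.3, 2.5, 3.2, 6),
    MQ = draw(52, 60, 25, 49),
    MQRankSum = draw(-1.5, 0.4, 1.0, 3.0),
    ReadPosRankSum = draw(-1.5, 1.5, 2.6, 5.0)
  )
}

#' Apply sequencing noise and build replicate callsets with injected FP-SNPs
#'
#' Produces (i) an annotated callset of the whole cohort and (ii) two
#' replicate callsets of one designated reference individual that differ by
#' independent noise and by injected false-positive SNPs: in each designated
#' 5-kb window, `fp_per_window` new positions are added at which the two
#' replicates carry discordant homozygous genotypes (the signature of a
#' mapping artifact). The truth record lists the injected positions and
#' windows so downstream filters can be scored exactly.
#'
#' @param cohort a `simulated_cohort`
#' @param noise a [noise_config()]
#' @param ref_individual column index of the replicate-sequenced individual
#' @param window_bp artifact window size (default 5000)
#' @return list with `callset` (all individuals, FP sites included),
#'   `replicate_a`, `replicate_b` (the reference individual), and `truth`
#'   (injected FP positions and window indices)
#' @export
apply_sequencing_noise <- function(cohort, noise, ref_individual = 1,
                                   window_bp = 5000) {
  stopifnot(inherits(cohort, "simulated_cohort"),
            inherits(noise, "noise_config"))
  n_windows <- ceiling(cohort$L / window_bp)
  if (noise$fp_window_count > n_windows)
    stop(sprintf("fp_window_count (%d) exceeds available %d windows",
                 noise$fp_window_count, n_windows), call. = FALSE)

  old <- .set_local_seed(substream_seed(noise$seed, "fp_windows"))
  on.exit(.restore_seed(old), add = TRUE)
  fp_windows <- integer(0)
  fp_pos <- integer(0)
  if (noise$fp_window_count > 0 && noise$fp_per_window > 0) {
    fp_windows <- sort(sample.int(n_windows, noise$fp_window_count))
    for (w in fp_windows) {
      span <- window_span(w, window_bp)
      hi <- min(span$end, cohort$L)
      cand <- setdiff(seq(span$start, hi), c(cohort$positions, fp_pos))
      if (length(cand) < noise$fp_per_window)
        stop("window too crowded to inject FP-SNPs", call. = FALSE)
      fp_pos <- c(fp_pos, sample(cand, noise$fp_per_window))
    }
    fp_pos <- sort(fp_pos)
  }

  # assemble the site table: true variants plus injected artifact positions
  pos_all <- c(cohort$positions, fp_pos)
  o <- order(pos_all)
  is_fp <- c(rep(FALSE, length(cohort$positions)), rep(TRUE, length(fp_pos)))[o]
  pos_all <- pos_all[o]
  n_ind <- ncol(cohort$genotypes)
  gt_all <- matrix(0L, length(pos_all), n_ind,
                   dimnames = list(NULL, colnames(cohort$genotypes)))
  gt_all[!is_fp, ] <- cohort$genotypes
  # artifact positions look like ordinary variants in the pooled callset
  gt_all[is_fp, ] <- 1L

  .set_local_seed(substream_seed(noise$seed, "bases"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos_all), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  .set_local_seed(substream_seed(noise$seed, "info"))
  info <- .draw_info(length(pos_all), noise$info_fail_fraction)
  qual <- round(runif(length(pos_all), 60, 2000), 1)

  .set_local_seed(substream_seed(noise$seed, "cohort_noise"))
  layers <- .noise_genotype_layers(gt_all, noise)
  callset <- genotype_callset(rep("1", length(pos_all)), pos_all, ref, alt,
                              qual, info, gt_all, layers$dp, layers$ad_ref,
                              layers$ad_alt, layers$gq, L = cohort$L)

  # replicate callsets of the reference individual: same sites/annotations,
  # independent genotype-level noise, discordant homozygotes at FP positions
  gt_ref <- gt_all[, ref_individual, drop = FALSE]
  gt_a <- gt_ref; gt_b <- gt_ref
  gt_a[is_fp, 1] <- 0L
  gt_b[is_fp, 1] <- 2L
  make_rep <- function(gt_rep, stream) {
    .set_local_seed(substream_seed(noise$seed, stream))
    ly <- .noise_genotype_layers(gt_rep, noise)
    genotype_callset(rep("1", length(pos_all)), pos_all, ref, alt, qual,
                     info, gt_rep, ly$dp, ly$ad_ref, ly$ad_alt, ly$gq,
                     L = cohort$L)
  }
  list(callset = callset,
       replicate_a = make_rep(gt_a, "replicate_a"),
       replicate_b = make_rep(gt_b, "replicate_b"),
       truth = list(fp_positions = fp_pos, fp_windows = fp_windows,
                    window_bp = window_bp, ref_individual = ref_individual))
}
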