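# Shared fixture builders. Everything is generated in code; no stored data.

# a small deterministic callset with explicit per-genotype layers
toy_callset <- function(pos = seq(100L, by = 100L,
                                  length.out = nrow(gt)),
                        gt = matrix(c(0L, 1L, 2L), 3, 1),
                        dp = matrix(10L, nrow(gt), ncol(gt)),
                        ad_alt = NULL, gq = matrix(99L, nrow(gt), ncol(gt)),
                        qual = rep(500, length(pos)),
                        info = NULL, L = 1e4) {
  n <- length(pos)
  if (is.null(ad_alt)) {
    ad_alt <- matrix(0L, n, ncol(gt))
    ad_alt[gt == 1L] <- as.integer(round(dp[gt == 1L] / 2))
    ad_alt[gt == 2L] <- dp[gt == 2L]
  }
  if (is.null(info))
    info <- data.frame(QD = rep(20, n), SOR = rep(1, n), MQ = rep(58, n),
                       MQRankSum = rep(0, n), ReadPosRankSum = rep(0, n))
  colnames(gt) <- sprintf("s%02d", seq_len(ncol(gt)))
  genotype_callset(rep("1", n), pos, rep("A", n), rep("T", n), qual, info,
                   gt, dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt,
                   gq = gq, L = L)
}

# a small simulated two-population cohort with sequencing noise applied
noisy_cohort_fixture <- function(seed = 11, fp_windows = 0, fp_per = 0,
                                 L = 5e5, mean_depth = 20) {
  cfg <- demography_config("IM", N_anc = 1e4, nu1 = 1, nu2 = 0.5,
                           T_split = 1, m12 = 1, m21 = 1, L = L)
  co <- simulate_two_pop_coalescent(cfg, 4, 4, seed = seed, n_loci = 5)
  nz <- apply_sequencing_noise(
    co, noise_config(mean_depth = mean_depth, fp_window_count = fp_windows,
                     fp_per_window = fp_per, seed = seed + 1))
  list(cohort = co, noisy = nz)
}
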