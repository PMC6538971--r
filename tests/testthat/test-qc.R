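test_that("genotype filter masks by depth, balance and GQ", {
  # het with 5 reads; het with AD 2:8 (ratio 0.20); hom with DP 10 / GQ 99
  gt <- matrix(c(1L, 1L, 0L), 3, 1)
  dp <- matrix(c(5L, 10L, 10L), 3, 1)
  ad_alt <- matrix(c(2L, 8L, 0L), 3, 1)
  cs <- toy_callset(gt = gt, dp = dp, ad_alt = ad_alt)
  out <- filter_genotypes(cs)
  expect_true(is.na(out$gt[1, 1]))  # < 6 supporting reads
  expect_true(is.na(out$gt[2, 1]))  # ref ratio 0.2 outside [0.23, 0.76]
  expect_equal(unname(out$gt[3, 1]), 0L)  # clean homozygote retained
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["depth"]), 1)
  expect_equal(unname(counts["balance"]), 1)
})

test_that("genotype filter masks GQ below 10 and errors on missing fields", {
  cs <- toy_callset(gt = matrix(1L, 1, 1), dp = matrix(20L, 1, 1),
                    gq = matrix(9L, 1, 1))
  out <- filter_genotypes(cs)
  expect_true(is.na(out$gt[1, 1]))
  cs$gq <- NULL
  expect_error(filter_genotypes(cs), "GQ")
})

test_that("site filter applies stage thresholds, coverage and hard filters", {
  n <- 6
  info <- data.frame(QD = rep(20, n), SOR = rep(1, n), MQ = rep(58, n),
                     MQRankSum = rep(0, n), ReadPosRankSum = rep(0, n))
  info$MQ[2] <- 19    # fails RMS MQ (and MQ > 50)
  info$QD[3] <- 1.5   # fails QD > 2
  dp <- matrix(20L, n, 2)
  dp[4, ] <- 60L      # about 2.3x the mean coverage, above the 200% cap
  qual <- rep(500, n); qual[5] <- 25  # below demography-stage QUAL 30
  cs <- toy_callset(pos = seq(100L, by = 100L, length.out = n),
                    gt = matrix(0L, n, 2), dp = dp, qual = qual,
                    info = info)
  het <- filter_sites(cs, stage = "heterozygosity")
  expect_false(any(het$pos %in% c(200L, 300L, 400L)))
  expect_true(500L %in% het$pos)  # QUAL 25 >= 20 passes this stage
  dem <- filter_sites(cs, stage = "demography")
  expect_false(500L %in% dem$pos)
  counts <- attr(dem, "site_filter_counts")
  expect_equal(unname(counts["qual"]), 1)
  expect_true(all(c("non_biallelic", "coverage", "rms_mq",
                    "hard_filters") %in% names(counts)))
})

test_that("RankSum boundaries are exclusion intervals", {
  info <- data.frame(QD = c(20, 20), SOR = c(1, 1), MQ = c(58, 58),
                     MQRankSum = c(-2.5, 0.5), ReadPosRankSum = c(0, 2.5))
  cs <- toy_callset(pos = c(100L, 200L), gt = matrix(0L, 2, 1),
                    dp = matrix(20L, 2, 1), info = info)
  out <- filter_sites(cs, stage = "demography")
  expect_equal(n_sites(out), 0)  # -2.5 < -2.4; 2.5 > 2.4
})

test_that("FP-window detection blacklists > 1 FP-SNP per 5-kb window", {
  # two homozygous-discordant positions in window 1, one in window 3,
  # a het-discordant position (not an FP-SNP) in window 2
  pos <- c(1000L, 4000L, 9000L, 12000L)
  ga <- matrix(c(0L, 2L, 1L, 0L), 4, 1)
  gb <- matrix(c(2L, 0L, 2L, 2L), 4, 1)
  a <- toy_callset(pos = pos, gt = ga, L = 2e4)
  b <- toy_callset(pos = pos, gt = gb, L = 2e4)
  rep <- detect_fp_windows(a, b)
  expect_equal(rep$blacklist$window, 1L)
  expect_equal(rep$blacklist$start, 1L)
  expect_equal(rep$blacklist$end, 5000L)
  expect_setequal(rep$fp_positions, c(1000L, 4000L, 12000L))
  expect_equal(rep$fp_discarded_fraction, 2 / 3)
  expect_equal(rep$genome_removed_fraction, 5000 / 2e4)
})

test_that("identical replicates give zero FP-SNPs; mismatched sites error", {
  a <- toy_callset()
  rep <- detect_fp_windows(a, a)
  expect_equal(length(rep$fp_positions), 0)
  expect_equal(nrow(rep$blacklist), 0)
  expect_equal(rep$fp_discarded_fraction, 0)
  b <- toy_callset(pos = c(100L, 200L, 301L))
  expect_error(detect_fp_windows(a, b), "mismatched")
})

test_that("fp_discarded_fraction matches a brute-force recount on synthetic truth", {
  fx <- noisy_cohort_fixture(seed = 41, fp_windows = 6, fp_per = 3)
  rep <- detect_fp_windows(fx$noisy$replicate_a, fx$noisy$replicate_b,
                           apply_to = fx$noisy$callset)
  tr <- fx$noisy$truth
  w <- window_index(tr$fp_positions, 5000)
  tab <- table(w)
  bad <- as.integer(names(tab)[tab > 1])
  brute <- mean(w %in% bad)
  expect_equal(rep$fp_discarded_fraction, brute)
  # blacklist applied genome-wide to the cohort callset
  expect_false(any(window_index(rep$filtered$pos, 5000) %in%
                     rep$blacklist$window))
})

test_that("thinning keeps the first SNP per occupied 20-kb window", {
  cs <- toy_callset(pos = c(100L, 10100L, 25000L), L = 1e5)
  th <- thin_variants(cs)
  expect_equal(th$pos, c(100L, 25000L))
  one <- toy_callset(pos = 5000L, gt = matrix(1L, 1, 1))
  expect_equal(thin_variants(one)$pos, 5000L)
})

test_that("thinned count equals an independent occupied-window count", {
  fx <- noisy_cohort_fixture(seed = 42)
  cs <- fx$noisy$callset
  th <- thin_variants(cs, window_bp = 20000)
  oracle <- length(unique(window_index(cs$pos, 20000)))
  expect_equal(n_sites(th), oracle)
  expect_true(all(table(window_index(th$pos, 20000)) == 1))
})

test_that("filters are idempotent and order-insensitive", {
  fx <- noisy_cohort_fixture(seed = 43)
  cs <- fx$noisy$callset
  g1 <- filter_genotypes(cs)
  g2 <- filter_genotypes(g1)
  expect_identical(g1$gt, g2$gt)
  s1 <- filter_sites(cs, stage = "demography")
  s2 <- filter_sites(s1, stage = "demography")
  expect_identical(s1$pos, s2$pos)
  # genotype-then-site equals site-then-genotype on the passing set
  a <- filter_sites(filter_genotypes(cs), stage = "demography")
  b <- filter_genotypes(filter_sites(cs, stage = "demography"))
  expect_identical(a$pos, b$pos)
  expect_identical(a$gt, b$gt)
  t1 <- thin_variants(cs)
  expect_identical(thin_variants(t1)$pos, t1$pos)
})
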