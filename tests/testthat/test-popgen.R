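test_that("heterozygosity per kb is the stated arithmetic", {
  expect_equal(heterozygosity_per_kb(3, 10000), 0.3)
  expect_equal(heterozygosity_per_kb(0, 10000), 0)
  expect_error(heterozygosity_per_kb(3, 0), "callable_bp")
})

test_that("simulated single-population heterozygosity matches 4*N*mu per site", {
  cfg <- demography_config("SI", N_anc = 1e4, T_split = 0, mu = 1e-8,
                           L = 1e6)
  hets <- vapply(1:60, function(s) {
    co <- simulate_two_pop_coalescent(cfg, 1, 1, seed = s, n_loci = 10)
    mean(colSums(co$genotypes == 1L))
  }, 0.0)
  expected <- 4 * 1e4 * 1e-8 * 1e6  # 400 het sites per individual
  se <- sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 4 * se)
})

test_that("RoH HMM recovers a planted homozygous tract", {
  set.seed(5)
  L <- 30e6
  pos <- sort(sample.int(L, 30000))
  het <- runif(length(pos)) < 0.35
  tract <- pos >= 10e6 & pos < 15e6
  het[tract] <- runif(sum(tract)) < 1e-3
  segs <- detect_roh(pos, het)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$start - 10e6), 5e4)
  expect_lt(abs(segs$end - 15e6), 5e4)
  expect_gt(segs$posterior, 0.95)
})

test_that("uniformly heterozygous-dense genomes yield no long RoH and short segments are excluded", {
  set.seed(6)
  pos <- sort(sample.int(20e6, 20000))
  het <- runif(length(pos)) < 0.35
  expect_equal(nrow(detect_roh(pos, het)), 0)
  # a 1.5-Mb planted tract is detected but excluded by the > 2 Mb default
  tract <- pos >= 5e6 & pos < 6.5e6
  het2 <- het
  het2[tract] <- FALSE
  all_segs <- detect_roh(pos, het2, keep_all = TRUE)
  expect_true(any(all_segs$length_bp > 1e6 & all_segs$length_bp < 2e6))
  expect_equal(nrow(detect_roh(pos, het2)), 0)
  expect_warning(detect_roh(c(100L), c(TRUE)), "fewer than 2")
})

test_that("RoH respects the autosome allow-list and segment invariants", {
  set.seed(7)
  pos <- rep(sort(sample.int(10e6, 8000)), 2)
  chrom <- rep(c("1", "X"), each = 8000)
  het <- runif(16000) < 0.3
  het[chrom == "X"] <- FALSE  # X fully homozygous
  segs <- detect_roh(pos, het, chrom, autosomes = "1", keep_all = TRUE)
  expect_false(any(segs$chrom == "X"))
  if (nrow(segs) > 1) {
    by_chr <- split(segs, segs$chrom)
    for (s in by_chr)
      if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
})

test_that("self-kinship is exactly 0.5 and kinship is symmetric", {
  set.seed(8)
  g <- sample(0:2, 5000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  self <- king_kinship(g, g)
  expect_equal(self$kinship, 0.5)
  g2 <- sample(0:2, 5000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  expect_equal(king_kinship(g, g2)$kinship, king_kinship(g2, g)$kinship)
  expect_error(king_kinship(rep(0L, 10), rep(2L, 10)), "heterozygotes")
})

test_that("parent-offspring kinship is about 0.25 and sibship ordering holds", {
  set.seed(9)
  n <- 20000
  p <- runif(n, 0.1, 0.9)
  draw <- function() rbinom(n, 1, p) + rbinom(n, 1, p)
  mendel <- function(a, b)  # one allele from each parent
    rbinom(n, 1, a / 2) + rbinom(n, 1, b / 2)
  mother <- draw(); father <- draw()
  child1 <- mendel(mother, father)
  child2 <- mendel(mother, father)
  unrel <- draw()
  half <- mendel(mother, draw())
  po <- king_kinship(mother, child1)$kinship
  fs <- king_kinship(child1, child2)$kinship
  hs <- king_kinship(child1, half)$kinship
  un <- king_kinship(child1, unrel)$kinship
  expect_lt(abs(po - 0.25), 0.03)
  expect_gt(fs, hs)
  expect_gt(hs, un)
  expect_lt(abs(un), 0.03)
})

test_that("long-isolated populations give non-positive kinship", {
  cfg <- demography_config("SI", N_anc = 1e4, T_split = 4, L = 2e6)
  co <- simulate_two_pop_coalescent(cfg, 2, 2, seed = 12)
  k <- king_kinship(co$genotypes[, 1], co$genotypes[, 3])
  expect_lte(k$kinship, 0)
})

test_that("inbreeding coefficient follows (O - E) / (N - E)", {
  # fully homozygous individual -> F = 1
  g <- rep(c(0L, 2L), 50)
  p <- rep(0.5, 100)
  expect_equal(inbreeding_coefficient(g, p, 20)$F, 1)
  # O == E -> F = 0: engineer frequencies so E equals the observed count
  set.seed(10)
  g2 <- c(rep(1L, 40), rep(0L, 30), rep(2L, 30))
  f <- inbreeding_coefficient(g2, rep(0.5, 100), n_chrom = 1e9)
  # E_hom = 100 * (1 - 0.5) = 50, O = 60 -> F = 10/50
  expect_equal(f$F, (60 - 50) / (100 - 50), tolerance = 1e-6)
  expect_equal(f$observed_hom, 60)
  # identity between returned components
  expect_equal(f$F, (f$observed_hom - f$expected_hom) /
                 (f$n_sites - f$expected_hom), tolerance = 1e-12)
})

test_that("genotype PCA separates groups and matches a dense eigendecomposition", {
  gt <- cbind(matrix(0L, 50, 3), matrix(2L, 50, 3))
  colnames(gt) <- sprintf("i%d", 1:6)
  p <- genotype_pca(gt)
  expect_gt(abs(diff(range(p$scores[, 1]))), 0)
  expect_true(all(abs(p$scores[1:3, 1] - p$scores[1, 1]) < 1e-10))
  expect_true(all(abs(p$scores[4:6, 1] - p$scores[4, 1]) < 1e-10))
  expect_gt(p$varexp[1], 0.999)

  set.seed(11)
  gt2 <- matrix(sample(0:2, 600, replace = TRUE), 100, 6)
  colnames(gt2) <- sprintf("i%d", 1:6)
  p2 <- genotype_pca(gt2)
  x <- gt2 - rowMeans(gt2)
  ev <- eigen(crossprod(x) / nrow(gt2), symmetric = TRUE)$values
  k <- length(p2$eigenvalues)
  expect_equal(p2$eigenvalues, ev[seq_len(k)], tolerance = 1e-8)

  expect_warning(p3 <- genotype_pca(matrix(1L, 10, 4)), "constant")
  expect_true(all(p3$scores == 0))
})

test_that("singleton exclusion drops singleton variants", {
  gt <- rbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L), c(2L, 1L, 1L, 0L))
  colnames(gt) <- sprintf("i%d", 1:4)
  p_with <- genotype_pca(gt, include_singletons = TRUE)
  p_without <- genotype_pca(gt, include_singletons = FALSE)
  expect_false(isTRUE(all.equal(p_with$eigenvalues[1],
                                p_without$eigenvalues[1])))
})
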