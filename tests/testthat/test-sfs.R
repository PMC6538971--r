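test_that("folded SFS bins follow the minor-allele convention", {
  # one site with derived count 3 of n = 8 increments bin 3
  gt <- matrix(c(2L, 1L, 0L, 0L), 1, 4)
  s <- build_folded_sfs(gt, 8)
  expect_equal(s$counts, c(0, 0, 1, 0))
  # derived counts i and n - i increment the same bin
  gt2 <- matrix(c(2L, 2L, 1L, 0L), 1, 4)  # count 5 of 8 -> bin 3
  expect_equal(build_folded_sfs(gt2, 8)$counts, c(0, 0, 1, 0))
  # ties go to floor(n/2)
  gt3 <- matrix(c(2L, 2L, 0L, 0L), 1, 4)
  expect_equal(build_folded_sfs(gt3, 8)$counts, c(0, 0, 0, 1))
})

test_that("folded SFS total equals the segregating-site count", {
  fx <- noisy_cohort_fixture(seed = 51)
  gt <- fx$cohort$genotypes
  s <- build_folded_sfs(gt, 16)
  ac <- rowSums(gt)
  oracle <- sum(ac > 0 & ac < 16)
  expect_equal(sum(s$counts), oracle)
})

test_that("projection is the identity at n and matches explicit subsampling", {
  s <- folded_sfs(c(30, 20, 10, 5), 8, L = 1000)
  expect_identical(project_sfs(s, 8), s)
  p <- project_sfs(s, 4)
  # Monte-Carlo oracle: draw 4 of 8 chromosomes explicitly per site
  set.seed(3)
  acc <- numeric(2)
  n_mc <- 10000
  for (r in seq_len(n_mc)) {
    for (i in 1:4) {
      if (s$counts[i] == 0) next
      k <- sum(sample(c(rep(1, i), rep(0, 8 - i)), 4) == 1)
      b <- min(k, 4 - k)
      if (b > 0) acc[b] <- acc[b] + s$counts[i]
    }
  }
  expect_equal(p$counts, acc / n_mc, tolerance = 0.05)
  # segregating sites never increase under projection
  expect_lte(sum(p$counts), sum(s$counts))
  expect_error(project_sfs(s, 10), "<= n")
  expect_error(project_sfs(s, 1), ">= 2")
})

test_that("joint folded SFS has the 0..4 range and transposes under swap", {
  fx <- noisy_cohort_fixture(seed = 52)
  gt <- fx$cohort$genotypes
  g1 <- gt[, fx$cohort$pop == 1]; g2 <- gt[, fx$cohort$pop == 2]
  j <- build_joint_folded_sfs(g1, g2)
  expect_equal(dim(j$counts), c(5, 5))
  expect_equal(j$n1_eff, 4)
  jt <- build_joint_folded_sfs(g2, g1)
  expect_equal(jt$counts, t(j$counts))
  expect_true(j$mask[1, 1])
  expect_equal(sum(j$counts[j$mask]), 0)
})

test_that("joint SFS cells match a brute-force per-site tabulation", {
  # complete data, 2 diploids per population: no projection needed
  fx <- noisy_cohort_fixture(seed = 53)
  gt <- fx$cohort$genotypes[, c(1, 2, 5, 6)]
  g1 <- gt[, 1:2]; g2 <- gt[, 3:4]
  j <- build_joint_folded_sfs(g1, g2)
  brute <- matrix(0, 5, 5)
  for (s in seq_len(nrow(gt))) {
    a1 <- sum(g1[s, ]); a2 <- sum(g2[s, ])
    if (a1 + a2 == 0 || a1 + a2 == 8) next
    if (2 * (a1 + a2) > 8) { a1 <- 4 - a1; a2 <- 4 - a2 }
    w <- if (2 * (a1 + a2) == 8) 0.5 else 1
    brute[a1 + 1, a2 + 1] <- brute[a1 + 1, a2 + 1] + w
    if (w == 0.5)
      brute[4 - a1 + 1, 4 - a2 + 1] <- brute[4 - a1 + 1, 4 - a2 + 1] + 0.5
  }
  expect_equal(j$counts, brute, tolerance = 1e-12)
})

test_that("monomorphic-only input warns with an empty joint spectrum", {
  g1 <- matrix(0L, 5, 2); g2 <- matrix(0L, 5, 2)
  expect_warning(j <- build_joint_folded_sfs(g1, g2), "empty")
  expect_equal(sum(j$counts), 0)
})

test_that("diversity statistics match the defining sums", {
  # n = 4, unfolded xi = (3, 2, 1), L = 1000
  # folded: bin 1 <- xi_1 + xi_3 = 4, bin 2 <- xi_2 = 2
  s <- folded_sfs(c(4, 2), 4, L = 1000)
  d <- sfs_diversity(s)
  # pi = sum_i 2 i (n - i) / (n (n-1)) xi_i = (2*3*3 + 4*2*2 + 2*3*1)/12
  pi_oracle <- (2 * 1 * 3 * 3 + 2 * 2 * 2 * 2 + 2 * 3 * 1 * 1) / (4 * 3)
  expect_equal(d$pi, pi_oracle / 1000)
  expect_equal(d$theta_w, 6 / ((1 + 1/2 + 1/3) * 1000))
  expect_equal(d$S, 6)
  expect_true(is.finite(d$tajima_d))
})

test_that("piN/piS is 1 for identical spectra and D is NA when S = 0", {
  s <- folded_sfs(c(10, 5, 3, 1), 8, L = 500)
  out <- diversity_summary(s, s, 500, 500)
  expect_equal(out$pin_pis, 1)
  empty <- folded_sfs(c(0, 0, 0, 0), 8, L = 500)
  expect_warning(d0 <- sfs_diversity(empty), "undefined")
  expect_true(is.na(d0$tajima_d))
})

test_that("pi from the SFS equals the direct mean pairwise difference", {
  fx <- noisy_cohort_fixture(seed = 54)
  gt <- fx$cohort$genotypes
  n <- 16
  s <- build_folded_sfs(gt, n, L = fx$cohort$L)
  d <- sfs_diversity(s)
  # direct: average pairwise difference over all chromosome pairs
  ac <- rowSums(gt)
  direct <- sum(ac * (n - ac)) / choose(n, 2) / fx$cohort$L
  expect_equal(d$pi, direct, tolerance = 1e-12)
})

test_that("summing per-gene spectra equals pooling all sites", {
  fx <- noisy_cohort_fixture(seed = 55)
  co <- annotate_site_classes(fx$cohort, 0.5, seed = 1)
  gt <- co$genotypes
  pooled <- build_folded_sfs(gt, 16)
  genes <- unique(co$gene_id)
  summed <- Reduce(`+`, lapply(genes, function(g)
    build_folded_sfs(gt[co$gene_id == g, , drop = FALSE], 16)$counts))
  expect_equal(pooled$counts, summed)
})

test_that("folding commutes with projection in expectation on toy spectra", {
  set.seed(12)
  for (rep in 1:5) {
    xi <- runif(5, 0, 10)  # unfolded spectrum, n = 6
    n <- 6; m <- 4
    # project unfolded then fold
    proj <- numeric(m - 1)
    for (i in 1:5) for (k in 0:m) {
      pr <- dhyper(k, i, n - i, m)
      if (k > 0 && k < m) proj[k] <- proj[k] + xi[i] * pr
    }
    fold_after <- c(proj[1] + proj[3], proj[2])
    # fold (with tie splitting) then project minor counts
    folded <- c(xi[1] + xi[5], xi[2] + xi[4], xi[3])
    fp <- project_sfs(folded_sfs(folded, n), m)
    expect_equal(fp$counts, fold_after, tolerance = 1e-10)
  }
})

test_that("SFS files round-trip through the TSV + JSON header format", {
  s <- folded_sfs(c(7, 3, 1, 0.5), 8, L = 1234)
  f <- tempfile(fileext = ".tsv")
  write_sfs(s, f)
  r <- read_sfs(f)
  expect_equal(r$counts, s$counts)
  expect_equal(r$n, s$n)
  expect_equal(r$L, s$L)
  fx <- noisy_cohort_fixture(seed = 56)
  j <- build_joint_folded_sfs(fx$cohort$genotypes[, 1:4],
                              fx$cohort$genotypes[, 5:8])
  f2 <- tempfile(fileext = ".tsv")
  write_sfs(j, f2)
  r2 <- read_sfs(f2)
  expect_equal(r2$counts, j$counts, tolerance = 1e-12)
  expect_equal(r2$mask, j$mask)
})
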