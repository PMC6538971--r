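test_that("model specifications carry the stated parameter vectors and nesting", {
  expect_equal(demographic_model_spec("SI")$k, 4)
  expect_equal(demographic_model_spec("IM")$k, 6)
  expect_equal(demographic_model_spec("AM")$k, 7)
  expect_equal(demographic_model_spec("SC")$k, 7)
  expect_equal(demographic_model_spec("AM")$param_names[7], "Ta")
  expect_equal(demographic_model_spec("SC")$param_names[7], "Tsc")
})

test_that("model-nesting limits hold exactly at matched engine seeds", {
  p <- c(theta = 50, nu1 = 1, nu2 = 0.5, Ts = 1, m12 = 2, m21 = 1)
  eIM <- expected_joint_sfs(demographic_model_spec("IM"), p, mc_reps = 5e4)
  eAM <- expected_joint_sfs(demographic_model_spec("AM"), c(p, Ta = 0),
                            mc_reps = 5e4)
  eSC <- expected_joint_sfs(demographic_model_spec("SC"),
                            c(p, Tsc = unname(p["Ts"])), mc_reps = 5e4)
  rel <- function(a, b) max(abs(a$counts - b$counts) /
                              pmax(b$counts, 1e-9))
  expect_lt(rel(eAM, eIM), 1e-2)
  expect_lt(rel(eSC, eIM), 1e-2)
  p0 <- p; p0[c("m12", "m21")] <- 0
  eIM0 <- expected_joint_sfs(demographic_model_spec("IM"), p0,
                             mc_reps = 5e4)
  eSI <- expected_joint_sfs(demographic_model_spec("SI"), p0[1:4],
                            mc_reps = 5e4)
  expect_lt(rel(eIM0, eSI), 1e-2)
})

test_that("the combined-sample marginal of a fresh split matches the neutral SFS", {
  # SI with Ts -> 0 and equal sizes is a single constant population of
  # 8 chromosomes; the combined folded marginal must match theta / i folded
  p <- c(theta = 1, nu1 = 1, nu2 = 1, Ts = 1e-6)
  e <- expected_joint_sfs(demographic_model_spec("SI"), p, mc_reps = 1e6)
  tot <- outer(0:4, 0:4, `+`)
  marg <- vapply(1:4, function(k) sum(e$counts[tot == k & !e$mask]), 0.0)
  # fold theta/i at n = 8, then project expectation from 8 to the summed
  # marginal of the 4+4 spectrum: the combined sample IS 8 chromosomes,
  # so the marginal equals the folded neutral spectrum directly
  neutral <- twopopgen:::.fold_vector(1 / (1:7), 8)
  expect_equal(marg, neutral, tolerance = 0.02)
})

test_that("expected spectra are non-negative and finite across the box", {
  spec <- demographic_model_spec("SC")
  set.seed(13)
  for (r in 1:6) {
    p <- c(theta = 10, nu1 = 10^runif(1, -2, 2), nu2 = 10^runif(1, -2, 2),
           Ts = 10^runif(1, -2, 0.5), m12 = runif(1, 0, 10),
           m21 = runif(1, 0, 10))
    p["Tsc"] <- unname(p["Ts"]) * runif(1)
    e <- expected_joint_sfs(spec, p, mc_reps = 5e3)
    expect_true(all(is.finite(e$counts)))
    expect_true(all(e$counts >= 0))
  }
})

test_that("composite likelihood matches a brute-force Poisson sum on a toy spectrum", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 4; m[2, 1] <- 6; m[2, 2] <- 2; m[1, 3] <- 1; m[3, 1] <- 3
  mask <- twopopgen:::.jsfs_mask(2, 2)
  obs <- folded_joint_sfs(m * !mask, mask)
  e <- matrix(0, 3, 3)
  e[1, 2] <- 3; e[2, 1] <- 7; e[2, 2] <- 3; e[1, 3] <- 2; e[3, 1] <- 2
  exp_sfs <- folded_joint_sfs(e * !mask, mask)
  cl <- composite_loglik(obs, exp_sfs)
  s <- sum(m[!mask]) / sum(e[!mask])
  oracle <- sum(dpois(m[!mask], s * e[!mask], log = TRUE))
  expect_equal(cl$loglik, oracle, tolerance = 1e-12)
  expect_equal(cl$theta_hat, s)
})

test_that("observed equal to expected gives theta_hat 1 and maximal scaling", {
  fx <- noisy_cohort_fixture(seed = 61)
  j <- build_joint_folded_sfs(fx$cohort$genotypes[, 1:4],
                              fx$cohort$genotypes[, 5:8])
  cl <- composite_loglik(j, j)
  expect_equal(cl$theta_hat, 1)
  # the analytic scale maximizes the likelihood over scalings
  scale_ll <- function(s) {
    e2 <- j; e2$counts <- j$counts * s
    sum(j$counts[!j$mask] * log(pmax(e2$counts[!j$mask], 1e-300)) -
          e2$counts[!j$mask])
  }
  expect_gte(scale_ll(1), scale_ll(0.9))
  expect_gte(scale_ll(1), scale_ll(1.1))
})

test_that("masked cells do not affect the likelihood", {
  m <- matrix(5, 5, 5)
  mask <- twopopgen:::.jsfs_mask(4, 4)
  m[mask] <- 0
  obs <- folded_joint_sfs(m, mask)
  e <- folded_joint_sfs(m * 1.3, mask)
  l1 <- composite_loglik(obs, e)$loglik
  # altering masked cells of either side changes nothing
  obs2 <- obs; obs2$counts[1, 1] <- 0  # already masked; keep zero (invariant)
  expect_equal(composite_loglik(obs2, e)$loglik, l1)
})

test_that("fit_model is deterministic given the seed and honors defaults", {
  expect_equal(formals(fit_model)$n_replicates, 50)
  fx <- noisy_cohort_fixture(seed = 62)
  j <- build_joint_folded_sfs(fx$cohort$genotypes[, 1:4],
                              fx$cohort$genotypes[, 5:8])
  f1 <- fit_model(j, "SI", n_replicates = 2, seed = 5, mc_reps = 5e3,
                  coarse_reps = 2e3, coarse_n = 6, n_refine = 1, maxit = 40)
  f2 <- fit_model(j, "SI", n_replicates = 2, seed = 5, mc_reps = 5e3,
                  coarse_reps = 2e3, coarse_n = 6, n_refine = 1, maxit = 40)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(nrow(f1$replicates), 2)
  expect_equal(f1$AIC, 2 * 4 - 2 * f1$loglik)
})

test_that("model comparison uses LRT for nested pairs and AIC otherwise", {
  mk <- function(kind, ll) {
    k <- demographic_model_spec(kind)$k
    structure(list(kind = kind, k = k, loglik = ll, AIC = 2 * k - 2 * ll,
                   observed_total = 100), class = "demog_fit")
  }
  fits <- list(mk("SI", -50), mk("IM", -48), mk("AM", -47.5),
               mk("SC", -46))
  cmp <- compare_models(fits)
  expect_true(all(c("SI", "IM") %in% cmp$lrt$null |
                    c("SI", "IM") %in% cmp$lrt$alternative))
  si_im <- cmp$lrt[cmp$lrt$null == "SI", ]
  expect_equal(si_im$statistic, 4)
  expect_equal(si_im$df, 2)
  expect_equal(si_im$p_value, pchisq(4, 2, lower.tail = FALSE))
  # AM vs SC decided by AIC, not LRT
  expect_false(any(cmp$lrt$null == "AM" | cmp$lrt$alternative == "AM" &
                     cmp$lrt$null == "SC"))
  expect_equal(cmp$aic_pairs$preferred, "SC")
  # equal log-likelihoods: fewer parameters wins by AIC
  fits2 <- list(mk("SI", -50), mk("IM", -50))
  expect_equal(compare_models(fits2)$ranking$model[1], "SI")
  # mismatched observed spectra are rejected
  bad <- mk("IM", -48); bad$observed_total <- 200
  expect_error(compare_models(list(mk("SI", -50), bad)), "same observed")
})

test_that("physical-unit conversion follows theta = 4 N mu L and round-trips", {
  # theta = 4 N mu L: with mu = 2e-9 and L = 1e6, theta = 8 gives
  # N_anc = 1000; a scaled time of 0.5 at g = 5 is then 5000 years
  pars <- c(theta = 8, nu1 = 2, nu2 = 0.5, Ts = 0.5, m12 = 1, m21 = 2,
            Ta = 0.1)
  phys <- to_physical_units(pars, mu = 2e-9, L = 1e6, g = 5)
  expect_equal(phys$N_anc, 1000)
  expect_equal(phys$N1, 2000)
  expect_equal(phys$T_split_years, 0.5 * 2 * 1000 * 5)  # 5000 years
  expect_equal(phys$T_change_years, 0.1 * 2 * 1000 * 5)
  expect_equal(formals(to_physical_units)$g, 5)
  back <- physical_to_scaled(phys)
  expect_equal(unname(back["theta"]), 8, tolerance = 1e-12)
  expect_equal(unname(back["nu1"]), 2, tolerance = 1e-12)
  expect_equal(unname(back["Ts"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(back["Tc"]), 0.1, tolerance = 1e-12)
  expect_error(to_physical_units(c(theta = 0, nu1 = 1), 1e-9, 1e6), "theta")
})

test_that("likelihood at the truth beats single-coordinate x4 perturbations", {
  spec <- demographic_model_spec("IM")
  true <- c(theta = 1, nu1 = 1, nu2 = 0.5, Ts = 1, m12 = 1, m21 = 0.5)
  shape <- expected_joint_sfs(spec, true, mc_reps = 5e5, engine_seed = 271)
  th <- 1e5 / sum(shape$counts)
  e <- shape; e$counts <- shape$counts * th
  wins <- 0; trials <- 0
  for (r in 1:4) {
    obs <- sample_sfs_counts(e, 700 + r)
    ll_true <- composite_loglik(
      obs, expected_joint_sfs(spec, true, mc_reps = 2e5))$loglik
    for (nm in c("nu2", "Ts", "m12")) {
      pp <- true
      pp[nm] <- pp[nm] * 4
      ll_p <- composite_loglik(
        obs, expected_joint_sfs(spec, pp, mc_reps = 2e5))$loglik
      trials <- trials + 1
      if (ll_true > ll_p) wins <- wins + 1
    }
  }
  expect_gte(wins / trials, 0.95)
})

test_that("LRT null rejection rate is calibrated (scaled-down null simulation)", {
  # null: SI truth; alternative: IM. Under the null with large counts the
  # MLE is near the truth, so truth-started local fits at reduced engine
  # precision stand in for the full multi-start protocol (scaled down to
  # 100 replicates for the time budget); common random numbers make the
  # Monte-Carlo error largely cancel between the nested fits.
  # the engine at fixed precision and fixed seed defines a deterministic
  # nested model family; generating the null data from a point of that
  # family and fitting both models on the same surface gives a
  # within-family LRT whose calibration does not depend on the engine's
  # Monte-Carlo precision (an independent high-precision surface would
  # reintroduce misspecification noise proportional to the count total)
  sSI <- demographic_model_spec("SI")
  sIM <- demographic_model_spec("IM")
  reps <- 5e3
  p0 <- c(theta = 1, nu1 = 1, nu2 = 0.6, Ts = 0.8)
  shape <- expected_joint_sfs(sSI, p0, mc_reps = reps)
  th <- 3e3 / sum(shape$counts)
  e <- shape; e$counts <- shape$counts * th
  boxSI <- twopopgen:::.param_box(sSI)
  boxIM <- twopopgen:::.param_box(sIM)
  fit_local <- function(obs, spec, box, x0, it) {
    obj <- function(x) {
      if (any(x < box$lo) || any(x > box$hi)) return(1e10)
      p <- twopopgen:::.box_to_params(spec, x, box)
      ex <- expected_joint_sfs(spec, p, mc_reps = reps)
      -composite_loglik(obs, ex)$loglik
    }
    -optim(x0, obj, method = "Nelder-Mead",
           control = list(maxit = it, reltol = 1e-8))$value
  }
  x_si <- log(c(1, 0.6, 0.8))
  x_im <- c(x_si, log(0.01), log(0.01))
  x_im2 <- c(x_si, log(0.5), log(0.5))
  n_rep <- 100
  stat <- vapply(seq_len(n_rep), function(r) {
    obs <- sample_sfs_counts(e, 5000 + r)
    ll0 <- fit_local(obs, sSI, boxSI, x_si, 80)
    ll1 <- max(fit_local(obs, sIM, boxIM, x_im, 120),
               fit_local(obs, sIM, boxIM, x_im2, 120))
    max(2 * (ll1 - ll0), 0)
  }, 0.0)
  rate <- mean(stat > qchisq(0.95, df = 2))
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.10)
})
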