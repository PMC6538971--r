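# Expected folded joint SFS under the SI/IM/AM/SC family, Poisson composite
# likelihood, multi-start fitting, nested/non-nested model comparison, and
# conversion of scaled parameters to physical units.
#
# The expected-SFS engine is a Monte-Carlo expectation over structured
# coalescent genealogies (C++ core). Within one fit the engine seed is held
# fixed (common random numbers), making the composite-likelihood surface a
# deterministic function of the parameters so that derivative-free
# optimization behaves; because zero-rate events consume no randomness, the
# model-nesting limits (AM with Ta = 0 equals IM, IM with m = 0 equals SI,
# SC with Tsc = Ts equals IM) hold exactly at matched seeds.

#' Demographic model specification
#'
#' Free-parameter vectors (theta is always fitted, via its analytic optimum):
#' SI `(theta, nu1, nu2, Ts)`; IM adds `(m12, m21)`; AM adds `Ta` (gene flow
#' from the split until `Ta` ago); SC adds `Tsc` (gene flow from `Tsc` ago to
#' the present). SI is nested in IM (`m = 0`); IM is nested in AM (`Ta = 0`)
#' and in SC (`Tsc = Ts`).
#'
#' @param kind one of `"SI"`, `"IM"`, `"AM"`, `"SC"`
#' @return object of class `demographic_model_spec` with `kind`,
#'   `param_names` and `k` (free-parameter count)
#' @export
demographic_model_spec <- function(kind = c("SI", "IM", "AM", "SC")) {
  kind <- match.arg(kind)
  pn <- switch(kind,
    SI = c("theta", "nu1", "nu2", "Ts"),
    IM = c("theta", "nu1", "nu2", "Ts", "m12", "m21"),
    AM = c("theta", "nu1", "nu2", "Ts", "m12", "m21", "Ta"),
    SC = c("theta", "nu1", "nu2", "Ts", "m12", "m21", "Tsc"))
  structure(list(kind = kind, param_names = pn, k = length(pn)),
            class = "demographic_model_spec")
}

.spec_params <- function(spec, params) {
  p <- setNames(rep(0, 7), c("theta", "nu1", "nu2", "Ts", "m12", "m21", "Tc"))
  nm <- spec$param_names
  if (is.null(names(params))) names(params) <- nm
  stopifnot(all(nm %in% names(params)))
  p[c("theta", "nu1", "nu2", "Ts")] <- params[c("theta", "nu1", "nu2", "Ts")]
  if (spec$kind != "SI") p[c("m12", "m21")] <- params[c("m12", "m21")]
  if (spec$kind == "AM") p["Tc"] <- params["Ta"]
  if (spec$kind == "SC") p["Tc"] <- params["Tsc"]
  p
}

#' Expected folded joint SFS under a demographic model
#'
#' Monte-Carlo expectation of the folded joint SFS: the coalescent engine
#' returns expected branch lengths classified by joint descendant
#' configuration, which are scaled by `theta / 2` and folded with the same
#' combined-minor-allele convention as [build_joint_folded_sfs()], so
#' observed and expected spectra are commensurable. Standard errors of the
#' Monte-Carlo mean scale as `1 / sqrt(mc_reps)`.
#'
#' @param spec a [demographic_model_spec()]
#' @param params named parameter vector (see the spec's `param_names`);
#'   `theta` scales the spectrum
#' @param n1_eff,n2_eff haploid sample sizes of the spectrum (defaults 4)
#' @param mc_reps Monte-Carlo genealogy replicates (default 1e5)
#' @param engine_seed fixed seed of the engine's private RNG stream
#' @return a real-valued `folded_joint_sfs`
#' @export
expected_joint_sfs <- function(spec, params, n1_eff = 4, n2_eff = 4,
                               mc_reps = 1e5, engine_seed = 20260910) {
  stopifnot(inherits(spec, "demographic_model_spec"), n1_eff >= 2,
            n2_eff >= 2)
  p <- .spec_params(spec, params)
  if (any(!is.finite(p)) || any(p < 0))
    stop("parameters must be finite and non-negative", call. = FALSE)
  if (p["Tc"] > p["Ts"] && spec$kind %in% c("AM", "SC"))
    stop("epoch-change time must not exceed the split time", call. = FALSE)
  b <- cpp_expected_jsfs(.model_code(spec$kind), p["nu1"], p["nu2"],
                         p["Ts"], p["Tc"], p["m12"], p["m21"],
                         as.integer(n1_eff), as.integer(n2_eff),
                         as.integer(mc_reps), as.double(engine_seed))
  if (any(!is.finite(b))) stop("non-finite expected spectrum", call. = FALSE)
  fold_joint_matrix(p["theta"] / 2 * b)
}

#' Poisson composite log-likelihood of an observed joint SFS
#'
#' Treats unmasked cells as independent Poisson counts with mean
#' `theta_scale * expected`, where the scale is set to its analytic optimum,
#' the ratio of total observed to total expected counts. Expected cells equal
#' to zero where the observation is positive are floored at `zero_floor`
#' times the smallest positive expected cell (with a warning).
#'
#' @param observed,expected `folded_joint_sfs` objects with matching shapes
#'   and masks
#' @param zero_floor relative floor for zero expected cells (default 1e-6)
#' @return list with `loglik`, `theta_hat` (the fitted scale) and `n_cells`
#' @export
composite_loglik <- function(observed, expected, zero_floor = 1e-6) {
  stopifnot(inherits(observed, "folded_joint_sfs"),
            inherits(expected, "folded_joint_sfs"))
  if (!all(dim(observed$counts) == dim(expected$counts)) ||
      !all(observed$mask == expected$mask))
    stop("observed and expected spectra have mismatched shapes or masks",
         call. = FALSE)
  use <- !observed$mask
  o <- observed$counts[use]
  e <- expected$counts[use]
  if (any(e == 0 & o > 0)) {
    warning("expected cells of zero where observations are positive; ",
            "applying the documented floor")
    e[e == 0] <- zero_floor * min(e[e > 0])
  }
  s <- sum(o) / sum(e)
  lambda <- s * e
  keep <- lambda > 0 | o > 0
  ll <- sum(o[keep] * log(lambda[keep]) - lambda[keep] - lgamma(o[keep] + 1))
  ll <- ll + sum(-lambda[!keep])
  list(loglik = ll, theta_hat = s, n_cells = sum(use))
}

# parameter box (log10 scale) for optimization
.param_box <- function(spec) {
  lo <- c(nu1 = 1e-3, nu2 = 1e-3, Ts = 1e-4, m12 = 1e-3, m21 = 1e-3,
          frac = 1e-3)
  hi <- c(nu1 = 1e3, nu2 = 1e3, Ts = 10, m12 = 50, m21 = 50, frac = 1)
  nm <- switch(spec$kind,
    SI = c("nu1", "nu2", "Ts"),
    IM = c("nu1", "nu2", "Ts", "m12", "m21"),
    AM = , SC = c("nu1", "nu2", "Ts", "m12", "m21", "frac"))
  list(lo = log(lo[nm]), hi = log(hi[nm]), names = nm)
}

# optimizer coordinates -> named model parameters (theta excluded; the
# epoch-change time is parameterized as a fraction of Ts so the constraint
# Tc <= Ts is built in)
.box_to_params <- function(spec, x, box) {
  v <- exp(x)
  names(v) <- box$names
  p <- c(theta = 1, v[setdiff(box$names, "frac")])
  if (spec$kind == "AM") p["Ta"] <- v["frac"] * v["Ts"]
  if (spec$kind == "SC") p["Tsc"] <- v["frac"] * v["Ts"]
  p
}

#' Fit a demographic model to an observed folded joint SFS
#'
#' Multi-start bounded optimization in log-parameter space. The coarse stage
#' combines a seeded random search over the parameter box with structured
#' candidate starts built from an internal strict-isolation warm fit (under
#' gene flow the apparent isolation time underestimates the true split, so
#' split-time multipliers crossed with a migration-rate grid are tried); the
#' best few candidates are refined by Nelder-Mead at reduced Monte-Carlo
#' precision. Each of `n_replicates` replicate runs then perturbs the
#' refined optimum multiplicatively (factor <= 4) and polishes it by
#' Nelder-Mead at full precision with a fixed engine seed (common random
#' numbers, so the surface is deterministic). theta is profiled out
#' analytically. Deterministic given `seed`.
#'
#' @param observed a `folded_joint_sfs`
#' @param spec a [demographic_model_spec()] (or model kind string)
#' @param n_replicates replicate runs (default 50)
#' @param seed integer seed
#' @param mc_reps engine replicates during replicate polishing (default 1e5)
#' @param coarse_reps engine replicates during the coarse/refine stages
#' @param coarse_n coarse random-search points
#' @param n_refine coarse candidates refined by Nelder-Mead
#' @param n_polish replicate endpoints re-polished at full precision
#' @param maxit Nelder-Mead iteration cap per run
#' @param replicate_reps engine replicates during the replicate stage
#'   (default: `mc_reps`; reduce to explore more starts per unit time)
#' @param engine_seed fixed engine seed (common random numbers)
#' @return object of class `demog_fit`: estimated `params` (including
#'   `theta`), `loglik`, `AIC = 2k - 2 loglik`, `replicates` table,
#'   `convergence` flag
#' @export
fit_model <- function(observed, spec, n_replicates = 50, seed = 1,
                      mc_reps = 1e5, coarse_reps = 2e4, coarse_n = 40,
                      n_refine = 3, n_polish = 3, maxit = 250,
                      replicate_reps = NULL, engine_seed = 20260910) {
  if (is.character(spec)) spec <- demographic_model_spec(spec)
  stopifnot(inherits(observed, "folded_joint_sfs"),
            sum(observed$counts) > 0)
  box <- .param_box(spec)
  n1 <- observed$n1_eff; n2 <- observed$n2_eff
  obj <- function(x, reps, es = engine_seed) {
    if (any(x < box$lo - 1e-9) || any(x > box$hi + 1e-9)) return(1e10)
    p <- .box_to_params(spec, pmin(pmax(x, box$lo), box$hi), box)
    e <- suppressWarnings(
      expected_joint_sfs(spec, p, n1, n2, mc_reps = reps,
                         engine_seed = es))
    -suppressWarnings(composite_loglik(observed, e))$loglik
  }
  nm <- function(x0, reps, it = maxit, es = engine_seed) {
    optim(x0, obj, reps = reps, es = es, method = "Nelder-Mead",
          control = list(maxit = it, reltol = 1e-9))
  }
  old <- .set_local_seed(substream_seed(seed, paste0("fit_", spec$kind)))
  on.exit(.restore_seed(old), add = TRUE)
  d <- length(box$lo)

  # coarse stage: random points plus structured warm starts
  starts <- matrix(runif(coarse_n * d, rep(box$lo, each = coarse_n),
                         rep(box$hi, each = coarse_n)), coarse_n, d)
  starts <- rbind(starts, rep(0, d))  # all parameters at 1 (box units)
  if (spec$kind != "SI") {
    si <- .si_warm_start(observed, coarse_reps, maxit, engine_seed)
    grid_m <- log(c(0.5, 4))
    grid_ts <- log(c(1, 2, 4))
    grid_fr <- if (d == 6) log(c(0.2, 0.6)) else 0
    for (ts in grid_ts) for (ma in grid_m) for (mb in grid_m)
      for (fr in grid_fr) {
        x <- c(si[1], si[2], si[3] + ts, ma, mb)
        if (d == 6) x <- c(x, fr)
        starts <- rbind(starts, pmin(pmax(x, box$lo), box$hi))
      }
  }
  if (is.null(replicate_reps)) replicate_reps <- max(coarse_reps,
                                                     mc_reps %/% 2)
  # rank candidates cheaply, then refine the best few at full precision
  # (refining at coarse precision lets Nelder-Mead stall in Monte-Carlo
  # noise minima, so the refinement runs at replicate/full precision)
  cvals <- apply(starts, 1, obj, reps = coarse_reps)
  # tier A: short descents from the leading candidates (a candidate's
  # static coarse value predicts its basin poorly, a brief descent less so)
  # full double-round descents of the leading candidates, entirely at full
  # precision -- descending a curved likelihood valley at low Monte-Carlo
  # precision strands the simplex partway down, where the full-precision
  # surface then shows a spurious local optimum, so no cheap pre-descent is
  # attempted
  top <- order(cvals)[seq_len(min(n_refine, nrow(starts)))]
  refined <- lapply(top, function(i) {
    g <- nm(starts[i, ], mc_reps)
    nm(g$par, mc_reps)
  })
  best_ref <- refined[[which.min(vapply(refined, `[[`, 0.0, "value"))]]
  x0 <- best_ref$par
  reps_tab <- vector("list", n_replicates)
  ends <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    # first replicate polishes the refined point itself; the rest perturb it
    pert <- if (r == 1) rep(0, d) else runif(d, -log(4), log(4))
    start <- pmin(pmax(x0 + pert, box$lo), box$hi)
    fit <- nm(start, replicate_reps)
    ends[[r]] <- fit
    reps_tab[[r]] <- data.frame(replicate = r, loglik = -fit$value,
                                converged = fit$convergence == 0,
                                t(setNames(exp(fit$par), box$names)))
  }
  reps_tab <- do.call(rbind, reps_tab)
  # polish the best replicate endpoint at full precision; the refined
  # optimum competes alongside it
  vals <- vapply(ends, `[[`, 0.0, "value")
  polish <- list(nm(ends[[which.min(vals)]]$par, mc_reps), best_ref)
  best <- polish[[which.min(vapply(polish, `[[`, 0.0, "value"))]]
  if (best$value >= 1e10)
    stop("no replicate converged; coarse-search diagnostics: best value ",
         min(cvals), call. = FALSE)
  pars <- .box_to_params(spec, best$par, box)
  e <- suppressWarnings(
    expected_joint_sfs(spec, pars, n1, n2, mc_reps = mc_reps,
                       engine_seed = engine_seed))
  cl <- composite_loglik(observed, e)
  pars["theta"] <- cl$theta_hat
  structure(list(kind = spec$kind, spec = spec, params = pars,
                 loglik = cl$loglik, k = spec$k,
                 AIC = 2 * spec$k - 2 * cl$loglik,
                 replicates = reps_tab,
                 convergence = best$convergence == 0,
                 observed_total = sum(observed$counts),
                 n1_eff = n1, n2_eff = n2,
                 mc_reps = mc_reps, engine_seed = engine_seed),
            class = "demog_fit")
}

# quick strict-isolation fit used to seed the structured starts of the
# migration models; returns box coordinates (log nu1, log nu2, log Ts)
.si_warm_start <- function(observed, reps, maxit, engine_seed) {
  si <- demographic_model_spec("SI")
  box <- .param_box(si)
  obj <- function(x) {
    if (any(x < box$lo) || any(x > box$hi)) return(1e10)
    p <- .box_to_params(si, x, box)
    e <- suppressWarnings(
      expected_joint_sfs(si, p, observed$n1_eff, observed$n2_eff,
                         mc_reps = reps, engine_seed = engine_seed))
    -suppressWarnings(composite_loglik(observed, e))$loglik
  }
  n <- 30
  pts <- matrix(runif(n * 3, rep(box$lo, each = n), rep(box$hi, each = n)),
                n, 3)
  pts <- rbind(pts, rep(0, 3))
  vals <- apply(pts, 1, obj)
  fits <- lapply(order(vals)[1:3], function(i) {
    f <- optim(pts[i, ], obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-9))
    optim(f$par, obj, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-9))
  })
  fits[[which.min(vapply(fits, `[[`, 0.0, "value"))]]$par
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik = %.3f, AIC = %.3f (k = %d)\n",
              x$kind, x$loglik, x$AIC, x$k))
  print(signif(x$params, 4))
  invisible(x)
}

#' Compare fitted demographic models
#'
#' Nested pairs (SI in IM, IM in AM, IM in SC) are compared by likelihood-
#' ratio tests of `2 * delta-loglik` against a chi-squared distribution with
#' degrees of freedom equal to the parameter difference; the non-nested pair
#' AM vs SC is compared by AIC. A full ranking table (by log-likelihood,
#' ties broken by AIC) is returned.
#'
#' @param fits list of `demog_fit` objects on the same observed spectrum
#' @return list with `ranking` (data.frame), `lrt` (data.frame of nested
#'   tests) and `aic_pairs` (non-nested comparisons)
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "demog_fit")))
  names(fits) <- vapply(fits, `[[`, "", "kind")
  tot <- vapply(fits, `[[`, 0.0, "observed_total")
  if (length(unique(tot)) != 1)
    stop("fits are not on the same observed spectrum", call. = FALSE)
  ranking <- data.frame(
    model = names(fits),
    k = vapply(fits, `[[`, 0L, "k"),
    loglik = vapply(fits, `[[`, 0.0, "loglik"),
    AIC = vapply(fits, `[[`, 0.0, "AIC"))
  ranking <- ranking[order(ranking$AIC, -ranking$loglik), ]
  rownames(ranking) <- NULL
  nested <- list(c("SI", "IM"), c("IM", "AM"), c("IM", "SC"))
  lrt <- do.call(rbind, lapply(nested, function(pr) {
    if (!all(pr %in% names(fits))) return(NULL)
    f0 <- fits[[pr[1]]]; f1 <- fits[[pr[2]]]
    stat <- max(2 * (f1$loglik - f0$loglik), 0)
    df <- f1$k - f0$k
    data.frame(null = pr[1], alternative = pr[2], statistic = stat, df = df,
               p_value = pchisq(stat, df, lower.tail = FALSE))
  }))
  aic_pairs <- NULL
  if (all(c("AM", "SC") %in% names(fits))) {
    aic_pairs <- data.frame(model_a = "AM", model_b = "SC",
                            delta_AIC = fits[["AM"]]$AIC - fits[["SC"]]$AIC,
                            preferred = if (fits[["AM"]]$AIC <= fits[["SC"]]$AIC)
                              "AM" else "SC")
  }
  list(ranking = ranking, lrt = lrt, aic_pairs = aic_pairs)
}

#' Convert scaled demographic parameters to physical units
#'
#' `N_anc = theta / (4 mu L)`; daughter sizes `N1 = nu1 N_anc`,
#' `N2 = nu2 N_anc`; times in years are scaled times times `2 N_anc g`;
#' migrants per generation `M_i = m_ij * nu_i * N_anc / N_anc ...` are
#' reported as `nu_i * m_ij / 2` (the expected number of immigrant lineages
#' per generation into daughter i).
#'
#' @param fit a `demog_fit` (or a named parameter vector with `theta`)
#' @param mu per-site per-generation mutation rate
#' @param L surveyed sequence length in bp
#' @param g generation time in years (default 5)
#' @return list of class `physical_params`
#' @export
to_physical_units <- function(fit, mu, L, g = 5) {
  stopifnot(mu > 0, L > 0, g > 0)
  params <- if (inherits(fit, "demog_fit")) fit$params else fit
  if (!("theta" %in% names(params)) || params["theta"] <= 0)
    stop("theta must be present and positive", call. = FALSE)
  N_anc <- unname(params["theta"] / (4 * mu * L))
  yrs <- function(t) unname(t * 2 * N_anc * g)
  out <- list(N_anc = N_anc,
              N1 = unname(params["nu1"] * N_anc),
              N2 = unname(params["nu2"] * N_anc),
              T_split_years = yrs(params["Ts"]),
              T_change_years = if ("Ta" %in% names(params)) yrs(params["Ta"])
                else if ("Tsc" %in% names(params)) yrs(params["Tsc"])
                else NA_real_,
              migrants_per_gen = if ("m12" %in% names(params))
                c(into_pop1 = unname(params["nu1"] * params["m12"] / 2),
                  into_pop2 = unname(params["nu2"] * params["m21"] / 2))
                else NULL,
              mu = mu, L = L, g = g)
  class(out) <- "physical_params"
  out
}

#' Inverse of [to_physical_units()]
#'
#' @param phys a `physical_params`
#' @return named vector of scaled parameters (`theta`, `nu1`, `nu2`, `Ts`
#'   and, when present, the epoch-change time `Tc`)
#' @export
physical_to_scaled <- function(phys) {
  stopifnot(inherits(phys, "physical_params"))
  theta <- 4 * phys$N_anc * phys$mu * phys$L
  out <- c(theta = theta, nu1 = phys$N1 / phys$N_anc,
           nu2 = phys$N2 / phys$N_anc,
           Ts = phys$T_split_years / (2 * phys$N_anc * phys$g))
  if (!is.na(phys$T_change_years))
    out["Tc"] <- phys$T_change_years / (2 * phys$N_anc * phys$g)
  out
}
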