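# Distribution of fitness effects of new nonsynonymous mutations, estimated
# from folded synonymous/nonsynonymous SFS pairs: synonymous sites fit a
# two-epoch neutral demographic nuisance; nonsynonymous sites fit a gamma
# distribution of scaled deleterious effects Ne*s, with the demographic
# distortion of the neutral spectrum carried over multiplicatively per
# frequency class.

# ---- neutral expectations -------------------------------------------------

# Occupancy times E[T_k] (time with k ancestral lineages, units of 2*N_anc
# generations) for a sample of n under a two-epoch history: relative size
# `size_ratio` from the present back to `change_time`, size 1 before that.
# Epoch occupancy uses the block matrix exponential trick
# expm([[Q, I], [0, 0]] t)[1:n, n+1:2n] = integral_0^t expm(Q s) ds.
.two_epoch_occupancy <- function(n, size_ratio, change_time) {
  ks <- n:2
  rates <- ks * (ks - 1) / 2 / size_ratio
  m <- length(ks)
  Q <- matrix(0, m + 1, m + 1)  # states: n, n-1, ..., 2, 1 lineages
  for (i in seq_len(m)) { Q[i, i] <- -rates[i]; Q[i, i + 1] <- rates[i] }
  occ1 <- numeric(m)
  if (change_time > 0) {
    A <- rbind(cbind(Q, diag(m + 1)),
               matrix(0, m + 1, 2 * (m + 1)))
    E <- as.matrix(Matrix::expm(Matrix::Matrix(A * change_time)))
    P <- E[1:(m + 1), 1:(m + 1)]
    Int <- E[1:(m + 1), (m + 2):(2 * m + 2)]
    occ1 <- Int[1, 1:m]
    p_at_change <- P[1, ]
  } else {
    p_at_change <- c(1, rep(0, m))
  }
  # ancestral epoch (size 1, unbounded): a chain currently at j lineages
  # surely passes every level k <= j, staying Exp(k(k-1)/2) at each
  occ2 <- vapply(seq_len(m), function(i) {
    k <- ks[i]
    sum(p_at_change[1:i]) * 2 / (k * (k - 1))
  }, 0.0)
  setNames(occ1 + occ2, ks)
}

#' Expected folded neutral SFS under a two-epoch history
#'
#' Expected spectrum (per unit theta = 4 N_anc mu L, i.e. the constant-size
#' unfolded expectation is `1 / i`) for a sample of `n` chromosomes from a
#' population of relative size `size_ratio` that changed from size 1 at
#' `change_time` (units of 2 N_anc generations) ago. Computed exactly from
#' lineage-count occupancy times and the standard probability that a branch
#' with k ancestral lineages subtends i of n tips.
#'
#' @param n haploid sample size
#' @param size_ratio current size relative to ancestral (1 = constant)
#' @param change_time time of the size change, backward, in 2 N_anc
#'   generations
#' @param fold return the folded spectrum (default) or the unfolded one
#' @return numeric vector: folded classes `1..floor(n/2)` or unfolded
#'   `1..n-1`
#' @export
expected_sfs_neutral_two_epoch <- function(n, size_ratio, change_time,
                                           fold = TRUE) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (size_ratio <= 0 || change_time < 0)
    stop("size_ratio must be > 0 and change_time >= 0", call. = FALSE)
  occ <- .two_epoch_occupancy(n, size_ratio, change_time)
  ks <- as.integer(names(occ))
  xi <- vapply(seq_len(n - 1), function(i) {
    # P(branch with k lineages subtends i tips) = C(n-i-1, k-2) / C(n-1, k-1)
    pr <- choose(n - i - 1, ks - 2) / choose(n - 1, ks - 1)
    0.5 * sum(ks * occ * pr)
  }, 0.0)
  if (!fold) return(xi)
  .fold_vector(xi, n)
}

.fold_vector <- function(xi, n) {
  counts <- numeric(floor(n / 2))
  for (i in seq_len(n - 1)) {
    b <- min(i, n - i)
    w <- if (2 * i == n) 1 else 1  # complementary bin adds the other half
    counts[b] <- counts[b] + xi[i] * w
  }
  # note: when n is even the class n/2 receives only its own mass (i = n/2
  # has no distinct complement), matching the folded-count convention
  counts
}

# ---- selected expectations ------------------------------------------------

# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenvalue
# method; cached per K.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre_01 <- function(K) {
  key <- as.character(K)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(K - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, K, K)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2
  w <- 2 * (e$vectors[1, ]^2) / 2
  o <- order(x)
  out <- list(x = x[o], w = w[o])
  .gl_cache[[key]] <- out
  out
}

# Sojourn-density factor H(x; gamma) = (1 - exp(-gamma (1 - x))) /
# (1 - exp(-gamma)), gamma = 4 Ne s (negative for deleterious mutations),
# evaluated stably; H -> (1 - x) as gamma -> 0.
.sojourn_h <- function(x, gamma) {
  if (abs(gamma) < 1e-8) return(1 - x)
  if (gamma < 0) {
    a <- -gamma
    # (exp(a(1-x)) - 1) / (exp(a) - 1) = exp(-a x) (1 - exp(-a(1-x))) /
    #                                    (1 - exp(-a))
    exp(-a * x) * (-expm1(-a * (1 - x))) / (-expm1(-a))
  } else {
    (-expm1(-gamma * (1 - x))) / (-expm1(-gamma))
  }
}

#' Expected folded SFS for mutations under genic selection
#'
#' Expectation from the diffusion sojourn-time integral for new mutations
#' with scaled deleterious strength `Nes = Ne * s >= 0` (gamma = -4 Nes in
#' the sojourn density), binomially sampled to `n` chromosomes and folded.
#' The constant-size selected spectrum is multiplied per (unfolded)
#' frequency class by the neutral two-epoch distortion factors
#' `r_i = neutral_two_epoch_i / neutral_constant_i`, carrying the
#' demographic nuisance over to selected sites. `Nes = 0` reduces exactly to
#' [expected_sfs_neutral_two_epoch()]. Scale: per unit theta of the
#' mutation class.
#'
#' @param n haploid sample size
#' @param Nes scaled selection strength (non-negative; deleterious)
#' @param size_ratio,change_time two-epoch demographic nuisance
#' @param fold fold the spectrum (default TRUE)
#' @param gl_nodes Gauss-Legendre quadrature size (default 400)
#' @return numeric vector of expected counts per class
#' @export
expected_sfs_selected <- function(n, Nes, size_ratio = 1, change_time = 0,
                                  fold = TRUE, gl_nodes = 400) {
  if (Nes < 0) stop("Nes must be >= 0 (deleterious-only gamma)",
                    call. = FALSE)
  xi <- .selected_unfolded(n, -4 * Nes, gl_nodes)
  if (any(!is.finite(xi)))
    stop(sprintf("numerical integration failure at Nes = %g", Nes),
         call. = FALSE)
  r <- .distortion_factors(n, size_ratio, change_time)
  xi <- xi * r
  if (!fold) return(xi)
  .fold_vector(xi, n)
}

# unfolded expected spectrum under constant size, per unit theta:
# xi_i = (1/2) int C(n,i) x^i (1-x)^(n-i) * 2/(x(1-x)) * H(x; gamma) dx
.selected_unfolded <- function(n, gamma, gl_nodes) {
  gl <- .gauss_legendre_01(gl_nodes)
  x <- gl$x
  i <- seq_len(n - 1)
  binom <- outer(i, x, function(i, x)
    exp(lchoose(n, i) + (i - 1) * log(x) + (n - i - 1) * log1p(-x)))
  h <- .sojourn_h(x, gamma)
  as.vector(binom %*% (gl$w * h))
}

.distortion_factors <- function(n, size_ratio, change_time) {
  if (size_ratio == 1 && change_time == 0) return(rep(1, n - 1))
  neut2 <- expected_sfs_neutral_two_epoch(n, size_ratio, change_time,
                                          fold = FALSE)
  neut2 / (1 / seq_len(n - 1))
}

# ---- gamma DFE ------------------------------------------------------------

#' Gamma probability mass per Ne*s bin
#'
#' @param shape,mean_Nes gamma shape and mean of Ne*s for new deleterious
#'   mutations
#' @param bins increasing breakpoints covering `[0, Inf)` (default
#'   `c(0, 1, 10, 100, Inf)`)
#' @return named vector of proportions summing to 1
#' @export
dfe_bin_proportions <- function(shape, mean_Nes, bins = c(0, 1, 10, 100, Inf)) {
  stopifnot(shape > 0, mean_Nes >= 0)
  if (is.unsorted(bins, strictly = TRUE) || bins[1] != 0 ||
      !is.infinite(bins[length(bins)]))
    stop("bins must be strictly increasing from 0 to Inf", call. = FALSE)
  labs <- paste0("[", head(bins, -1), ",", tail(bins, -1), ")")
  if (mean_Nes == 0)
    return(setNames(c(1, rep(0, length(bins) - 2)), labs))
  p <- diff(pgamma(bins, shape = shape, rate = shape / mean_Nes))
  setNames(p, labs)
}

# mixture expected spectrum over a gamma of Nes, discretized at G
# equal-mass quantile nodes
.gamma_mixture_sfs <- function(n, shape, mean_Nes, size_ratio, change_time,
                               G = 64, gl_nodes = 400) {
  q <- qgamma((seq_len(G) - 0.5) / G, shape = shape, rate = shape / mean_Nes)
  gl <- .gauss_legendre_01(gl_nodes)
  x <- gl$x
  i <- seq_len(n - 1)
  binom <- outer(i, x, function(i, x)
    exp(lchoose(n, i) + (i - 1) * log(x) + (n - i - 1) * log1p(-x)))
  H <- vapply(q, function(nes) .sojourn_h(x, -4 * nes), numeric(length(x)))
  xi <- (binom %*% (gl$w * H)) %*% rep(1 / G, G)
  as.vector(xi) * .distortion_factors(n, size_ratio, change_time)
}

# Poisson log-likelihood of a folded SFS against a shape with free total
# scale (profiled analytically)
.scaled_poisson_ll <- function(obs, shape_counts) {
  if (any(shape_counts <= 0)) return(-Inf)
  s <- sum(obs) / sum(shape_counts)
  lambda <- s * shape_counts
  sum(obs * log(lambda) - lambda - lgamma(obs + 1))
}

#' Fit a gamma distribution of fitness effects
#'
#' Stage 1 fits the two-epoch demographic nuisance `(size_ratio,
#' change_time)` to the synonymous folded SFS by maximum Poisson likelihood
#' (total mutational input profiled out analytically). Stage 2, conditional
#' on the stage-1 nuisance, fits the gamma `(shape, mean_Nes)` of scaled
#' deleterious effects to the nonsynonymous folded SFS, integrating the
#' selected expectation over the gamma by equal-mass quantile discretization
#' (`G` nodes). When both spectra carry a surveyed length `L`, the
#' nonsynonymous mutational input is anchored to the synonymous per-site
#' estimate (`theta_ns = theta_s * L_nonsyn / L_syn`): the deficit of
#' nonsynonymous variants relative to that input is what identifies the mass
#' of strongly deleterious mutations, which never segregate and are
#' invisible to the spectrum shape alone. Without lengths, the nonsynonymous
#' total rate is profiled freely (and `mean_Nes` is then only weakly
#' identified; a warning is issued). Both stages use multi-start Nelder-Mead
#' in log-parameter space.
#'
#' @param syn_sfs,nonsyn_sfs `folded_sfs` objects sharing `n`
#' @param G gamma discretization nodes (default 64)
#' @param bins Ne*s bin breakpoints for the reported proportions
#' @param gl_nodes quadrature size for the sojourn integrals
#' @return object of class `dfe_fit`: `shape`, `mean_Nes`, `nuisance`,
#'   per-stage log-likelihoods, and `bin_proportions`
#' @export
fit_dfe <- function(syn_sfs, nonsyn_sfs, G = 64,
                    bins = c(0, 1, 10, 100, Inf), gl_nodes = 400) {
  stopifnot(inherits(syn_sfs, "folded_sfs"), inherits(nonsyn_sfs, "folded_sfs"))
  if (syn_sfs$n != nonsyn_sfs$n)
    stop("spectra must share the haploid sample size n", call. = FALSE)
  if (sum(syn_sfs$counts) == 0 || sum(nonsyn_sfs$counts) == 0)
    stop("both spectra must be non-empty", call. = FALSE)
  n <- syn_sfs$n
  anchored <- !is.na(syn_sfs$L) && !is.na(nonsyn_sfs$L) &&
    syn_sfs$L > 0 && nonsyn_sfs$L > 0
  if (!anchored)
    warning("surveyed lengths missing: nonsynonymous rate profiled freely; ",
            "mean_Nes is only weakly identified")

  # stage 1: two-epoch nuisance on synonymous sites
  obj1 <- function(x) {
    nu <- exp(x[1]); tau <- exp(x[2])
    if (nu < 1e-3 || nu > 1e3 || tau < 1e-5 || tau > 10) return(1e10)
    shape <- .fold_vector(
      expected_sfs_neutral_two_epoch(n, nu, tau, fold = FALSE), n)
    -.scaled_poisson_ll(syn_sfs$counts, shape)
  }
  starts1 <- expand.grid(lnu = log(c(0.2, 1, 5)), ltau = log(c(0.05, 0.3, 1)))
  fits1 <- lapply(seq_len(nrow(starts1)), function(i)
    optim(as.numeric(starts1[i, ]), obj1, method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-10)))
  f1 <- fits1[[which.min(vapply(fits1, `[[`, 0.0, "value"))]]
  nuis <- c(size_ratio = exp(f1$par[1]), change_time = exp(f1$par[2]))
  syn_shape <- .fold_vector(
    expected_sfs_neutral_two_epoch(n, nuis[1], nuis[2], fold = FALSE), n)
  theta_syn <- sum(syn_sfs$counts) / sum(syn_shape)

  # stage 2: gamma DFE on nonsynonymous sites, nuisance fixed; mutational
  # input anchored to the synonymous per-site rate when lengths are known
  obj2 <- function(x) {
    shp <- exp(x[1]); mn <- exp(x[2])
    if (shp < 0.01 || shp > 50 || mn < 1e-4 || mn > 1e6) return(1e10)
    shape <- .fold_vector(
      .gamma_mixture_sfs(n, shp, mn, nuis[1], nuis[2], G, gl_nodes), n)
    if (anchored) {
      lambda <- theta_syn * nonsyn_sfs$L / syn_sfs$L * shape
      if (any(lambda <= 0)) return(1e10)
      return(-sum(nonsyn_sfs$counts * log(lambda) - lambda -
                    lgamma(nonsyn_sfs$counts + 1)))
    }
    -.scaled_poisson_ll(nonsyn_sfs$counts, shape)
  }
  starts2 <- expand.grid(lsh = log(c(0.1, 0.3, 1)), lmn = log(c(1, 50, 1000)))
  fits2 <- lapply(seq_len(nrow(starts2)), function(i)
    optim(as.numeric(starts2[i, ]), obj2, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-10)))
  vals <- vapply(fits2, `[[`, 0.0, "value")
  if (all(vals >= 1e10)) stop("DFE fit did not converge", call. = FALSE)
  f2 <- fits2[[which.min(vals)]]
  shape_hat <- exp(f2$par[1]); mean_hat <- exp(f2$par[2])
  props <- dfe_bin_proportions(shape_hat, mean_hat, bins)
  structure(list(shape = shape_hat, mean_Nes = mean_hat, nuisance = nuis,
                 loglik_syn = -f1$value, loglik_nonsyn = -f2$value,
                 bin_proportions = props, bins = bins,
                 convergence = f2$convergence == 0),
            class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("Gamma DFE: shape = %.3f, mean Ne*s = %.2f\n", x$shape,
              x$mean_Nes))
  cat(sprintf("Two-epoch nuisance: size ratio %.3f, change time %.4f\n",
              x$nuisance[1], x$nuisance[2]))
  print(round(x$bin_proportions, 4))
  invisible(x)
}
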