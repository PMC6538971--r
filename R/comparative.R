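# Comparative layer: life-history two-factor projection, the propagule-size /
# diversity regression, ancestral-diversity rescaling, and divergence-based
# mutation-rate derivation.

.LH_VARS <- c("neonatal_mass_g", "litter_size", "gestation_length_d",
              "interbirth_interval_d", "weaning_age_d", "sexual_maturity_d")

#' Factor loadings for the life-history projection
#'
#' Two weight vectors over the six mass-corrected life-history variables: the
#' "reproductive output" factor loads on neonatal mass, litter size and
#' gestation length; the "reproductive timing" factor on interbirth interval,
#' weaning age and age at sexual maturity. Published Eutherian loadings are
#' not redistributed here: they ship as an editable configuration the user
#' populates from the literature. The bundled default
#' (`inst/extdata/loadings_synthetic.tsv`) is a synthetic placeholder
#' (equal weights) used by the tests.
#'
#' @param output named numeric weights over the three output variables
#' @param timing named numeric weights over the three timing variables
#' @return object of class `factor_loadings`
#' @export
factor_loadings <- function(output, timing) {
  stopifnot(all(is.finite(output)), all(is.finite(timing)),
            all(names(output) %in% .LH_VARS), all(names(timing) %in% .LH_VARS))
  structure(list(output = output, timing = timing), class = "factor_loadings")
}

#' Read factor loadings from a TSV configuration file
#'
#' Expected columns: `variable`, `factor` (`output` or `timing`), `loading`.
#'
#' @param path TSV file
#' @return a [factor_loadings()] object
#' @export
read_factor_loadings <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "factor", "loading") %in% names(tab)))
  pull <- function(f) setNames(tab$loading[tab$factor == f],
                               tab$variable[tab$factor == f])
  factor_loadings(pull("output"), pull("timing"))
}

#' Mass-corrected life-history factor scores
#'
#' All seven quantities (six life-history variables plus adult body mass) are
#' log-transformed; each variable is regressed onto log body mass by ordinary
#' least squares across species, and the residuals are combined into
#' (output, timing) scores by the loading vectors. Scores are invariant to
#' multiplicative rescaling of body mass and to species order.
#'
#' @param records data.frame with columns `species`, `adult_mass_g` and the
#'   six life-history variables (`neonatal_mass_g`, `litter_size`,
#'   `gestation_length_d`, `interbirth_interval_d`, `weaning_age_d`,
#'   `sexual_maturity_d`), all positive
#' @param loadings a [factor_loadings()]
#' @param log_base base for the life-history logs (default natural)
#' @return data.frame with species, `output_score` and `timing_score`
#' @export
mass_residual_factors <- function(records, loadings, log_base = exp(1)) {
  stopifnot(inherits(loadings, "factor_loadings"),
            all(c("species", "adult_mass_g", .LH_VARS) %in% names(records)))
  if (nrow(records) < 3) stop("need at least 3 species", call. = FALSE)
  if (any(records[, c("adult_mass_g", .LH_VARS)] <= 0))
    stop("all life-history quantities must be positive", call. = FALSE)
  lmass <- log(records$adult_mass_g, base = log_base)
  if (var(lmass) == 0) stop("singular regression: constant body mass",
                            call. = FALSE)
  res <- sapply(.LH_VARS, function(v)
    resid(lm(log(records[[v]], base = log_base) ~ lmass)))
  score <- function(w) as.vector(res[, names(w), drop = FALSE] %*% w)
  data.frame(species = records$species,
             output_score = score(loadings$output),
             timing_score = score(loadings$timing))
}

#' Regression of synonymous diversity on propagule size
#'
#' Ordinary least squares of `log10(pi_s)` on `log10(propagule_cm)` across
#' species, fitted both with and without an excluded species set (to check
#' the fit is not driven by a focal species). Predictions are returned on
#' the pi_s scale.
#'
#' @param table data.frame with columns `species`, `pi_s` (proportion in
#'   (0, 1)) and `propagule_cm` (> 0)
#' @param exclude character vector of species to exclude from the second fit
#' @return list with `slope`, `intercept` (full fit), `fit_excluded`
#'   (slope/intercept without the excluded set), and `predict(propagule_cm)`
#' @export
propagule_diversity_regression <- function(table, exclude = character(0)) {
  stopifnot(all(c("species", "pi_s", "propagule_cm") %in% names(table)),
            all(table$pi_s > 0 & table$pi_s < 1), all(table$propagule_cm > 0))
  fit1 <- .loglog_fit(table)
  keep <- !(table$species %in% exclude)
  if (sum(keep) < 3) stop("fewer than 3 species after exclusion",
                          call. = FALSE)
  fit2 <- .loglog_fit(table[keep, , drop = FALSE])
  list(slope = fit1$slope, intercept = fit1$intercept,
       fit_excluded = fit2,
       predict = function(propagule_cm)
         10^(fit1$intercept + fit1$slope * log10(propagule_cm)))
}

.loglog_fit <- function(tab) {
  x <- log10(tab$propagule_cm)
  if (var(x) == 0) stop("degenerate regressor: constant propagule size",
                        call. = FALSE)
  f <- lm(log10(tab$pi_s) ~ x)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]))
}

#' Rescale current diversity to an inferred ancestral population
#'
#' Under the equilibrium proportionality of neutral diversity and effective
#' size, `pi_anc = pi_current * N_ancestral / N_current`.
#'
#' @param pi_current current synonymous diversity (proportion)
#' @param N_current,N_ancestral current and ancestral effective sizes
#' @return the rescaled ancestral diversity
#' @export
rescale_ancestral_diversity <- function(pi_current, N_current, N_ancestral) {
  if (pi_current <= 0 || N_current <= 0 || N_ancestral <= 0)
    stop("all inputs must be > 0", call. = FALSE)
  pi_current * N_ancestral / N_current
}

#' Per-year mutation rate from synonymous divergence
#'
#' `mu = ds / (2 T_split)` for divergence accumulated along both lineages
#' since the split.
#'
#' @param ds substitutions per synonymous site between the two species
#' @param T_split_years split time in years
#' @param signif_digits optional rounding to significant figures for
#'   reporting (e.g. 1)
#' @return mutation rate per site per year
#' @export
mutation_rate_from_divergence <- function(ds, T_split_years,
                                          signif_digits = NULL) {
  if (ds < 0) stop("ds must be >= 0", call. = FALSE)
  if (T_split_years <= 0) stop("T_split_years must be > 0", call. = FALSE)
  mu <- ds / (2 * T_split_years)
  if (!is.null(signif_digits)) mu <- signif(mu, signif_digits)
  mu
}
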