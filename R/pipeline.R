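# Orchestration: configuration, structured logging and the end-to-end
# synthetic pipeline (simulate -> QC -> individual stats -> SFS/diversity ->
# demography -> DFE -> comparative).

#' Default pipeline configuration
#'
#' Nested list of stage toggles and module configurations, validated against
#' the set of known keys before any stage runs (unknown keys are rejected).
#' All randomness derives from the single `seed` through named substreams.
#'
#' @param seed global seed
#' @param ... replacements for any default entry, as nested lists (e.g.
#'   `demography = list(enabled = FALSE)`)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, ...) {
  base <- list(
    seed = seed,
    simulate = list(
      model_kind = "IM", N_anc = 1e4, nu1 = 1, nu2 = 0.3, T_split = 0.5,
      T_change = 0, m12 = 1, m21 = 1, mu = 1e-8, L = 2e6, g = 5,
      n1 = 4, n2 = 4, n_loci = 20, syn_fraction = 0.25, other_fraction = 0.4),
    noise = list(
      mean_depth = 20, depth_dispersion = 0.05, balance_noise = 0.02,
      fp_window_count = 5, fp_per_window = 2, info_fail_fraction = 0.02),
    qc = list(enabled = TRUE, window_bp = 5000, thin_bp = 20000),
    stats = list(enabled = TRUE, roh = TRUE),
    sfs = list(enabled = TRUE, n1_eff = 4, n2_eff = 4),
    demography = list(enabled = TRUE, models = c("SI", "IM"),
                      n_replicates = 3, mc_reps = 2e4, coarse_reps = 5e3,
                      coarse_n = 12, maxit = 60),
    dfe = list(enabled = TRUE, G = 32, gl_nodes = 200),
    comparative = list(enabled = TRUE,
                       life_history_csv = NULL, diversity_csv = NULL,
                       loadings_tsv = NULL),
    out_dir = NULL)
  cfg <- utils::modifyList(base, list(...))
  validate_pipeline_config(cfg, base)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration against the known-key schema
#'
#' @param cfg candidate configuration (nested list)
#' @param reference the default configuration defining the schema
#' @return TRUE invisibly; errors on unknown keys
#' @export
validate_pipeline_config <- function(cfg, reference = pipeline_config()) {
  walk <- function(x, ref, path) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop(sprintf("unknown configuration key%s: %s",
                   if (length(unknown) > 1) "s" else "",
                   paste0(path, unknown, collapse = ", ")), call. = FALSE)
    for (nm in names(x))
      if (is.list(ref[[nm]]) && is.list(x[[nm]]))
        walk(x[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  walk(unclass(cfg), unclass(reference), "")
  invisible(TRUE)
}

# structured logging: one JSON object per event, plus a plain-text mirror
.new_log <- function() new.env(parent = emptyenv())
.log_event <- function(log, stage, event, data = list()) {
  rec <- c(list(stage = stage, event = event), data)
  log$events <- c(log$events, list(rec))
  invisible(rec)
}
.write_log <- function(log, dir) {
  jl <- vapply(log$events, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)), "")
  writeLines(jl, file.path(dir, "pipeline_log.jsonl"))
  writeLines(vapply(log$events, function(e)
    sprintf("[%s] %s: %s", e$stage, e$event,
            paste(names(e)[-(1:2)], unlist(e[-(1:2)]), sep = "=",
                  collapse = " ")), ""),
    file.path(dir, "pipeline_log.txt"))
}

#' Read a pipeline configuration from a JSON file
#'
#' The file holds any subset of the [pipeline_config()] entries; unknown
#' keys are rejected. (JSON rather than YAML: no YAML parser is part of the
#' package's dependency footprint.)
#'
#' @param path JSON file
#' @return a validated `pipeline_config`
#' @export
pipeline_config_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a two-population cohort, applies sequencing noise, runs the QC
#' chain (genotype filters, site filters, FP-window blacklist, thinning),
#' per-individual statistics, folded spectra and diversity, demographic model
#' fits, the DFE, and the comparative layer, and returns a machine-readable
#' summary. Fully reproducible given `config$seed`; two runs with the same
#' seed produce byte-identical summaries.
#'
#' @param config a [pipeline_config()]
#' @return the summary list (invisibly written as JSON plus logs and TSV/VCF
#'   artifacts under `config$out_dir` when set)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  log <- .new_log()
  # on stage failure, persist the partial summary as a checkpoint
  summary <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    on.exit({
      if (!is.null(summary) && !isTRUE(summary$complete))
        jsonlite::write_json(summary,
                             file.path(config$out_dir, "checkpoint.json"),
                             auto_unbox = TRUE, digits = NA)
    }, add = TRUE)
  }
  seed <- config$seed
  summary <- list(seed = seed)
  sim <- config$simulate

  dcfg <- demography_config(sim$model_kind, N_anc = sim$N_anc,
                            nu1 = sim$nu1, nu2 = sim$nu2,
                            T_split = sim$T_split, T_change = sim$T_change,
                            m12 = sim$m12, m21 = sim$m21, mu = sim$mu,
                            L = sim$L, g = sim$g)
  cohort <- simulate_two_pop_coalescent(dcfg, sim$n1, sim$n2,
                                        seed = substream_seed(seed, "sim"),
                                        n_loci = sim$n_loci)
  cohort <- annotate_site_classes(cohort, sim$syn_fraction,
                                  seed = substream_seed(seed, "classes"),
                                  other_fraction = sim$other_fraction)
  .log_event(log, "simulate", "cohort", list(sites = nrow(cohort$genotypes)))
  summary$simulate <- list(n_sites = nrow(cohort$genotypes),
                           n_individuals = ncol(cohort$genotypes),
                           model = sim$model_kind)

  ncfg <- noise_config(mean_depth = config$noise$mean_depth,
                       depth_dispersion = config$noise$depth_dispersion,
                       balance_noise = config$noise$balance_noise,
                       fp_window_count = config$noise$fp_window_count,
                       fp_per_window = config$noise$fp_per_window,
                       info_fail_fraction = config$noise$info_fail_fraction,
                       seed = substream_seed(seed, "noise"))
  noisy <- apply_sequencing_noise(cohort, ncfg, window_bp = config$qc$window_bp)
  cs <- noisy$callset

  if (config$qc$enabled) {
    cs <- filter_genotypes(cs)
    gc_counts <- attr(cs, "filter_counts")
    cs <- filter_sites(cs, stage = "demography")
    sc_counts <- attr(cs, "site_filter_counts")
    fp <- detect_fp_windows(noisy$replicate_a, noisy$replicate_b,
                            window_bp = config$qc$window_bp, apply_to = cs)
    cs <- fp$filtered
    thinned <- thin_variants(cs, window_bp = config$qc$thin_bp)
    summary$qc <- list(
      genotype_mask_counts = as.list(gc_counts),
      site_filter_counts = as.list(sc_counts),
      fp_snps = length(fp$fp_positions),
      fp_windows_blacklisted = nrow(fp$blacklist),
      fp_discarded_fraction = fp$fp_discarded_fraction,
      genome_removed_fraction = fp$genome_removed_fraction,
      snps_after_blacklist = n_sites(cs),
      snps_after_thinning = n_sites(thinned))
    .log_event(log, "qc", "filters", summary$qc[c("fp_snps",
                                                  "snps_after_thinning")])
  } else thinned <- cs

  if (config$stats$enabled) {
    het <- vapply(seq_len(ncol(cs$gt)), function(j)
      heterozygosity_per_kb(sum(cs$gt[, j] == 1L, na.rm = TRUE),
                            cs$L * (1 - summary$qc$genome_removed_fraction)),
      0.0)
    p <- rowSums(cs$gt, na.rm = TRUE) / (2 * rowSums(!is.na(cs$gt)))
    Fs <- vapply(seq_len(ncol(cs$gt)), function(j)
      inbreeding_coefficient(cs$gt[, j], p, 2 * ncol(cs$gt))$F, 0.0)
    nind <- ncol(cs$gt)
    kin <- matrix(NA_real_, nind, nind, dimnames = list(cs$samples, cs$samples))
    for (i in seq_len(nind)) for (j in i:nind)
      kin[i, j] <- kin[j, i] <- king_kinship(cs$gt[, i], cs$gt[, j])$kinship
    pca <- genotype_pca(cs$gt, include_singletons = TRUE, n_components = 2)
    summary$stats <- list(het_per_kb = as.list(setNames(het, cs$samples)),
                          inbreeding_F = as.list(setNames(Fs, cs$samples)),
                          kinship_max_offdiag =
                            max(kin[upper.tri(kin)], na.rm = TRUE),
                          pc1_varexp = pca$varexp[1])
    if (config$stats$roh) {
      roh <- detect_roh(cs$pos, cs$gt[, 1] == 1L, cs$chrom, keep_all = TRUE)
      summary$stats$roh_segments <- nrow(roh)
    }
    .log_event(log, "stats", "done", list(mean_het = mean(het)))
  }

  if (config$sfs$enabled) {
    pop1 <- which(cohort$pop == 1); pop2 <- which(cohort$pop == 2)
    jsfs <- build_joint_folded_sfs(thinned$gt[, pop1, drop = FALSE],
                                   thinned$gt[, pop2, drop = FALSE],
                                   config$sfs$n1_eff, config$sfs$n2_eff)
    cls <- cohort$site_class[match(cs$pos, cohort$positions)]
    syn_idx <- which(!is.na(cls) & cls == "synonymous")
    non_idx <- which(!is.na(cls) & cls == "nonsynonymous")
    n_hap <- 2 * ncol(cs$gt)
    syn <- build_folded_sfs(cs$gt[syn_idx, , drop = FALSE], n_hap,
                            L = sim$L * sim$syn_fraction)
    non <- build_folded_sfs(cs$gt[non_idx, , drop = FALSE], n_hap,
                            L = sim$L * (1 - sim$syn_fraction -
                                           sim$other_fraction))
    div <- diversity_summary(syn, non)
    summary$sfs <- list(joint_total = sum(jsfs$counts),
                        syn_S = div$synonymous$S,
                        nonsyn_S = div$nonsynonymous$S,
                        theta_w_syn = div$synonymous$theta_w,
                        pi_syn = div$synonymous$pi,
                        tajima_d_syn = div$synonymous$tajima_d,
                        pin_pis = div$pin_pis)
    .log_event(log, "sfs", "built", list(S = sum(jsfs$counts)))
  }

  if (config$demography$enabled && config$sfs$enabled) {
    dcfg2 <- config$demography
    fits <- lapply(dcfg2$models, function(kind)
      fit_model(jsfs, kind, n_replicates = dcfg2$n_replicates,
                seed = substream_seed(seed, paste0("fit", kind)),
                mc_reps = dcfg2$mc_reps, coarse_reps = dcfg2$coarse_reps,
                coarse_n = dcfg2$coarse_n, maxit = dcfg2$maxit))
    cmp <- if (length(fits) >= 2) compare_models(fits) else NULL
    best <- fits[[which.max(vapply(fits, `[[`, 0.0, "loglik"))]]
    phys <- to_physical_units(best, mu = sim$mu,
                              L = sim$L / config$qc$thin_bp, g = sim$g)
    summary$demography <- list(
      models = dcfg2$models,
      loglik = as.list(setNames(vapply(fits, `[[`, 0.0, "loglik"),
                                dcfg2$models)),
      AIC = as.list(setNames(vapply(fits, `[[`, 0.0, "AIC"), dcfg2$models)),
      best_model = best$kind,
      best_params = as.list(best$params),
      ranking = if (!is.null(cmp)) cmp$ranking$model else best$kind,
      N_anc_physical = phys$N_anc)
    .log_event(log, "demography", "fitted", list(best = best$kind))
  }

  if (config$dfe$enabled && config$sfs$enabled) {
    dfe <- fit_dfe(syn, non, G = config$dfe$G,
                   gl_nodes = config$dfe$gl_nodes)
    summary$dfe <- list(shape = dfe$shape, mean_Nes = dfe$mean_Nes,
                        bin_proportions = as.list(dfe$bin_proportions))
    .log_event(log, "dfe", "fitted", list(shape = dfe$shape))
  }

  if (config$comparative$enabled) {
    lh_csv <- config$comparative$life_history_csv
    if (is.null(lh_csv))
      lh_csv <- system.file("extdata", "life_history_synthetic.csv",
                            package = "twopopgen")
    dv_csv <- config$comparative$diversity_csv
    if (is.null(dv_csv))
      dv_csv <- system.file("extdata", "diversity_table_synthetic.csv",
                            package = "twopopgen")
    ld_tsv <- config$comparative$loadings_tsv
    if (is.null(ld_tsv))
      ld_tsv <- system.file("extdata", "loadings_synthetic.tsv",
                            package = "twopopgen")
    lh <- read.table(lh_csv, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE)
    dv <- read.table(dv_csv, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE)
    factors <- mass_residual_factors(lh, read_factor_loadings(ld_tsv))
    reg <- propagule_diversity_regression(dv)
    summary$comparative <- list(
      n_species = nrow(factors),
      output_score_range = range(factors$output_score),
      regression_slope = reg$slope,
      regression_intercept = reg$intercept)
    .log_event(log, "comparative", "done", list(slope = reg$slope))
  }

  summary$complete <- TRUE
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_log(log, config$out_dir)
    write_vcf(thinned, file.path(config$out_dir, "thinned.vcf"))
    if (config$qc$enabled && nrow(fp$blacklist))
      write_bed(fp$blacklist, file.path(config$out_dir, "fp_blacklist.bed"))
  }
  invisible(summary)
}

#' Validate a pipeline summary against the bundled schema
#'
#' The schema file lists the sections and keys a complete summary must
#' contain; it is bundled under `inst/extdata/pipeline_summary_schema.json`.
#'
#' @param summary a summary list from [run_pipeline()]
#' @param schema_path optional path to an alternative schema
#' @return TRUE invisibly; errors listing missing sections/keys
#' @export
validate_summary <- function(summary, schema_path = NULL) {
  if (is.null(schema_path))
    schema_path <- system.file("extdata", "pipeline_summary_schema.json",
                               package = "twopopgen")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  missing <- character(0)
  for (section in names(schema)) {
    if (!(section %in% names(summary))) {
      missing <- c(missing, section)
      next
    }
    need <- unlist(schema[[section]])
    absent <- setdiff(unlist(need), names(summary[[section]]))
    if (length(absent))
      missing <- c(missing, paste0(section, "$", absent))
  }
  if (length(missing))
    stop("summary is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
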