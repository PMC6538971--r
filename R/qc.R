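# Genotype- and site-level filters, the replicate-based false-positive SNP
# window filter, and per-window SNP thinning.

#' Genotype-level filter configuration
#'
#' Defaults follow common resequencing practice for ~20x genomes: a genotype
#' needs at least 6 supporting reads; heterozygotes must have a reference
#' allele ratio `ref / (ref + alt)` within `[0.23, 0.76]`; genotypes with
#' GQ below 10 are masked.
#'
#' @param min_depth minimum DP per genotype (default 6)
#' @param balance_min,balance_max allowed ref-allele ratio for heterozygotes
#'   (defaults 0.23 and 0.76)
#' @param min_gq minimum genotype quality (default 10, applied as masking)
#' @return object of class `genotype_filter_config`
#' @export
genotype_filter_config <- function(min_depth = 6, balance_min = 0.23,
                                   balance_max = 0.76, min_gq = 10) {
  stopifnot(min_depth >= 0, balance_min >= 0, balance_max <= 1,
            balance_min < balance_max)
  structure(list(min_depth = min_depth, balance_min = balance_min,
                 balance_max = balance_max, min_gq = min_gq),
            class = "genotype_filter_config")
}

#' Site-level filter configuration
#'
#' Two stages share most rules but use different QUAL thresholds and coverage
#' criteria: the heterozygosity stage requires QUAL >= 20 and site coverage
#' within 20%--200% of the callset mean; the demography stage requires
#' QUAL >= 30 and mean genotype DP within `[10, 50]`. Both apply a minimum
#' RMS mapping quality of 20 and the GATK-style hard filters, read as
#' exclusion boundaries: a site passes iff QD > 2, SOR < 3, MQ > 50,
#' MQRankSum in `[-2.4, 0.6]` and ReadPosRankSum in `[-2.2, 2.4]` (missing
#' annotations pass, as in standard hard filtering).
#'
#' @param biallelic_only drop non-biallelic sites (default TRUE)
#' @param min_qual_het,min_qual_demog stage-specific QUAL thresholds
#' @param min_rms_mq minimum RMS mapping quality
#' @param cov_min_frac,cov_max_frac coverage bounds as fractions of mean
#'   coverage (heterozygosity stage)
#' @param dp_min,dp_max mean-DP bounds (demography stage)
#' @param qd_min,sor_max,mq_min hard-filter thresholds
#' @param mqrs_range,rprs_range allowed MQRankSum and ReadPosRankSum intervals
#' @return object of class `site_filter_config`
#' @export
site_filter_config <- function(biallelic_only = TRUE, min_qual_het = 20,
                               min_qual_demog = 30, min_rms_mq = 20,
                               cov_min_frac = 0.2, cov_max_frac = 2.0,
                               dp_min = 10, dp_max = 50, qd_min = 2,
                               sor_max = 3, mq_min = 50,
                               mqrs_range = c(-2.4, 0.6),
                               rprs_range = c(-2.2, 2.4)) {
  stopifnot(cov_min_frac < cov_max_frac, dp_min < dp_max,
            length(mqrs_range) == 2, length(rprs_range) == 2)
  structure(list(biallelic_only = biallelic_only, min_qual_het = min_qual_het,
                 min_qual_demog = min_qual_demog, min_rms_mq = min_rms_mq,
                 cov_min_frac = cov_min_frac, cov_max_frac = cov_max_frac,
                 dp_min = dp_min, dp_max = dp_max, qd_min = qd_min,
                 sor_max = sor_max, mq_min = mq_min, mqrs_range = mqrs_range,
                 rprs_range = rprs_range),
            class = "site_filter_config")
}

#' Mask genotypes failing depth, allele-balance and quality rules
#'
#' A genotype is retained iff DP >= `min_depth`, GQ >= `min_gq`, and -- if
#' heterozygous -- the reference allele ratio `ref / (ref + alt)` lies within
#' `[balance_min, balance_max]`. Failing genotypes are set missing (NA);
#' per-rule masking counts are attached as attribute `"filter_counts"`.
#'
#' @param callset a `genotype_callset` carrying DP, AD and GQ
#' @param config a [genotype_filter_config()]
#' @return the callset with failing genotypes set to NA
#' @export
filter_genotypes <- function(callset, config = genotype_filter_config()) {
  stopifnot(inherits(callset, "genotype_callset"),
            inherits(config, "genotype_filter_config"))
  for (f in c("dp", "ad_ref", "ad_alt", "gq"))
    if (is.null(callset[[f]]))
      stop(sprintf("callset lacks required FORMAT field '%s'", toupper(f)),
           call. = FALSE)
  gt <- callset$gt
  called <- !is.na(gt)
  fail_dp <- called & callset$dp < config$min_depth
  ratio <- callset$ad_ref / (callset$ad_ref + callset$ad_alt)
  fail_bal <- called & gt == 1L &
    (is.na(ratio) | ratio < config$balance_min | ratio > config$balance_max)
  fail_gq <- called & callset$gq < config$min_gq
  gt[fail_dp | fail_bal | fail_gq] <- NA_integer_
  out <- callset
  out$gt <- gt
  attr(out, "filter_counts") <- c(depth = sum(fail_dp, na.rm = TRUE),
                                  balance = sum(fail_bal, na.rm = TRUE),
                                  gq = sum(fail_gq, na.rm = TRUE))
  out
}

#' Filter sites by QUAL, coverage, mapping quality and hard filters
#'
#' @param callset a `genotype_callset`
#' @param config a [site_filter_config()]
#' @param stage `"heterozygosity"` (QUAL >= 20, coverage within fractions of
#'   the mean) or `"demography"` (QUAL >= 30, mean DP within `[dp_min,
#'   dp_max]`)
#' @return the passing-site callset, with per-rule exclusion counts attached
#'   as attribute `"site_filter_counts"`
#' @export
filter_sites <- function(callset, config = site_filter_config(),
                         stage = c("heterozygosity", "demography")) {
  stopifnot(inherits(callset, "genotype_callset"),
            inherits(config, "site_filter_config"))
  stage <- match.arg(stage)
  ns <- n_sites(callset)
  if (ns == 0) stop("empty callset: mean coverage undefined", call. = FALSE)
  pass_na <- function(x, ok) is.na(x) | ok  # missing annotation passes

  biallelic <- !grepl(",", callset$alt) & nchar(callset$ref) == 1 &
    nchar(callset$alt) == 1
  if (!config$biallelic_only) biallelic <- rep(TRUE, ns)
  qual_thr <- if (stage == "heterozygosity") config$min_qual_het else
    config$min_qual_demog
  qual_ok <- callset$qual >= qual_thr
  if (is.null(callset$dp)) stop("callset lacks required FORMAT field 'DP'",
                                call. = FALSE)
  site_dp <- rowMeans(callset$dp, na.rm = TRUE)
  if (stage == "heterozygosity") {
    mean_cov <- mean(site_dp, na.rm = TRUE)
    cov_ok <- site_dp >= config$cov_min_frac * mean_cov &
      site_dp <= config$cov_max_frac * mean_cov
  } else {
    cov_ok <- site_dp >= config$dp_min & site_dp <= config$dp_max
  }
  info <- callset$info
  mq_rms_ok <- pass_na(info$MQ, info$MQ >= config$min_rms_mq)
  hard_ok <- pass_na(info$QD, info$QD > config$qd_min) &
    pass_na(info$SOR, info$SOR < config$sor_max) &
    pass_na(info$MQ, info$MQ > config$mq_min) &
    pass_na(info$MQRankSum, info$MQRankSum >= config$mqrs_range[1] &
              info$MQRankSum <= config$mqrs_range[2]) &
    pass_na(info$ReadPosRankSum, info$ReadPosRankSum >= config$rprs_range[1] &
              info$ReadPosRankSum <= config$rprs_range[2])
  keep <- biallelic & qual_ok & cov_ok & mq_rms_ok & hard_ok
  out <- subset_sites(callset, which(keep))
  attr(out, "site_filter_counts") <- c(
    non_biallelic = sum(!biallelic), qual = sum(!qual_ok),
    coverage = sum(!cov_ok), rms_mq = sum(!mq_rms_ok),
    hard_filters = sum(!hard_ok), passed = sum(keep))
  out
}

#' Detect false-positive SNP windows from two replicate callsets
#'
#' A position where the two replicate callsets of the same individual carry
#' different homozygous genotypes is a false-positive SNP (FP-SNP). FP-SNP
#' density is computed in fixed windows (default 5 kb, grid anchored at
#' position 1, half-open); any window with more than `max_fp_per_window`
#' FP-SNPs is blacklisted genome-wide.
#'
#' @param callset_a,callset_b replicate callsets of one individual on the
#'   same coordinates
#' @param window_bp window size (default 5000)
#' @param max_fp_per_window blacklist windows with more FP-SNPs than this
#'   (default 1)
#' @param apply_to optional callset to filter by the blacklist (e.g. the full
#'   cohort callset)
#' @return list with `fp_positions`, `blacklist` (data.frame window/start/
#'   end), `fp_discarded_fraction` (FP-SNPs falling in blacklisted windows),
#'   `genome_removed_fraction`, and `filtered` (the blacklist-filtered
#'   `apply_to` callset, if given)
#' @export
detect_fp_windows <- function(callset_a, callset_b, window_bp = 5000,
                              max_fp_per_window = 1, apply_to = NULL) {
  stopifnot(inherits(callset_a, "genotype_callset"),
            inherits(callset_b, "genotype_callset"))
  if (length(callset_a$pos) != length(callset_b$pos) ||
      any(callset_a$pos != callset_b$pos) ||
      any(callset_a$chrom != callset_b$chrom))
    stop("replicate callsets have mismatched site sets", call. = FALSE)
  ga <- callset_a$gt[, 1]; gb <- callset_b$gt[, 1]
  is_fp <- !is.na(ga) & !is.na(gb) & ga != 1L & gb != 1L & ga != gb
  fp_pos <- callset_a$pos[is_fp]
  fp_chrom <- callset_a$chrom[is_fp]
  key <- paste(fp_chrom, window_index(fp_pos, window_bp))
  tab <- table(key)
  bad <- names(tab)[tab > max_fp_per_window]
  bl_chrom <- sub(" .*", "", bad)
  bl_idx <- as.integer(sub(".* ", "", bad))
  o <- order(bl_chrom, bl_idx)
  span <- window_span(bl_idx[o], window_bp)
  blacklist <- data.frame(chrom = bl_chrom[o], window = bl_idx[o],
                          start = span$start, end = span$end)
  fp_discarded <- if (length(fp_pos)) mean(key %in% bad) else 0
  genome_removed <- nrow(blacklist) * window_bp / callset_a$L
  filtered <- NULL
  if (!is.null(apply_to)) {
    in_bad <- paste(apply_to$chrom, window_index(apply_to$pos, window_bp)) %in% bad
    filtered <- subset_sites(apply_to, which(!in_bad))
  }
  list(fp_positions = fp_pos, blacklist = blacklist,
       fp_discarded_fraction = fp_discarded,
       genome_removed_fraction = min(genome_removed, 1),
       window_bp = window_bp, filtered = filtered)
}

#' Thin variants to one SNP per window
#'
#' Keeps the first SNP (by coordinate) in every occupied window of a fixed
#' grid anchored at position 1 (default 20 kb), as a crude guarantee of
#' independence among loci. Deterministic.
#'
#' @param callset a `genotype_callset`
#' @param window_bp window size (default 20000)
#' @return the thinned callset
#' @export
thin_variants <- function(callset, window_bp = 20000) {
  stopifnot(inherits(callset, "genotype_callset"))
  if (n_sites(callset) == 0) return(callset)
  key <- paste(callset$chrom, window_index(callset$pos, window_bp))
  keep <- !duplicated(key)
  subset_sites(callset, which(keep))
}
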