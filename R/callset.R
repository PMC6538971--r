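# Genotype callset container: sites x individuals diploid genotype calls with
# per-genotype DP/AD/GQ and per-site QC annotations, mirroring a VCF record.

#' Construct a genotype callset
#'
#' @param chrom character vector of chromosome names (one per site)
#' @param pos integer vector of 1-based positions
#' @param ref,alt reference and alternate alleles (single bases for biallelic
#'   SNPs; `alt` may contain comma-separated alleles for multi-allelic sites)
#' @param qual per-site Phred QUAL
#' @param info data.frame of per-site annotations (QD, SOR, MQ, MQRankSum,
#'   ReadPosRankSum); missing annotations may be NA
#' @param gt sites x individuals integer matrix of alt-allele dosages
#'   (0/1/2, NA = missing)
#' @param dp,ad_ref,ad_alt,gq sites x individuals matrices of depth, ref/alt
#'   allele depth and genotype quality (may be NULL if unavailable)
#' @param L total genome length in bp (for window fractions)
#' @return an object of class `genotype_callset`
#' @export
genotype_callset <- function(chrom, pos, ref, alt, qual, info, gt,
                             dp = NULL, ad_ref = NULL, ad_alt = NULL,
                             gq = NULL, L = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, nrow(gt) == n, nrow(info) == n)
  if (is.unsorted(order(chrom, pos)) && n > 1) {
    o <- order(chrom, pos)
  } else o <- seq_len(n)
  structure(list(chrom = as.character(chrom)[o], pos = as.integer(pos)[o],
                 ref = as.character(ref)[o], alt = as.character(alt)[o],
                 qual = as.numeric(qual)[o], info = info[o, , drop = FALSE],
                 gt = gt[o, , drop = FALSE],
                 dp = if (!is.null(dp)) dp[o, , drop = FALSE],
                 ad_ref = if (!is.null(ad_ref)) ad_ref[o, , drop = FALSE],
                 ad_alt = if (!is.null(ad_alt)) ad_alt[o, , drop = FALSE],
                 gq = if (!is.null(gq)) gq[o, , drop = FALSE],
                 samples = colnames(gt),
                 L = if (is.null(L)) max(pos) else L),
            class = "genotype_callset")
}

#' @export
print.genotype_callset <- function(x, ...) {
  cat(sprintf("Genotype callset: %d sites x %d individuals (L = %g bp)\n",
              length(x$pos), ncol(x$gt), x$L))
  invisible(x)
}

#' Number of sites in a callset
#' @param cs a `genotype_callset`
#' @return integer site count
#' @export
n_sites <- function(cs) length(cs$pos)

#' Subset a callset to a set of sites
#' @param cs a `genotype_callset`
#' @param keep logical or integer index over sites
#' @return the subset callset
#' @export
subset_sites <- function(cs, keep) {
  stopifnot(inherits(cs, "genotype_callset"))
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  out <- cs
  out$chrom <- cs$chrom[keep]; out$pos <- cs$pos[keep]
  out$ref <- cs$ref[keep]; out$alt <- cs$alt[keep]
  out$qual <- cs$qual[keep]; out$info <- cs$info[keep, , drop = FALSE]
  out$gt <- cs$gt[keep, , drop = FALSE]
  out$dp <- sub(cs$dp); out$ad_ref <- sub(cs$ad_ref)
  out$ad_alt <- sub(cs$ad_alt); out$gq <- sub(cs$gq)
  for (a in c("filter_counts", "site_filter_counts")) attr(out, a) <- attr(cs, a)
  out
}
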