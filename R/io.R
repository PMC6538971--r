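# VCF / BED / TSV readers and writers and coordinate conversions.

#' Write a genotype callset as VCF v4.2
#'
#' Emits FORMAT fields GT, DP, AD, GQ and INFO fields QD, SOR, MQ, MQRankSum,
#' ReadPosRankSum.
#'
#' @param cs a `genotype_callset`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(cs, path) {
  stopifnot(inherits(cs, "genotype_callset"))
  con <- file(path, "w"); on.exit(close(con))
  contigs <- unique(cs$chrom)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=twopopgen",
    sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(cs$L)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cs$samples), collapse = "\t")), con)
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  info <- sprintf("QD=%s;SOR=%s;MQ=%s;MQRankSum=%s;ReadPosRankSum=%s",
                  fmt_num(cs$info$QD), fmt_num(cs$info$SOR),
                  fmt_num(cs$info$MQ), fmt_num(cs$info$MQRankSum),
                  fmt_num(cs$info$ReadPosRankSum))
  gt_code <- c("0/0", "0/1", "1/1")
  ns <- n_sites(cs)
  body <- character(ns)
  sample_cols <- matrix("", ns, length(cs$samples))
  for (j in seq_along(cs$samples)) {
    g <- cs$gt[, j]
    gs <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    sample_cols[, j] <- paste(gs,
                              fmt_num(cs$dp[, j]),
                              paste0(fmt_num(cs$ad_ref[, j]), ",",
                                     fmt_num(cs$ad_alt[, j])),
                              fmt_num(cs$gq[, j]), sep = ":")
  }
  lines <- paste(cs$chrom, cs$pos, ".", cs$ref, cs$alt,
                 fmt_num(cs$qual), "PASS", info, "GT:DP:AD:GQ",
                 apply(sample_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# Light structural validation so malformed/truncated files fail with a line
# number before the full parser runs.
.validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop(sprintf("%s: malformed VCF header (line 1)", path), call. = FALSE)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr))
    stop(sprintf("%s: missing #CHROM header line", path), call. = FALSE)
  nfield <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- seq(hdr[1] + 1, length.out = length(lines) - hdr[1])
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != nfield)
      stop(sprintf("%s: parse error at line %d: %d fields, expected %d",
                   path, i, nf, nfield), call. = FALSE)
  }
  invisible(length(body))
}

#' Read a VCF v4.2 into a genotype callset
#'
#' Coordinates stay 1-based as in the file. In strict mode (default) the
#' FORMAT fields DP, AD and GQ must be present; in lenient mode missing
#' per-genotype fields are left NULL.
#'
#' @param path VCF file (uncompressed)
#' @param strict require DP/AD/GQ FORMAT fields
#' @param L genome length (defaults to the first contig header length, else
#'   the maximum position)
#' @return a `genotype_callset`
#' @export
read_vcf <- function(path, strict = TRUE, L = NULL) {
  .validate_vcf_lines(path)
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  for (f in c("DP", "AD", "GQ"))
    if (strict && !(f %in% names(g)))
      stop(sprintf("missing required FORMAT field '%s'", f), call. = FALSE)
  gt_str <- g$GT
  gt <- matrix(NA_integer_, nrow(gt_str), ncol(gt_str),
               dimnames = dimnames(gt_str))
  code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "0|1" = 1L, "1/0" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  hit <- gt_str %in% names(code)
  gt[hit] <- code[gt_str[hit]]
  rr <- SummarizedExperiment::rowRanges(vcf)
  df <- as.data.frame(rr)
  alt_list <- VariantAnnotation::alt(vcf)
  alt <- S4Vectors::unstrsplit(methods::as(alt_list, "CharacterList"), ",")
  ad <- g$AD
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad)) {
    if (is.array(ad) && length(dim(ad)) == 3) {
      ad_ref <- ad[, , 1, drop = TRUE]
      ad_alt <- ad[, , 2, drop = TRUE]
      if (!is.matrix(ad_ref)) {
        ad_ref <- matrix(ad_ref, nrow(gt)); ad_alt <- matrix(ad_alt, nrow(gt))
      }
    } else {  # matrix of integer vectors
      ad_ref <- apply(ad, c(1, 2), function(x) x[[1]][1])
      ad_alt <- apply(ad, c(1, 2), function(x) x[[1]][2])
    }
  }
  info_df <- as.data.frame(VariantAnnotation::info(vcf))
  keep_info <- intersect(c("QD", "SOR", "MQ", "MQRankSum", "ReadPosRankSum"),
                         names(info_df))
  info <- info_df[, keep_info, drop = FALSE]
  for (f in setdiff(c("QD", "SOR", "MQ", "MQRankSum", "ReadPosRankSum"),
                    keep_info))
    info[[f]] <- NA_real_
  if (is.null(L)) {
    sl <- GenomeInfoDb::seqlengths(vcf)
    L <- if (length(sl) && !all(is.na(sl))) sum(as.numeric(sl), na.rm = TRUE)
      else max(df$start)
  }
  genotype_callset(as.character(df$seqnames), df$start,
                   as.character(VariantAnnotation::ref(vcf)), alt,
                   as.numeric(df$QUAL), info, gt,
                   dp = g$DP, ad_ref = ad_ref, ad_alt = ad_alt, gq = g$GQ,
                   L = L)
}

#' Write intervals as BED (0-based half-open)
#'
#' Converts 1-based inclusive `[start, end]` intervals to BED's 0-based
#' half-open convention explicitly.
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#' @param path BED file
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive)
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1]]), start = tab[[2]] + 1L,
             end = tab[[3]])
}
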