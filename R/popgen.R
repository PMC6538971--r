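# Per-individual and pairwise statistics: heterozygosity per kb, runs of
# homozygosity (two-state HMM), KING-robust kinship, inbreeding coefficient,
# and genotype PCA.

#' Heterozygosity per kilobase
#'
#' @param het_count number of heterozygous sites
#' @param callable_bp callable genome length in bp (excluding blacklisted
#'   windows and failed sites)
#' @return heterozygous sites per kb
#' @export
heterozygosity_per_kb <- function(het_count, callable_bp) {
  if (callable_bp <= 0) stop("callable_bp must be > 0", call. = FALSE)
  1000 * het_count / callable_bp
}

#' Runs of homozygosity via a two-state HMM
#'
#' States are RoH (heterozygote emission probability `p_het_roh`, a
#' genotyping-error allowance) and non-RoH (`p_het_bg`, defaulting to the
#' individual's genome-wide fraction of heterozygous calls). Transitions
#' between sites at distance d bp occur with probability
#' `(1 - exp(-2 * transition_rate * d)) / 2`. The most probable state path
#' is decoded by the Viterbi algorithm per chromosome, and the mean posterior
#' probability of the RoH state (forward-backward) is reported per segment.
#' Segments shorter than `min_length_bp` (default 2 Mb, indicative of recent
#' inbreeding when exceeded) are dropped unless `keep_all`.
#'
#' @param pos 1-based positions of informative (called, polymorphic) sites
#' @param is_het logical vector: is the individual heterozygous at each site
#' @param chrom chromosome of each site (default all `"1"`)
#' @param p_het_roh heterozygote emission probability inside RoH
#'   (default 1e-3)
#' @param p_het_bg heterozygote emission probability outside RoH (default:
#'   observed fraction of heterozygous sites)
#' @param transition_rate per-bp state switch rate (default 1e-7)
#' @param min_length_bp minimum reported segment length (default 2e6)
#' @param keep_all report all segments regardless of length
#' @param autosomes optional allow-list of chromosome names; sites on other
#'   chromosomes (e.g. sex chromosomes) are excluded
#' @return data.frame with chrom, start, end, length_bp, n_sites and mean
#'   RoH-state posterior per segment
#' @export
detect_roh <- function(pos, is_het, chrom = rep("1", length(pos)),
                       p_het_roh = 1e-3, p_het_bg = NULL,
                       transition_rate = 1e-7, min_length_bp = 2e6,
                       keep_all = FALSE, autosomes = NULL) {
  stopifnot(length(pos) == length(is_het), length(chrom) == length(pos))
  ok <- !is.na(is_het) & !is.na(pos)  # missing genotypes are uninformative
  pos <- pos[ok]; is_het <- is_het[ok]; chrom <- chrom[ok]
  if (!is.null(autosomes)) {
    keep <- chrom %in% autosomes
    pos <- pos[keep]; is_het <- is_het[keep]; chrom <- chrom[keep]
  }
  if (is.null(p_het_bg)) p_het_bg <- max(mean(is_het), 1e-6)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      n_sites = integer(0), posterior = numeric(0))
  out <- empty
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2) {
      warning(sprintf("chromosome %s: fewer than 2 informative sites", ch))
      next
    }
    o <- idx[order(pos[idx])]
    segs <- .roh_decode(pos[o], is_het[o], p_het_roh, p_het_bg,
                        transition_rate)
    segs$chrom <- rep(ch, nrow(segs))
    out <- rbind(out, segs[, c("chrom", "start", "end", "length_bp",
                               "n_sites", "posterior")])
  }
  if (!keep_all) out <- out[out$length_bp > min_length_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Viterbi + forward-backward over one chromosome. State 1 = non-RoH,
# state 2 = RoH.
.roh_decode <- function(pos, is_het, p_roh, p_bg, rate) {
  n <- length(pos)
  le <- cbind(ifelse(is_het, log(p_bg), log1p(-p_bg)),
              ifelse(is_het, log(p_roh), log1p(-p_roh)))
  d <- diff(pos)
  p_switch <- (1 - exp(-2 * rate * d)) / 2
  lsw <- log(pmax(p_switch, 1e-300)); lst <- log1p(-p_switch)
  # Viterbi
  v <- matrix(0, n, 2); bp <- matrix(1L, n, 2)
  v[1, ] <- log(0.5) + le[1, ]
  for (i in 2:n) {
    for (s in 1:2) {
      cand <- v[i - 1, ] + c(ifelse(s == 1, lst[i - 1], lsw[i - 1]),
                             ifelse(s == 2, lst[i - 1], lsw[i - 1]))
      bp[i, s] <- which.max(cand)
      v[i, s] <- cand[bp[i, s]] + le[i, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (i in (n - 1):1) path[i] <- bp[i + 1, path[i + 1]]
  post <- .roh_posterior(le, lsw, lst)
  r <- rle(path == 2L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  in_roh <- which(r$values)
  if (!length(in_roh))
    return(data.frame(start = integer(0), end = integer(0),
                      length_bp = integer(0), n_sites = integer(0),
                      posterior = numeric(0)))
  data.frame(
    start = pos[starts[in_roh]], end = pos[ends[in_roh]],
    length_bp = pos[ends[in_roh]] - pos[starts[in_roh]] + 1L,
    n_sites = r$lengths[in_roh],
    posterior = vapply(in_roh, function(k)
      mean(post[starts[k]:ends[k]]), 0.0))
}

# forward-backward posterior of the RoH state, in log space
.roh_posterior <- function(le, lsw, lst, chunk = NULL) {
  n <- nrow(le)
  lse <- function(a, b) { m <- pmax(a, b); m + log(exp(a - m) + exp(b - m)) }
  fw <- matrix(0, n, 2)
  fw[1, ] <- log(0.5) + le[1, ]
  for (i in 2:n) {
    fw[i, 1] <- lse(fw[i - 1, 1] + lst[i - 1], fw[i - 1, 2] + lsw[i - 1]) + le[i, 1]
    fw[i, 2] <- lse(fw[i - 1, 1] + lsw[i - 1], fw[i - 1, 2] + lst[i - 1]) + le[i, 2]
  }
  bw <- matrix(0, n, 2)
  for (i in (n - 1):1) {
    bw[i, 1] <- lse(bw[i + 1, 1] + lst[i] + le[i + 1, 1],
                    bw[i + 1, 2] + lsw[i] + le[i + 1, 2])
    bw[i, 2] <- lse(bw[i + 1, 1] + lsw[i] + le[i + 1, 1],
                    bw[i + 1, 2] + lst[i] + le[i + 1, 2])
  }
  lp <- fw + bw
  1 / (1 + exp(lp[, 1] - lp[, 2]))
}

#' KING-robust kinship from joint genotype counts
#'
#' The allele-frequency-free robust estimator
#' `phi = (N_HetHet - 2 * N_OppHom) / (N_Het_i + N_Het_j)`, where counts are
#' over jointly non-missing biallelic sites, `N_OppHom` counts opposite
#' homozygotes, and the denominator sums the two individuals' heterozygote
#' counts (the symmetric variant, so `phi(i, j) = phi(j, i)`). Self-kinship
#' is 0.5, parent-offspring about 0.25, unrelated about 0 (negative between
#' diverged populations).
#'
#' @param genotypes_i,genotypes_j integer vectors of 0/1/2 dosages (NA =
#'   missing) on the same sites
#' @return list with `kinship`, `n_shared` (jointly called sites) and the
#'   underlying counts
#' @export
king_kinship <- function(genotypes_i, genotypes_j) {
  stopifnot(length(genotypes_i) == length(genotypes_j))
  ok <- !is.na(genotypes_i) & !is.na(genotypes_j)
  gi <- genotypes_i[ok]; gj <- genotypes_j[ok]
  if (!length(gi)) stop("no jointly called sites", call. = FALSE)
  het_i <- sum(gi == 1L); het_j <- sum(gj == 1L)
  if (het_i + het_j == 0)
    stop("kinship undefined: no heterozygotes in either individual",
         call. = FALSE)
  n_hethet <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  list(kinship = (n_hethet - 2 * n_opp) / (het_i + het_j),
       n_shared = length(gi),
       counts = c(het_het = n_hethet, opp_hom = n_opp,
                  het_i = het_i, het_j = het_j))
}

#' Method-of-moments inbreeding coefficient
#'
#' `F = (O - E) / (N - E)` where O is the observed homozygous call count, N
#' the number of biallelic sites used, and E the expected homozygous count
#' under Hardy-Weinberg with the small-sample correction,
#' `E = sum_sites (1 - 2 p (1 - p) * n / (n - 1))` with p the pooled-sample
#' allele frequency and n the number of called chromosomes at the site.
#'
#' @param genotypes integer 0/1/2 vector for one individual
#' @param allele_frequencies pooled-sample alt-allele frequency per site
#' @param n_chrom number of chromosomes the frequencies were estimated from
#'   (scalar or per-site vector)
#' @return list with `F`, `observed_hom`, `expected_hom` and `n_sites`
#' @export
inbreeding_coefficient <- function(genotypes, allele_frequencies, n_chrom) {
  ok <- !is.na(genotypes) & !is.na(allele_frequencies)
  g <- genotypes[ok]; p <- allele_frequencies[ok]
  n <- rep(n_chrom, length.out = length(allele_frequencies))[ok]
  N <- length(g)
  if (!N) stop("no usable sites", call. = FALSE)
  E <- sum(1 - 2 * p * (1 - p) * n / (n - 1))
  O <- sum(g != 1L)
  if (abs(N - E) < .Machine$double.eps * N)
    stop("degenerate: N equals expected homozygous count", call. = FALSE)
  list(F = (O - E) / (N - E), observed_hom = O, expected_hom = E,
       n_sites = N)
}

#' Genotype PCA by singular value decomposition
#'
#' Centers each variant (row) of the sites x individuals dosage matrix,
#' imputes missing dosages at the variant mean, and decomposes by SVD.
#' Singletons are included by default.
#'
#' @param gt sites x individuals 0/1/2 matrix
#' @param include_singletons keep variants whose minor allele is observed
#'   exactly once (default TRUE)
#' @param n_components number of leading components to return
#' @return list with `scores` (individuals x components), `varexp`
#'   (proportion of variance per component) and `eigenvalues`
#' @export
genotype_pca <- function(gt, include_singletons = TRUE, n_components = NULL) {
  stopifnot(is.matrix(gt))
  if (ncol(gt) < 2 || nrow(gt) < 1)
    stop("need >= 2 individuals and >= 1 variant", call. = FALSE)
  if (!include_singletons) {
    ac <- rowSums(gt, na.rm = TRUE)
    nc <- 2 * rowSums(!is.na(gt))
    mac <- pmin(ac, nc - ac)
    gt <- gt[mac != 1L, , drop = FALSE]
  }
  mu <- rowMeans(gt, na.rm = TRUE)
  x <- gt - mu
  x[is.na(x)] <- 0
  if (all(abs(x) < .Machine$double.eps)) {
    warning("constant genotype matrix: all component scores are zero")
    k <- min(ncol(gt) - 1, if (is.null(n_components)) ncol(gt) - 1 else n_components)
    return(list(scores = matrix(0, ncol(gt), k,
                                dimnames = list(colnames(gt), NULL)),
                varexp = rep(0, k), eigenvalues = rep(0, k)))
  }
  s <- svd(t(x))
  k <- length(s$d)
  if (!is.null(n_components)) k <- min(k, n_components)
  ev <- s$d^2 / nrow(gt)
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  rownames(scores) <- colnames(gt)
  list(scores = scores, varexp = ev[seq_len(k)] / sum(ev),
       eigenvalues = ev[seq_len(k)])
}
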