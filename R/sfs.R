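# Folded 1D and joint 2D site frequency spectra, hypergeometric projection,
# and diversity statistics (Watterson's theta, pi, Tajima's D, piN/piS).

#' Construct a folded site frequency spectrum
#'
#' @param counts numeric vector of length `floor(n / 2)`; entry i is the
#'   number of sites with minor-allele count i
#' @param n haploid sample size
#' @param L number of surveyed sites (monomorphic included), for per-site
#'   rates
#' @return object of class `folded_sfs`
#' @export
folded_sfs <- function(counts, n, L = NA_real_) {
  stopifnot(n >= 2, length(counts) == floor(n / 2), all(counts >= 0))
  structure(list(counts = as.numeric(counts), n = as.integer(n), L = L),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("Folded SFS, n = %d haploids, S = %g%s\n", x$n, sum(x$counts),
              if (is.na(x$L)) "" else sprintf(", L = %g sites", x$L)))
  print(setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

#' Build a folded SFS from a genotype matrix
#'
#' Each site's alternate-allele count is tallied among called chromosomes;
#' sites where the number of called chromosomes exceeds `n` are hypergeometric
#' down-projected to `n`, sites with fewer called chromosomes than `n` are
#' dropped (count reported as attribute `"dropped"`). Minor-allele convention:
#' a derived count of i and of n - i increment the same bin; monomorphic
#' outcomes contribute nothing.
#'
#' @param gt sites x individuals 0/1/2 dosage matrix (NA = missing)
#' @param n target haploid sample size (default: 2 x individuals)
#' @param site_class optional per-site class labels
#' @param keep_class optional class to restrict to (e.g. `"synonymous"`)
#' @param L surveyed length for per-site rates
#' @return a `folded_sfs`
#' @export
build_folded_sfs <- function(gt, n = 2 * ncol(gt), site_class = NULL,
                             keep_class = NULL, L = NA_real_) {
  stopifnot(is.matrix(gt))
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.null(keep_class)) {
    stopifnot(length(site_class) == nrow(gt))
    gt <- gt[site_class == keep_class, , drop = FALSE]
  }
  ac <- rowSums(gt, na.rm = TRUE)
  nc <- 2 * rowSums(!is.na(gt))
  dropped <- sum(nc < n)
  counts <- numeric(floor(n / 2))
  use <- which(nc >= n)
  for (s in use) {
    if (ac[s] == 0 || ac[s] == nc[s]) next
    if (nc[s] == n) {
      b <- min(ac[s], n - ac[s])
      counts[b] <- counts[b] + 1
    } else {
      k <- 0:n
      pr <- dhyper(k, ac[s], nc[s] - ac[s], n)
      b <- pmin(k, n - k)
      for (j in which(b > 0)) counts[b[j]] <- counts[b[j]] + pr[j]
    }
  }
  out <- folded_sfs(counts, n, L)
  attr(out, "dropped") <- dropped
  out
}

#' Hypergeometric projection of a folded SFS to a smaller sample size
#'
#' The expectation over drawing `n_target` of the `n` chromosomes without
#' replacement: a site with minor count i contributes `dhyper(k; i, n - i,
#' n_target)` to projected minor class `min(k, n_target - k)`. Linear in the
#' input; the identity when `n_target == n`.
#'
#' @param sfs a `folded_sfs`
#' @param n_target haploid size to project to (`2 <= n_target <= n`)
#' @return a real-valued `folded_sfs` at `n_target`
#' @export
project_sfs <- function(sfs, n_target) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (n_target < 2) stop("n_target must be >= 2", call. = FALSE)
  if (n_target > sfs$n) stop("n_target must be <= n", call. = FALSE)
  if (n_target == sfs$n) return(sfs)
  counts <- numeric(floor(n_target / 2))
  for (i in seq_along(sfs$counts)) {
    if (sfs$counts[i] == 0) next
    k <- 0:n_target
    pr <- dhyper(k, i, sfs$n - i, n_target)
    b <- pmin(k, n_target - k)
    for (j in which(b > 0))
      counts[b[j]] <- counts[b[j]] + sfs$counts[i] * pr[j]
  }
  folded_sfs(counts, n_target, sfs$L)
}

#' Construct a folded joint SFS container
#'
#' @param counts (n1_eff + 1) x (n2_eff + 1) matrix indexed by allele counts
#'   0..n1_eff (rows) and 0..n2_eff (columns)
#' @param mask logical matrix of folded-away / invalid cells (these carry no
#'   counts); the (0, 0) cell is always masked
#' @param ambiguous logical matrix flagging cells whose total count is
#'   exactly half the pooled sample (mass split with the complementary cell)
#' @param L surveyed length
#' @return object of class `folded_joint_sfs`
#' @export
folded_joint_sfs <- function(counts, mask = NULL, ambiguous = NULL,
                             L = NA_real_) {
  n1 <- nrow(counts) - 1L; n2 <- ncol(counts) - 1L
  if (is.null(mask)) mask <- .jsfs_mask(n1, n2)
  if (is.null(ambiguous)) ambiguous <- .jsfs_ambiguous(n1, n2)
  stopifnot(all(dim(mask) == dim(counts)), all(counts[mask] == 0))
  structure(list(counts = counts, mask = mask, ambiguous = ambiguous,
                 n1_eff = n1, n2_eff = n2, L = L),
            class = "folded_joint_sfs")
}

#' @export
print.folded_joint_sfs <- function(x, ...) {
  cat(sprintf("Folded joint SFS, %d x %d haploids, S = %g\n",
              x$n1_eff, x$n2_eff, sum(x$counts)))
  m <- round(x$counts, 2)
  m[x$mask] <- NA
  dimnames(m) <- list(pop1 = 0:x$n1_eff, pop2 = 0:x$n2_eff)
  print(m, na.print = ".")
  invisible(x)
}

.jsfs_mask <- function(n1, n2) {
  tot <- outer(0:n1, 0:n2, `+`)
  mask <- tot * 2 > (n1 + n2)
  mask[1, 1] <- TRUE  # monomorphic
  mask
}

.jsfs_ambiguous <- function(n1, n2) {
  outer(0:n1, 0:n2, `+`) * 2 == (n1 + n2)
}

# Fold an unfolded (alt-allele count) joint matrix on the combined minor
# allele. Cells with total count exactly half the pooled sample are split
# evenly with the complementary cell and flagged as ambiguous.
fold_joint_matrix <- function(m, L = NA_real_) {
  n1 <- nrow(m) - 1L; n2 <- ncol(m) - 1L
  rev_m <- m[(n1 + 1):1, (n2 + 1):1, drop = FALSE]
  f <- m + rev_m
  amb <- .jsfs_ambiguous(n1, n2)
  f[amb] <- f[amb] / 2
  mask <- .jsfs_mask(n1, n2)
  f[mask] <- 0
  folded_joint_sfs(f, mask, amb, L)
}

#' Build the folded joint SFS of two population samples
#'
#' Each population is hypergeometric down-projected to `n1_eff` / `n2_eff`
#' chromosomes (default 4 and 4, so the spectrum axes span allele counts 0 to
#' 4), the per-site projected distributions are tabulated into an unfolded
#' matrix, and the matrix is folded on the combined minor allele. Sites with
#' fewer called chromosomes than the projection size in either population are
#' dropped (attribute `"dropped"`).
#'
#' @param gt_pop1,gt_pop2 sites x individuals dosage matrices on the same
#'   sites
#' @param n1_eff,n2_eff haploid projection sizes (defaults 4)
#' @param L surveyed length
#' @return a `folded_joint_sfs`
#' @export
build_joint_folded_sfs <- function(gt_pop1, gt_pop2, n1_eff = 4, n2_eff = 4,
                                   L = NA_real_) {
  stopifnot(nrow(gt_pop1) == nrow(gt_pop2))
  ac1 <- rowSums(gt_pop1, na.rm = TRUE); nc1 <- 2 * rowSums(!is.na(gt_pop1))
  ac2 <- rowSums(gt_pop2, na.rm = TRUE); nc2 <- 2 * rowSums(!is.na(gt_pop2))
  usable <- nc1 >= n1_eff & nc2 >= n2_eff
  poly <- (ac1 + ac2) > 0 & (ac1 + ac2) < (nc1 + nc2)
  use <- which(usable & poly)
  m <- matrix(0, n1_eff + 1, n2_eff + 1)
  if (!length(use)) {
    warning("no polymorphic usable sites: empty joint spectrum")
  }
  for (s in use) {
    p1 <- dhyper(0:n1_eff, ac1[s], nc1[s] - ac1[s], n1_eff)
    p2 <- dhyper(0:n2_eff, ac2[s], nc2[s] - ac2[s], n2_eff)
    m <- m + outer(p1, p2)
  }
  out <- fold_joint_matrix(m, L)
  attr(out, "dropped") <- sum(!usable)
  out
}

# Tajima's D normalization constants for haploid sample size n
.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# pi (total pairwise diversity, not per site) from a folded SFS
.pi_from_folded <- function(sfs) {
  n <- sfs$n
  i <- seq_along(sfs$counts)
  sum(sfs$counts * 2 * i * (n - i) / (n * (n - 1)))
}

#' Diversity statistics from a folded SFS
#'
#' @param sfs a `folded_sfs` with `L` set
#' @return list with `S`, `theta_w` (per site), `pi` (per site) and
#'   `tajima_d` (NA when S = 0, with a warning)
#' @export
sfs_diversity <- function(sfs) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (is.na(sfs$L) || sfs$L <= 0) stop("sfs$L must be set and > 0",
                                       call. = FALSE)
  S <- sum(sfs$counts)
  k <- .tajima_constants(sfs$n)
  pi_tot <- .pi_from_folded(sfs)
  if (S == 0) {
    warning("no segregating sites: Tajima's D undefined")
    D <- NA_real_
  } else {
    D <- (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  list(S = S, theta_w = S / (k$a1 * sfs$L), pi = pi_tot / sfs$L,
       tajima_d = D)
}

#' Diversity summary for synonymous and nonsynonymous spectra
#'
#' Computes Watterson's theta, pi and Tajima's D per class from the summed
#' folded spectra, and the ratio of per-site nonsynonymous to synonymous
#' diversity `piN / piS` with `L_syn` and `L_nonsyn` as the per-class
#' surveyed lengths.
#'
#' @param syn_sfs,nonsyn_sfs `folded_sfs` objects sharing `n`
#' @param L_syn,L_nonsyn surveyed synonymous / nonsynonymous lengths (override
#'   the spectra's own `L` if given)
#' @return list with per-class statistics and `pin_pis`
#' @export
diversity_summary <- function(syn_sfs, nonsyn_sfs, L_syn = syn_sfs$L,
                              L_nonsyn = nonsyn_sfs$L) {
  stopifnot(inherits(syn_sfs, "folded_sfs"),
            inherits(nonsyn_sfs, "folded_sfs"))
  if (syn_sfs$n != nonsyn_sfs$n)
    stop("spectra must share the haploid sample size n", call. = FALSE)
  if (is.na(L_syn) || is.na(L_nonsyn) || L_syn <= 0 || L_nonsyn <= 0)
    stop("L_syn and L_nonsyn must be positive", call. = FALSE)
  syn_sfs$L <- L_syn; nonsyn_sfs$L <- L_nonsyn
  s <- sfs_diversity(syn_sfs)
  ns <- sfs_diversity(nonsyn_sfs)
  list(synonymous = s, nonsynonymous = ns,
       pin_pis = if (s$pi > 0) ns$pi / s$pi else NA_real_)
}

#' Write / read a folded (joint) SFS as TSV with a JSON header line
#'
#' The first line is a `#`-prefixed JSON object holding n, L and fold status;
#' the remainder is a plain TSV matrix (2D) or vector (1D), compatible with
#' common SFS tools' plain-text layouts.
#'
#' @param sfs a `folded_sfs` or `folded_joint_sfs`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sfs <- function(sfs, path) {
  if (inherits(sfs, "folded_sfs")) {
    hdr <- jsonlite::toJSON(list(type = "folded_sfs", n = sfs$n, L = sfs$L),
                            auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(c(paste0("#", hdr),
                 paste(sfs$counts, collapse = "\t")), path)
  } else if (inherits(sfs, "folded_joint_sfs")) {
    hdr <- jsonlite::toJSON(list(type = "folded_joint_sfs",
                                 n1_eff = sfs$n1_eff, n2_eff = sfs$n2_eff,
                                 L = sfs$L,
                                 mask = which(sfs$mask)),
                            auto_unbox = TRUE, digits = NA, na = "null")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("#", hdr), con)
    write.table(sfs$counts, con, sep = "\t", row.names = FALSE,
                col.names = FALSE)
  } else stop("not an SFS object", call. = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  if (identical(hdr$type, "folded_sfs")) {
    counts <- as.numeric(strsplit(lines[2], "\t")[[1]])
    folded_sfs(counts, hdr$n, if (is.null(hdr$L)) NA_real_ else hdr$L)
  } else if (identical(hdr$type, "folded_joint_sfs")) {
    m <- as.matrix(read.table(text = lines[-1], sep = "\t"))
    dimnames(m) <- NULL
    mask <- matrix(FALSE, hdr$n1_eff + 1, hdr$n2_eff + 1)
    mask[hdr$mask] <- TRUE
    folded_joint_sfs(m, mask, L = if (is.null(hdr$L)) NA_real_ else hdr$L)
  } else stop("unrecognized SFS file header", call. = FALSE)
}
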