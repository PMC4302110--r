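#' Exploratory population structure
#'
#' Genotype PCA on dosage-coded SNPs (missing calls mean-imputed per SNP,
#' columns centered, covariance eigendecomposition), allele-sharing
#' (identity-by-state) distances, and Saitou-Nei neighbor-joining trees.
#'
#' @name structure_explore
NULL

#' Genotype PCA
#'
#' Biallelic SNPs are coded 0/1/2 by ALT-allele dosage; multiallelic sites
#' are dropped with a note.  Missing genotypes are imputed with the SNP mean,
#' columns are centered (optionally standardized by `sqrt(p(1-p))`), and the
#' sample covariance is eigendecomposed.
#'
#' @param gm a `genotype_matrix`.
#' @param sites optional site index defining the SNP subset.
#' @param samples optional sample subset.
#' @param standardize divide each SNP column by `sqrt(p(1-p))` (default
#'   FALSE: plain covariance PCA).
#' @return list of class `pca_result`: `coordinates` (samples x components),
#'   `variance_fraction`.
#' @export
genotype_pca <- function(gm, sites = NULL, samples = NULL,
                         standardize = FALSE) {
  sub <- subset_matrix(gm, sites, samples)
  if (length(sub$samples) < 2L) stop("need at least two samples")
  multi <- grepl(",", sub$sites$alt, fixed = TRUE)
  if (any(multi)) {
    tasrdiv_msg("dropping ", sum(multi), " multiallelic site(s) from PCA")
    sub <- subset_matrix(sub, which(!multi))
  }
  if (n_sites(sub) == 0L) stop("no biallelic SNPs in subset")
  dose <- t((sub$a1 == 1L) + (sub$a2 == 1L))     # samples x sites
  mu <- colMeans(dose, na.rm = TRUE)
  for (j in seq_len(ncol(dose))) dose[is.na(dose[, j]), j] <- mu[j]
  x <- sweep(dose, 2, mu)
  if (standardize) {
    p <- mu / 2
    sc <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    x <- sweep(x, 2, sc, "/")
  }
  if (all(abs(x) < 1e-12)) stop("zero-variance genotype matrix")
  pc <- stats::prcomp(x, center = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = pc$x, variance_fraction = vf),
            class = "pca_result")
}

# per-allele genotype count matrices keeping missingness explicit
ibs_counts <- function(gm) {
  a1 <- gm$a1; a2 <- gm$a2
  vals <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
  counts <- lapply(vals, function(v)
    (!is.na(a1) & a1 == v) + (!is.na(a2) & a2 == v))
  list(counts = counts, called = !geno_missing(gm))
}

#' Allele-sharing (IBS) distance matrix
#'
#' `d(i,j) = 1 - mean(shared allele proportion)` over mutually called sites;
#' the shared proportion per site is in {0, 0.5, 1} for diploids.
#'
#' @param gm a `genotype_matrix`.
#' @return symmetric distance matrix with zero diagonal, labeled by sample.
#' @export
allele_sharing_distance <- function(gm) {
  ib <- ibs_counts(gm)
  n <- length(gm$samples)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mutual <- ib$called[, i] & ib$called[, j]
    if (!any(mutual))
      stop("samples ", gm$samples[i], " and ", gm$samples[j],
           " share no mutually called site")
    shared <- Reduce(`+`, lapply(ib$counts, function(m)
      pmin(m[, i], m[, j])))[mutual] / 2
    d[i, j] <- d[j, i] <- 1 - mean(shared)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Ties are broken
#' by the smallest index pair; negative branch lengths are clamped to zero
#' with a note.  Returns an unrooted `ape::phylo` tree (serializable with
#' `ape::write.tree`).
#'
#' @param d symmetric distance matrix with row/col names (>= 3 taxa).
#' @return an `ape` `phylo` object.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least three taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  clamp <- function(x) {
    if (x < 0) {
      tasrdiv_msg("negative branch length ", signif(x, 3), " clamped to 0")
      0
    } else x
  }
  nwk <- labels                       # newick fragment per active cluster
  act <- seq_len(n)                   # original indices for tie-breaking
  D <- d
  while (length(act) > 3L) {
    r <- length(act)
    R <- rowSums(D)
    best <- NULL; best_q <- Inf
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * D[i, j] - R[i] - R[j]
      if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], bi, nwk[j], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    act <- c(act[keep], max(act) + 1L)
  }
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  tree <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                  nwk[1], b1, nwk[2], b2, nwk[3], b3)
  ape::read.tree(text = tree)
}
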