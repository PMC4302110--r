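#' Hudson-style fixation index with permutation significance
#'
#' `FST = 1 - pi_w / pi_t`, where `pi_w` is the mean number of differences
#' between two sequences sampled within the same population and `pi_t` the
#' mean over all pairs in the pooled sample (within + between).  Both are
#' ratios of sums over sites, so populations are weighted by their number of
#' pairs.  Significance comes from permuting sample-to-population labels
#' (whole columns, missing patterns included) with the add-one p-value
#' estimator.
#'
#' @name fst
NULL

# allele presence matrices: list over allele values v of (sites x samples)
# counts in {0,1,2}, NA treated as 0 (uncalled)
fst_dosage <- function(gm, sites = NULL) {
  sub <- if (is.null(sites)) gm else subset_matrix(gm, sites)
  a1 <- sub$a1; a2 <- sub$a2
  vals <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
  lapply(stats::setNames(vals, vals), function(v)
    (!is.na(a1) & a1 == v) + (!is.na(a2) & a2 == v))
}

# core computation given dosage list and a samples x pops indicator matrix
fst_from_dosage <- function(dosage, ind) {
  cs <- lapply(dosage, function(m) m %*% ind)     # sites x pops per allele
  n_pop <- Reduce(`+`, cs)
  sumsq_pop <- Reduce(`+`, lapply(cs, function(x) x^2))
  tot_v <- lapply(cs, rowSums)                    # pooled count per allele
  n_tot <- Reduce(`+`, tot_v)
  sumsq_tot <- Reduce(`+`, lapply(tot_v, function(x) x^2))
  use <- rowSums(n_pop >= 2) > 0                  # site usable for within
  ok <- n_pop >= 2
  w_mism <- rowSums(((n_pop^2 - sumsq_pop) / 2) * ok)
  w_pairs <- rowSums((n_pop * (n_pop - 1) / 2) * ok)
  t_mism <- (n_tot^2 - sumsq_tot) / 2
  t_pairs <- n_tot * (n_tot - 1) / 2
  pi_w <- sum(w_mism[use]) / sum(w_pairs[use])
  pi_t <- sum(t_mism[use]) / sum(t_pairs[use])
  b_mism <- sum(t_mism[use]) - sum(w_mism[use])
  b_pairs <- sum(t_pairs[use]) - sum(w_pairs[use])
  list(pi_w = pi_w, pi_t = pi_t,
       pi_b = if (b_pairs > 0) b_mism / b_pairs else NA_real_)
}

pop_indicator <- function(gm, panel, pops = NULL) {
  panel <- panel[!panel$is_outgroup, , drop = FALSE]
  if (!is.null(pops)) panel <- panel[panel$population %in% pops, , drop = FALSE]
  pops <- unique(panel$population)
  if (length(pops) < 2L) stop("need at least two populations")
  idx <- match(panel$sample, gm$samples)
  if (anyNA(idx)) stop("panel sample(s) missing from matrix: ",
                       paste(panel$sample[is.na(idx)], collapse = ", "))
  ind <- matrix(0L, nrow = length(gm$samples), ncol = length(pops),
                dimnames = list(gm$samples, pops))
  ind[cbind(idx, match(panel$population, pops))] <- 1L
  ind
}

#' Hudson F_ST
#'
#' @param gm a `genotype_matrix`.
#' @param panel panel data.frame; outgroup samples are excluded.
#' @param sites optional site index (e.g. one gene's window).
#' @param pops optional subset of population labels (e.g. one pair).
#' @param between_only use the between-population pairs only for the
#'   denominator instead of the pooled all-pairs `pi_t` (sensitivity
#'   variant; default FALSE, matching `1 - pi_iw/pi_it`).
#' @return list of class `fst_result`: `fst, pi_w, pi_t_all, scope`.
#'   `fst` is `NA` when `pi_t` is 0.
#' @export
fst_hudson <- function(gm, panel, sites = NULL, pops = NULL,
                       between_only = FALSE) {
  ind <- pop_indicator(gm, panel, pops)
  dosage <- fst_dosage(gm, sites)
  tot_called <- Reduce(`+`, lapply(dosage, function(m) colSums(m)))
  dead <- colnames(ind)[colSums(ind * tot_called[rownames(ind)]) == 0]
  if (length(dead))
    stop("population(s) with no called alleles at any site: ",
         paste(dead, collapse = ", "))
  est <- fst_from_dosage(dosage, ind)
  denom <- if (between_only) est$pi_b else est$pi_t
  fst <- if (!is.na(denom) && denom > 0) 1 - est$pi_w / denom else NA_real_
  structure(list(fst = fst, pi_w = est$pi_w, pi_t_all = est$pi_t,
                 pi_between = est$pi_b,
                 scope = paste(colnames(ind), collapse = "+")),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %s: FST = %.4f (pi_w %.4g, pi_t %.4g)\n",
              x$scope, x$fst, x$pi_w, x$pi_t_all))
  invisible(x)
}

#' Permutation test for F_ST
#'
#' Sample-to-population labels are permuted preserving population sizes;
#' whole sample columns (with their missing patterns) move together.
#'
#' @inheritParams fst_hudson
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (reproducible).
#' @return list `fst_obs, p_perm, n_perm, seed`; `p_perm` is
#'   `(1 + #[fst_perm >= fst_obs]) / (1 + n_perm)`.
#' @export
fst_permutation_test <- function(gm, panel, n_perm = 1000L, seed = NULL,
                                 sites = NULL, pops = NULL,
                                 between_only = FALSE) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  ind <- pop_indicator(gm, panel, pops)
  dosage <- fst_dosage(gm, sites)
  members <- which(rowSums(ind) > 0)
  fst_of <- function(ind) {
    est <- fst_from_dosage(dosage, ind)
    denom <- if (between_only) est$pi_b else est$pi_t
    if (!is.na(denom) && denom > 0) 1 - est$pi_w / denom else NA_real_
  }
  fst_obs <- fst_of(ind)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      perm <- ind
      perm[members, ] <- ind[sample(members), , drop = FALSE]
      f <- fst_of(perm)
      !is.na(f) && !is.na(fst_obs) && f >= fst_obs
    }, TRUE))
  })
  list(fst_obs = fst_obs, p_perm = (1 + hits) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

# mean pairwise difference between haplotype rows (0/1 derived matrix)
mean_pairwise_diff <- function(hap) {
  n <- nrow(hap)
  if (n < 2L || ncol(hap) == 0L) return(0)
  c_s <- colSums(hap)
  sum(c_s * (n - c_s)) / choose(n, 2)
}
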