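#' Negative-log transform of p-values
#'
#' \eqn{R_k = -\log p_k} (natural log). p-values that underflowed to zero
#' are clamped to the smallest positive normalized double, with a warning,
#' so that partial sums stay finite.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return nonnegative numeric vector.
#' @export
neglog_transform <- function(p) {
  if (any(!is.finite(p)) || any(p > 1) || any(p < 0)) {
    af_error("p-values must lie in (0, 1]", "afset_domain")
  }
  if (any(p == 0)) {
    af_warn("p-value underflow: clamping 0 to .Machine$double.xmin", "afset_underflow")
    p <- pmax(p, .Machine$double.xmin)
  }
  -log(p)
}

#' Weighted descending partial sums
#'
#' Forms \eqn{X_k = w_k R_k}, sorts the \eqn{X_k} in descending order and
#' returns the cumulative partial sums \eqn{S^*_k = \sum_{l \le k} X_{(l)}}.
#' The result depends only on the multiset of X values, so tie order in the
#' sort is immaterial.
#'
#' @param R nonnegative vector (typically from [neglog_transform()]).
#' @param w nonnegative weight vector of the same length, not all zero.
#' @return list with `X` (weighted values, input order) and `S_star`
#'   (nondecreasing partial sums of the sorted X).
#' @export
weighted_partial_sums <- function(R, w) {
  if (length(R) != length(w)) af_error("length mismatch between R and w", "afset_dim_mismatch")
  if (any(w < 0)) af_error("weights must be nonnegative", "afset_domain")
  if (all(w == 0)) af_error("at least one weight must be positive", "afset_domain")
  X <- w * R
  list(X = X, S_star = cumsum(sort(X, decreasing = TRUE)))
}

#' Permutation p-values of the partial sums
#'
#' Given the observed partial-sum profile (row 1, replicate b = 0) stacked
#' with B permutation profiles, computes for a chosen replicate \eqn{b^*}
#' the per-k inclusive tail probabilities
#' \eqn{P_{S^*_k}^{(b^*)} = (B+1)^{-1} \sum_{b=0}^{B} I\{S_k^{*(b)} \ge S_k^{*(b^*)}\}}.
#' Inclusive counting (the replicate ties with itself) bounds every value
#' below by \eqn{1/(B+1)}.
#'
#' @param S_star_all (B+1) x K matrix; row 1 is the observed profile.
#' @param b_star replicate whose p-values are wanted, 0-based as in the
#'   permutation indexing (0 = observed). Default 0.
#' @return length-K vector of partial-sum p-values in \[1/(B+1), 1\].
#' @export
partial_sum_pvalues <- function(S_star_all, b_star = 0L) {
  S_star_all <- as.matrix(S_star_all)
  i <- b_star + 1L
  if (i < 1L || i > nrow(S_star_all)) af_error("b_star out of range", "afset_domain")
  psum_pvalues_all(S_star_all)[i, ]
}

# inclusive tail p-values for every replicate at once:
# #{b : S[b, k] >= S[b*, k]} = N - rank_min(S[b*, k]) + 1
psum_pvalues_all <- function(S) {
  N <- nrow(S)
  cnt <- apply(S, 2, function(x) N - rank(x, ties.method = "min") + 1)
  cnt / N
}

#' Adaptive Fisher statistic from partial-sum p-values
#'
#' The (w)AF statistic is the minimum over k of the partial-sum p-values;
#' small values are extreme.
#'
#' @param partial_pvalues nonempty vector of values in (0, 1].
#' @return scalar minimum.
#' @export
af_statistic <- function(partial_pvalues) {
  if (length(partial_pvalues) == 0L) af_error("empty partial p-value vector", "afset_domain")
  min(partial_pvalues)
}

#' Directed wAF statistic
#'
#' Minimum of the two-sided wAF statistic and the two one-sided (risk and
#' protective direction) wAF statistics computed from the same data.
#'
#' @param T_two,T_plus,T_minus component statistics in (0, 1].
#' @return scalar minimum of the three.
#' @export
wafd_statistic <- function(T_two, T_plus, T_minus) {
  min(T_two, T_plus, T_minus)
}

#' Default MAF-based variant weights
#'
#' \eqn{w_k = \sqrt{f_k (1 - f_k)}} with \eqn{f_k} the in-sample allele
#' frequency `mean(G[, k]) / 2`. Symmetric in \eqn{f \leftrightarrow 1 - f},
#' hence invariant to allele flips; proportional to the binomial standard
#' deviation of a haplotype, it up-weights common variants relative to flat
#' weights while damping the noisiest rare ones.
#'
#' @param G genotype matrix of minor-allele counts/dosages in \[0, 2\].
#' @return nonnegative weight vector, one per column of `G`.
#' @export
default_weights <- function(G) {
  G <- as.matrix(G)
  if (ncol(G) == 0L) af_error("empty genotype matrix", "afset_domain")
  f <- colMeans(G) / 2
  sqrt(f * (1 - f))
}
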