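#' Score statistics for a trait-genotype variant set
#'
#' Computes the per-variant score vector \eqn{U} and its estimated null
#' covariance \eqn{V} for the generalized linear model relating a trait to
#' minor-allele counts, with or without covariate adjustment. Without
#' covariates, \eqn{U = \sum_i (Y_i - \bar Y) G_i} and
#' \eqn{V = \hat\sigma^2 \sum_i (G_i - \bar G)(G_i - \bar G)^T}, where the
#' variance factor is \eqn{\bar Y (1 - \bar Y)} for a binary trait and the
#' unbiased sample variance of \eqn{Y} for a continuous trait. With
#' covariates, the trait is replaced by residuals from the null model
#' (logistic or linear on covariates alone) and each genotype column by its
#' residual from an ordinary least-squares regression on the covariates.
#'
#' @param Y numeric trait vector of length n; binary traits are coded 0/1.
#' @param G n x K numeric matrix of minor-allele counts or dosages in
#'   \[0, 2\]. Columns must have nonzero sample variance (see
#'   [drop_monomorphic()]).
#' @param C optional n x J numeric covariate matrix (no intercept column).
#' @param trait_type `"auto"` (default; 0/1 values are treated as binary),
#'   `"binary"`, or `"continuous"`.
#' @return An object of class `"af_score"`: a list with elements `U`
#'   (length-K score vector), `V` (K x K covariance), `sigma_sq` (variance
#'   factor used), `e` (residuals to be permuted), `G_adj` (genotype matrix
#'   the permuted residuals are scored against), `model`
#'   (`"marginal"`/`"adjusted"`) and `trait_type`.
#' @seealso [marginal_pvalues()], [snvset_test()]
#' @examples
#' G <- cbind(v1 = c(2, 1, 0, 1))
#' s <- compute_score(c(1, 1, 0, 0), G)
#' s$U  # 1
#' s$V  # 0.5
#' @export
compute_score <- function(Y, G, C = NULL, trait_type = c("auto", "binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  Y <- as.numeric(Y)
  G <- as.matrix(G)
  n <- length(Y)
  if (n < 2L) af_error("need at least 2 subjects", "afset_degenerate_trait")
  if (nrow(G) != n) af_error("nrow(G) must equal length(Y)", "afset_dim_mismatch")
  if (anyNA(Y) || anyNA(G)) af_error("missing values not allowed; impute at read time", "afset_missing")
  if (trait_type == "auto") {
    trait_type <- if (all(Y %in% c(0, 1))) "binary" else "continuous"
  }
  if (trait_type == "binary" && !all(Y %in% c(0, 1))) {
    af_error("binary trait must be coded 0/1", "afset_bad_trait")
  }
  if (stats::var(Y) == 0) af_error("trait is constant", "afset_degenerate_trait")
  v <- apply(G, 2, stats::var)
  if (any(v == 0)) {
    af_error(sprintf("monomorphic variant column(s): %s",
                     paste(which(v == 0), collapse = ", ")),
             "afset_degenerate_variant")
  }

  if (is.null(C)) {
    ybar <- mean(Y)
    e <- Y - ybar
    Gc <- sweep(G, 2, colMeans(G))
    U <- drop(crossprod(G, e))          # == crossprod(Gc, e) since sum(e) = 0
    sigma_sq <- if (trait_type == "binary") ybar * (1 - ybar) else stats::var(Y)
    V <- sigma_sq * crossprod(Gc)
    G_adj <- G
    model <- "marginal"
  } else {
    C <- as.matrix(C)
    if (nrow(C) != n) af_error("nrow(C) must equal length(Y)", "afset_dim_mismatch")
    X0 <- cbind(`(Intercept)` = 1, C)
    qrX <- qr(X0)
    if (qrX$rank < ncol(X0)) {
      af_error("covariate matrix is rank deficient after adding an intercept",
               "afset_collinearity")
    }
    if (trait_type == "binary") {
      fit <- stats::glm.fit(X0, Y, family = stats::binomial(),
                            control = list(epsilon = 1e-8, maxit = 100))
      if (!fit$converged) {
        af_error("logistic null model did not converge (possible separation)",
                 "afset_fit_failure")
      }
      mu <- fit$fitted.values
      sigma_sq <- mean(mu * (1 - mu))
    } else {
      mu <- qr.fitted(qrX, Y)
      e_tmp <- Y - mu
      sigma_sq <- sum((e_tmp - mean(e_tmp))^2) / (n - 1)
    }
    e <- Y - mu
    G_adj <- G - qr.fitted(qrX, G)      # per-variant OLS residuals on covariates
    U <- drop(crossprod(G_adj, e))
    V <- sigma_sq * crossprod(G_adj)
    model <- "adjusted"
  }
  dimnames(V) <- list(colnames(G), colnames(G))
  names(U) <- colnames(G)
  structure(list(U = U, V = V, sigma_sq = sigma_sq, e = e, G_adj = G_adj,
                 model = model, trait_type = trait_type, n = n, K = ncol(G)),
            class = "af_score")
}

#' Standardized scores and marginal p-values
#'
#' Standardizes each score statistic by its null standard deviation,
#' \eqn{\tilde U_k = U_k / \sqrt{V_{kk}}}, and converts to marginal normal
#' p-values: two-sided \eqn{p_k = 2[1 - \Phi(|\tilde U_k|)]}, risk-direction
#' one-sided \eqn{p_k^+ = 1 - \Phi(\tilde U_k)} and protective-direction
#' \eqn{p_k^- = \Phi(\tilde U_k)}, so that \eqn{p^+ + p^- = 1} and
#' \eqn{p = 2\min(p^+, p^-)}.
#'
#' @param score an `"af_score"` object from [compute_score()].
#' @return list with elements `U_std`, `p_two`, `p_plus`, `p_minus`.
#' @export
marginal_pvalues <- function(score) {
  vkk <- diag(score$V)
  if (any(vkk <= 0)) af_error("zero-variance variant in V", "afset_degenerate_variant")
  u <- score$U / sqrt(vkk)
  list(U_std = u,
       p_two = 2 * stats::pnorm(-abs(u)),
       p_plus = stats::pnorm(u, lower.tail = FALSE),
       p_minus = stats::pnorm(u))
}

#' Drop monomorphic (zero-variance) variant columns
#'
#' Variants with no variation carry no association information and make the
#' score standardization undefined; they are removed with a warning.
#'
#' @param G genotype matrix.
#' @param quiet suppress the warning (used inside simulation loops).
#' @return `G` restricted to polymorphic columns (possibly with 0 columns).
#' @export
drop_monomorphic <- function(G, quiet = FALSE) {
  G <- as.matrix(G)
  keep <- apply(G, 2, function(x) stats::var(x) > 0)
  if (!all(keep) && !quiet) {
    af_warn(sprintf("dropping %d monomorphic variant(s)", sum(!keep)),
            "afset_monomorphic_dropped")
  }
  G[, keep, drop = FALSE]
}
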