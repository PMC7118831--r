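#' Permutation-calibrated adaptive Fisher tests for one SNV set
#'
#' Runs one or more of the AF, wAF, directed wAF (wAFd) and Min-P tests on a
#' variant set, calibrating all of them on a single shared set of B residual
#' permutations. Residuals are \eqn{e_i = Y_i - \bar Y} without covariates,
#' or \eqn{e_i = Y_i - \hat\mu_{Y_i}} from the covariate null model; for
#' each permutation the score vector is recomputed as
#' \eqn{U^{(b)} = \sum_i e^{(b)}_i G_i} (adjusted genotypes when covariates
#' are present) while the null covariance V stays fixed at its observed
#' value. Marginal p-values, weighted partial sums and partial-sum p-values
#' are recomputed per replicate; the final p-value counts permutation
#' replicates whose statistic is at least as extreme (small) as the
#' observed one, over B + 1.
#'
#' For wAFd the two-sided and both one-sided component statistics are
#' computed from the same permuted scores and the minimum of the three is
#' taken within each replicate before counting. Min-P uses the smallest
#' marginal two-sided p-value as its statistic, calibrated on the same
#' permutations.
#'
#' @param Y trait vector (binary 0/1 or continuous).
#' @param G n x K genotype matrix of minor-allele counts/dosages; columns
#'   must be polymorphic ([drop_monomorphic()]).
#' @param C optional covariate matrix.
#' @param methods character vector from `c("wAF", "AF", "wAFd", "MinP")`,
#'   or `"all"`.
#' @param weights `"maf"` (default, \eqn{\sqrt{f(1-f)}}), `"flat"`, or a
#'   numeric vector of K nonnegative weights. AF always uses flat weights;
#'   the weights argument applies to wAF/wAFd.
#' @param B number of permutations (default 1000).
#' @param seed integer seed for the permutation draw; `NULL` leaves the RNG
#'   state alone.
#' @param trait_type `"auto"`, `"binary"` or `"continuous"`.
#' @param perm optional B x n integer matrix of permutation orderings
#'   (each row a permutation of 1..n); overrides `B` and the RNG. Used for
#'   exact enumeration on tiny samples.
#' @return object of class `"snvset_test"`: list with `results` (data frame
#'   with one row per method: method, statistic, p.value, K, B), `details`
#'   (per-method list holding `partial_pvalues` where defined), the weights
#'   used, `score` (the `"af_score"` object) and `seed`.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(200 * 10, 2, 0.3), 200, 10)
#' Y <- rbinom(200, 1, 0.5)
#' snvset_test(Y, G, methods = c("wAF", "MinP"), B = 200, seed = 42)
#' @export
snvset_test <- function(Y, G, C = NULL,
                        methods = "wAF",
                        weights = "maf",
                        B = 1000L, seed = NULL,
                        trait_type = "auto",
                        perm = NULL) {
  all_methods <- c("wAF", "AF", "wAFd", "MinP")
  if (identical(methods, "all")) methods <- all_methods
  methods <- all_methods[match(tolower(methods), tolower(all_methods))]
  if (anyNA(methods)) af_error("unknown method; choose from wAF, AF, wAFd, MinP", "afset_domain")

  G <- as.matrix(G)
  score <- compute_score(Y, G, C, trait_type = trait_type)
  K <- score$K
  n <- score$n
  w <- resolve_weights(weights, G)

  if (is.null(perm)) {
    B <- as.integer(B)
    if (B < 1L) af_error("B must be >= 1", "afset_domain")
    if (!is.null(seed)) set.seed(seed)
    perm <- t(replicate(B, sample.int(n)))
    if (B == 1L) perm <- matrix(perm, nrow = 1L)
  } else {
    perm <- as.matrix(perm)
    if (ncol(perm) != n) af_error("perm must have n columns", "afset_dim_mismatch")
    B <- nrow(perm)
  }

  # (B+1) x n residual matrix, observed data first
  E <- rbind(score$e, matrix(score$e[perm], nrow = B))
  U <- E %*% score$G_adj                       # (B+1) x K permuted scores
  sdk <- sqrt(diag(score$V))
  Ustd <- sweep(U, 2, sdk, "/")
  p_two <- pmax(2 * stats::pnorm(-abs(Ustd)), .Machine$double.xmin)

  details <- list()
  res <- list()

  need_waf_pipeline <- any(methods %in% c("wAF", "wAFd"))
  if (need_waf_pipeline) {
    P_two <- psum_pvalues_all(partial_sum_profiles(-log(p_two), w))
    T_two <- row_mins(P_two)
  }
  if ("wAF" %in% methods) {
    res$wAF <- list(statistic = T_two[1], p.value = perm_pvalue(T_two))
    details$wAF <- list(partial_pvalues = P_two[1, ])
  }
  if ("AF" %in% methods) {
    P_af <- psum_pvalues_all(partial_sum_profiles(-log(p_two), rep(1, K)))
    T_af <- row_mins(P_af)
    res$AF <- list(statistic = T_af[1], p.value = perm_pvalue(T_af))
    details$AF <- list(partial_pvalues = P_af[1, ])
  }
  if ("wAFd" %in% methods) {
    p_plus <- pmax(stats::pnorm(Ustd, lower.tail = FALSE), .Machine$double.xmin)
    p_minus <- pmax(stats::pnorm(Ustd), .Machine$double.xmin)
    T_plus <- row_mins(psum_pvalues_all(partial_sum_profiles(-log(p_plus), w)))
    T_minus <- row_mins(psum_pvalues_all(partial_sum_profiles(-log(p_minus), w)))
    T_d <- pmin(T_two, T_plus, T_minus)
    res$wAFd <- list(statistic = T_d[1], p.value = perm_pvalue(T_d))
    details$wAFd <- list(components = c(two = T_two[1], plus = T_plus[1], minus = T_minus[1]))
  }
  if ("MinP" %in% methods) {
    T_mp <- row_mins(p_two)
    res$MinP <- list(statistic = T_mp[1], p.value = perm_pvalue(T_mp))
  }

  results <- data.frame(
    method = names(res),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p.value = vapply(res, `[[`, numeric(1), "p.value"),
    K = K, B = B, row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(results = results[match(methods, results$method), , drop = FALSE],
                 details = details, weights = w, score = score,
                 B = B, seed = seed),
            class = "snvset_test")
}

#' @rdname snvset_test
#' @param x,... print method arguments.
#' @method print snvset_test
#' @export
print.snvset_test <- function(x, ...) {
  cat(sprintf("Adaptive Fisher SNV-set test (%s model, %s trait)\n",
              x$score$model, x$score$trait_type))
  cat(sprintf("  n = %d subjects, K = %d variants, B = %d permutations\n",
              x$score$n, x$score$K, x$B))
  df <- x$results
  df$p.value <- format(df$p.value, digits = 3, scientific = TRUE)
  df$statistic <- signif(df$statistic, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

resolve_weights <- function(weights, G) {
  K <- ncol(G)
  if (is.character(weights)) {
    switch(match.arg(weights, c("maf", "flat")),
           maf = default_weights(G),
           flat = rep(1, K))
  } else {
    w <- as.numeric(weights)
    if (length(w) != K) af_error("weight vector length must equal K", "afset_dim_mismatch")
    if (any(w < 0) || all(w == 0)) af_error("weights must be nonnegative, not all zero", "afset_domain")
    w
  }
}

# rows of R -> sorted-descending weighted partial sums, vectorized over rows
partial_sum_profiles <- function(R, w) {
  X <- sweep(R, 2, w, "*")
  o <- order(row(X), -X)                       # row-major, descending within row
  Xs <- matrix(X[o], nrow = nrow(X), byrow = TRUE)
  K <- ncol(X)
  Xs %*% upper.tri(matrix(0, K, K), diag = TRUE)   # row-wise cumulative sums
}

row_mins <- function(M) do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))

# final Monte-Carlo p-value: count permutation replicates at least as
# extreme (small) as the observed statistic, over B + 1 (row 1 = observed)
perm_pvalue <- function(T_all) {
  sum(T_all[-1] <= T_all[1]) / length(T_all)
}

#' Step-up permutation budget policy
#'
#' Every gene is first tested with `B_init` permutations; any gene whose
#' estimated p-value falls below `threshold / B` is retested with B
#' multiplied by `factor`, iterating until no gene beats the threshold or
#' `B_max` is reached. This concentrates compute on the genes where p-value
#' precision matters.
#'
#' @param B_init initial permutation count (default 100).
#' @param factor escalation multiplier per round (default 10).
#' @param threshold numerator of the continue rule p < threshold / B
#'   (default 5).
#' @param B_max cap on B (default 1e6); genes still below the threshold at
#'   the cap are flagged censored.
#' @return list of class `"scan_policy"`.
#' @export
scan_policy <- function(B_init = 100L, factor = 10L, threshold = 5, B_max = 1e6) {
  if (B_init < 1L || factor < 2L || B_max < B_init) {
    af_error("invalid scan policy", "afset_domain")
  }
  structure(list(B_init = as.integer(B_init), factor = as.integer(factor),
                 threshold = threshold, B_max = B_max),
            class = "scan_policy")
}

#' Adaptive genome-scan over many gene regions
#'
#' Applies [snvset_test()] to each gene with the step-up permutation budget
#' of [scan_policy()]: all genes start at `B_init` permutations and only
#' genes with small estimated p-values are escalated to larger B.
#'
#' @param genes named list; each element a list with components `Y`, `G`
#'   and optionally `C` (covariates) and `id`.
#' @param method single test method (default `"wAF"`).
#' @param weights weight specification passed to [snvset_test()].
#' @param policy a [scan_policy()].
#' @param seed integer; per-gene, per-round seeds are derived from it.
#' @param trait_type passed to [snvset_test()].
#' @return data frame with one row per gene: `gene_id`, `K`, `method`,
#'   `statistic`, `p.value`, `B` (final permutation count) and `censored`
#'   (TRUE when the p-value was still below threshold/B at `B_max`).
#' @export
adaptive_scan <- function(genes, method = "wAF", weights = "maf",
                          policy = scan_policy(), seed = 1L,
                          trait_type = "auto") {
  if (length(genes) == 0L) af_error("empty gene list", "afset_domain")
  ids <- names(genes)
  if (is.null(ids)) ids <- vapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    if (!is.null(g$id)) as.character(g$id) else sprintf("gene%03d", i)
  }, character(1))

  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    B <- policy$B_init
    round <- 0L
    repeat {
      fit <- snvset_test(g$Y, g$G, g$C, methods = method, weights = weights,
                         B = B, seed = derive_seed(seed, i, round),
                         trait_type = trait_type)
      p <- fit$results$p.value
      stat <- fit$results$statistic
      below <- p < policy$threshold / B
      if (!below || B >= policy$B_max) {
        return(data.frame(gene_id = ids[i], K = fit$score$K, method = method,
                          statistic = stat, p.value = p, B = B,
                          censored = below && B >= policy$B_max,
                          stringsAsFactors = FALSE))
      }
      B <- min(B * policy$factor, policy$B_max)
      round <- round + 1L
    }
  })
  do.call(rbind, rows)
}

# deterministic 31-bit seed stream from a master seed
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 48271 + i * 65537 + j * 7919) %% 2147483647) + 1L
}
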