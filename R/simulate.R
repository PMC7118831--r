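#' Simulation scenario description
#'
#' Bundles the parameters of one simulation condition: sample size, number
#' of variants, linkage-disequilibrium strength, allele-frequency regime,
#' effect sparsity and size, and trait type.
#'
#' Genotypes are generated from two independent latent Gaussian vectors
#' (one per haplotype) with AR(1) correlation \eqn{c^{|k-k'|}} across loci,
#' thresholded at the normal quantile of each locus MAF, so nearby variants
#' are correlated as under linkage disequilibrium. MAFs are redrawn for
#' every simulated dataset: log-uniform on \[0.001, 0.5\] by default, or
#' uniform on \[0.001, 0.01\] in the rare-variant regime.
#'
#' @param n number of subjects (default 1000).
#' @param K number of variants in the set.
#' @param c AR(1) correlation parameter of the latent Gaussians, in
#'   \[0, 1) (default 0.9).
#' @param maf_mode `"loguniform"` (log MAF ~ U(log 0.001, log 0.5)) or
#'   `"rare"` (MAF ~ U(0.001, 0.01)).
#' @param pi proportion of variants with nonzero effect (round(pi * K)
#'   effects are nonzero).
#' @param delta effect-size bound; nonzero effects are uniform on
#'   \[-delta, delta\] (`effect_mode = "two_sided"`) or \[0, delta\]
#'   (`"one_sided"`).
#' @param trait_type `"binary"` (logit link, null prevalence 0.5) or
#'   `"continuous"` (identity link, standard normal errors).
#' @param effect_mode `"two_sided"` or `"one_sided"`.
#' @return list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n = 1000L, K = 50L, c = 0.9,
                         maf_mode = c("loguniform", "rare"),
                         pi = 0, delta = 0,
                         trait_type = c("binary", "continuous"),
                         effect_mode = c("two_sided", "one_sided")) {
  maf_mode <- match.arg(maf_mode)
  trait_type <- match.arg(trait_type)
  effect_mode <- match.arg(effect_mode)
  if (n < 2L || K < 1L) af_error("need n >= 2 and K >= 1", "afset_domain")
  if (c < 0 || c >= 1) af_error("AR(1) parameter c must be in [0, 1)", "afset_domain")
  if (pi < 0 || pi > 1) af_error("pi must be in [0, 1]", "afset_domain")
  if (delta < 0) af_error("delta must be >= 0", "afset_domain")
  structure(list(n = as.integer(n), K = as.integer(K), c = c,
                 maf_mode = maf_mode, pi = pi, delta = delta,
                 trait_type = trait_type, effect_mode = effect_mode),
            class = "sim_scenario")
}

# latent AR(1) normal matrix: rows subjects, cols loci; exact recursion
ar1_normal <- function(n, K, c) {
  Z <- matrix(stats::rnorm(n * K), n, K)
  if (c > 0 && K > 1L) {
    s <- sqrt(1 - c^2)
    for (k in 2:K) Z[, k] <- c * Z[, k - 1] + s * Z[, k]
  }
  Z
}

#' Simulate correlated genotypes
#'
#' Draws MAFs per the scenario's regime, then per subject two independent
#' latent N(0, A) haplotype vectors with AR(1) covariance
#' \eqn{A_{kk'} = c^{|k-k'|}}, and sets
#' \eqn{G_{ik} = I(\Phi(Z_{1k}) \le MAF_k) + I(\Phi(Z_{2k}) \le MAF_k)},
#' giving minor-allele counts in \{0, 1, 2\} with locus frequency MAF_k and
#' LD decaying with distance.
#'
#' @param scenario a [sim_scenario()].
#' @param maf optional fixed MAF vector (length K) overriding the random
#'   draw, for calibration checks.
#' @return n x K integer genotype matrix with attribute `"maf"` (the MAFs
#'   used). Columns may be monomorphic for very rare variants; filter with
#'   [drop_monomorphic()] before testing.
#' @export
simulate_genotypes <- function(scenario, maf = NULL) {
  n <- scenario$n; K <- scenario$K
  if (is.null(maf)) {
    maf <- switch(scenario$maf_mode,
                  loguniform = exp(stats::runif(K, log(0.001), log(0.5))),
                  rare = stats::runif(K, 0.001, 0.01))
  } else if (length(maf) != K || any(maf <= 0) || any(maf > 0.5)) {
    af_error("maf must be length K with values in (0, 0.5]", "afset_domain")
  }
  thr <- stats::qnorm(maf)
  Z1 <- ar1_normal(n, K, scenario$c)
  Z2 <- ar1_normal(n, K, scenario$c)
  G <- (sweep(Z1, 2, thr, "<=") + 0L) + (sweep(Z2, 2, thr, "<=") + 0L)
  attr(G, "maf") <- maf
  G
}

#' Sample a sparse effect vector
#'
#' Chooses round(pi * K) positions uniformly without replacement and draws
#' their effects uniform on \[-delta, delta\] (two-sided) or \[0, delta\]
#' (one-sided); all other effects are exactly zero.
#'
#' @param scenario a [sim_scenario()].
#' @return numeric length-K effect vector with attribute
#'   `"nonzero_indices"`.
#' @export
sample_effects <- function(scenario) {
  K <- scenario$K
  m <- round(scenario$pi * K)
  if (scenario$pi > 0 && m == 0L) {
    af_warn("pi * K rounds to 0: scenario degenerates to the null", "afset_null_scenario")
  }
  beta <- numeric(K)
  idx <- integer(0)
  if (m > 0L) {
    idx <- sort(sample.int(K, m))
    beta[idx] <- switch(scenario$effect_mode,
                        two_sided = stats::runif(m, -scenario$delta, scenario$delta),
                        one_sided = stats::runif(m, 0, scenario$delta))
  }
  attr(beta, "nonzero_indices") <- idx
  beta
}

#' Simulate a trait from genotypes and effects
#'
#' Binary: \eqn{Y_i \sim Bernoulli(logit^{-1}(\sum_k \beta_k G_{ik}))} with
#' zero intercept, so the null prevalence is 0.5. Continuous:
#' \eqn{Y_i = \sum_k \beta_k G_{ik} + \epsilon_i} with standard normal
#' errors and zero intercept.
#'
#' @param G n x K genotype matrix.
#' @param beta length-K effect vector.
#' @param trait_type `"binary"` or `"continuous"`.
#' @return numeric length-n trait vector.
#' @export
simulate_trait <- function(G, beta, trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  eta <- drop(as.matrix(G) %*% beta)
  n <- length(eta)
  if (trait_type == "binary") {
    stats::rbinom(n, 1L, stats::plogis(eta))
  } else {
    eta + stats::rnorm(n)
  }
}

#' Empirical rejection rate (type-I error or power) by simulation
#'
#' Repeatedly simulates a dataset from the scenario, runs the requested
#' tests (sharing one permutation set per replicate), and reports the
#' fraction of replicates with p-value at or below `alpha`, with an exact
#' binomial confidence interval. Monomorphic simulated variants are dropped
#' silently before testing. Replicate seeds are derived deterministically
#' from `seed`.
#'
#' @param scenario a [sim_scenario()].
#' @param methods methods passed to [snvset_test()].
#' @param alpha nominal significance level (default 0.05).
#' @param reps number of simulation replicates.
#' @param B permutations per replicate.
#' @param seed master seed.
#' @param weights weight specification for wAF/wAFd (default `"maf"`).
#' @param conf.level confidence level of the binomial interval.
#' @param keep_pvalues return the reps x methods p-value matrix as
#'   attribute `"pvalues"`.
#' @return data frame with one row per method: `method`, `reject` (rate),
#'   `lo`, `hi` (binomial CI), `reps`, `alpha`.
#' @export
estimate_power <- function(scenario, methods = "wAF", alpha = 0.05,
                           reps = 500L, B = 500L, seed = 1L,
                           weights = "maf", conf.level = 0.95,
                           keep_pvalues = FALSE) {
  if (reps < 1L) af_error("reps must be >= 1", "afset_domain")
  if (identical(methods, "all")) methods <- c("wAF", "AF", "wAFd", "MinP")
  pv <- matrix(NA_real_, reps, length(methods),
               dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    G <- simulate_genotypes(scenario)
    beta <- sample_effects(scenario)
    Y <- simulate_trait(G, beta, scenario$trait_type)
    G <- drop_monomorphic(G, quiet = TRUE)
    if (ncol(G) == 0L || stats::var(Y) == 0) next   # degenerate draw: no test
    fit <- snvset_test(Y, G, methods = methods, weights = weights, B = B,
                       seed = derive_seed(seed, r, 1L),
                       trait_type = scenario$trait_type)
    pv[r, fit$results$method] <- fit$results$p.value
  }
  out <- do.call(rbind, lapply(methods, function(m) {
    p <- pv[, m]
    ok <- !is.na(p)
    x <- sum(p[ok] <= alpha)
    ci <- stats::binom.test(x, sum(ok), conf.level = conf.level)$conf.int
    data.frame(method = m, reject = x / sum(ok), lo = ci[1], hi = ci[2],
               reps = sum(ok), alpha = alpha, stringsAsFactors = FALSE)
  }))
  if (keep_pvalues) attr(out, "pvalues") <- pv
  out
}
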