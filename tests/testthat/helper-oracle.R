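# Brute-force oracles and small fixtures, written as plain loops so they are
# independent of the package's vectorized implementation.

# all n! orderings of 1..n as rows (recursive construction)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# straight-line wAF permutation test: observed data as replicate 0 followed
# by the supplied residual orderings; explicit loops throughout
oracle_waf <- function(Y, G, w, perm) {
  n <- length(Y); K <- ncol(G); B <- nrow(perm)
  ybar <- mean(Y)
  e <- Y - ybar
  binary <- all(Y %in% c(0, 1))
  sig <- if (binary) ybar * (1 - ybar) else sum((Y - ybar)^2) / (n - 1)
  Gc <- G
  for (k in seq_len(K)) Gc[, k] <- G[, k] - mean(G[, k])
  Vkk <- numeric(K)
  for (k in seq_len(K)) Vkk[k] <- sig * sum(Gc[, k]^2)
  S <- matrix(0, B + 1, K)
  for (b in 0:B) {
    eb <- if (b == 0) e else e[perm[b, ]]
    U <- numeric(K)
    for (i in seq_len(n)) U <- U + eb[i] * G[i, ]
    p <- 2 * (1 - pnorm(abs(U / sqrt(Vkk))))
    p <- pmax(p, .Machine$double.xmin)
    X <- sort(w * (-log(p)), decreasing = TRUE)
    acc <- 0
    for (k in seq_len(K)) { acc <- acc + X[k]; S[b + 1, k] <- acc }
  }
  P <- matrix(0, B + 1, K)
  for (b in seq_len(B + 1)) for (k in seq_len(K)) {
    P[b, k] <- sum(S[, k] >= S[b, k]) / (B + 1)
  }
  Tall <- apply(P, 1, min)
  list(statistic = Tall[1],
       pvalue = sum(Tall[-1] <= Tall[1]) / (B + 1),
       partial = P[1, ])
}

# small correlated genotype matrix guaranteed polymorphic
toy_genotypes <- function(n, K, seed, maf = 0.3, c = 0.5) {
  set.seed(seed)
  sc <- sim_scenario(n = n, K = K, c = c)
  repeat {
    G <- simulate_genotypes(sc, maf = rep(maf, K))
    if (all(apply(G, 2, var) > 0)) return(G)
  }
}
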