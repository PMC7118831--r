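test_that("wAF with the full enumeration permutation set matches the brute-force oracle", {
  perm <- all_perms(6)
  G <- matrix(c(0, 1, 2, 0, 1, 0,
                2, 1, 0, 1, 0, 1,
                1, 0, 1, 2, 0, 0), 6, 3)
  w <- default_weights(G)
  for (Y in list(c(1, 1, 1, 0, 0, 0), c(0.3, -1.2, 2.1, 0.4, -0.5, 1.1))) {
    fit <- snvset_test(Y, G, methods = "wAF", weights = w, perm = perm)
    orc <- oracle_waf(Y, G, w, perm)
    expect_equal(fit$results$statistic, orc$statistic, tolerance = 1e-12)
    expect_equal(fit$results$p.value, orc$pvalue, tolerance = 1e-12)
    expect_equal(unname(fit$details$wAF$partial_pvalues), orc$partial, tolerance = 1e-12)
  }
})

test_that("flat weights make wAF identical to AF", {
  for (i in 1:10) {
    G <- toy_genotypes(30, 6, seed = 100 + i)
    set.seed(200 + i)
    Y <- rbinom(30, 1, 0.5)
    fit <- snvset_test(Y, G, methods = c("wAF", "AF"), weights = "flat",
                       B = 100, seed = 300 + i)
    expect_identical(fit$results$statistic[1], fit$results$statistic[2])
    expect_identical(fit$results$p.value[1], fit$results$p.value[2])
  }
})

test_that("single-variant wAF collapses to the permutation test of |U|", {
  G <- toy_genotypes(40, 1, seed = 41)
  set.seed(42)
  Y <- rnorm(40)
  perm <- t(replicate(200, sample.int(40)))
  fit <- snvset_test(Y, G, methods = "wAF", perm = perm)
  # direct permutation test of |standardized score|: S*_1 is monotone in |U|
  s <- compute_score(Y, G)
  u_obs <- abs(sum(s$e * G[, 1]))
  u_perm <- abs(apply(perm, 1, function(o) sum(s$e[o] * G[, 1])))
  expect_equal(fit$results$p.value, sum(u_perm >= u_obs) / 201)
})

test_that("Min-P p-value equals the first-partial-sum permutation p-value", {
  G <- toy_genotypes(50, 5, seed = 51)
  set.seed(52)
  Y <- rbinom(50, 1, 0.5)
  perm <- t(replicate(150, sample.int(50)))
  fit <- snvset_test(Y, G, methods = "MinP", perm = perm)
  # S_1 = max(-log p) is a monotone transform of min p: counts must agree
  s <- compute_score(Y, G)
  vk <- sqrt(diag(s$V))
  minp <- function(e) min(2 * pnorm(-abs(colSums(e * G) / vk)))
  t_obs <- minp(s$e)
  t_perm <- apply(perm, 1, function(o) minp(s$e[o]))
  expect_equal(fit$results$p.value, sum(t_perm <= t_obs) / 151)
  expect_equal(fit$results$statistic, t_obs)
})

test_that("identical seed and inputs reproduce the result bit for bit", {
  G <- toy_genotypes(60, 8, seed = 61)
  set.seed(62)
  Y <- rnorm(60)
  a <- snvset_test(Y, G, methods = "all", B = 150, seed = 99)
  b <- snvset_test(Y, G, methods = "all", B = 150, seed = 99)
  expect_identical(a$results, b$results)
  c <- snvset_test(Y, G, methods = "all", B = 150, seed = 100)
  expect_false(identical(a$results$p.value, c$results$p.value))
})

test_that("relabeling subjects jointly leaves the test invariant", {
  n <- 40
  G <- toy_genotypes(n, 4, seed = 71)
  set.seed(72)
  Y <- rnorm(n)
  perm <- t(replicate(100, sample.int(n)))
  s <- sample.int(n)              # fixed relabeling
  inv <- order(s)
  perm2 <- t(apply(perm, 1, function(p) inv[p[s]]))
  a <- snvset_test(Y, G, methods = "wAF", perm = perm)
  b <- snvset_test(Y[s], G[s, , drop = FALSE], methods = "wAF", perm = perm2)
  expect_equal(a$results$statistic, b$results$statistic)
  expect_equal(a$results$p.value, b$results$p.value)
})

test_that("sign-flipping a continuous trait leaves wAFd unchanged", {
  n <- 50
  G <- toy_genotypes(n, 5, seed = 81)
  set.seed(82)
  Y <- rnorm(n) + 0.3 * G[, 2]
  perm <- t(replicate(120, sample.int(n)))
  a <- snvset_test(Y, G, methods = "wAFd", perm = perm)
  b <- snvset_test(-Y, G, methods = "wAFd", perm = perm)
  # the two one-sided components swap; the min of three is unchanged
  expect_equal(a$results$statistic, b$results$statistic)
  expect_equal(a$results$p.value, b$results$p.value)
  expect_equal(unname(a$details$wAFd$components[c("plus", "minus")]),
               unname(b$details$wAFd$components[c("minus", "plus")]))
})

test_that("partial-sum p-values respect the 1/(B+1) floor and p-values are proper", {
  G <- toy_genotypes(30, 4, seed = 91)
  set.seed(92)
  Y <- rbinom(30, 1, 0.5)
  fit <- snvset_test(Y, G, methods = "all", B = 50, seed = 93)
  expect_true(all(fit$details$wAF$partial_pvalues >= 1 / 51))
  expect_true(all(fit$details$wAF$partial_pvalues <= 1))
  expect_true(all(fit$results$p.value >= 0 & fit$results$p.value <= 1))
  expect_true(all(fit$results$statistic >= 1 / 51))
})

test_that("adaptive scan stops null genes early and escalates signal genes", {
  set.seed(123)
  n <- 200
  genes <- list()
  for (j in 1:5) {
    G <- toy_genotypes(n, 6, seed = 400 + j)
    Y <- rnorm(n)
    if (j == 3) Y <- Y + G %*% rep(0.8, 6)   # planted strong signal
    genes[[sprintf("g%02d", j)]] <- list(Y = as.numeric(Y), G = G)
  }
  res <- adaptive_scan(genes, method = "wAF",
                       policy = scan_policy(B_init = 100, B_max = 1000),
                       seed = 5)
  expect_identical(nrow(res), 5L)
  sig <- res[res$gene_id == "g03", ]
  expect_equal(sig$B, 1000)
  expect_true(sig$p.value < 5 / 100)
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))
})

test_that("scan policy validates its fields", {
  expect_error(scan_policy(B_init = 0), class = "afset_domain")
  expect_error(scan_policy(factor = 1), class = "afset_domain")
  expect_error(scan_policy(B_max = 10), class = "afset_domain")
})
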