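test_that("marginal score statistics match hand evaluation", {
  s <- compute_score(c(1, 1, 0, 0), cbind(c(2, 1, 0, 1)))
  expect_equal(unname(s$U), 1.0)
  expect_equal(unname(s$V[1, 1]), 0.5)
  expect_identical(s$trait_type, "binary")
  expect_identical(s$model, "marginal")

  s2 <- compute_score(c(1, 2, 3), cbind(c(0, 1, 2)))
  expect_equal(unname(s2$U), 2.0)
  expect_equal(unname(s2$V[1, 1]), 2.0)
  expect_identical(s2$trait_type, "continuous")
})

test_that("degenerate inputs raise classed errors", {
  expect_error(compute_score(c(1, 1, 0, 0), cbind(c(1, 1, 1, 1))),
               class = "afset_degenerate_variant")
  expect_error(compute_score(c(1, 1, 1, 1), cbind(c(0, 1, 2, 0))),
               class = "afset_degenerate_trait")
  expect_error(compute_score(c(1, 0, 1, 0), cbind(c(0, 1, 2, 0)),
                             C = cbind(rep(2, 4))),
               class = "afset_collinearity")
})

test_that("adjusted binary score matches the frozen straight-line oracle", {
  # oracle: Newton-Raphson logistic null (analytic gradient/Hessian,
  # tolerance 1e-14) + explicit summation of the score and covariance;
  # values frozen from that independent route
  Y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  C <- c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1, -0.3, 0.8)
  G <- matrix(c(0, 1, 2, 1, 0, 1, 2, 0,
                1, 0, 0, 2, 1, 0, 1, 1), 8, 2)
  s <- compute_score(Y, G, cbind(C))
  expect_equal(unname(s$U), c(1.55823317042358, 0.612979311554027), tolerance = 1e-10)
  expect_equal(unname(s$V[1, 1]), 1.08790947809844, tolerance = 1e-10)
  expect_equal(unname(s$V[1, 2]), -0.258597731405743, tolerance = 1e-10)
  expect_equal(unname(s$V[2, 2]), 0.605790872464974, tolerance = 1e-10)
  expect_equal(s$sigma_sq, 0.223671418679134, tolerance = 1e-10)
  expect_identical(s$model, "adjusted")
})

test_that("covariate orthogonal to trait and genotypes reduces to the marginal model", {
  G <- toy_genotypes(40, 3, seed = 7)
  set.seed(8)
  Y <- rnorm(40)
  # build a covariate orthogonal to centered Y and all centered G columns
  M <- cbind(scale(Y, scale = FALSE), scale(G, scale = FALSE), 1)
  cand <- rnorm(40)
  C <- cbind(residuals(lm(cand ~ M)))
  marg <- compute_score(Y, G)
  adj <- compute_score(Y, G, C)
  expect_equal(adj$U, marg$U, tolerance = 1e-8)
  expect_equal(adj$V, marg$V, tolerance = 1e-8)
})

test_that("continuous score is sign- and scale-equivariant, p-values invariant", {
  G <- toy_genotypes(50, 4, seed = 11)
  set.seed(12)
  Y <- rnorm(50)
  s <- compute_score(Y, G)
  neg <- compute_score(-Y, G)
  expect_equal(neg$U, -s$U)
  expect_equal(neg$V, s$V)
  a <- 3.7
  sca <- compute_score(a * Y, G)
  expect_equal(sca$U, a * s$U)
  expect_equal(sca$V, a^2 * s$V)
  expect_equal(marginal_pvalues(sca)$p_two, marginal_pvalues(s)$p_two)
})

test_that("marginal p-values obey the one-sided/two-sided identities", {
  G <- toy_genotypes(60, 5, seed = 21)
  set.seed(22)
  Y <- rbinom(60, 1, 0.5)
  mp <- marginal_pvalues(compute_score(Y, G))
  expect_equal(mp$p_plus + mp$p_minus, rep(1, 5), ignore_attr = TRUE)
  expect_equal(mp$p_two, 2 * pmin(mp$p_plus, mp$p_minus), ignore_attr = TRUE)
  # quantile anchors
  fake <- list(U = c(0, 1.959964, 1.644854), V = diag(3))
  mp2 <- marginal_pvalues(structure(fake, class = "af_score"))
  expect_equal(mp2$p_two[1], 1)
  expect_equal(mp2$p_plus[1], 0.5)
  expect_equal(mp2$p_two[2], 0.05, tolerance = 1e-6)
  expect_equal(mp2$p_plus[3], 0.05, tolerance = 1e-6)
  expect_equal(mp2$p_minus[3], 0.95, tolerance = 1e-6)
})

test_that("dosage (non-integer) genotypes are accepted", {
  set.seed(31)
  G <- matrix(runif(40, 0, 2), 20, 2)
  Y <- rnorm(20)
  expect_silent(s <- compute_score(Y, G))
  expect_length(s$U, 2)
})

test_that("drop_monomorphic removes constant columns with a warning", {
  G <- cbind(a = c(0, 1, 2), b = c(1, 1, 1))
  expect_warning(G2 <- drop_monomorphic(G), class = "afset_monomorphic_dropped")
  expect_identical(colnames(G2), "a")
  expect_silent(drop_monomorphic(G, quiet = TRUE))
})
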