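test_that("population model enforces its invariants", {
  expect_error(population_model(matrix(1.2, 2, 1)), "loadings")
  expect_error(population_model(matrix(0.8, 2, 1),
                                thresholds = c(1, 0, 2, 3)), "increasing")
  bad_phi <- matrix(c(1, 1.2, 1.2, 1), 2)
  L <- matrix(c(0.8, 0, 0, 0.8), 2, 2)
  expect_error(population_model(L, bad_phi), "positive definite")
  ## cross-loading rows violate simple structure
  expect_error(population_model(matrix(0.5, 2, 2), diag(2)), "single factor")
})

test_that("implied latent correlations follow the product rule", {
  L <- matrix(c(0.8, 0.8, 0, 0, 0, 0, 0.8, 0.8), 4, 2)
  Phi <- matrix(c(1, -0.37, -0.37, 1), 2)
  m <- population_model(L, Phi)
  R <- implied_latent_cor(m)
  expect_equal(R[1, 2], 0.64)
  expect_equal(R[1, 3], -0.2368)
  ## Monte-Carlo oracle for the cross-factor entry
  tabs <- with_seed_test(99, {
    f <- matrix(rnorm(2e5 * 2), ncol = 2) %*% chol(Phi)
    y1 <- 0.8 * f[, 1] + sqrt(1 - 0.64) * rnorm(2e5)
    y3 <- 0.8 * f[, 2] + sqrt(1 - 0.64) * rnorm(2e5)
    cor(y1, y3)
  })
  expect_lt(abs(tabs - (-0.2368)), 0.01)
})

test_that("generation is deterministic and respects the code range", {
  m <- pss14_population()
  t1 <- simulate_responses(m, 300, seed = 5)
  t2 <- simulate_responses(m, 300, seed = 5)
  expect_identical(t1, t2)
  codes <- as.matrix(t1[, m$items])
  expect_true(all(is.na(codes) | (codes >= 0 & codes <= 4)))
  expect_true(all(table(t1$person, t1$wave) <= 1))
  expect_error(simulate_responses(m, 0), "n must be")
})

test_that("zero loadings give independent items (alpha near zero)", {
  m <- population_model(matrix(0, 6, 1), thresholds = c(-1.2, -0.4, 0.4, 1.2))
  tab <- simulate_responses(m, 50000, waves = 1, missing_rate = 0, seed = 17)
  a <- cronbach_alpha(tab, m$items)
  expect_lt(abs(a), 0.02)
})

test_that("observed sum-score correlations match the analytic oracle", {
  m <- pss14_population()
  s1 <- c("item01", "item11"); s2 <- c("item06", "item07")
  implied <- as.numeric(implied_sumscore_cor(m, s1, s2))
  tab <- simulate_responses(m, 100000, waves = 1, missing_rate = 0, seed = 23)
  obs <- cor(rowSums(tab[, s1]), rowSums(tab[, s2]))
  expect_lt(abs(obs - implied), 0.04)
})

test_that("perfect stability with unit communality reproduces wave 1", {
  m <- population_model(matrix(1, 3, 1), retest_stability = 1)
  tab <- simulate_responses(m, 500, waves = 2, missing_rate = 0, seed = 31)
  w1 <- as.matrix(tab[tab$wave == 1, m$items])
  w2 <- as.matrix(tab[tab$wave == 2, m$items])
  expect_true(all(w1 == w2))
})

test_that("covariate targets verify within tolerance and fail for noise", {
  m <- pss14_population()
  tab <- simulate_responses(m, 100000, waves = 1, missing_rate = 0, seed = 41)
  chk <- verify_targets(tab, m)
  expect_true(all(chk$pass))
  expect_true(all(abs(chk$observed - chk$target) < 0.03))
  ## pure-noise covariate misses a 0.59 target at tolerance 0.15
  tab$noise <- with_seed_test(7, rnorm(nrow(tab)))
  spec <- covariate_spec("noise", c(helplessness = 1), 0.59,
                         m$covariates[[1]]$score_items)
  chk2 <- verify_targets(tab, list(spec))
  expect_false(chk2$pass)
  ## unknown score name errors
  bad <- covariate_spec("nope", c(helplessness = 1), 0.5, "item01")
  expect_error(verify_targets(tab, list(bad)), "unknown covariate")
})

test_that("polychoric estimates of generated pairs converge to the truth", {
  m <- pss14_population()
  tab <- big_table()
  pr <- acoshort:::polychoric_pair(tab$item01, tab$item02)
  expect_equal(pr$rho, implied_latent_cor(m)["item01", "item02"],
               tolerance = 0.02)
})
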