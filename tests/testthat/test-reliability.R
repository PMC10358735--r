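test_that("Cronbach's alpha closed forms hold", {
  x <- with_seed_test(3, rnorm(100000))
  perfect <- data.frame(a = x, b = x)
  expect_equal(cronbach_alpha(perfect), 1)
  ## standardized items at r = 0.5: alpha = 2r / (1 + r)
  y <- with_seed_test(4, 0.5 * x + sqrt(0.75) * rnorm(100000))
  a <- cronbach_alpha(data.frame(a = x, b = y))
  expect_equal(a, 2 * 0.5 / 1.5, tolerance = 0.01)
  indep <- with_seed_test(5, data.frame(a = rnorm(50000), b = rnorm(50000)))
  expect_lt(abs(cronbach_alpha(indep)), 0.02)
  expect_error(cronbach_alpha(data.frame(a = rep(1, 10), b = rep(2, 10))),
               "variance")
})

test_that("McDonald's omega formula and edge cases", {
  expect_equal(mcdonald_omega(rep(0.8, 4), rep(0.36, 4)),
               3.2^2 / (3.2^2 + 4 * 0.36))
  expect_equal(mcdonald_omega(rep(0.8, 4), rep(0.36, 4)), 0.8767,
               tolerance = 1e-4)
  expect_equal(mcdonald_omega(1, 0), 1)
  expect_equal(mcdonald_omega(rep(0, 3), rep(1, 3)), 0)
  expect_error(mcdonald_omega(rep(0, 2), rep(0, 2)), "undefined")
  expect_error(mcdonald_omega(0.5, -0.1), "negative")
})

test_that("retest ICC distinguishes agreement from consistency", {
  s <- with_seed_test(6, rnorm(5000, sd = 2))
  expect_equal(icc_retest(s, s), 1)
  indep <- with_seed_test(7, cbind(rnorm(50000), rnorm(50000)))
  expect_lt(abs(icc_retest(indep[, 1], indep[, 2])), 0.02)
  ## constant shift: consistency unaffected, agreement penalized
  shifted <- s + 2
  expect_equal(icc_retest(s, shifted, "consistency"), 1)
  expect_lt(icc_retest(s, shifted, "agreement"), 1)
  ## oracle: two-way ANOVA mean squares computed directly
  x1 <- with_seed_test(8, rnorm(2000)); x2 <- 0.7 * x1 + rnorm(2000, sd = 0.5)
  n <- 2000; X <- cbind(x1, x2)
  rm_ <- rowMeans(X); cm <- colMeans(X); gm <- mean(X)
  msr <- 2 * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2)
  mse <- sum((X - outer(rm_, c(1, 1)) - outer(rep(1, n), cm) + gm)^2) /
    (n - 1)
  icc_hand <- (msr - mse) / (msr + mse + 2 / n * (msc - mse))
  expect_equal(icc_retest(x1, x2), icc_hand)
  expect_error(icc_retest(1, 2), "paired")
})

test_that("alpha is bounded above by omega for congeneric items", {
  lam <- c(0.9, 0.7, 0.5, 0.3)
  f <- with_seed_test(9, rnorm(50000))
  X <- sapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(50000))
  a <- cronbach_alpha(as.data.frame(X))
  om_true <- mcdonald_omega(lam, 1 - lam^2)
  expect_lte(a, om_true + 0.005)
})

test_that("omega for two-item sets uses the equal-loading solution", {
  b <- study_bundle()
  om <- omega_from_items(b$pc, c("item02", "item14"))
  r <- b$pc$rho["item02", "item14"]
  lam <- sqrt(r)
  expect_equal(om, (2 * lam)^2 / ((2 * lam)^2 + 2 * (1 - r)))
})
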