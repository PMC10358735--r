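implied_polycor <- function(model, n = 1437) {
  R <- implied_latent_cor(model)
  structure(list(rho = R, avar = matrix(1 / n, nrow(R), ncol(R),
                                        dimnames = dimnames(R)),
                 n = n, items = rownames(R), thresholds = NULL,
                 method = "polychoric"), class = "polycor")
}

test_that("a just-identified one-factor model is saturated", {
  tab <- study_table()[study_table()$wave == 1, ]
  fit <- cfa(tab, cfa_spec(list(h = c("item01", "item02", "item03"))))
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
  expect_equal(fit$df, 0)
  expect_equal(fit$rmsea, 0)
})

test_that("fitting the exact implied matrix recovers the population", {
  m <- pss14_population()
  fit <- cfa(implied_polycor(m), cfa_spec(default_pools()))
  expect_true(fit$converged)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$loadings[fit$loadings != 0],
               m$loadings[m$loadings != 0], tolerance = 1e-4)
  expect_equal(fit$factor_cor[1, 2], -0.37, tolerance = 1e-4)
})

test_that("two-indicator factors are identified via unit variances", {
  tab <- study_table()[study_table()$wave == 1, ]
  fit <- cfa(tab, short_spec())
  expect_true(fit$converged)
  expect_equal(fit$df, 1)
  expect_true(all(abs(fit$loadings[fit$loadings != 0]) > 0.5))
})

test_that("fit_indices implements the CFI and RMSEA formulas", {
  fi <- fit_indices(150, 77, 4000, 91, 1437)
  expect_equal(fi$cfi, 1 - (150 - 77) / (4000 - 91))
  expect_lt(abs(fi$cfi - 0.9813), 1e-4)
  expect_equal(fi$rmsea, sqrt((150 - 77) / (77 * 1436)))
  expect_lt(abs(fi$rmsea - 0.0257), 1e-4)
  perfect <- fit_indices(77, 77, 4000, 91, 1437)
  expect_equal(perfect$cfi, 1)
  expect_equal(perfect$rmsea, 0)
  floorcase <- fit_indices(500, 10, 100, 91, 1437)
  expect_equal(floorcase$cfi, 0)
  expect_error(fit_indices(-1, 10, 100, 91, 1437), "negative")
})

test_that("chi-square difference testing matches the survival function", {
  f1 <- list(chisq = 100, df = 50); f2 <- list(chisq = 100, df = 40)
  d0 <- chi2_diff(f1, f2)
  expect_equal(d0$dchisq, 0)
  expect_equal(d0$p, 1)
  expect_lt(abs(chi2_diff(list(chisq = 10.4, df = 10),
                          list(chisq = 0, df = 0))$p - 0.407), 2e-3)
  expect_lt(abs(chi2_diff(list(chisq = 8.4, df = 2),
                          list(chisq = 0, df = 0))$p - 0.015), 5e-4)
  expect_error(chi2_diff(f2, f1), "nested")
})

test_that("freeing parameters never worsens the optimal discrepancy", {
  tab <- study_table()[study_table()$wave == 1, ]
  items <- c("item02", "item14", "item03", "item06", "item10", "item07")
  pc <- polychoric_matrix(tab, items)
  spec2 <- cfa_spec(list(h = c("item02", "item14", "item03"),
                         s = c("item06", "item10", "item07")))
  spec1 <- cfa_spec(list(g = items))
  f2 <- cfa(pc, spec2); f1 <- cfa(pc, spec1)
  expect_gte(f1$chisq, f2$chisq - 1e-6)   # two-factor nests one-factor
  expect_gte(f2$chisq, 0)
  ## adding a cross-loading can only decrease chisq
  spec2x <- cfa_spec(list(h = c("item02", "item14", "item03"),
                          s = c("item06", "item10", "item07")),
                     free_cross = data.frame(item = "item03", factor = "s"))
  f2x <- cfa(pc, spec2x)
  expect_lte(f2x$chisq, f2$chisq + 1e-6)
})

test_that("fit indices stored in a fit equal the standalone computation", {
  tab <- study_table()[study_table()$wave == 1, ]
  fit <- cfa(tab, short_spec())
  fi <- fit_indices(fit$chisq, fit$df, fit$baseline_chisq, fit$baseline_df,
                    fit$n)
  expect_equal(fit$cfi, fi$cfi)
  expect_equal(fit$rmsea, fi$rmsea)
})

test_that("ML and DWLS loadings agree on mild ordinal data", {
  m <- pss14_population()
  tab <- simulate_responses(m, 20000, waves = 1, missing_rate = 0, seed = 77)
  spec_d <- cfa_spec(default_pools())
  spec_m <- cfa_spec(default_pools(), estimator = "ML")
  fd <- cfa(tab, spec_d); fm <- cfa(tab, spec_m)
  expect_true(fd$converged && fm$converged)
  ## polychoric disattenuation exceeds Pearson-based ML slightly
  expect_equal(fm$loadings[fm$loadings != 0], fd$loadings[fd$loadings != 0],
               tolerance = 0.12)
})

test_that("modification candidates recover a planted cross-loading", {
  m0 <- pss14_population(covariates = NULL)
  L <- m0$loadings
  L["item03", "selfefficacy"] <- 0.4   # planted omitted cross-loading
  R <- L %*% m0$factor_cor %*% t(L); diag(R) <- 1
  pc <- structure(list(rho = R, avar = matrix(1 / 20000, 14, 14,
                                              dimnames = dimnames(R)),
                       n = 20000L, items = rownames(R), thresholds = NULL,
                       method = "polychoric"), class = "polycor")
  fit <- cfa(pc, cfa_spec(default_pools()))
  pool <- expand.grid(item = rownames(R),
                      factor = c("helplessness", "selfefficacy"),
                      stringsAsFactors = FALSE)
  pool <- pool[!(pool$item %in% default_pools()[[1]] &
                   pool$factor == "helplessness") &
               !(pool$item %in% default_pools()[[2]] &
                   pool$factor == "selfefficacy"), ]
  mc <- modification_candidates(fit, pc, pool)
  expect_equal(mc$item[1], "item03")
  expect_equal(mc$factor[1], "selfefficacy")
  ## a perfectly fitting model yields only negligible drops
  fit0 <- cfa(implied_polycor(pss14_population()), cfa_spec(default_pools()))
  mc0 <- modification_candidates(fit0, implied_polycor(pss14_population()),
                                 pool[1:4, ])
  expect_true(all(mc0$dchisq < 0.1, na.rm = TRUE))
  expect_error(modification_candidates(fit, pc, pool[0, ]), "empty")
})
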