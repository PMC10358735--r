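make_scale_table <- function() {
  data.frame(person = 1:4, wave = 1L, group = "g",
             item01 = c(2, NA, 2, 1), item02 = c(2, 2, NA, 2),
             item03 = c(2, 3, NA, 3))
}

test_that("person-mean imputation follows the one-missing rule", {
  tab <- make_scale_table()
  sc <- scale_def("s", c("item01", "item02", "item03"))
  out <- impute_missing(tab, list(sc))
  ## person 2: one missing, remaining mean (2 + 3) / 2
  expect_equal(out$table$item01[2], 2.5)
  ## person 3: two missing -> flagged, values left missing
  expect_true(out$table$.unusable_s[3])
  expect_true(is.na(out$table$item02[3]))
  expect_equal(out$log$imputed, 1L)
  expect_equal(out$log$unusable, 1L)
  ## constant remainder imputes that constant
  tab2 <- data.frame(item01 = NA_real_, item02 = 2, item03 = 2)
  out2 <- impute_missing(tab2, list(sc))
  expect_equal(out2$table$item01, 2)
  ## no missing -> unchanged, zero log
  tab3 <- data.frame(item01 = 1, item02 = 2, item03 = 3)
  out3 <- impute_missing(tab3, list(sc))
  expect_equal(out3$table[, sc$items], tab3)
  expect_equal(out3$log$imputed + out3$log$unusable, 0L)
  expect_error(impute_missing(tab3, list(scale_def("x", "item99"))), "absent")
})

test_that("reverse scoring and summation behave as specified", {
  sc <- scale_def("s", c("i1", "i2", "i3"), reverse = "i1", max_code = 4)
  tab <- data.frame(i1 = 0, i2 = 2, i3 = 3)
  expect_equal(score_scale(tab, sc), 4 + 2 + 3)
  sc2 <- scale_def("s", c("i1", "i2", "i3"), max_code = 4)
  expect_equal(score_scale(data.frame(i1 = 1, i2 = 2, i3 = 3), sc2), 6)
  expect_equal(score_scale(data.frame(i1 = 4, i2 = 4, i3 = 4), sc2), 12)
  expect_error(score_scale(data.frame(i1 = 5, i2 = 0, i3 = 0), sc2),
               "outside")
  ## reversal is an involution
  x <- data.frame(i1 = c(0, 1, 4), i2 = 1, i3 = 2)
  twice <- 4 - (4 - x$i1)
  expect_equal(twice, x$i1)
})

test_that("item screening flags by the joint Shapiro + moment rule", {
  sym <- data.frame(item01 = rep(0:4, times = c(10, 20, 40, 20, 10)))
  d <- describe_items(sym, "item01")
  expect_equal(d$skewness, 0, tolerance = 1e-10)
  expect_false(grepl("skewness", d$reason))
  skewed <- data.frame(item01 = rep(0:4, times = c(250, 30, 10, 6, 4)))
  d2 <- describe_items(skewed, "item01")
  expect_gt(d2$skewness, 1.5)
  expect_true(d2$flagged)
  cst <- data.frame(item01 = rep(2, 50))
  d3 <- describe_items(cst, "item01")
  expect_true(d3$flagged)
  expect_match(d3$reason, "constant")
})

test_that("generated item skewness stays in the mild range", {
  d <- describe_items(big_table())
  expect_true(all(d$skewness > -0.06 - 0.05 & d$skewness < 0.77))
  expect_true(all(abs(d$kurtosis) < 1.5))
})

test_that("polychoric correlation handles canonical tables", {
  x <- rep(c(0, 0, 1, 1), 25); y <- rep(c(0, 1, 0, 1), 25)
  expect_equal(acoshort:::polychoric_pair(x, y)$rho, 0, tolerance = 1e-6)
  z <- rep(0:4, each = 20)
  expect_equal(acoshort:::polychoric_pair(z, z)$rho, 0.999)
  expect_error(polychoric_matrix(data.frame(item01 = rep(1, 50),
                                            item02 = rep(0:4, 10))),
               "item01")
})

test_that("polychoric is symmetric and matches Pearson for mild data", {
  tab <- big_table()
  p12 <- acoshort:::polychoric_pair(tab$item12, tab$item13)
  p21 <- acoshort:::polychoric_pair(tab$item13, tab$item12)
  expect_equal(p12$rho, p21$rho, tolerance = 1e-5)
  ## attenuation check at |rho| <= 0.3, symmetric cuts
  r_pearson <- cor(tab$item12, tab$item13)
  expect_lt(abs(p12$rho - r_pearson), 0.03)
})
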