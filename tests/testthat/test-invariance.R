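test_that("the ladder requires at least two adequate groups", {
  tab <- study_table()[study_table()$wave == 1, ]
  tab1 <- tab; tab1$group <- "only"
  expect_error(invariance_ladder(tab1, short_spec()), "2 groups")
  tab2 <- tab; tab2$group <- c("a", rep("b", nrow(tab) - 1))
  expect_error(invariance_ladder(tab2, short_spec()), "at least")
})

test_that("constraints are nested: chisq non-decreasing up the ladder", {
  tab <- study_table()[study_table()$wave == 1, ]
  lad <- invariance_ladder(tab, short_spec())
  chis <- vapply(lad$fits, `[[`, 0, "chisq")
  dfs <- vapply(lad$fits, `[[`, 0, "df")
  expect_true(all(diff(chis) >= -1e-6))
  expect_true(all(diff(dfs) > 0))
  expect_true(all(vapply(lad$fits, `[[`, TRUE, "converged")))
  ## clean data holds every level
  expect_true(all(lad$comparisons$p > 0.01))
})

test_that("a planted loading difference is detected and localized", {
  m <- shortform_population()
  m$group_deltas <- list("2" = list(loadings = c(item03 = -0.35)))
  spec <- cfa_spec(list(helplessness = c("item02", "item14", "item03", "item08"),
                        selfefficacy = c("item06", "item10", "item07", "item04")))
  tab <- simulate_responses(m, 1437, waves = 1, missing_rate = 0, seed = 303)
  lad <- invariance_ladder(tab, spec, levels = c("configural", "metric"))
  expect_equal(lad$comparisons$decision[1], "reject")
  pr <- partial_release(lad, "metric")
  expect_equal(pr$freed[1], "item03")
  expect_true(pr$established)
  expect_length(pr$freed, 1)
})

test_that("partial release degenerates sensibly", {
  tab <- study_table()[study_table()$wave == 1, ]
  lad <- invariance_ladder(tab, short_spec(),
                           levels = c("configural", "metric"))
  ## metric holds on clean data: nothing to free
  pr <- partial_release(lad, "metric")
  expect_length(pr$freed, 0)
  expect_true(pr$established)
  ## max_freed = 0 on a failing level reports not established
  m <- shortform_population()
  m$group_deltas <- list("2" = list(loadings = c(item14 = -0.4)))
  tab2 <- simulate_responses(m, 1437, waves = 1, missing_rate = 0, seed = 71)
  lad2 <- invariance_ladder(tab2, short_spec(),
                            levels = c("configural", "metric"))
  if (lad2$comparisons$decision[1] == "reject") {
    pr2 <- partial_release(lad2, "metric", max_freed = 0)
    expect_false(pr2$established)
    expect_length(pr2$freed, 0)
  }
})

test_that("group offsets shift thresholds where planted", {
  m <- shortform_population()
  m$group_deltas <- list("2" = list(thresholds = list(item06 = rep(0.5, 4))))
  tab <- simulate_responses(m, 20000, waves = 1, missing_rate = 0, seed = 88)
  g <- sort(unique(tab$group))
  th1 <- acoshort:::poly_thresholds(tab$item06[tab$group == g[1]])
  th2 <- acoshort:::poly_thresholds(tab$item06[tab$group == g[2]])
  expect_lt(abs(mean(th2 - th1) - 0.5), 0.06)
  ## untouched item unchanged
  ua <- acoshort:::poly_thresholds(tab$item02[tab$group == g[1]])
  ub <- acoshort:::poly_thresholds(tab$item02[tab$group == g[2]])
  expect_lt(abs(mean(ub - ua)), 0.06)
})
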