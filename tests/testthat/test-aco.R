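test_that("pheromone mapping is 0.5 at every cut-off and monotone", {
  crits <- default_criteria()
  at_thr <- c(cfi = 0.96, rmsea = 0.05, omega_min = 0.85, icc_min = 0.70,
              covariate_dev = 0.15)
  phis <- vapply(crits, function(cr)
    acoshort:::pheromone_phi(at_thr[[cr$extractor]], cr), 0)
  expect_equal(unname(phis), rep(0.5, 5))
  expect_equal(sum(phis), 2.5)
  ## direction-respecting monotonicity
  cfi_cr <- crits[[1]]; rmsea_cr <- crits[[2]]
  expect_gt(acoshort:::pheromone_phi(0.98, cfi_cr),
            acoshort:::pheromone_phi(0.94, cfi_cr))
  expect_gt(acoshort:::pheromone_phi(0.03, rmsea_cr),
            acoshort:::pheromone_phi(0.07, rmsea_cr))
  expect_error(criterion("x", "cfi", "higher", 0.9, scale = 0), "scale")
})

test_that("itemset sampling is pheromone-proportional", {
  pool <- list(f = paste0("i", 1:7))
  tau <- setNames(rep(1, 7), pool$f)
  draws <- with_seed_test(11, replicate(40000, paste(sort(
    sample_itemset(tau, pool, 2)$f), collapse = "+")))
  tab <- table(draws)
  expect_equal(length(tab), 21)
  ## chi-square uniformity over all 21 pairs at alpha = 0.01
  chi <- sum((tab - 40000 / 21)^2 / (40000 / 21))
  expect_lt(chi, qchisq(0.99, 20))
  ## concentrated pheromone dominates
  tau2 <- setNames(c(9999, rep(0.0001, 6)), pool$f)
  draws2 <- with_seed_test(12, replicate(2000,
    sample_itemset(tau2, pool, 1)$f))
  expect_gt(mean(draws2 == "i1"), 0.999)
  expect_error(sample_itemset(tau, pool, 8), "pool")
})

test_that("solution evaluation reflects the fitted short form", {
  b <- study_bundle()
  sol <- evaluate_solution(list(helplessness = c("item02", "item14"),
                                selfefficacy = c("item06", "item10")), b)
  expect_true(sol$converged)
  expect_gt(sol$raw["cfi"], 0.95)
  expect_gt(sol$raw["omega_min"], 0.85)
  expect_lt(sol$raw["covariate_dev"], 0.15)
  expect_lte(sol$Phi, 5)
  ## item sets disjoint across factors
  expect_length(intersect(sol$items[[1]], sol$items[[2]]), 0)
})

test_that("ACO runs are deterministic and respect degenerate configs", {
  b <- study_bundle()
  cfg <- aco_config(n_ants = 10, n_iterations = 5, seed = 3)
  r1 <- run_aco(b, config = cfg)
  r2 <- run_aco(b, config = cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best$items, r2$best$items)
  ## global-best pheromone never decreases along the trace
  expect_true(all(diff(r1$trace$best_Phi) >= 0))
  ## a 2+2 pool has a single candidate, found at iteration 1
  b2 <- aco_bundle(study_table(),
                   pools = list(helplessness = c("item02", "item14"),
                                selfefficacy = c("item06", "item10")))
  r3 <- run_aco(b2, config = aco_config(n_ants = 2, n_iterations = 2, seed = 1))
  expect_equal(r3$best$items$helplessness, c("item02", "item14"))
  ## zero-weight criteria deposit nothing: pheromone stays uniform
  crits0 <- lapply(default_criteria(), function(cr) { cr$weight <- 0; cr })
  r4 <- run_aco(b2, crits0, aco_config(n_ants = 2, n_iterations = 3,
                                       evaporation = 1, seed = 1))
  expect_true(all(r4$tau == r4$tau[1]))
})

test_that("ACO with consensus matches the exhaustive oracle", {
  b <- study_bundle()
  bf <- brute_force_optimum(b)
  expect_equal(bf$n_candidates, choose(7, 2)^2)
  cons <- repeat_runs(b, config = aco_config(seed = 91))
  expect_gte(cons$consistency, 4)
  expect_identical(cons$modal$items, bf$best$items)
  ## optimality against random subsets
  rand <- with_seed_test(13, replicate(200, {
    sel <- lapply(b$pools, sample, 2)
    evaluate_solution(sel, b)$Phi
  }))
  expect_true(all(bf$best$Phi >= rand - 1e-9))
  expect_error(brute_force_optimum(b, k = 2, cap = 10), "cap")
})

test_that("unconstrained selection gravitates to a dominant factor", {
  help_items <- sprintf("item%02d", c(1, 2, 3, 8, 11, 12, 14))
  self_items <- sprintf("item%02d", c(4, 5, 6, 7, 9, 10, 13))
  L <- matrix(0, 14, 2, dimnames = list(sprintf("item%02d", 1:14),
                                        c("helplessness", "selfefficacy")))
  L[help_items, 1] <- 0.85
  L[self_items, 2] <- 0.35
  m <- population_model(L, matrix(c(1, -0.37, -0.37, 1), 2))
  tab <- simulate_responses(m, 1437, waves = 2, missing_rate = 0, seed = 61)
  b <- aco_bundle(tab, pools = list(any = sprintf("item%02d", 1:14)),
                  covariate_targets = NULL)
  crits <- default_criteria()[1:3]   # fit + reliability only
  bf <- brute_force_optimum(b, crits, k = 4, cap = 1500)
  expect_true(all(bf$best$items$any %in% help_items))
})
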