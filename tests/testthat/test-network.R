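test_that("nonparanormal transform is rank-preserving and standardized", {
  z <- with_seed_test(21, rnorm(10000))
  tz <- npn_transform(data.frame(z = z))$z
  expect_gt(cor(tz, z), 0.99)
  ## monotone (Winsorized tails tie, so non-strict)
  expect_true(all(diff(tz[order(z)]) >= 0))
  x <- with_seed_test(22, rexp(5000))
  tx <- npn_transform(data.frame(x = x))$x
  expect_lt(abs(mean(tx)), 0.05)
  expect_equal(var(tx), 1, tolerance = 0.02)
  expect_error(npn_transform(data.frame(c = rep(1, 100))), "constant")
  expect_error(npn_transform(data.frame(a = 1:10)), "20 rows")
})

test_that("the penalty path starts empty and the chain support is exact", {
  X <- chain_data()
  S <- cor(X)
  net <- ebic_glasso(S, nrow(X))
  expect_equal(net$path$E[1], 0)
  ## at an empty graph the EBIC is the diagonal-model deviance
  expect_equal(net$path$ebic[1], -2 * net$path$loglik[1])
  ## planted chain recovered exactly
  W <- net$weights
  expect_true(all(W[cbind(1:4, 2:5)] != 0))
  expect_equal(sum(W[upper.tri(W)] != 0), 4)
  ## edge count non-increasing in lambda
  expect_true(all(diff(net$path$E) >= 0))
  ## EBIC selection is at least as sparse as the smallest penalty
  expect_lte(sum(W[upper.tri(W)] != 0), net$path$E[nrow(net$path)])
  ## identity input stays empty everywhere
  neti <- ebic_glasso(diag(4), 1000)
  expect_true(all(neti$weights == 0))
})

test_that("EBIC reduces to BIC at gamma zero, term by term", {
  X <- chain_data()
  net <- ebic_glasso(cor(X), nrow(X), gamma = 0)
  expect_equal(net$path$ebic,
               -2 * net$path$loglik + net$path$E * log(nrow(X)))
})

test_that("partial correlations from precision match residual regression", {
  expect_true(all(partial_cor_from_precision(diag(3)) == 0))
  ## 3-node chain precision: non-adjacent pair has zero partial correlation
  Om <- matrix(c(1.5, -0.5, 0, -0.5, 1.4, -0.5, 0, -0.5, 1.5), 3)
  W <- partial_cor_from_precision(Om)
  expect_equal(W[1, 3], 0)
  ## residual-regression oracle in closed form from the covariance
  S <- solve(Om)
  r12_3 <- (S[1, 2] / sqrt(S[1, 1] * S[2, 2]) -
              S[1, 3] * S[2, 3] / sqrt(S[1, 1] * S[3, 3] * S[2, 2] * S[3, 3])) /
    sqrt((1 - S[1, 3]^2 / (S[1, 1] * S[3, 3])) *
           (1 - S[2, 3]^2 / (S[2, 2] * S[3, 3])))
  expect_equal(W[1, 2], r12_3, tolerance = 1e-10)
  expect_error(partial_cor_from_precision(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("network weights are insensitive to the nonparanormal transform
           on already-normal data", {
  X <- chain_data()
  n1 <- pcor_network(X, transform = FALSE)
  n2 <- pcor_network(X, transform = TRUE)
  expect_equal(n1$weights, n2$weights, tolerance = 0.02)
})

test_that("centrality indices follow the star/chain geometry", {
  W <- matrix(0, 5, 5); W[1, 2:5] <- W[2:5, 1] <- 0.5
  ct <- centrality_indices(W)
  expect_equal(ct$strength, c(2, 0.5, 0.5, 0.5, 0.5))
  expect_gt(ct$betweenness[1], 0)
  expect_true(all(ct$betweenness[-1] == 0))
  Wc <- matrix(0, 3, 3); Wc[1, 2] <- Wc[2, 1] <- 0.4; Wc[2, 3] <- Wc[3, 2] <- 0.4
  ctc <- centrality_indices(Wc)
  expect_gt(ctc$betweenness[2], ctc$betweenness[1])
  expect_equal(ctc$betweenness[c(1, 3)], c(0, 0))
  empty <- centrality_indices(matrix(0, 4, 4))
  expect_true(all(empty$strength == 0 & empty$closeness == 0 &
                    empty$betweenness == 0))
})

test_that("bootstrap edge intervals separate true and null edges", {
  X <- chain_data(n = 2000, seed = 66)[1:2000, ]
  expect_error(bootstrap_edges(X, B = 50), "100")
  ci <- bootstrap_edges(X, B = 120, seed = 5)
  true_edge <- paste(ci$node1, ci$node2) %in%
    paste0("V", 1:4, " V", 2:5)
  expect_true(all(ci$lower[true_edge] > 0))
  null_cover <- ci$lower[!true_edge] <= 0 & ci$upper[!true_edge] >= 0
  expect_gte(mean(null_cover), 0.9)
})

test_that("case-drop stability separates redundant from noise networks", {
  expect_error(casedrop_stability(chain_data(), drop_grid = numeric()),
               "empty")
  ## strong heterogeneous signal: centrality order survives heavy dropping
  f <- with_seed_test(31, rnorm(4000))
  lam <- c(0.95, 0.85, 0.75, 0.6, 0.45)
  Xr <- as.data.frame(sapply(lam, function(l)
    l * f + sqrt(1 - l^2) * rnorm(4000)))
  cs_r <- casedrop_stability(Xr, drop_grid = c(0.2, 0.5, 0.7), B = 12,
                             seed = 2)
  expect_equal(cs_r$cs, 0.7)
  ## pure noise: centralities unstable, CS collapses
  Xn <- with_seed_test(32, as.data.frame(matrix(rnorm(400 * 5), ncol = 5)))
  cs_n <- casedrop_stability(Xn, drop_grid = c(0.2, 0.5), B = 12, seed = 3)
  expect_equal(cs_n$cs, 0)
})
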