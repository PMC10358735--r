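## shared fixtures, built lazily once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## two-wave study-scale table from the marker/distractor population
study_table <- function() fixture("study_table", function()
  simulate_responses(shortform_population(), 1437, waves = 2,
                     missing_rate = 0, seed = 20260901))

study_bundle <- function() fixture("study_bundle", function()
  aco_bundle(study_table()))

## large one-wave table from the published-loadings population
big_table <- function() fixture("big_table", function()
  simulate_responses(pss14_population(), 50000, waves = 1,
                     missing_rate = 0, seed = 8121))

short_spec <- function(items = list(helplessness = c("item02", "item14"),
                                    selfefficacy = c("item06", "item10")))
  cfa_spec(items)

## chain-graph fixture: 5 nodes, partial correlations 0.4 along the chain
chain_data <- function(n = 10000, seed = 55) fixture(paste0("chain", n), function() {
  p <- 5
  Om <- diag(p)
  for (i in 1:(p - 1)) Om[i, i + 1] <- Om[i + 1, i] <- -0.4
  S <- solve(Om)
  D <- diag(1 / sqrt(diag(S)))
  S <- D %*% S %*% D
  with_seed_test(seed, as.data.frame(matrix(rnorm(n * p), ncol = p) %*% chol(S)))
})

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
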