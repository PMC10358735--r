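#' Simulate two-wave, two-group ordinal item responses
#'
#' Draws person-level factor scores (wave-2 factors follow a latent
#' first-order autoregression with the model's retest stability), builds
#' latent item responses \code{loadings . factors + unique noise},
#' discretizes them by the item thresholds into codes \code{0..K}, and
#' generates covariates from the wave-1 factors with calibrated weights.
#' Fully reproducible from the master seed.
#'
#' @param model a [population_model()].
#' @param n number of persons (>= 1).
#' @param waves 1 or 2.
#' @param group_prop named group proportions (must sum to 1).
#' @param missing_rate completely-at-random missingness on item cells.
#' @param seed master seed; all child streams derive from it.
#' @return a data.frame with columns \code{person}, \code{wave},
#'   \code{group}, the item columns, and one column per covariate
#'   (covariates are trait scores: identical across waves).
#' @export
simulate_responses <- function(model, n, waves = 2,
                               group_prop = c(female = 0.5, male = 0.5),
                               missing_rate = 0.001, seed = 1L) {
  if (n < 1) stop_("n must be >= 1")
  if (!waves %in% 1:2) stop_("waves must be 1 or 2")
  if (abs(sum(group_prop) - 1) > 1e-8) stop_("group proportions must sum to 1")
  if (missing_rate < 0 || missing_rate >= 1) stop_("missing_rate must lie in [0, 1)")
  p <- length(model$items); q <- length(model$factors)
  bifactor <- !is.null(model$general)

  group <- with_seed(child_seed(seed, "group"), {
    sample(names(group_prop), n, replace = TRUE, prob = group_prop)
  })
  groups <- names(group_prop)

  cal <- NULL
  if (!is.null(model$covariates))
    cal <- lapply(model$covariates, function(s) calibrate_covariate(model, s))

  Phi <- model$factor_cor
  cPhi <- chol(Phi)
  f1 <- with_seed(child_seed(seed, "factors", 1), {
    matrix(rnorm(n * q), n, q) %*% cPhi
  })
  G1 <- if (bifactor) with_seed(child_seed(seed, "general", 1), rnorm(n)) else NULL

  make_wave <- function(wave, f, G) {
    out <- matrix(NA_integer_, n, p, dimnames = list(NULL, model$items))
    eps <- with_seed(child_seed(seed, "unique", wave), matrix(rnorm(n * p), n, p))
    for (g in groups) {
      idx <- which(group == g)
      if (!length(idx)) next
      gp <- group_params(model, match(g, groups))
      comm <- rowSums((gp$loadings %*% Phi) * gp$loadings)
      if (bifactor) comm <- comm + gp$general^2
      usd <- sqrt(pmax(1 - comm, 0))
      ystar <- f[idx, , drop = FALSE] %*% t(gp$loadings)
      if (bifactor) ystar <- ystar + outer(G[idx], gp$general)
      ystar <- ystar + eps[idx, , drop = FALSE] %*% diag(usd, p)
      for (j in seq_len(p)) {
        out[idx, j] <- as.integer(
          rowSums(outer(ystar[, j], gp$thresholds[j, ], `>`)))
      }
    }
    out
  }

  X1 <- make_wave(1L, f1, G1)
  rows <- list(data.frame(person = seq_len(n), wave = 1L, group = group, X1,
                          check.names = FALSE))
  if (waves == 2) {
    s <- model$retest_stability
    Svar <- Phi - diag(s, q) %*% Phi %*% diag(s, q)
    innov <- with_seed(child_seed(seed, "factors", 2), {
      if (max(abs(Svar)) < 1e-12) matrix(0, n, q)
      else matrix(rnorm(n * q), n, q) %*% chol(Svar + diag(1e-12, q))
    })
    f2 <- sweep(f1, 2, s, `*`) + innov
    G2 <- if (bifactor) {
      sg <- mean(s)
      g_in <- with_seed(child_seed(seed, "general", 2), rnorm(n))
      sg * G1 + sqrt(1 - sg^2) * g_in
    } else NULL
    X2 <- make_wave(2L, f2, G2)
    rows[[2]] <- data.frame(person = seq_len(n), wave = 2L, group = group, X2,
                            check.names = FALSE)
  }
  tab <- do.call(rbind, rows)

  if (!is.null(cal)) {
    for (i in seq_along(cal)) {
      nm <- model$covariates[[i]]$name
      e <- with_seed(child_seed(seed, "covariate", nm), rnorm(n))
      val <- as.numeric(f1 %*% cal[[i]]$alpha) + cal[[i]]$resid_sd * e
      tab[[nm]] <- val[tab$person]
    }
  }

  if (missing_rate > 0) {
    itemcols <- model$items
    mi <- with_seed(child_seed(seed, "missing"), {
      matrix(runif(nrow(tab) * p) < missing_rate, nrow(tab), p)
    })
    for (j in seq_len(p)) tab[[itemcols[j]]][mi[, j]] <- NA_integer_
  }
  rownames(tab) <- NULL
  tab
}

#' Verify covariate correlation targets in a generated table
#'
#' For each covariate spec of the model, computes the observed Pearson
#' correlation between the covariate and the ordinal sum of its
#' calibration items (wave 1), the absolute deviation from the target,
#' and a pass flag at the spec's tolerance.
#'
#' @param table a table from [simulate_responses()].
#' @param model the generating [population_model()] (holds the targets),
#'   or a list of [covariate_spec()]s.
#' @return data.frame with columns covariate, observed, target,
#'   deviation, tolerance, pass.
#' @export
verify_targets <- function(table, model) {
  specs <- if (inherits(model, "population_model")) model$covariates else model
  if (is.null(specs)) stop_("no covariate targets to verify")
  w1 <- table[table$wave == 1L, , drop = FALSE]
  out <- lapply(specs, function(s) {
    if (!s$name %in% names(w1)) stop_("unknown covariate '%s'", s$name)
    if (!all(s$score_items %in% names(w1)))
      stop_("unknown score items for covariate '%s'", s$name)
    S <- rowSums(w1[, s$score_items, drop = FALSE])
    obs <- cor(S, w1[[s$name]], use = "complete.obs")
    data.frame(covariate = s$name, observed = obs, target = s$target,
               deviation = abs(obs - s$target), tolerance = s$tolerance,
               pass = abs(obs - s$target) <= s$tolerance)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read an item response table as CSV
#' @param table a response table.
#' @param path file path.
#' @export
write_responses <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Serialize a population model (with generation settings) as JSON
#'
#' @param model a [population_model()].
#' @param path output path.
#' @param seed optional master seed to record alongside the model.
#' @export
write_model_json <- function(model, path, seed = NULL) {
  out <- list(
    items = model$items, factors = model$factors,
    loadings = as.data.frame(model$loadings),
    factor_cor = model$factor_cor,
    thresholds = as.data.frame(model$thresholds),
    general = model$general,
    retest_stability = model$retest_stability,
    group_deltas = model$group_deltas,
    covariates = model$covariates,
    seed = seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
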