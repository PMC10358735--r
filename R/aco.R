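#' Define an optimization criterion for item selection
#'
#' Each criterion maps a raw psychometric value through a logistic
#' pheromone function centred at its cut-off,
#' \deqn{\phi = 1 / (1 + \exp(-(x - thr) / s))}
#' (sign flipped for lower-is-better criteria), so that \eqn{\phi = 0.5}
#' exactly at the cut-off.  The overall pheromone of a candidate item set
#' is the weighted sum of its criterion pheromones.
#'
#' @param name criterion name.
#' @param extractor one of \code{"cfi"}, \code{"rmsea"},
#'   \code{"omega_min"}, \code{"icc_min"}, \code{"covariate_dev"}.
#' @param direction \code{"higher"} or \code{"lower"}.
#' @param threshold the cut-off at which \eqn{\phi = 0.5}.
#' @param scale logistic scale \code{s} (default: 10\% of the threshold,
#'   halved).
#' @param weight weight in the pheromone sum (default 1).
#' @return a \code{criterion} list.
#' @export
criterion <- function(name, extractor, direction = c("higher", "lower"),
                      threshold, scale = NULL, weight = 1) {
  direction <- match.arg(direction)
  extractor <- match.arg(extractor, c("cfi", "rmsea", "omega_min",
                                      "icc_min", "covariate_dev"))
  scale <- scale %||% (abs(threshold) * 0.1 / 2)
  if (scale <= 0) stop_("criterion scale must be positive")
  if (weight < 0) stop_("criterion weight must be non-negative")
  list(name = name, extractor = extractor, direction = direction,
       threshold = threshold, scale = scale, weight = weight)
}

#' Default criteria for short-form selection
#'
#' CFI >= 0.96, RMSEA <= 0.05, McDonald's omega >= 0.85 (worse factor),
#' retest ICC >= 0.70 (worse factor) and mean absolute covariate-target
#' deviation <= 0.15, all unit-weighted.
#'
#' @return list of [criterion()]s.
#' @export
default_criteria <- function() {
  list(
    criterion("cfi", "cfi", "higher", 0.96),
    criterion("rmsea", "rmsea", "lower", 0.05),
    criterion("omega", "omega_min", "higher", 0.85),
    criterion("icc", "icc_min", "higher", 0.70),
    criterion("covdev", "covariate_dev", "lower", 0.15, scale = 0.15 / 2)
  )
}

pheromone_phi <- function(x, crit) {
  z <- (x - crit$threshold) / crit$scale
  if (crit$direction == "lower") z <- -z
  1 / (1 + exp(-z))
}

#' Default covariate validity targets
#' @return data.frame (name, factor, target) of target correlations
#'   between covariates and short-form factor sum scores.
#' @export
default_covariate_targets <- function() {
  data.frame(name = c("mhp", "recovery", "ase"),
             factor = c("helplessness", "helplessness", "selfefficacy"),
             target = c(0.59, -0.53, 0.44))
}

#' Bundle a two-wave table for item selection
#'
#' Precomputes the wave-1 polychoric matrix over all pool items (with
#' asymptotic variances, shared by every candidate CFA), aligns wave-2
#' responses by person for retest ICCs, extracts covariate columns and
#' sets up the evaluation cache.
#'
#' @param table two-wave response table ([simulate_responses()] layout).
#' @param pools named list of item pools per factor.
#' @param covariate_targets data.frame as [default_covariate_targets()]
#'   (names must exist as columns); \code{NULL} disables the validity
#'   criterion.
#' @return an \code{aco_bundle} object.
#' @export
aco_bundle <- function(table, pools = default_pools(),
                       covariate_targets = default_covariate_targets()) {
  items <- unlist(pools, use.names = FALSE)
  w1 <- table[table$wave == 1L, , drop = FALSE]
  has_w2 <- any(table$wave == 2L)
  w2 <- if (has_w2) table[table$wave == 2L, , drop = FALSE] else NULL
  if (has_w2) {
    pid <- intersect(w1$person, w2$person)
    w1m <- w1[match(pid, w1$person), , drop = FALSE]
    w2m <- w2[match(pid, w2$person), , drop = FALSE]
  } else { w1m <- w1; w2m <- NULL }
  if (!is.null(covariate_targets)) {
    missing_cov <- setdiff(covariate_targets$name, names(w1))
    if (length(missing_cov))
      stop_("covariate column(s) absent: %s", paste(missing_cov, collapse = ", "))
  }
  pc <- polychoric_matrix(w1, items)
  structure(list(pools = pools, items = items, pc = pc,
                 w1 = w1, w1m = w1m, w2m = w2m,
                 covariate_targets = covariate_targets,
                 cache = new.env(parent = emptyenv())),
            class = "aco_bundle")
}

sub_polycor <- function(pc, items) {
  structure(list(rho = pc$rho[items, items], avar = pc$avar[items, items],
                 thresholds = pc$thresholds[items], n = pc$n,
                 items = items, method = "polychoric"), class = "polycor")
}

#' Evaluate a candidate item set
#'
#' Fits the correlated-factors CFA (DWLS on the bundled polychorics) to
#' the selected items, computes McDonald's omega per factor (worse factor
#' retained), the retest ICC of each factor's sum score (worse factor
#' retained) and the mean absolute deviation of covariate correlations
#' from their targets, then maps each raw value through its criterion
#' pheromone.  A non-convergent CFA yields total pheromone 0 (penalized,
#' not fatal).
#'
#' @param sel named list: selected item names per factor.
#' @param bundle an [aco_bundle()].
#' @param criteria list of [criterion()]s.
#' @return an \code{aco_solution}: items, raw criterion values, per-
#'   criterion \code{phi}, total pheromone \code{Phi}, convergence flag.
#' @export
evaluate_solution <- function(sel, bundle, criteria = default_criteria()) {
  key <- paste(unlist(lapply(sel, sort)), collapse = "|")
  hit <- bundle$cache[[key]]
  if (!is.null(hit)) return(hit)
  items <- unlist(sel, use.names = FALSE)
  fit <- tryCatch(cfa(sub_polycor(bundle$pc, items), cfa_spec(sel)),
                  error = function(e) NULL)
  raw <- c(cfi = NA_real_, rmsea = NA_real_, omega_min = NA_real_,
           icc_min = NA_real_, covariate_dev = NA_real_)
  ok <- !is.null(fit) && fit$converged
  if (ok) {
    raw["cfi"] <- fit$cfi
    raw["rmsea"] <- fit$rmsea
    raw["omega_min"] <- min(vapply(sel, function(it)
      omega_from_items(sub_polycor(bundle$pc, it), it), 0))
    if (!is.null(bundle$w2m)) {
      raw["icc_min"] <- min(vapply(sel, function(it) {
        icc_retest(rowSums(bundle$w1m[, it, drop = FALSE]),
                   rowSums(bundle$w2m[, it, drop = FALSE]))
      }, 0))
    }
    if (!is.null(bundle$covariate_targets)) {
      ct <- bundle$covariate_targets
      devs <- vapply(seq_len(nrow(ct)), function(r) {
        s <- rowSums(bundle$w1[, sel[[ct$factor[r]]], drop = FALSE])
        abs(cor(s, bundle$w1[[ct$name[r]]], use = "complete.obs") - ct$target[r])
      }, 0)
      raw["covariate_dev"] <- mean(devs)
    }
  }
  phis <- vapply(criteria, function(cr) {
    x <- raw[[cr$extractor]]
    if (!ok || is.na(x)) 0 else pheromone_phi(x, cr)
  }, 0)
  names(phis) <- vapply(criteria, `[[`, "", "name")
  Phi <- if (ok) sum(phis * vapply(criteria, `[[`, 0, "weight")) else 0
  sol <- structure(list(items = lapply(sel, sort), raw = raw, phi = phis,
                        Phi = Phi, converged = ok), class = "aco_solution")
  bundle$cache[[key]] <- sol
  sol
}

#' @export
print.aco_solution <- function(x, digits = 3, ...) {
  cat("Item solution:",
      paste(vapply(names(x$items), function(f)
        sprintf("%s={%s}", f, paste(x$items[[f]], collapse = ",")), ""),
        collapse = "  "), "\n")
  cat("Raw:", paste(sprintf("%s=%.3f", names(x$raw), x$raw), collapse = ", "), "\n")
  cat(sprintf("Total pheromone Phi = %.3f%s\n", x$Phi,
              if (!x$converged) " [non-convergent CFA]" else ""))
  invisible(x)
}

#' ACO configuration
#'
#' @param k items selected per factor.
#' @param n_ants ants per iteration (default 40).
#' @param n_iterations iteration cap (default 30).
#' @param evaporation pheromone retention multiplier in (0, 1]
#'   (\code{tau <- evaporation * tau + deposit}; default 0.70).
#' @param n_runs independent runs for the consensus (default 5).
#' @param patience early stop after this many iterations without a new
#'   global best (default: no early stop within the iteration cap).
#' @param floor absolute pheromone floor (default 0.01).
#' @param floor_frac max-min-style relative floor: pheromone never falls
#'   below this fraction of the current maximum (default 0.1), keeping
#'   exploration alive once the elitist deposit concentrates.
#' @param seed master seed.
#' @param deposit \code{"global"} (elitist, default) or \code{"iteration"}
#'   best deposits its pheromone.
#' @return an \code{aco_config} list.
#' @export
aco_config <- function(k = 2, n_ants = 40, n_iterations = 30,
                       evaporation = 0.70, n_runs = 5,
                       patience = n_iterations,
                       floor = 0.01, floor_frac = 0.1, seed = 1L,
                       deposit = c("global", "iteration")) {
  deposit <- match.arg(deposit)
  if (k < 1 || n_ants < 1 || n_iterations < 1 || n_runs < 1)
    stop_("k, n_ants, n_iterations, n_runs must be >= 1")
  if (evaporation <= 0 || evaporation > 1)
    stop_("evaporation must lie in (0, 1]")
  if (floor <= 0) stop_("pheromone floor must be positive")
  if (floor_frac < 0 || floor_frac >= 1)
    stop_("floor_frac must lie in [0, 1)")
  list(k = k, n_ants = n_ants, n_iterations = n_iterations,
       evaporation = evaporation, n_runs = n_runs, patience = patience,
       floor = floor, floor_frac = floor_frac, seed = seed,
       deposit = deposit)
}

#' Sample an item set proportional to pheromone
#'
#' Within each factor pool, draws \code{k} distinct items sequentially
#' without replacement with probability proportional to the current
#' pheromone levels.
#'
#' @param tau named numeric vector of pheromone per item.
#' @param pools named list of item pools.
#' @param k items per factor.
#' @return named list of selected items per factor.
#' @export
sample_itemset <- function(tau, pools, k) {
  lapply(pools, function(pool) {
    if (length(pool) < k) stop_("pool smaller than k")
    sel <- character(k)
    avail <- pool
    for (i in seq_len(k)) {
      pr <- tau[avail]
      pick <- avail[sample.int(length(avail), 1L, prob = pr)]
      sel[i] <- pick
      avail <- setdiff(avail, pick)
    }
    sel
  })
}

#' Run one ant-colony-optimization item search
#'
#' Pheromone starts equal across items (the first iteration is a
#' pseudo-random selection).  Each iteration every ant samples and is
#' evaluated; if the iteration's best beats the global best the latter is
#' updated; pheromone then evaporates (\code{tau <- evaporation * tau})
#' and the best solution's items receive a deposit equal to its total
#' pheromone, floored below.  Stops at the iteration cap or when the
#' global best has not changed for \code{patience} iterations.
#'
#' @param bundle an [aco_bundle()].
#' @param criteria list of [criterion()]s.
#' @param config an [aco_config()].
#' @param seed overrides \code{config$seed}.
#' @return an object of class \code{"aco_fit"}: best solution, final
#'   pheromone, iteration trace.
#' @export
run_aco <- function(bundle, criteria = default_criteria(),
                    config = aco_config(), seed = NULL) {
  seed <- seed %||% config$seed
  tau <- setNames(rep(1, length(bundle$items)), bundle$items)
  best <- NULL
  trace <- NULL
  stale <- 0L
  with_seed(seed, {
    for (iter in seq_len(config$n_iterations)) {
      it_best <- NULL
      any_ok <- FALSE
      for (a in seq_len(config$n_ants)) {
        sel <- sample_itemset(tau, bundle$pools, config$k)
        sol <- evaluate_solution(sel, bundle, criteria)
        if (sol$converged) any_ok <- TRUE
        if (is.null(it_best) || sol$Phi > it_best$Phi) it_best <- sol
      }
      improved <- !is.null(it_best) &&
        (is.null(best) || it_best$Phi > best$Phi)
      if (improved) { best <- it_best; stale <- 0L } else stale <- stale + 1L
      if (any_ok) {
        dep_sol <- if (config$deposit == "global") best else it_best
        tau <- config$evaporation * tau
        tau[unlist(dep_sol$items)] <- tau[unlist(dep_sol$items)] + dep_sol$Phi
        tau <- pmax(tau, config$floor, config$floor_frac * max(tau))
      }
      trace <- rbind(trace, data.frame(
        iteration = iter, best_Phi = best$Phi,
        best_items = paste(unlist(best$items), collapse = ","),
        stale = stale))
      if (stale >= config$patience) break
    }
  })
  structure(list(best = best, tau = tau, trace = trace, seed = seed,
                 config = config), class = "aco_fit")
}

#' @export
print.aco_fit <- function(x, ...) {
  cat(sprintf("ACO run (seed %d): %d iterations\n", x$seed, nrow(x$trace)))
  print(x$best)
  invisible(x)
}

#' @export
plot.aco_fit <- function(x, ...) {
  plot(x$trace$iteration, x$trace$best_Phi, type = "s",
       xlab = "iteration", ylab = "best total pheromone", ...)
  invisible(x)
}

solution_key <- function(sol) paste(unlist(sol$items), collapse = ",")

#' Repeat ACO runs and form a consensus
#'
#' Runs [run_aco()] \code{n_runs} times with independently derived
#' seeds; the modal solution is the most frequent best item set, ties
#' broken by higher pheromone.
#'
#' @inheritParams run_aco
#' @return class \code{"aco_consensus"}: modal solution, per-run bests,
#'   consistency count.
#' @export
repeat_runs <- function(bundle, criteria = default_criteria(),
                        config = aco_config()) {
  runs <- lapply(seq_len(config$n_runs), function(r)
    run_aco(bundle, criteria, config,
            seed = child_seed(config$seed, "aco-run", r)))
  keys <- vapply(runs, function(r) solution_key(r$best), "")
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    phi_of <- vapply(top, function(k)
      max(vapply(runs[keys == k], function(r) r$best$Phi, 0)), 0)
    top <- top[which.max(phi_of)]
  }
  modal <- runs[[which(keys == top)[1L]]]$best
  structure(list(modal = modal, runs = runs, keys = keys,
                 consistency = max(tab), n_runs = config$n_runs),
            class = "aco_consensus")
}

#' @export
print.aco_consensus <- function(x, ...) {
  cat(sprintf("ACO consensus over %d runs: modal solution in %d run(s)\n",
              x$n_runs, x$consistency))
  print(x$modal)
  invisible(x)
}

#' Exhaustive-search oracle over all candidate item sets
#'
#' Enumerates every per-factor k-subset combination (e.g. two 7-item
#' pools at k = 2 give \code{choose(7,2)^2 = 441} candidates), evaluates
#' each and returns the pheromone argmax.  Deterministic.
#'
#' @param bundle an [aco_bundle()].
#' @param criteria list of [criterion()]s.
#' @param k items per factor.
#' @param cap refuse enumeration above this candidate count.
#' @return list with \code{best} solution and \code{n_candidates}.
#' @export
brute_force_optimum <- function(bundle, criteria = default_criteria(),
                                k = 2, cap = 10000) {
  subsets <- lapply(bundle$pools, function(pool)
    combn(pool, k, simplify = FALSE))
  n_cand <- prod(vapply(subsets, length, 0L))
  if (n_cand > cap)
    stop_("candidate space %d exceeds cap %d; use run_aco", n_cand, cap)
  grid <- expand.grid(lapply(subsets, seq_along))
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    sel <- lapply(seq_along(subsets), function(fi)
      subsets[[fi]][[grid[r, fi]]])
    names(sel) <- names(bundle$pools)
    sol <- evaluate_solution(sel, bundle, criteria)
    if (is.null(best) || sol$Phi > best$Phi) best <- sol
  }
  list(best = best, n_candidates = n_cand)
}
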