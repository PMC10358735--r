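#' Default study configuration
#'
#' Bundles the settings of the full short-form derivation pipeline on
#' synthetic data: the marker/distractor two-factor population
#' ([shortform_population()]) at n = 1437 with two waves and two groups,
#' the scale definitions, the model-comparison list (one-factor,
#' two-factor, bifactor), the ACO settings (40 ants, 30 iterations,
#' evaporation 0.70, 5 runs, 2 items per factor), the invariance ladder
#' and a network preset of the two short-form factors plus the three
#' covariates.
#'
#' @param seed master seed.
#' @param n sample size.
#' @param n_boot bootstrap draws for edge intervals.
#' @return a config list for [run_study()].
#' @export
default_study_config <- function(seed = 1L, n = 1437, n_boot = 1000) {
  pools <- default_pools()
  list(
    seed = seed,
    data = list(model = shortform_population(), n = n, waves = 2,
                group_prop = c(female = 0.528, male = 0.472),
                missing_rate = 0.001),
    scales = list(
      scale_def("helplessness", pools$helplessness),
      scale_def("selfefficacy", pools$selfefficacy)),
    pools = pools,
    aco = aco_config(k = 2, seed = seed),
    criteria = default_criteria(),
    covariate_targets = default_covariate_targets(),
    invariance = TRUE,
    network = list(nodes = c("helplessness", "selfefficacy",
                             "mhp", "recovery", "ase")),
    n_boot = n_boot
  )
}

validate_config <- function(config, table) {
  cols <- names(table)
  for (sc in config$scales) {
    bad <- setdiff(sc$items, cols)
    if (length(bad)) stop_("config scale '%s' references absent column(s): %s",
                           sc$name, paste(bad, collapse = ", "))
  }
  if (!is.null(config$covariate_targets)) {
    bad <- setdiff(config$covariate_targets$name, cols)
    if (length(bad)) stop_("config names unknown covariate(s): %s",
                           paste(bad, collapse = ", "))
  }
  net_cov <- setdiff(config$network$nodes, c(names(config$pools), cols))
  if (length(net_cov)) stop_("network preset names unknown node(s): %s",
                             paste(net_cov, collapse = ", "))
  invisible(TRUE)
}

#' Run the full short-form derivation study
#'
#' Executes the stages in order: simulate (or load) the two-wave table;
#' person-mean imputation and item descriptives; long-form model
#' comparison (one-factor vs two-factor vs bifactor, DWLS, chi-square
#' difference tests); ACO short-form selection with multi-run consensus;
#' reliability of the selected factors; gender invariance ladder of the
#' selected short form; regularized partial-correlation network of the
#' short-form factor scores and covariates.  Identical config + seed
#' give identical results.
#'
#' @param config a config list, see [default_study_config()].
#' @param stages subset of
#'   \code{c("data","prepare","compare","select","reliability",
#'   "invariance","network")}; later stages require earlier ones.
#' @return an object of class \code{"study_report"}.
#' @export
run_study <- function(config = default_study_config(),
                      stages = c("data", "prepare", "compare", "select",
                                 "reliability", "invariance", "network")) {
  all_stages <- c("data", "prepare", "compare", "select", "reliability",
                  "invariance", "network")
  stages <- all_stages[all_stages %in% stages]
  rep <- list(seed = config$seed, stages = stages, log = character())
  note <- function(...) rep$log <<- c(rep$log, sprintf(...))

  ## data
  if (!is.null(config$data$csv)) {
    tab <- read_responses(config$data$csv)
    note("loaded %d rows from %s", nrow(tab), config$data$csv)
  } else {
    d <- config$data
    tab <- simulate_responses(d$model, d$n, waves = d$waves,
                              group_prop = d$group_prop,
                              missing_rate = d$missing_rate,
                              seed = child_seed(config$seed, "data"))
    note("simulated n=%d, waves=%d (seed stream 'data')", d$n, d$waves)
  }
  validate_config(config, tab)
  rep$n <- length(unique(tab$person))

  ## prepare: imputation feeds scoring-based outputs; ordinal stages
  ## (polychorics, CFA, invariance) keep the raw codes with pairwise
  ## deletion, since person-mean imputation creates fractional categories
  tab_imp <- tab
  if ("prepare" %in% stages) {
    imp <- impute_missing(tab, config$scales)
    tab_imp <- imp$table
    rep$imputation <- imp$log
    rep$descriptives <- describe_items(tab[tab$wave == 1L, ],
                                       unlist(lapply(config$scales, `[[`, "items")))
    if (!is.null(config$covariate_targets) && !is.null(config$data$model))
      rep$target_check <- verify_targets(tab_imp, config$data$model)
  }
  w1 <- tab[tab$wave == 1L, , drop = FALSE]

  ## long-form model comparison
  if ("compare" %in% stages) {
    pools <- config$pools
    pc <- polychoric_matrix(w1, unlist(pools))
    fits <- list(
      one_factor = cfa(pc, cfa_spec(list(general = unlist(pools, use.names = FALSE)))),
      two_factor = cfa(pc, cfa_spec(pools)),
      bifactor = cfa(pc, cfa_spec(pools, bifactor = TRUE)))
    cmp <- data.frame(model = names(fits),
                      chisq = vapply(fits, `[[`, 0, "chisq"),
                      df = vapply(fits, `[[`, 0, "df"),
                      cfi = vapply(fits, `[[`, 0, "cfi"),
                      rmsea = vapply(fits, `[[`, 0, "rmsea"),
                      converged = vapply(fits, `[[`, TRUE, "converged"))
    d12 <- chi2_diff(fits$one_factor, fits$two_factor)
    d2b <- chi2_diff(fits$two_factor, fits$bifactor)
    rep$model_comparison <- list(
      table = cmp,
      tests = data.frame(
        comparison = c("one vs two", "two vs bifactor"),
        dchisq = c(d12$dchisq, d2b$dchisq),
        ddf = c(d12$ddf, d2b$ddf),
        p = c(d12$p, d2b$p)))
    rep$fits <- fits
  }

  ## short-form selection
  if ("select" %in% stages) {
    bundle <- aco_bundle(tab, config$pools, config$covariate_targets)
    cons <- repeat_runs(bundle, config$criteria, config$aco)
    rep$selection <- cons
    rep$selected_items <- cons$modal$items
    note("ACO consensus %d/%d", cons$consistency, cons$n_runs)
  }

  ## reliability of the selection
  if ("reliability" %in% stages && !is.null(rep$selected_items)) {
    rep$reliability <- lapply(rep$selected_items, function(it)
      reliability_report(tab, it))
  }

  ## invariance of the selected short form
  if ("invariance" %in% stages && isTRUE(config$invariance) &&
      !is.null(rep$selected_items)) {
    spec <- cfa_spec(rep$selected_items)
    lad <- tryCatch(invariance_ladder(w1, spec, "group"),
                    error = function(e) { note("invariance failed: %s",
                                               conditionMessage(e)); NULL })
    rep$invariance <- lad
    if (!is.null(lad) && !is.null(lad$comparisons)) {
      failing <- lad$comparisons$comparison[lad$comparisons$decision == "reject"]
      if (length(failing)) {
        lvl <- sub(".* vs ", "", failing[1])
        rep$partial <- partial_release(lad, lvl)
        note("partial search at %s level: freed %s", lvl,
             paste(rep$partial$freed, collapse = ", "))
      }
    }
  }

  ## network of short-form factor scores + covariates
  if ("network" %in% stages && !is.null(rep$selected_items)) {
    nodes <- config$network$nodes
    X <- data.frame(row.names = seq_len(nrow(w1)))
    for (nd in nodes) {
      X[[nd]] <- if (nd %in% names(rep$selected_items))
        rowSums(w1[, rep$selected_items[[nd]], drop = FALSE])
      else w1[[nd]]
    }
    X <- X[complete.cases(X), , drop = FALSE]
    net <- pcor_network(X)
    rep$network <- net
    rep$centrality <- centrality_indices(net)
    if (!is.null(config$n_boot) && config$n_boot >= 100)
      rep$edge_ci <- bootstrap_edges(X, B = config$n_boot,
                                     seed = child_seed(config$seed, "boot"))
  }

  structure(rep, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Short-form derivation report (seed %d, n = %d)\n",
              x$seed, x$n))
  if (!is.null(x$model_comparison)) {
    cat("\n-- Long-form model comparison --\n")
    tb <- x$model_comparison$table
    tb$chisq <- round(tb$chisq, 1); tb$cfi <- round(tb$cfi, 3)
    tb$rmsea <- round(tb$rmsea, 3)
    print(tb, row.names = FALSE)
    print(transform(x$model_comparison$tests, dchisq = round(dchisq, 1),
                    p = signif(p, 3)), row.names = FALSE)
  }
  if (!is.null(x$selection)) {
    cat("\n-- Short-form selection --\n")
    print(x$selection)
  }
  if (!is.null(x$reliability)) {
    cat("\n-- Reliability of selected factors --\n")
    for (f in names(x$reliability)) {
      r <- x$reliability[[f]]
      cat(sprintf("  %s: alpha = %.3f, omega = %.3f, ICC = %.3f\n",
                  f, r$alpha, r$omega, r$icc))
    }
  }
  if (!is.null(x$invariance)) {
    cat("\n-- Invariance of the short form --\n")
    print(x$invariance)
  }
  if (!is.null(x$network)) {
    cat("\n-- Partial-correlation network --\n")
    print(x$network)
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report a [run_study()] result.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  out <- list(
    seed = report$seed, n = report$n, log = report$log,
    descriptives = report$descriptives,
    model_comparison = report$model_comparison[c("table", "tests")],
    selected_items = report$selected_items,
    selection_consistency = report$selection$consistency,
    selection_raw = as.list(report$selection$modal$raw),
    selection_Phi = report$selection$modal$Phi,
    reliability = report$reliability,
    invariance = if (!is.null(report$invariance))
      report$invariance$comparisons,
    network_edges = if (!is.null(report$network)) edge_list(report$network),
    centrality = report$centrality)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
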