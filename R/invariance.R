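## Multigroup ordinal CFA and the measurement-invariance ladder.
##
## Delta-parameterization: each item's latent response in group g has total
## variance v_gj (fixed to 1 in the reference group), implied standardized
## correlation rho_gij = (L Phi L')_ij / sqrt(v_i v_j) and standardized
## thresholds (tau_jk - (L mu_g)_j) / sqrt(v_gj).  Thresholds are saturated
## (and therefore omitted from the discrepancy) as long as they are free per
## group; once constrained equal (scalar level) they enter the weighted
## least-squares discrepancy with multinomial delta-method weights, and
## group-2+ latent means and item scales are freed.  At the strict level
## item unique variances are equated instead, which determines the scales.
##
## Ladder decisions use a mean-scaled chi-square difference: the naive
## difference of diagonally weighted discrepancies is conservative, so it
## is rescaled by c = tr((V_r - V_f) Gamma) / ddf, with Gamma the
## influence-function covariance of the threshold and polychoric moment
## estimates and V = W - W D (D' W D)^{-1} D' W the residual weight
## operator of each fit (D = Jacobian of the implied moments).

inv_levels <- c("configural", "metric", "scalar", "strict")
mg_level_num <- function(level) match(level, inv_levels)

## Influence-function covariance of the moment vector
## [thresholds by item; polychoric correlations, lower-tri column-major]
## for one group's data.  Thresholds: psi_k(x) = (1{x<=k} - c_k)/phi(tau_k).
## Two-step polychoric: psi_rho = -(s_rho(x) + sum_v H_rho,tau_v psi_v(x))
## / H_rho,rho with numeric derivatives of the cell log-probabilities.
mom_influence <- function(X, pc) {
  items <- pc$items
  X <- as.matrix(X[, items, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  p <- length(items)
  K <- vapply(items, function(it) length(pc$thresholds[[it]]), 0L)
  cat_idx <- matrix(0L, n, p)
  for (j in seq_len(p))
    cat_idx[, j] <- findInterval(X[, j], sort(unique(X[, j])))
  sumK <- sum(K)
  npair <- p * (p - 1L) / 2L
  psi <- matrix(0, n, sumK + npair)
  off <- c(0L, cumsum(K))
  for (j in seq_len(p)) {
    tau <- pc$thresholds[[items[j]]]
    ck <- pnorm(tau)
    for (k in seq_len(K[j]))
      psi[, off[j] + k] <- ((cat_idx[, j] <= k) - ck[k]) / dnorm(tau[k])
  }
  h <- 1e-4
  m <- sumK
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    m <- m + 1L
    th1 <- pc$thresholds[[items[i]]]; th2 <- pc$thresholds[[items[j]]]
    rho <- pc$rho[items[i], items[j]]
    rho <- max(min(rho, 0.995), -0.995)
    a <- K[i] + 1L
    cell <- (cat_idx[, j] - 1L) * a + cat_idx[, i]
    cnt <- tabulate(cell, nbins = a * (K[j] + 1L))
    phat <- cnt / n
    lp <- function(r, t1 = th1, t2 = th2)
      log(pmax(bvn_cell_probs(t1, t2, r), 1e-12))
    lp_p <- lp(rho + h); lp_m <- lp(rho - h); lp_0 <- lp(rho)
    s_rho <- (lp_p - lp_m) / (2 * h)
    d2 <- (lp_p - 2 * lp_0 + lp_m) / h^2
    Hrr <- sum(phat * d2)
    corr_term <- numeric(n)
    for (side in 1:2) {
      th <- if (side == 1) th1 else th2
      base <- if (side == 1) off[i] else off[j]
      for (k in seq_along(th)) {
        perturb <- function(d) { t <- th; t[k] <- t[k] + d; t }
        if (side == 1) {
          sp <- (lp(rho + h, t1 = perturb(h)) - lp(rho - h, t1 = perturb(h))) / (2 * h)
          sm <- (lp(rho + h, t1 = perturb(-h)) - lp(rho - h, t1 = perturb(-h))) / (2 * h)
        } else {
          sp <- (lp(rho + h, t2 = perturb(h)) - lp(rho - h, t2 = perturb(h))) / (2 * h)
          sm <- (lp(rho + h, t2 = perturb(-h)) - lp(rho - h, t2 = perturb(-h))) / (2 * h)
        }
        Hrt <- sum(phat * (sp - sm) / (2 * h))
        corr_term <- corr_term + Hrt * psi[, base + k]
      }
    }
    if (is.finite(Hrr) && Hrr < -1e-10)
      psi[, m] <- -(s_rho[cell] + corr_term) / Hrr
  }
  psi <- sweep(psi, 2, colMeans(psi))
  crossprod(psi) / (n * n)
}

## per-group sample moments: polychoric matrix, standardized thresholds
## with delta-method variances, and the influence covariance Gamma
mg_moments <- function(table, spec, group_col) {
  g <- as.character(table[[group_col]])
  groups <- sort(unique(g))
  if (length(groups) < 2) stop_("need >= 2 groups")
  lapply(setNames(groups, groups), function(gr) {
    sub <- table[g == gr, , drop = FALSE]
    pc <- polychoric_matrix(sub, spec$items)
    th <- pc$thresholds
    n <- pc$n
    tha <- lapply(spec$items, function(it) {
      tau <- th[[it]]
      cum <- pnorm(tau)
      cum * (1 - cum) / (n * dnorm(tau)^2)
    })
    names(tha) <- spec$items
    gamma <- mom_influence(sub, pc)
    list(pc = pc, thresholds = th, th_avar = tha, n = n, gamma = gamma)
  })
}

#' Fit a multigroup ordinal CFA at a given invariance level
#'
#' @param table response table with a group column (use one wave).
#' @param spec a [cfa_spec()] (DWLS estimator).
#' @param group_col name of the group column.
#' @param level one of \code{"configural"}, \code{"metric"},
#'   \code{"scalar"}, \code{"strict"} (each adds constraints to the
#'   previous one).
#' @param free_loadings,free_thresholds,free_residuals item names whose
#'   loadings / thresholds / unique variances stay group-specific despite
#'   the level (partial invariance).
#' @param moments precomputed moment cache (internal reuse).
#' @return an object of class \code{"mg_cfa"} (chisq, df, cfi, rmsea,
#'   per-group estimates, converged flag).
#' @export
mg_cfa <- function(table, spec, group_col = "group",
                   level = "configural",
                   free_loadings = character(),
                   free_thresholds = character(),
                   free_residuals = character(),
                   moments = NULL) {
  level <- match.arg(level, inv_levels)
  lv <- mg_level_num(level)
  P <- loading_pattern(spec)
  p <- nrow(P); q <- ncol(P)
  mom <- moments %||% mg_moments(table, spec, group_col)
  groups <- names(mom)
  G <- length(groups)
  items <- spec$items
  K <- vapply(items, function(it) length(mom[[1]]$thresholds[[it]]), 0L)
  if (any(vapply(mom, function(m) !identical(
    vapply(items, function(it) length(m$thresholds[[it]]), 0L), K), TRUE)))
    stop_("groups observe different category sets; cannot align thresholds")

  np_meas <- cfa_npar(spec, P)
  nl <- sum(P)
  nc <- if (spec$bifactor || q == 1L) 0L else q * (q - 1L) / 2L
  qq <- q + (if (spec$bifactor) 1L else 0L)

  share_load <- lv >= 2
  share_th <- lv >= 3
  idx_free_load <- which(items %in% free_loadings)
  idx_free_th <- which(items %in% free_thresholds)
  idx_free_res <- which(items %in% free_residuals)

  ## --- parameter layout -------------------------------------------------
  lay <- list(); pos <- 0L
  add <- function(name, len) {
    if (len > 0L) { lay[[name]] <<- pos + seq_len(len); pos <<- pos + len }
  }
  add("meas1", np_meas)
  for (g in groups[-1]) {
    if (!share_load) add(paste0("meas_", g), np_meas)
    else {
      add(paste0("fcor_", g), nc)
      add(paste0("pload_", g),
          length(idx_free_load) * (if (spec$bifactor) 2L else 1L))
    }
  }
  if (share_th) {
    add("thr", sum(K))
    for (g in groups[-1]) {
      add(paste0("mean_", g), qq)
      if (lv == 3L) add(paste0("scale_", g), p)
      if (lv == 4L) add(paste0("scale_", g), length(idx_free_res))
      add(paste0("pthr_", g), sum(K[idx_free_th]))
    }
  }
  npar_total <- pos

  nmom_cor <- G * p * (p - 1L) / 2L
  nmom_th <- if (share_th) G * sum(K) else 0L
  df <- nmom_cor + nmom_th - npar_total
  if (df < 0) stop_("under-identified multigroup model (df = %d)", df)

  lt <- lower.tri(diag(p))
  obs <- lapply(mom, function(m) {
    list(r = m$pc$rho[items, items][lt],
         wr = 1 / m$pc$avar[items, items][lt],
         t = unlist(m$thresholds[items]),
         wt = 1 / unlist(m$th_avar[items]),
         n = m$n)
  })
  obs_stack <- unlist(lapply(obs, function(o) if (share_th) c(o$t, o$r) else o$r))
  w_stack <- unlist(lapply(obs, function(o) if (share_th) c(o$wt, o$wr) else o$wr))

  th_starts <- unlist(mom[[1]]$thresholds[items])
  start <- numeric(npar_total)
  meas_start <- c(rep(0.6, nl), rep(0, nc), if (spec$bifactor) rep(0.4, p))
  start[lay$meas1] <- meas_start
  for (g in groups[-1]) {
    if (!is.null(lay[[paste0("meas_", g)]]))
      start[lay[[paste0("meas_", g)]]] <- meas_start
    if (!is.null(lay[[paste0("pload_", g)]]))
      start[lay[[paste0("pload_", g)]]] <- 0.6
  }
  if (share_th) start[lay$thr] <- th_starts
  for (g in groups[-1]) {
    if (!is.null(lay[[paste0("pthr_", g)]]))
      start[lay[[paste0("pthr_", g)]]] <- th_starts[
        unlist(lapply(idx_free_th, function(i)
          sum(K[seq_len(i - 1L)]) + seq_len(K[i])))]
  }
  th_offsets <- c(0L, cumsum(K))

  group_struct <- function(par, gi) {
    g <- groups[gi]
    if (gi == 1L || !share_load) {
      ix <- if (gi == 1L) lay$meas1 else lay[[paste0("meas_", g)]]
      im <- cfa_implied(par[ix], spec, P)
    } else {
      im <- cfa_implied(par[lay$meas1], spec, P)
      if (nc) {
        z <- par[lay[[paste0("fcor_", g)]]]
        Phi <- diag(q)
        Phi[upper.tri(Phi)] <- tanh(z)
        Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
        im$Phi <- Phi
      }
      if (length(idx_free_load)) {
        pl <- par[lay[[paste0("pload_", g)]]]
        k <- 0L
        for (i in idx_free_load) {
          f <- which(P[i, ])[1L]
          k <- k + 1L; im$L[i, f] <- pl[k]
          if (spec$bifactor) { k <- k + 1L; im$g[i] <- pl[k] }
        }
      }
      R <- im$L %*% im$Phi %*% t(im$L)
      if (!is.null(im$g)) R <- R + tcrossprod(im$g)
      im$comm <- diag(R); diag(R) <- 1; im$R <- R
    }
    im
  }

  implied_vec <- function(par) {
    out <- numeric(0)
    ims <- lapply(seq_len(G), group_struct, par = par)
    for (gi in seq_len(G)) {
      im <- ims[[gi]]
      g <- groups[gi]
      v <- rep(1, p)
      if (gi > 1L && share_th) {
        if (lv == 4L) {
          theta1 <- 1 - ims[[1L]]$comm
          v <- im$comm + theta1
          if (length(idx_free_res))
            v[idx_free_res] <- exp(par[lay[[paste0("scale_", g)]]])
        } else if (!is.null(lay[[paste0("scale_", g)]])) {
          v <- exp(par[lay[[paste0("scale_", g)]]])
        }
      }
      sv <- sqrt(pmax(v, 1e-8))
      Rg <- im$R / outer(sv, sv)
      if (share_th) {
        tau <- par[lay$thr]
        if (gi > 1L && length(idx_free_th)) {
          pt <- par[lay[[paste0("pthr_", g)]]]
          k <- 0L
          for (i in idx_free_th) {
            tau[th_offsets[i] + seq_len(K[i])] <- pt[k + seq_len(K[i])]
            k <- k + K[i]
          }
        }
        mu <- if (gi > 1L) par[lay[[paste0("mean_", g)]]] else rep(0, qq)
        Lfull <- if (spec$bifactor) cbind(im$L, im$g) else im$L
        shift <- as.numeric(Lfull %*% mu)
        tstd <- (tau - rep(shift, times = K)) / rep(sv, times = K)
        out <- c(out, tstd, Rg[lt])
      } else out <- c(out, Rg[lt])
    }
    out
  }

  objective <- function(par) sum(w_stack * (obs_stack - implied_vec(par))^2)

  opt <- tryCatch(
    optim(start, objective, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-10)),
    error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0
  if (is.null(opt)) opt <- list(par = start, value = objective(start),
                                convergence = 99L)

  chisq <- max(opt$value, 0)
  base_chisq <- sum(vapply(obs, function(o) sum(o$wr * o$r^2), 0))
  base_df <- nmom_cor
  ntot <- sum(vapply(obs, `[[`, 0, "n"))
  ## baseline has saturated (free) thresholds, so at scalar+ its df can be
  ## below the model df; the max() in the CFI denominator covers this case
  ncp_m <- max(chisq - df, 0)
  ncp_b <- max(base_chisq - base_df, ncp_m, 0)
  fi <- list(cfi = if (ncp_b == 0) 1 else 1 - ncp_m / ncp_b,
             rmsea = if (df == 0) 0 else sqrt(ncp_m / (df * (ntot - 1))))
  est <- lapply(seq_len(G), group_struct, par = opt$par)
  names(est) <- groups
  structure(list(
    spec = spec, level = level, groups = groups,
    free_loadings = free_loadings, free_thresholds = free_thresholds,
    free_residuals = free_residuals,
    chisq = chisq, df = df, baseline_chisq = base_chisq,
    baseline_df = base_df, cfi = fi$cfi, rmsea = fi$rmsea,
    n = ntot, converged = converged,
    estimates = lapply(est, function(e) list(loadings = e$L,
                                             factor_cor = e$Phi,
                                             general = e$g)),
    implied_fun = implied_vec, par = opt$par, w = w_stack,
    share_th = share_th, p_items = p, K = K
  ), class = c("mg_cfa"))
}

#' @export
print.mg_cfa <- function(x, ...) {
  cat(sprintf("Multigroup CFA [%s], %d groups, n = %d\n",
              x$level, length(x$groups), x$n))
  cat(sprintf("chisq(%d) = %.2f, CFI = %.3f, RMSEA = %.3f%s\n",
              x$df, x$chisq, x$cfi, x$rmsea,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

## Residual weight operator V = W - W D (D' W D)^{-1} D' W of one fit,
## embedded in the full per-group [thresholds; correlations] moment space
## (a saturated threshold block contributes a zero block).
mg_V_full <- function(fit, mom) {
  sumK <- sum(fit$K)
  npair <- fit$p_items * (fit$p_items - 1L) / 2L
  mg <- sumK + npair                           # full per-group dimension
  G <- length(mom)
  own <- if (fit$share_th) seq_len(mg) else sumK + seq_len(npair)
  sel <- unlist(lapply(seq_len(G) - 1L, function(gi) gi * mg + own))
  par <- fit$par; f0 <- fit$implied_fun(par)
  npar <- length(par)
  D <- matrix(0, length(f0), npar)
  h <- 1e-5
  for (k in seq_len(npar)) {
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    D[, k] <- (fit$implied_fun(pp) - fit$implied_fun(pm)) / (2 * h)
  }
  w <- fit$w
  WD <- D * w
  A <- crossprod(D, WD)
  Ainv <- tryCatch(solve(A), error = function(e)
    solve(A + diag(1e-8, nrow(A))))
  Vown <- diag(w, length(w)) - WD %*% Ainv %*% t(WD)
  V <- matrix(0, G * mg, G * mg)
  V[sel, sel] <- Vown
  V
}

mg_gamma_full <- function(mom) {
  mg <- nrow(mom[[1]]$gamma)
  G <- length(mom)
  Gam <- matrix(0, G * mg, G * mg)
  for (gi in seq_len(G)) {
    ix <- (gi - 1L) * mg + seq_len(mg)
    Gam[ix, ix] <- mom[[gi]]$gamma
  }
  Gam
}

#' Mean-scaled chi-square difference for multigroup fits
#'
#' Satorra-Bentler-type scaling of the naive DWLS difference: with
#' \code{U = V_r - V_f} (difference of the fits' residual weight
#' operators) and \code{Gamma} the influence-function covariance of the
#' moment estimates, \code{dchisq / c} with \code{c = tr(U Gamma) / ddf}
#' is referred to a chi-square with \code{ddf} degrees of freedom.
#' Falls back to the naive difference when the trace degenerates.
#'
#' @param fit_restricted,fit_free nested [mg_cfa()] fits.
#' @param moments the shared moment cache (with influence covariances).
#' @return list with dchisq, ddf, scaling, statistic, p.
#' @export
scaled_chi2_diff <- function(fit_restricted, fit_free, moments) {
  ddf <- fit_restricted$df - fit_free$df
  if (ddf <= 0) stop_("models not nested: ddf must be positive")
  dchisq <- max(fit_restricted$chisq - fit_free$chisq, 0)
  tr1 <- tryCatch({
    UG <- (mg_V_full(fit_restricted, moments) -
             mg_V_full(fit_free, moments)) %*% mg_gamma_full(moments)
    sum(diag(UG))
  }, error = function(e) NA_real_)
  cc <- if (is.finite(tr1) && tr1 > 0) tr1 / ddf else 1
  stat <- dchisq / cc
  list(dchisq = dchisq, ddf = ddf, scaling = cc, statistic = stat,
       p = pchisq(stat, ddf, lower.tail = FALSE))
}

#' Measurement-invariance ladder across groups
#'
#' Fits the configural, metric, scalar and strict multigroup models in
#' order, compares each adjacent pair with the mean-scaled chi-square
#' difference test and records a decision at \code{alpha}.  A
#' non-convergent level truncates the ladder with a flag.
#'
#' @param table one-wave response table.
#' @param spec a [cfa_spec()].
#' @param group_col group column name (>= 2 non-empty groups, each with
#'   at least \code{min_n} rows).
#' @param levels subset of the ladder to fit (ordered).
#' @param alpha significance level for the difference decisions.
#' @param min_n per-group sample-size floor.
#' @param scaled use the mean-scaled difference (default) or the naive
#'   difference.
#' @return an object of class \code{"invariance_ladder"}: per-level fits,
#'   comparison table, decisions.
#' @export
invariance_ladder <- function(table, spec, group_col = "group",
                              levels = inv_levels, alpha = 0.05,
                              min_n = 100, scaled = TRUE) {
  levels <- inv_levels[sort(match(levels, inv_levels))]
  tabg <- table(as.character(table[[group_col]]))
  if (length(tabg) < 2) stop_("need >= 2 groups")
  if (any(tabg < min_n))
    stop_("every group needs at least %d rows", min_n)
  mom <- mg_moments(table, spec, group_col)
  fits <- list(); comp <- NULL; truncated <- FALSE
  for (i in seq_along(levels)) {
    f <- mg_cfa(table, spec, group_col, level = levels[i], moments = mom)
    fits[[levels[i]]] <- f
    if (!f$converged) { truncated <- TRUE; break }
    if (i > 1) {
      d <- if (scaled) scaled_chi2_diff(f, fits[[levels[i - 1L]]], mom)
           else c(chi2_diff(f, fits[[levels[i - 1L]]]), scaling = 1)
      comp <- rbind(comp, data.frame(
        comparison = paste(levels[i - 1L], "vs", levels[i]),
        dchisq = d$dchisq, ddf = d$ddf, scaling = d$scaling, p = d$p,
        decision = ifelse(d$p < alpha, "reject", "hold")))
    }
  }
  structure(list(fits = fits, comparisons = comp, alpha = alpha,
                 truncated = truncated, moments = mom, spec = spec,
                 group_col = group_col, table = table, scaled = scaled),
            class = "invariance_ladder")
}

#' @export
print.invariance_ladder <- function(x, ...) {
  cat("Measurement-invariance ladder\n")
  tab <- do.call(rbind, lapply(names(x$fits), function(l) {
    f <- x$fits[[l]]
    data.frame(model = l,
               `chisq(df)` = sprintf("%.1f (%d)", f$chisq, f$df),
               CFI = round(f$cfi, 3), RMSEA = round(f$rmsea, 3),
               check.names = FALSE)
  }))
  print(tab, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nComparisons:\n")
    cc <- x$comparisons
    cc$dchisq <- round(cc$dchisq, 1)
    cc$scaling <- round(cc$scaling, 2)
    cc$p <- signif(cc$p, 3)
    print(cc, row.names = FALSE)
  }
  if (x$truncated) cat("\n(ladder truncated: non-convergence)\n")
  invisible(x)
}

#' Greedy partial-invariance search
#'
#' For a failing ladder level, repeatedly frees the constrained parameter
#' whose release yields the largest chi-square drop, refits and re-tests
#' against the preceding level, stopping when the difference test is
#' non-significant or \code{max_freed} parameters have been released.
#'
#' @param ladder an [invariance_ladder()].
#' @param level the failing level (\code{"metric"}, \code{"scalar"} or
#'   \code{"strict"}).
#' @param pool item names eligible for release (default: all spec items).
#' @param max_freed maximum number of releases (default 4).
#' @return list with \code{freed} (items in release order), \code{fit}
#'   (final partial fit), \code{test} (final comparison),
#'   \code{established} (logical).
#' @export
partial_release <- function(ladder, level, pool = NULL, max_freed = 4) {
  stopifnot(inherits(ladder, "invariance_ladder"))
  level <- match.arg(level, inv_levels[-1])
  lv <- mg_level_num(level)
  spec <- ladder$spec
  pool <- pool %||% spec$items
  prev <- ladder$fits[[inv_levels[lv - 1L]]]
  if (is.null(prev)) stop_("ladder lacks the preceding level fit")
  arg <- switch(level, metric = "free_loadings",
                scalar = "free_thresholds", strict = "free_residuals")
  base_fit <- ladder$fits[[level]]
  refit <- function(freed) {
    args <- list(table = ladder$table, spec = spec,
                 group_col = ladder$group_col, level = level,
                 moments = ladder$moments)
    if (!is.null(base_fit)) {
      args$free_loadings <- base_fit$free_loadings
      args$free_thresholds <- base_fit$free_thresholds
    }
    args[[arg]] <- freed
    do.call(mg_cfa, args)
  }
  run_test <- function(fit) {
    if (ladder$scaled) scaled_chi2_diff(fit, prev, ladder$moments)
    else chi2_diff(fit, prev)
  }
  freed <- character()
  fit <- base_fit %||% refit(character())
  test <- run_test(fit)
  while (test$p < ladder$alpha && length(freed) < max_freed) {
    cand <- setdiff(pool, freed)
    if (!length(cand)) break
    drops <- vapply(cand, function(it) {
      f2 <- refit(c(freed, it))
      if (!f2$converged) NA_real_ else fit$chisq - f2$chisq
    }, 0)
    if (all(is.na(drops))) break
    best <- cand[which.max(drops)]
    freed <- c(freed, best)
    fit <- refit(freed)
    test <- run_test(fit)
  }
  list(freed = freed, fit = fit, test = test,
       established = test$p >= ladder$alpha)
}
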