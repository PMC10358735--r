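#' Specify a confirmatory factor model
#'
#' @param factors named list mapping factor names to item-name vectors.
#'   In bifactor mode these are the specific factors (disjoint item
#'   sets); a general factor loading on all items is added.
#' @param bifactor logical; add an orthogonal general factor (specific
#'   factors are then orthogonal to it and to each other).
#' @param estimator \code{"DWLS"} (diagonally weighted least squares on
#'   polychoric correlations, the default for ordinal items) or
#'   \code{"ML"} (normal-theory maximum likelihood on the covariance
#'   matrix).
#' @param free_cross optional data.frame with columns \code{item},
#'   \code{factor}: cross-loadings freed in addition to the simple
#'   structure.
#' @return an object of class \code{"cfa_spec"}.  Identification is by
#'   unit factor variances throughout.
#' @export
cfa_spec <- function(factors, bifactor = FALSE,
                     estimator = c("DWLS", "ML"), free_cross = NULL) {
  estimator <- match.arg(estimator)
  items <- unlist(factors, use.names = FALSE)
  if (bifactor && anyDuplicated(items))
    stop_("bifactor specific factors must cover disjoint item sets")
  if (anyDuplicated(items))
    stop_("an item may load on a single factor in simple structure")
  structure(list(factors = factors, items = items, bifactor = bifactor,
                 estimator = estimator, free_cross = free_cross),
            class = "cfa_spec")
}

## loading pattern: items x factors logical matrix of free loadings
loading_pattern <- function(spec) {
  items <- spec$items
  fnames <- names(spec$factors)
  P <- matrix(FALSE, length(items), length(fnames),
              dimnames = list(items, fnames))
  for (f in fnames) P[spec$factors[[f]], f] <- TRUE
  if (!is.null(spec$free_cross))
    for (r in seq_len(nrow(spec$free_cross)))
      P[spec$free_cross$item[r], spec$free_cross$factor[r]] <- TRUE
  P
}

## Assemble implied correlation matrix from a parameter vector.
## Layout: [loadings (by free pattern, column-major)] [atanh fcor upper-tri]
## [general loadings if bifactor].
cfa_implied <- function(par, spec, P) {
  p <- nrow(P); q <- ncol(P)
  nl <- sum(P)
  L <- matrix(0, p, q, dimnames = dimnames(P))
  L[P] <- par[seq_len(nl)]
  idx <- nl
  if (spec$bifactor || q == 1L) {
    Phi <- diag(q)
  } else {
    nc <- q * (q - 1L) / 2L
    Phi <- diag(q)
    Phi[upper.tri(Phi)] <- tanh(par[idx + seq_len(nc)])
    Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    idx <- idx + nc
  }
  g <- NULL
  if (spec$bifactor) {
    g <- par[idx + seq_len(p)]
    idx <- idx + p
  }
  R <- L %*% Phi %*% t(L)
  if (!is.null(g)) R <- R + tcrossprod(g)
  comm <- diag(R)
  diag(R) <- 1
  list(R = R, L = L, Phi = Phi, g = g, comm = comm)
}

cfa_npar <- function(spec, P) {
  q <- ncol(P)
  sum(P) + (if (spec$bifactor || q == 1L) 0L else q * (q - 1L) / 2L) +
    (if (spec$bifactor) nrow(P) else 0L)
}

cfa_start <- function(spec, P, R) {
  par <- rep(0.6, sum(P))
  q <- ncol(P)
  if (!spec$bifactor && q > 1L) par <- c(par, rep(0, q * (q - 1L) / 2L))
  if (spec$bifactor) par <- c(par, rep(0.4, nrow(P)))
  par
}

#' Fit a confirmatory factor model to ordinal or continuous data
#'
#' DWLS minimizes \eqn{\sum_m (r_m - \sigma_m(\theta))^2 / avar_m} over
#' the unique correlations of a polychoric matrix, with weights from the
#' pairwise asymptotic variances; the unadjusted statistic is the
#' minimized discrepancy.  ML minimizes the normal-theory discrepancy on
#' the item covariance matrix with unique variances parameterized on the
#' log scale.  Factor variances are fixed at 1.  Heywood cases
#' (communality above 1 or negative unique variance) are flagged, not
#' clipped; non-convergence is returned as a flagged fit, not an error.
#'
#' @param data a response table (data.frame), a \code{polycor} object
#'   (DWLS), or a covariance matrix with attribute \code{n} (ML).
#' @param spec a [cfa_spec()].
#' @param n sample size (required when \code{data} is a plain matrix
#'   without attribute \code{n}).
#' @return an object of class \code{"cfa"} with loadings, factor
#'   correlations, unique variances, \code{chisq}, \code{df}, baseline
#'   statistics, \code{cfi}, \code{rmsea}, \code{converged},
#'   \code{heywood}, \code{estimator}, \code{n}.
#' @export
cfa <- function(data, spec, n = NULL) {
  stopifnot(inherits(spec, "cfa_spec"))
  P <- loading_pattern(spec)
  items <- spec$items
  if (spec$estimator == "DWLS") {
    pc <- if (inherits(data, "polycor")) data
          else polychoric_matrix(data, items)
    if (!all(items %in% pc$items)) stop_("polychoric matrix lacks model items")
    R <- pc$rho[items, items]
    W <- 1 / pc$avar[items, items]
    n <- n %||% pc$n
    lt <- lower.tri(R)
    r_obs <- R[lt]; w <- W[lt]
    if (any(!is.finite(w))) stop_("non-finite DWLS weights")
    nmom <- sum(lt)
    objective <- function(par) {
      im <- cfa_implied(par, spec, P)
      sum(w * (r_obs - im$R[lt])^2)
    }
    baseline_chisq <- sum(w * r_obs^2)
    df_b <- nmom
  } else {
    if (is.data.frame(data)) {
      X <- data[, items, drop = FALSE]
      X <- X[complete.cases(X), , drop = FALSE]
      S <- cov(as.matrix(X))
      n <- n %||% nrow(X)
    } else {
      S <- as.matrix(data)[items, items]
      n <- n %||% attr(data, "n")
      if (is.null(n)) stop_("supply n with a covariance matrix")
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
      stop_("singular input covariance matrix")
    p <- length(items)
    ldS <- determinant(S)$modulus
    f_ml <- function(Sig) {
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      as.numeric(2 * sum(log(diag(ch))) - ldS +
                   sum(S * chol2inv(ch)) - p)
    }
    sdS <- sqrt(diag(S))
    objective <- function(par) {
      np0 <- cfa_npar(spec, P)
      im <- cfa_implied(par[seq_len(np0)], spec, P)
      theta <- exp(par[np0 + seq_len(p)])
      Lam <- im$L * sdS          # scale standardized params to covariance metric
      gg <- if (!is.null(im$g)) im$g * sdS else NULL
      Sig <- Lam %*% im$Phi %*% t(Lam) + diag(theta, p)
      if (!is.null(gg)) Sig <- Sig + tcrossprod(gg)
      f_ml(Sig)
    }
    nmom <- length(items) * (length(items) + 1L) / 2L
    baseline_chisq <- (n - 1) * f_ml(diag(diag(S), length(items)))
    df_b <- length(items) * (length(items) - 1L) / 2L
  }

  np <- cfa_npar(spec, P) + if (spec$estimator == "ML") length(items) else 0L
  df <- nmom - np
  if (df < 0) stop_("model under-identified: %d moments, %d parameters", nmom, np)

  start <- cfa_start(spec, P, NULL)
  if (spec$estimator == "ML") start <- c(start, rep(log(0.5), length(items)))
  opt <- tryCatch(
    optim(start, objective, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0
  if (is.null(opt))
    opt <- list(par = start, value = objective(start), convergence = 99L)

  np0 <- cfa_npar(spec, P)
  im <- cfa_implied(opt$par[seq_len(np0)], spec, P)
  chisq <- if (spec$estimator == "DWLS") max(opt$value, 0)
           else max((n - 1) * opt$value, 0)
  theta <- if (spec$estimator == "ML")
    exp(opt$par[np0 + seq_along(items)]) else 1 - im$comm
  heywood <- any(im$comm > 1 + 1e-8) | any(theta < -1e-8)

  fi <- fit_indices(chisq, df, baseline_chisq, df_b, n)
  structure(list(
    spec = spec, estimator = spec$estimator,
    loadings = im$L, factor_cor = im$Phi, general = im$g,
    unique_var = setNames(as.numeric(theta), items),
    chisq = chisq, df = df,
    baseline_chisq = baseline_chisq, baseline_df = df_b,
    cfi = fi$cfi, rmsea = fi$rmsea, n = n,
    converged = converged, heywood = heywood,
    objective = opt$value
  ), class = "cfa")
}

#' Incremental and absolute fit indices from chi-square statistics
#'
#' \code{CFI = 1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b,
#' chisq_m - df_m, 0)} and \code{RMSEA = sqrt(max(chisq_m - df_m, 0) /
#' (df_m (n - 1)))}; a saturated model (\code{df_m = 0}) reports RMSEA 0.
#'
#' @param chisq_m,df_m model statistic and degrees of freedom.
#' @param chisq_b,df_b baseline (independence) statistic and df.
#' @param n sample size.
#' @return list with \code{cfi} and \code{rmsea}.
#' @export
fit_indices <- function(chisq_m, df_m, chisq_b, df_b, n) {
  if (any(c(chisq_m, df_m, chisq_b, df_b) < 0) || n < 2)
    stop_("fit_indices: negative inputs or n < 2")
  if (df_b < df_m) stop_("baseline df must be >= model df")
  ncp_m <- max(chisq_m - df_m, 0)
  ncp_b <- max(chisq_b - df_b, ncp_m, 0)
  cfi <- if (ncp_b == 0) 1 else 1 - ncp_m / ncp_b
  rmsea <- if (df_m == 0) 0 else sqrt(ncp_m / (df_m * (n - 1)))
  list(cfi = cfi, rmsea = rmsea)
}

#' Chi-square difference test for nested fits
#'
#' @param fit_restricted,fit_free nested \code{cfa} (or multigroup) fits;
#'   the restricted model must have larger df.
#' @return list with \code{dchisq}, \code{ddf}, \code{p}.
#' @export
chi2_diff <- function(fit_restricted, fit_free) {
  dchisq <- max(fit_restricted$chisq - fit_free$chisq, 0)
  ddf <- fit_restricted$df - fit_free$df
  if (ddf <= 0) stop_("models not nested: ddf must be positive")
  list(dchisq = dchisq, ddf = ddf, p = pchisq(dchisq, ddf, lower.tail = FALSE))
}

#' @export
anova.cfa <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- fits[order(vapply(fits, `[[`, 0, "df"), decreasing = TRUE)]
  tab <- data.frame(
    df = vapply(fits, `[[`, 0, "df"),
    chisq = vapply(fits, `[[`, 0, "chisq"),
    dchisq = NA_real_, ddf = NA_real_, p = NA_real_)
  if (length(fits) > 1) for (i in 2:length(fits)) {
    d <- chi2_diff(fits[[i - 1L]], fits[[i]])
    tab$dchisq[i] <- d$dchisq; tab$ddf[i] <- d$ddf; tab$p[i] <- d$p
  }
  class(tab) <- c("anova", "data.frame")
  tab
}

#' @export
print.cfa <- function(x, digits = 3, ...) {
  cat(sprintf("CFA (%s): %d items, %d factor(s)%s, n = %d\n",
              x$estimator, nrow(x$loadings), ncol(x$loadings),
              if (x$spec$bifactor) " + general" else "", x$n))
  cat(sprintf("chisq(%d) = %.2f, CFI = %.3f, RMSEA = %.3f%s%s\n",
              x$df, x$chisq, x$cfi, x$rmsea,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$heywood) " [Heywood]" else ""))
  invisible(x)
}

#' @export
summary.cfa <- function(object, digits = 3, ...) {
  print(object)
  cat("\nStandardized loadings:\n")
  L <- object$loadings
  if (!is.null(object$general)) L <- cbind(general = object$general, L)
  print(round(L, digits))
  if (ncol(object$loadings) > 1 && !object$spec$bifactor) {
    cat("\nFactor correlations:\n")
    print(round(object$factor_cor, digits))
  }
  cat("\nUnique variances:\n")
  print(round(object$unique_var, digits))
  invisible(object)
}

#' @export
coef.cfa <- function(object, ...) {
  L <- object$loadings
  out <- setNames(L[L != 0],
                  paste(rep(colnames(L), each = nrow(L)),
                        rep(rownames(L), ncol(L)), sep = "=~")[as.vector(L != 0)])
  if (!object$spec$bifactor && ncol(L) > 1) {
    fc <- object$factor_cor[upper.tri(object$factor_cor)]
    cn <- outer(colnames(L), colnames(L), paste, sep = "~~")[upper.tri(object$factor_cor)]
    out <- c(out, setNames(fc, cn))
  }
  if (!is.null(object$general))
    out <- c(out, setNames(object$general, paste0("g=~", rownames(L))))
  out
}

#' Serialize a fitted CFA as JSON (estimates, statistics, convergence)
#'
#' @param fit a [cfa()] or [mg_cfa()] fit.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(
    estimator = fit$estimator %||% "DWLS",
    level = fit$level,
    loadings = if (!is.null(fit$loadings)) as.data.frame(fit$loadings),
    factor_cor = fit$factor_cor,
    general = fit$general,
    unique_var = fit$unique_var,
    chisq = fit$chisq, df = fit$df,
    baseline_chisq = fit$baseline_chisq, baseline_df = fit$baseline_df,
    cfi = fit$cfi, rmsea = fit$rmsea, n = fit$n,
    converged = fit$converged, heywood = fit$heywood)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Rank fixed parameters by the chi-square drop when freed
#'
#' Refits the model once per candidate with that single parameter freed
#' and records the resulting chi-square decrease, ranked descending.  A
#' refit that fails to converge is reported with \code{NA}, not dropped.
#'
#' @param fit a converged [cfa()] fit.
#' @param data the data used for the fit (table or \code{polycor}).
#' @param pool data.frame with columns \code{item}, \code{factor}:
#'   candidate cross-loadings currently fixed to zero.
#' @return data.frame (item, factor, dchisq), ranked descending.
#' @export
modification_candidates <- function(fit, data, pool) {
  if (!fit$converged) stop_("fit did not converge")
  if (is.null(pool) || nrow(pool) == 0) stop_("empty candidate pool")
  res <- lapply(seq_len(nrow(pool)), function(r) {
    sp <- fit$spec
    sp$free_cross <- rbind(sp$free_cross, pool[r, c("item", "factor")])
    f2 <- tryCatch(cfa(data, sp, n = fit$n), error = function(e) NULL)
    drop <- if (is.null(f2) || !f2$converged) NA_real_
            else fit$chisq - f2$chisq
    data.frame(item = pool$item[r], factor = pool$factor[r], dchisq = drop)
  })
  out <- do.call(rbind, res)
  out[order(-ifelse(is.na(out$dchisq), -Inf, out$dchisq)), , drop = FALSE]
}
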