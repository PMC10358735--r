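#' Define a population model for ordinal questionnaire items
#'
#' A population model fixes the simulation truth for a threshold factor
#' model of Likert-type items: standardized loadings on correlated factors
#' (optionally plus an orthogonal general factor), per-item ordered
#' thresholds on the standard-normal latent-response scale, a latent
#' retest autocorrelation per factor, optional per-group parameter offsets
#' (to plant measurement non-invariance) and covariate specifications
#' calibrated to target correlations with named sum scores.
#'
#' Each item's latent response is
#' \deqn{y^*_j = g_j G + \lambda_j' f + e_j,\qquad Var(y^*_j) = 1,}
#' discretized by its thresholds into codes \code{0..K}.  The implied
#' latent correlation of items \code{i, j} on factors \code{p, q} is
#' \eqn{\lambda_i \lambda_j corr(p, q)} (plus \eqn{g_i g_j} in bifactor
#' mode).
#'
#' @param loadings items x factors matrix of standardized loadings; in
#'   two-factor (simple-structure) mode each row has at most one nonzero
#'   entry.  Row names become item names (default \code{item01}, ...).
#' @param factor_cor factor correlation matrix (symmetric, unit diagonal,
#'   positive definite).  Ignored (forced identity) when
#'   \code{general != NULL}: bifactor specifics are orthogonal.
#' @param thresholds per-item thresholds: a numeric vector (recycled to
#'   all items) or an items x (K) matrix of strictly increasing cut-points.
#' @param general optional vector of general-factor loadings (bifactor
#'   mode).
#' @param retest_stability latent first-order autocorrelation per factor
#'   (recycled), each in \code{[0, 1]}.
#' @param group_deltas optional list of per-group offsets, e.g.
#'   \code{list(`2` = list(loadings = c(item03 = -0.25),
#'   thresholds = list(item06 = rep(0.3, 4))))}; offsets are added to the
#'   named items' parameters in that group.
#' @param covariates optional list of covariate specs created by
#'   [covariate_spec()].
#' @return an object of class \code{"population_model"}.
#' @seealso [pss14_population()], [shortform_population()],
#'   [simulate_responses()]
#' @export
population_model <- function(loadings, factor_cor = NULL, thresholds = c(-1.2, -0.4, 0.4, 1.2),
                             general = NULL, retest_stability = 0.85,
                             group_deltas = NULL, covariates = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings); q <- ncol(loadings)
  if (is.null(rownames(loadings)))
    rownames(loadings) <- sprintf("item%02d", seq_len(p))
  if (is.null(colnames(loadings)))
    colnames(loadings) <- paste0("f", seq_len(q))
  if (any(abs(loadings) > 1))
    stop_("standardized loadings must lie in [-1, 1]")
  bifactor <- !is.null(general)
  if (bifactor) {
    general <- rep_len(general, p)
    if (any(abs(general) > 1)) stop_("general loadings must lie in [-1, 1]")
    factor_cor <- diag(q)
  } else if (is.null(factor_cor)) {
    factor_cor <- diag(q)
  }
  factor_cor <- as.matrix(factor_cor)
  if (!is_square_sym(factor_cor) || any(abs(diag(factor_cor) - 1) > 1e-8))
    stop_("factor_cor must be symmetric with unit diagonal")
  if (!is_pd(factor_cor)) stop_("factor_cor is not positive definite")
  if (!bifactor && q > 1 && any(rowSums(loadings != 0) > 1))
    stop_("simple structure required: each item loads on a single factor")

  if (is.null(dim(thresholds)))
    thresholds <- matrix(thresholds, nrow = p, ncol = length(thresholds),
                         byrow = TRUE)
  thresholds <- as.matrix(thresholds)
  rownames(thresholds) <- rownames(loadings)
  if (any(apply(thresholds, 1, function(x) any(diff(x) <= 0))))
    stop_("thresholds must be strictly increasing per item")

  comm <- rowSums((loadings %*% factor_cor) * loadings)
  if (bifactor) comm <- comm + general^2
  if (any(comm > 1 + 1e-10))
    stop_("item communality exceeds 1; reduce loadings")

  retest_stability <- rep_len(retest_stability, q)
  if (any(retest_stability < 0 | retest_stability > 1))
    stop_("retest_stability must lie in [0, 1]")

  m <- structure(list(
    loadings = loadings, factor_cor = factor_cor, thresholds = thresholds,
    general = if (bifactor) general else NULL,
    retest_stability = retest_stability,
    group_deltas = group_deltas, covariates = covariates,
    items = rownames(loadings), factors = colnames(loadings)
  ), class = "population_model")
  R <- implied_latent_cor(m)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_("implied latent item correlation matrix is not positive semi-definite")
  m
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population model: %d items, %d factor(s)%s\n",
              length(x$items), length(x$factors),
              if (!is.null(x$general)) " + general factor" else ""))
  cat("Factors:", paste(x$factors, collapse = ", "), "\n")
  if (length(x$factors) > 1 && is.null(x$general))
    cat("Factor correlations (lower triangle):",
        paste(round(x$factor_cor[lower.tri(x$factor_cor)], 3), collapse = ", "), "\n")
  cat("Retest stability:", paste(round(x$retest_stability, 3), collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("Covariates:", paste(vapply(x$covariates, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}

## Model parameters for one group, with that group's deltas applied.
group_params <- function(model, group = 1L) {
  L <- model$loadings; Th <- model$thresholds; g <- model$general
  gd <- model$group_deltas[[as.character(group)]]
  if (!is.null(gd)) {
    if (!is.null(gd$loadings))
      for (it in names(gd$loadings)) {
        nz <- which(L[it, ] != 0)
        if (!length(nz)) nz <- 1L
        L[it, nz[1L]] <- L[it, nz[1L]] + gd$loadings[[it]]
      }
    if (!is.null(gd$thresholds))
      for (it in names(gd$thresholds))
        Th[it, ] <- Th[it, ] + gd$thresholds[[it]]
  }
  list(loadings = L, thresholds = Th, general = g)
}

#' Model-implied latent item correlation matrix
#'
#' @param model a [population_model()].
#' @param group group whose deltas to apply (default 1, the reference).
#' @return items x items correlation matrix of the latent responses.
#' @export
implied_latent_cor <- function(model, group = 1L) {
  gp <- group_params(model, group)
  R <- gp$loadings %*% model$factor_cor %*% t(gp$loadings)
  if (!is.null(gp$general)) R <- R + tcrossprod(gp$general)
  diag(R) <- 1
  dimnames(R) <- list(model$items, model$items)
  R
}

## ---- model-implied moments of the *ordinal* codes -------------------------
## X_j = sum_k 1{y*_j > tau_jk}; with standardized y* these have closed
## forms in Phi and Phi2, used for covariate calibration and as test oracles.

ordinal_item_mean <- function(th) sum(1 - pnorm(th))

ordinal_item_var <- function(th) {
  K <- length(th)
  s <- 1 - pnorm(th)
  ## E[X^2] = sum_k sum_m P(y* > max(tau_k, tau_m))
  ex2 <- sum(outer(seq_len(K), seq_len(K),
                   Vectorize(function(k, m) 1 - pnorm(max(th[k], th[m])))))
  ex2 - sum(s)^2
}

ordinal_pair_cov <- function(th1, th2, rho) {
  if (abs(rho) < 1e-12) return(0)
  s1 <- 1 - pnorm(th1); s2 <- 1 - pnorm(th2)
  g <- expand.grid(a = th1, b = th2)
  surv <- 1 - pnorm(g$a) - pnorm(g$b) + pbvnorm(g$a, g$b, rho)
  sum(surv) - sum(s1) * sum(s2)
}

## Covariance matrix of ordinal codes implied by the model (one group).
implied_ordinal_cov <- function(model, items = model$items, group = 1L) {
  gp <- group_params(model, group)
  R <- implied_latent_cor(model, group)[items, items, drop = FALSE]
  th <- gp$thresholds[items, , drop = FALSE]
  p <- length(items)
  V <- matrix(0, p, p, dimnames = list(items, items))
  for (i in seq_len(p)) {
    V[i, i] <- ordinal_item_var(th[i, ])
    if (i < p) for (j in (i + 1):p) {
      V[i, j] <- V[j, i] <- ordinal_pair_cov(th[i, ], th[j, ], R[i, j])
    }
  }
  V
}

## cov(factor scores, ordinal item codes): cov(f_p, X_j) =
## corr(f_p, y*_j) * sum_k dnorm(tau_jk).
implied_factor_item_cov <- function(model, items = model$items, group = 1L) {
  gp <- group_params(model, group)
  fy <- gp$loadings %*% model$factor_cor           # items x factors
  phi_sum <- apply(gp$thresholds, 1, function(t) sum(dnorm(t)))
  out <- fy[items, , drop = FALSE] * phi_sum[items]
  out
}

#' Model-implied correlation between two ordinal sum scores
#'
#' Closed-form Pearson correlation of the sums of two (disjoint or
#' overlapping) item sets under the population model, accounting for
#' threshold attenuation; serves as an analytic oracle for simulated data.
#'
#' @param model a [population_model()].
#' @param items1,items2 character vectors of item names.
#' @return scalar correlation.
#' @export
implied_sumscore_cor <- function(model, items1, items2) {
  all_items <- union(items1, items2)
  V <- implied_ordinal_cov(model, all_items)
  a <- as.numeric(all_items %in% items1)
  b <- as.numeric(all_items %in% items2)
  (a %*% V %*% b) / sqrt((a %*% V %*% a) * (b %*% V %*% b))
}

## ---- covariates -----------------------------------------------------------

#' Specify a covariate calibrated to a target correlation
#'
#' The covariate is generated as \eqn{c = \beta d' f + \sigma \epsilon}
#' with unit total variance, where \code{d} is a direction over factors
#' and \eqn{\beta} is solved in closed form so that the model-implied
#' correlation between \code{c} and the ordinal sum score of
#' \code{score_items} equals \code{target}.
#'
#' @param name covariate (column) name.
#' @param weights named numeric vector: direction over factors.
#' @param target target Pearson correlation with the named sum score.
#' @param score_items item names whose sum is the calibration score.
#' @param tolerance acceptance half-width used by [verify_targets()].
#' @return a covariate spec list.
#' @export
covariate_spec <- function(name, weights, target, score_items, tolerance = 0.15) {
  stopifnot(is.character(name), length(target) == 1L, abs(target) < 1)
  list(name = name, weights = weights, target = target,
       score_items = score_items, tolerance = tolerance)
}

## Solve the loading scale beta for one covariate spec. Returns a list
## with the factor weight vector (beta * d) and residual sd.
calibrate_covariate <- function(model, spec) {
  d <- rep(0, length(model$factors)); names(d) <- model$factors
  d[names(spec$weights)] <- spec$weights
  FI <- implied_factor_item_cov(model, spec$score_items)   # items x factors
  cfS <- colSums(FI)                                       # cov(f, S)
  V <- implied_ordinal_cov(model, spec$score_items)
  sdS <- sqrt(sum(V))
  denom <- sum(d * cfS)
  if (abs(denom) < 1e-12)
    stop_("covariate '%s': direction is orthogonal to the target score", spec$name)
  beta <- spec$target * sdS / denom
  v_sys <- beta^2 * as.numeric(d %*% model$factor_cor %*% d)
  if (v_sys > 1)
    stop_("covariate '%s': target correlation %.2f unattainable in this direction",
          spec$name, spec$target)
  list(alpha = beta * d, resid_sd = sqrt(1 - v_sys))
}
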