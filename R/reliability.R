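#' Cronbach's alpha
#'
#' \code{alpha = k/(k-1) (1 - sum(item variances) / var(sum))} over
#' listwise-complete rows.
#'
#' @param table data.frame or matrix of item scores.
#' @param items item columns (default all columns).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(table, items = colnames(table)) {
  X <- as.matrix(as.data.frame(table)[, items, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2 || nrow(X) < 2) stop_("alpha needs >= 2 items and >= 2 complete rows")
  vs <- var(rowSums(X))
  if (vs < 1e-12) stop_("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(X, 2, var)) / vs)
}

#' McDonald's omega from a one-factor solution
#'
#' \code{omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)}.
#'
#' @param lambda loadings.
#' @param theta unique variances (same length).
#' @return scalar omega.
#' @export
mcdonald_omega <- function(lambda, theta) {
  if (length(lambda) != length(theta)) stop_("lambda and theta lengths differ")
  if (any(theta < 0)) stop_("negative unique variance")
  denom <- sum(lambda)^2 + sum(theta)
  if (denom < 1e-12) stop_("omega undefined: zero total variance")
  sum(lambda)^2 / denom
}

#' Omega of an item set from its own one-factor polychoric solution
#'
#' Fits a one-factor model to the item set and applies
#' [mcdonald_omega()].  With exactly two items the one-factor model is
#' identified by an equal-loadings constraint
#' (\eqn{\lambda = \sqrt{r_{12}}}); a negative inter-item correlation
#' yields \code{NA} with a warning.
#'
#' @param data response table or \code{polycor} object.
#' @param items item names.
#' @return scalar omega.
#' @export
omega_from_items <- function(data, items) {
  pc <- if (inherits(data, "polycor")) data else polychoric_matrix(data, items)
  R <- pc$rho[items, items]
  k <- length(items)
  if (k == 2) {
    r <- R[1, 2]
    if (r < 0) { warning("negative inter-item correlation; omega undefined"); return(NA_real_) }
    lam <- rep(sqrt(r), 2)
    return(mcdonald_omega(lam, 1 - lam^2))
  }
  fit <- cfa(pc, cfa_spec(setNames(list(items), "f")))
  lam <- fit$loadings[, 1]
  mcdonald_omega(lam, pmax(fit$unique_var, 0))
}

#' Test-retest intraclass correlation
#'
#' Default variant ICC(2,1): two-way random effects, absolute agreement,
#' single measurement,
#' \deqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' with k = 2 waves.  The consistency variant ICC(3,1) is
#' \code{(MS_R - MS_E) / (MS_R + (k-1) MS_E)}.
#'
#' @param score1,score2 paired per-person scores at waves 1 and 2
#'   (missing pairs dropped).
#' @param variant \code{"agreement"} (default) or \code{"consistency"}.
#' @return scalar ICC.
#' @export
icc_retest <- function(score1, score2, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  ok <- !is.na(score1) & !is.na(score2)
  x <- cbind(score1[ok], score2[ok])
  n <- nrow(x); k <- 2
  if (n < 2) stop_("need >= 2 paired persons")
  rm_ <- rowMeans(x); cm <- colMeans(x); gm <- mean(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (variant == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Reliability report for a scale across two waves
#'
#' @param table two-wave response table ([simulate_responses()] layout).
#' @param items item names of the scale.
#' @param variant ICC variant, see [icc_retest()].
#' @return list with alpha, omega, icc, variant, n per coefficient.
#' @export
reliability_report <- function(table, items, variant = "agreement") {
  w1 <- table[table$wave == 1L, , drop = FALSE]
  alpha <- cronbach_alpha(w1, items)
  omega <- omega_from_items(w1, items)
  icc <- NA_real_
  if (any(table$wave == 2L)) {
    w2 <- table[table$wave == 2L, , drop = FALSE]
    s1 <- rowSums(w1[, items, drop = FALSE])
    s2 <- rowSums(w2[, items, drop = FALSE])
    pid <- intersect(w1$person, w2$person)
    icc <- icc_retest(s1[match(pid, w1$person)], s2[match(pid, w2$person)],
                      variant)
  }
  list(alpha = alpha, omega = omega, icc = icc, icc_variant = variant,
       n = nrow(w1))
}
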