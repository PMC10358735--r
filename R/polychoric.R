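## Polychoric correlations by the two-step method: per-item thresholds are
## fixed at inverse-normal cumulative category proportions, then each
## pairwise latent correlation maximizes the bivariate-normal two-way-table
## likelihood over the bounded interval [-0.999, 0.999] (golden-section /
## parabolic refinement, tolerance 1e-6).  The asymptotic variance of each
## estimate is taken from the observed information of the pairwise
## likelihood (numeric second derivative) and feeds the DWLS weights.

poly_thresholds <- function(x, item = "item") {
  x <- x[!is.na(x)]
  tab <- table(factor(x, levels = sort(unique(x))))
  if (length(tab) < 2L)
    stop_("item %s has a single observed category; polychoric undefined", item)
  cum <- cumsum(as.numeric(tab)) / sum(tab)
  qnorm(cum[-length(cum)])
}

pair_loglik <- function(rho, counts, th1, th2) {
  P <- bvn_cell_probs(th1, th2, rho)
  sum(counts * log(pmax(P, 1e-300)))
}

polychoric_pair <- function(x, y, th1 = NULL, th2 = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(th1)) th1 <- poly_thresholds(x)
  if (is.null(th2)) th2 <- poly_thresholds(y)
  lx <- findInterval(x, sort(unique(x)))
  ly <- findInterval(y, sort(unique(y)))
  a <- length(th1) + 1L; b <- length(th2) + 1L
  counts <- matrix(tabulate((ly - 1L) * a + lx, nbins = a * b), a, b)
  opt <- optimize(pair_loglik, c(-0.999, 0.999), counts = counts,
                  th1 = th1, th2 = th2, maximum = TRUE, tol = 1e-6)
  rho <- opt$maximum
  ## boundary snap: optimize never returns an endpoint exactly
  if (rho > 0.996 && pair_loglik(0.999, counts, th1, th2) >= opt$objective)
    rho <- 0.999
  if (rho < -0.996 && pair_loglik(-0.999, counts, th1, th2) >= opt$objective)
    rho <- -0.999
  h <- 1e-3
  r0 <- max(min(rho, 0.995), -0.995)
  d2 <- (pair_loglik(r0 + h, counts, th1, th2) -
         2 * pair_loglik(r0, counts, th1, th2) +
         pair_loglik(r0 - h, counts, th1, th2)) / h^2
  avar <- if (is.finite(d2) && d2 < 0) -1 / d2 else 1 / sum(counts)
  list(rho = rho, avar = avar, n = sum(counts))
}

#' Polychoric correlation matrix of ordinal items
#'
#' @param table data.frame of ordinal item responses (rows may include
#'   several waves; filter first if needed).
#' @param items item column names (default: columns matching
#'   \code{^item}).
#' @return an object of class \code{"polycor"}: list with \code{rho}
#'   (correlation matrix), \code{thresholds} (named list of per-item
#'   cut-points), \code{avar} (asymptotic variance of each pairwise
#'   estimate), \code{n}.
#' @export
polychoric_matrix <- function(table, items = grep("^item", names(table), value = TRUE)) {
  X <- table[, items, drop = FALSE]
  th <- lapply(items, function(it) poly_thresholds(X[[it]], it))
  names(th) <- items
  p <- length(items)
  R <- diag(p); A <- matrix(NA_real_, p, p)
  dimnames(R) <- dimnames(A) <- list(items, items)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    pr <- polychoric_pair(X[[i]], X[[j]], th[[i]], th[[j]])
    R[i, j] <- R[j, i] <- pr$rho
    A[i, j] <- A[j, i] <- pr$avar
  }
  structure(list(rho = R, thresholds = th, avar = A,
                 n = sum(complete.cases(X)), method = "polychoric",
                 items = items),
            class = "polycor")
}

#' @export
print.polycor <- function(x, digits = 3, ...) {
  cat(sprintf("Polychoric correlations (%d items, n = %d)\n",
              length(x$items), x$n))
  print(round(x$rho, digits))
  invisible(x)
}

#' Export a correlation matrix as TSV
#' @param x a \code{polycor} object or plain matrix.
#' @param path output path.
#' @export
write_cormat <- function(x, path) {
  m <- if (inherits(x, "polycor")) x$rho else x
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
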