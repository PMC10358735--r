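#' Nonparanormal (rank-Gaussianizing) transform
#'
#' Per column: ranks, truncated empirical CDF (Winsorized at
#' \eqn{1/(4 n^{1/4} \sqrt{\pi \log n})}), standard-normal quantiles,
#' rescaled to unit variance.  Monotone and rank-preserving.
#'
#' @param table data.frame of continuous or ordinal node scores
#'   (\code{n >= 20} rows, no constant columns).
#' @return data.frame of transformed scores.
#' @export
npn_transform <- function(table) {
  X <- as.data.frame(table)
  n <- nrow(X)
  if (n < 20) stop_("need at least 20 rows")
  for (j in names(X)) {
    x <- X[[j]]
    if (length(unique(x[!is.na(x)])) < 2) stop_("constant column: %s", j)
    delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
    u <- rank(x, ties.method = "average", na.last = "keep") / n
    u <- pmin(pmax(u, delta), 1 - delta)
    z <- qnorm(u)
    X[[j]] <- z / sd(z, na.rm = TRUE)
  }
  X
}

## lasso subproblem of the graphical lasso: min .5 b'Wb - s'b + |pen * b|_1
## (pen may be a vector for entry-specific penalties)
lasso_cd_ <- function(W11, s12, pen, beta, maxit = 200, tol = 1e-8) {
  p <- length(s12)
  pen <- rep_len(pen, p)
  for (it in seq_len(maxit)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      r <- s12[j] - sum(W11[, j] * beta) + W11[j, j] * beta[j]
      bj <- sign(r) * max(abs(r) - pen[j], 0) / W11[j, j]
      delta_max <- max(delta_max, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta_max < tol) break
  }
  beta
}

## graphical lasso (block coordinate descent, Friedman et al. scheme);
## pen is a scalar or a p x p matrix of entry penalties; warm supplies
## (W, B) from a neighbouring penalty for path continuation
glasso_fit_ <- function(S, pen, maxit = 200, tol = 1e-7, warm = NULL) {
  p <- nrow(S)
  if (is.null(dim(pen))) pen <- matrix(pen, p, p)
  W <- if (!is.null(warm)) warm$W else S + diag(pen) * diag(p)
  diag(W) <- diag(S) + diag(pen)
  B <- if (!is.null(warm)) warm$B else matrix(0, p - 1, p)
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      B[, j] <- lasso_cd_(W[-j, -j], S[-j, j], pen[-j, j], B[, j])
      w12 <- W[-j, -j] %*% B[, j]
      W[-j, j] <- w12; W[j, -j] <- w12
    }
    if (mean(abs(W - W_old)) < tol * (mean(abs(S)) + 1e-12)) break
  }
  Omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    th22 <- 1 / (W[j, j] - sum(W[-j, j] * B[, j]))
    Omega[j, j] <- th22
    Omega[-j, j] <- -B[, j] * th22
  }
  Omega <- (Omega + t(Omega)) / 2
  ## exact zeros from the lasso supports
  supp <- matrix(TRUE, p, p)
  for (j in seq_len(p)) {
    z <- B[, j] == 0
    supp[-j, j][z] <- FALSE
  }
  supp <- supp & t(supp)
  Omega[!supp] <- 0
  diag(Omega) <- abs(diag(Omega))
  list(Omega = Omega, W = W, B = B, support = supp)
}

## unpenalized Gaussian MLE restricted to a given support, via the
## entry-penalty trick (huge ridge off support, none on it)
restricted_mle_ <- function(S, supp) {
  p <- nrow(S)
  pen <- matrix(1e6 * max(abs(S)), p, p)
  pen[supp] <- 0
  diag(pen) <- 0
  glasso_fit_(S, pen)$Omega * ifelse(supp | diag(p) == 1, 1, 0)
}

#' Partial correlations from a precision matrix
#'
#' \code{w_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)}, zero diagonal.
#'
#' @param Omega symmetric positive-definite precision matrix.
#' @return partial-correlation matrix.
#' @export
partial_cor_from_precision <- function(Omega) {
  if (!is_square_sym(Omega, tol = 1e-6)) stop_("Omega must be symmetric")
  if (!is_pd(Omega)) stop_("Omega must be positive definite")
  d <- sqrt(diag(Omega))
  W <- -Omega / outer(d, d)
  diag(W) <- 0
  W
}

#' EBIC-selected regularized partial-correlation network
#'
#' Solves the l1-penalized Gaussian precision problem along a 100-point
#' log-spaced penalty path from \eqn{\lambda_{max}} (smallest penalty
#' giving an empty graph) down to \code{0.01} \eqn{\lambda_{max}} and
#' selects the penalty minimizing
#' \deqn{EBIC = -2 loglik + E \log n + 4 \gamma E \log p,}
#' with E the number of edges.  Edge weights are partial correlations
#' from the selected precision matrix.
#'
#' @param S correlation (or covariance) matrix of the node scores; a
#'   near-singular matrix gets a logged ridge fix-up.
#' @param n sample size.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param n_lambda,lambda_ratio path resolution and lower ratio.
#' @param refit compute the EBIC log-likelihood (and the reported
#'   precision) from the unpenalized MLE restricted to each penalty's
#'   support (default TRUE); \code{FALSE} uses the penalized estimate.
#' @return object of class \code{"pcor_network"}: \code{weights},
#'   \code{lambda}, \code{path} (lambda, loglik, E, ebic), \code{gamma},
#'   \code{Omega}, \code{nodes}, \code{n}.
#' @export
ebic_glasso <- function(S, n, gamma = 0.25, n_lambda = 100,
                        lambda_ratio = 0.01, refit = TRUE) {
  S <- as.matrix(S)
  p <- nrow(S)
  nodes <- colnames(S) %||% paste0("V", seq_len(p))
  ridge_applied <- FALSE
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    S <- S + diag(1e-3, p); ridge_applied <- TRUE
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
      stop_("input matrix not positive definite after ridge fix-up")
  }
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max < 1e-12) lam_max <- 1e-6
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_ratio),
                     length.out = n_lambda))
  path <- data.frame(lambda = lambdas, loglik = NA_real_, E = NA_integer_,
                     ebic = NA_real_)
  best <- NULL
  warm <- NULL
  refit_cache <- list()
  for (i in seq_along(lambdas)) {
    pen <- matrix(lambdas[i], p, p)
    diag(pen) <- 0                       # diagonal left unpenalized
    fit <- glasso_fit_(S, pen, warm = warm)
    warm <- fit
    ut <- upper.tri(S)
    E <- sum(fit$support[ut])
    if (refit) {
      key <- paste(which(fit$support[ut]), collapse = ",")
      Om <- refit_cache[[key]]
      if (is.null(Om)) {
        Om <- restricted_mle_(S, fit$support)
        refit_cache[[key]] <- Om
      }
    } else Om <- fit$Omega
    ld <- determinant(Om, logarithm = TRUE)$modulus
    ll <- n / 2 * (as.numeric(ld) - sum(S * Om))
    ebic <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
    path$loglik[i] <- ll; path$E[i] <- E; path$ebic[i] <- ebic
    if (is.null(best) || ebic < best$ebic)
      best <- list(ebic = ebic, Omega = Om, lambda = lambdas[i])
  }
  Wt <- partial_cor_from_precision(best$Omega +
                                     diag(1e-12, p))
  dimnames(Wt) <- list(nodes, nodes)
  structure(list(weights = Wt, lambda = best$lambda, path = path,
                 gamma = gamma, Omega = best$Omega, nodes = nodes, n = n,
                 ridge_applied = ridge_applied),
            class = "pcor_network")
}

#' Estimate a network from node scores
#'
#' Convenience wrapper: nonparanormal transform, Pearson correlation,
#' [ebic_glasso()].
#'
#' @param table data.frame of node scores.
#' @param gamma EBIC hyperparameter.
#' @param transform apply [npn_transform()] first (default TRUE).
#' @return a \code{pcor_network}.
#' @export
pcor_network <- function(table, gamma = 0.25, transform = TRUE) {
  X <- as.data.frame(table)
  X <- X[complete.cases(X), , drop = FALSE]
  if (transform) X <- npn_transform(X)
  ebic_glasso(cor(X), nrow(X), gamma = gamma)
}

#' @export
print.pcor_network <- function(x, digits = 2, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("Partial-correlation network: %d nodes, %d edges (lambda = %.4f, gamma = %.2f, n = %d)\n",
              length(x$nodes), E, x$lambda, x$gamma, x$n))
  print(round(x$weights, digits))
  invisible(x)
}

#' @export
plot.pcor_network <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(abs(x$weights), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::plot.igraph(g, edge.width = 5 * igraph::E(g)$weight, ...)
  invisible(x)
}

#' Node centrality indices of a weighted network
#'
#' Strength is the sum of absolute edge weights; closeness is the
#' reciprocal of the summed shortest-path distances (edge length
#' \code{1/|w|}) to reachable nodes, zero when nothing is reachable;
#' betweenness counts shortest paths through the node.
#'
#' @param weights symmetric zero-diagonal weight matrix, or a
#'   \code{pcor_network}.
#' @return data.frame (node, strength, closeness, betweenness).
#' @export
centrality_indices <- function(weights) {
  W <- if (inherits(weights, "pcor_network")) weights$weights else weights
  nodes <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  A <- abs(W)
  strength <- rowSums(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  } else {
    D <- matrix(Inf, ncol(W), ncol(W)); diag(D) <- 0
    btw <- rep(0, ncol(W))
  }
  closeness <- vapply(seq_len(ncol(W)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / sum(d)
  }, 0)
  data.frame(node = nodes, strength = strength, closeness = closeness,
             betweenness = as.numeric(btw), row.names = NULL)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Nonparametric case resampling with full re-estimation (transform,
#' correlation, penalty selection) per draw; percentile 2.5/97.5
#' intervals per edge.
#'
#' @param table node-score table.
#' @param B bootstrap draws (>= 100).
#' @param gamma EBIC hyperparameter.
#' @param transform apply the nonparanormal transform per draw.
#' @param seed RNG seed.
#' @return data.frame (node1, node2, estimate, lower, upper) plus
#'   attribute \code{skipped} (draws with a constant column).
#' @export
bootstrap_edges <- function(table, B = 1000, gamma = 0.25, transform = TRUE,
                            seed = 1L) {
  if (B < 100) stop_("B must be >= 100")
  X <- as.data.frame(table)
  X <- X[complete.cases(X), , drop = FALSE]
  full <- pcor_network(X, gamma = gamma, transform = transform)
  p <- length(full$nodes)
  ut <- which(upper.tri(full$weights), arr.ind = TRUE)
  draws <- matrix(NA_real_, B, nrow(ut))
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      net <- tryCatch(pcor_network(Xb, gamma = gamma, transform = transform),
                      error = function(e) NULL)
      if (is.null(net)) { skipped <- skipped + 1L; next }
      draws[b, ] <- net$weights[upper.tri(net$weights)]
    }
  })
  if (skipped > 0) warning(sprintf("%d bootstrap draws skipped", skipped))
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(node1 = full$nodes[ut[, 1]], node2 = full$nodes[ut[, 2]],
                    estimate = full$weights[upper.tri(full$weights)],
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "skipped") <- skipped
  attr(out, "network") <- full
  out
}

#' Correlation-stability coefficient of a centrality index
#'
#' For each case-drop proportion, draws \code{B} subsamples, recomputes
#' the network and the chosen centrality, and correlates it with the
#' full-sample centrality.  The CS coefficient is the largest tested
#' proportion at which that correlation is at least 0.7 in at least 95
#' percent of subsamples (0 if none).
#'
#' @param table node-score table.
#' @param kind \code{"strength"}, \code{"closeness"} or
#'   \code{"betweenness"}.
#' @param drop_grid case-drop proportions in (0, 0.95).
#' @param B subsamples per grid point.
#' @param gamma EBIC hyperparameter.
#' @param transform apply the nonparanormal transform.
#' @param seed RNG seed.
#' @return list: \code{cs} coefficient, \code{detail} per-proportion
#'   retention rates.
#' @export
casedrop_stability <- function(table, kind = "strength",
                               drop_grid = seq(0.1, 0.75, by = 0.05),
                               B = 50, gamma = 0.25, transform = TRUE,
                               seed = 1L) {
  kind <- match.arg(kind, c("strength", "closeness", "betweenness"))
  if (!length(drop_grid)) stop_("empty drop grid")
  if (any(drop_grid <= 0 | drop_grid >= 0.95))
    stop_("drop proportions must lie in (0, 0.95)")
  X <- as.data.frame(table)
  X <- X[complete.cases(X), , drop = FALSE]
  full <- centrality_indices(pcor_network(X, gamma, transform))[[kind]]
  drop_grid <- sort(drop_grid)
  detail <- data.frame(drop = drop_grid, retain = NA_real_)
  with_seed(seed, {
    for (d in seq_along(drop_grid)) {
      keep_n <- max(round(nrow(X) * (1 - drop_grid[d])), 20)
      ok <- logical(B)
      for (b in seq_len(B)) {
        idx <- sample.int(nrow(X), keep_n)
        ct <- tryCatch(
          centrality_indices(pcor_network(X[idx, , drop = FALSE],
                                          gamma, transform))[[kind]],
          error = function(e) NULL)
        r <- if (is.null(ct) || sd(ct) == 0 || sd(full) == 0) 0
             else cor(ct, full)
        ok[b] <- !is.na(r) && r >= 0.7
      }
      detail$retain[d] <- mean(ok)
    }
  })
  passing <- detail$drop[detail$retain >= 0.95]
  list(cs = if (length(passing)) max(passing) else 0, detail = detail,
       kind = kind)
}

#' Export a network as a long-form edge list
#' @param net a \code{pcor_network}.
#' @param path optional TSV path; returned invisibly if written.
#' @return data.frame (node1, node2, weight) of present edges.
#' @export
edge_list <- function(net, path = NULL) {
  W <- net$weights
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  out <- data.frame(node1 = net$nodes[ut[, 1]], node2 = net$nodes[ut[, 2]],
                    weight = W[ut])
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
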