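#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm dnorm pchisq cor var aov optim optimize
#'   rnorm runif quantile shapiro.test rbinom complete.cases sd setNames
#' @importFrom utils combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

## Deterministic child seeds: one master seed, named streams.  A small
## multiplicative hash keeps every derived seed inside 32-bit integer range.
child_seed <- function(master, ...) {
  label <- paste(c(...), collapse = "/")
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h %% 2147483563) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_square_sym <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) < tol
}

is_pd <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}
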