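#' Define a scale (item set with scoring rules)
#'
#' @param name scale name.
#' @param items item column names.
#' @param reverse subset of \code{items} scored in reverse
#'   (\code{max_code - value}).
#' @param max_code maximum ordinal code (codes run \code{0..max_code}).
#' @return an object of class \code{"scale_def"}.
#' @export
scale_def <- function(name, items, reverse = character(), max_code = 4L) {
  if (!all(reverse %in% items)) stop_("reverse items must be a subset of items")
  if (max_code < 1) stop_("max_code must be >= 1")
  structure(list(name = name, items = items, reverse = reverse,
                 max_code = as.integer(max_code)), class = "scale_def")
}

#' Person-mean imputation of single missing items per scale
#'
#' Within each scale and row: exactly one missing item is replaced by the
#' person's mean over that scale's remaining items; rows missing more
#' than one item on a scale keep their missing values and the scale score
#' is flagged unusable for them (column \code{.unusable_<scale>}).
#'
#' @param table response table.
#' @param scales list of [scale_def()]s; each must reference existing
#'   columns.
#' @param method \code{"person"} (person mean of remaining items, the
#'   default) or \code{"item"} (sample mean of the missing item).
#' @return list with elements \code{table} (imputed) and \code{log}
#'   (per-scale counts of imputed cells and unusable rows).
#' @export
impute_missing <- function(table, scales, method = c("person", "item")) {
  method <- match.arg(method)
  if (inherits(scales, "scale_def")) scales <- list(scales)
  log <- data.frame(scale = character(), imputed = integer(),
                    unusable = integer())
  for (sc in scales) {
    miss_cols <- setdiff(sc$items, names(table))
    if (length(miss_cols))
      stop_("scale '%s' references absent column(s): %s", sc$name,
            paste(miss_cols, collapse = ", "))
    X <- as.matrix(table[, sc$items, drop = FALSE])
    nmiss <- rowSums(is.na(X))
    one <- which(nmiss == 1L)
    many <- which(nmiss > 1L)
    for (i in one) {
      j <- which(is.na(X[i, ]))
      X[i, j] <- if (method == "person") mean(X[i, -j])
                 else mean(X[, j], na.rm = TRUE)
    }
    table[, sc$items] <- X
    table[[paste0(".unusable_", sc$name)]] <-
      seq_len(nrow(table)) %in% many
    log <- rbind(log, data.frame(scale = sc$name, imputed = length(one),
                                 unusable = length(many)))
  }
  list(table = table, log = log)
}

#' Reverse-score and sum a scale
#'
#' Reversed item value is \code{max_code - value}; the scale score is the
#' sum over items after reversal.  Any remaining missing item propagates
#' to a missing score, as does an \code{.unusable_} flag from
#' [impute_missing()].
#'
#' @param table response table (optionally after [impute_missing()]).
#' @param scale a [scale_def()].
#' @return numeric vector of per-row scores.
#' @export
score_scale <- function(table, scale) {
  X <- as.matrix(table[, scale$items, drop = FALSE])
  rng <- range(X, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > scale$max_code)
    stop_("item codes outside 0..%d for scale '%s'", scale$max_code, scale$name)
  for (it in scale$reverse) X[, it] <- scale$max_code - X[, it]
  s <- rowSums(X)
  flag <- table[[paste0(".unusable_", scale$name)]]
  if (!is.null(flag)) s[flag] <- NA_real_
  s
}

#' Per-item distribution screening
#'
#' Computes skewness and excess kurtosis (both SPSS-style, type 2) and a
#' Shapiro-Wilk p-value per item.  An item is flagged as non-normal when
#' the Shapiro-Wilk test rejects at \code{alpha} \emph{and} skewness or
#' kurtosis leaves the \code{[-1.5, 1.5]} band; the three components are
#' also reported separately in \code{reason}.  Shapiro-Wilk is evaluated
#' on a fixed-seed subsample of at most 5000 values.
#'
#' @param table response table.
#' @param items item column names (default: columns matching
#'   \code{^item}).
#' @param alpha significance level for the normality test.
#' @return data.frame with one row per item.
#' @export
describe_items <- function(table, items = grep("^item", names(table), value = TRUE),
                           alpha = 0.05) {
  out <- lapply(items, function(it) {
    x <- table[[it]]
    if (is.null(x)) stop_("no such item column: %s", it)
    x <- x[!is.na(x)]
    if (length(x) < 3) stop_("item %s has fewer than 3 observations", it)
    if (length(unique(x)) == 1L)
      return(data.frame(item = it, mean = mean(x), sd = 0,
                        skewness = NA_real_, kurtosis = NA_real_,
                        shapiro_p = NA_real_, flagged = TRUE,
                        reason = "constant item"))
    sk <- e1071::skewness(x, type = 2)
    ku <- e1071::kurtosis(x, type = 2)
    xs <- if (length(x) > 5000) with_seed(child_seed(1L, "shapiro", it),
                                          sample(x, 5000)) else x
    sw <- tryCatch(shapiro.test(xs)$p.value, error = function(e) NA_real_)
    comp <- c(if (abs(sk) > 1.5) "skewness",
              if (abs(ku) > 1.5) "kurtosis",
              if (!is.na(sw) && sw < alpha) "shapiro")
    flagged <- (!is.na(sw) && sw < alpha) && (abs(sk) > 1.5 || abs(ku) > 1.5)
    data.frame(item = it, mean = mean(x), sd = sd(x), skewness = sk,
               kurtosis = ku, shapiro_p = sw, flagged = flagged,
               reason = paste(comp, collapse = "+"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
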