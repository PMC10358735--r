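#' Default 14-item two-factor population model
#'
#' A two-factor population resembling the long form of the Perceived
#' Stress Scale: 7 helplessness items and 7 self-efficacy items with the
#' published standardized loadings, inter-factor correlation -0.37,
#' symmetric default thresholds, latent retest stability 0.85 and three
#' covariates (mental-health problems, stressor recovery ability,
#' self-efficacy beliefs) calibrated to target correlations 0.59, -0.53
#' and 0.44 with the relevant factor sum scores.
#'
#' @param factor_cor inter-factor correlation (scalar).
#' @param retest_stability latent autocorrelation per factor.
#' @param thresholds default per-item cut-points on the latent scale.
#' @param covariates replace the default covariate specs (or \code{NULL}
#'   for none).
#' @return a [population_model()].
#' @export
pss14_population <- function(factor_cor = -0.37, retest_stability = 0.85,
                             thresholds = c(-1.2, -0.4, 0.4, 1.2),
                             covariates = "default") {
  help_items <- c(1, 2, 3, 8, 11, 12, 14)
  self_items <- c(4, 5, 6, 7, 9, 10, 13)
  help_load <- c(0.78, 0.87, 0.82, 0.74, 0.69, 0.50, 0.87)
  self_load <- c(0.65, 0.75, 0.88, 0.79, 0.56, 0.90, 0.54)
  L <- matrix(0, 14, 2, dimnames = list(sprintf("item%02d", 1:14),
                                        c("helplessness", "selfefficacy")))
  L[help_items, 1] <- help_load
  L[self_items, 2] <- self_load
  Phi <- matrix(c(1, factor_cor, factor_cor, 1), 2)
  covs <- NULL
  if (identical(covariates, "default")) {
    hnames <- sprintf("item%02d", help_items)
    snames <- sprintf("item%02d", self_items)
    covs <- list(
      covariate_spec("mhp", c(helplessness = 1), 0.59, hnames),
      covariate_spec("recovery", c(helplessness = -1), -0.53, hnames),
      covariate_spec("ase", c(selfefficacy = 1), 0.44, snames)
    )
  } else if (!is.null(covariates)) covs <- covariates
  population_model(L, Phi, thresholds = thresholds,
                   retest_stability = retest_stability, covariates = covs)
}

#' Marker/distractor population for short-form selection studies
#'
#' A clean two-factor population used to exercise the item-selection
#' machinery: each 7-item factor has two marker items with loadings 0.90
#' and five distractors with loadings at most 0.60, inter-factor
#' correlation -0.37, retest stability 0.85, and the three calibrated
#' covariates of [pss14_population()].  The marker pairs are items 2 and
#' 14 (helplessness) and items 6 and 10 (self-efficacy).
#'
#' @inheritParams pss14_population
#' @param marker_loading loading of the two markers per factor.
#' @return a [population_model()].
#' @export
shortform_population <- function(marker_loading = 0.90, factor_cor = -0.37,
                                 retest_stability = 0.85) {
  help_items <- c(1, 2, 3, 8, 11, 12, 14)
  self_items <- c(4, 5, 6, 7, 9, 10, 13)
  ## markers first-listed per factor; distractors all <= 0.60
  help_load <- c(0.55, marker_loading, 0.60, 0.50, 0.45, 0.40, marker_loading)
  self_load <- c(0.50, 0.55, marker_loading, 0.60, 0.40, marker_loading, 0.45)
  L <- matrix(0, 14, 2, dimnames = list(sprintf("item%02d", 1:14),
                                        c("helplessness", "selfefficacy")))
  L[help_items, 1] <- help_load
  L[self_items, 2] <- self_load
  Phi <- matrix(c(1, factor_cor, factor_cor, 1), 2)
  hnames <- sprintf("item%02d", help_items)
  snames <- sprintf("item%02d", self_items)
  covs <- list(
    covariate_spec("mhp", c(helplessness = 1), 0.59, hnames),
    covariate_spec("recovery", c(helplessness = -1), -0.53, hnames),
    covariate_spec("ase", c(selfefficacy = 1), 0.44, snames)
  )
  population_model(L, Phi, retest_stability = retest_stability,
                   covariates = covs)
}

#' Items of the default two-factor pools
#' @return named list of item-name vectors per factor.
#' @export
default_pools <- function() {
  list(helplessness = sprintf("item%02d", c(1, 2, 3, 8, 11, 12, 14)),
       selfefficacy = sprintf("item%02d", c(4, 5, 6, 7, 9, 10, 13)))
}
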