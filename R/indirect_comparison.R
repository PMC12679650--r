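EFFECT_SCALES <- c("mean_difference", "log_gmr", "log_hr")

#' Construct a relative-effect summary
#'
#' A within-trial contrast (active minus control) on one analysis scale:
#' mean difference for eGFR change, log geometric-mean ratio for proteinuria
#' ratios, log hazard ratio for the composite endpoint.
#'
#' @param scale One of `"mean_difference"`, `"log_gmr"`, `"log_hr"`.
#' @param estimate Point estimate on the analysis scale.
#' @param se Standard error (> 0).
#' @param timepoint Canonical timepoint label, or `NA` for `"overall"`.
#' @param source `"index_weighted"` or `"comparator_published"`.
#' @return Object of class `relative_effect`.
#' @export
relative_effect <- function(scale, estimate, se, timepoint = NA_real_,
                            source = "index_weighted") {
  scale <- match.arg(scale, EFFECT_SCALES)
  if (!is_number(estimate)) stop_maic("estimate must be a finite number")
  if (!is_number(se) || se <= 0) stop_maic("se must be a positive number")
  structure(list(scale = scale, timepoint = as.numeric(timepoint),
                 estimate = estimate, se = se, source = source),
            class = "relative_effect")
}

#' Standard error from a reported 95% interval
#'
#' Published comparator effects arrive as point estimates with 95% intervals;
#' the SE on the analysis scale is `(upper - lower) / (2 * 1.959964)`.
#' Ratio-scale (`log_gmr`, `log_hr`) intervals are log-transformed first, so
#' asymmetry on the natural scale is expected.
#'
#' @param lower,upper Interval bounds on the reporting scale.
#' @param scale Analysis scale of the effect.
#' @param interval_type `"confidence"` or `"credible"` (label only).
#' @return Standard error on the analysis scale.
#' @export
se_from_interval <- function(lower, upper,
                             scale = c("mean_difference", "log_gmr", "log_hr"),
                             interval_type = c("confidence", "credible")) {
  scale <- match.arg(scale)
  match.arg(interval_type)
  if (!is_number(lower) || !is_number(upper) || lower >= upper)
    stop_maic("interval bounds must satisfy lower < upper")
  if (scale != "mean_difference") {
    if (lower <= 0) stop_maic("ratio-scale interval must be strictly positive")
    lower <- log(lower)
    upper <- log(upper)
  }
  (upper - lower) / (2 * Z95)
}

new_comparison_result <- function(scale, timepoint, estimate, se, method,
                                  interval_type, extra = list()) {
  res <- c(list(scale = scale, timepoint = timepoint, estimate = estimate,
                se = se, lower = estimate - Z95 * se,
                upper = estimate + Z95 * se,
                interval_type = interval_type, method = method), extra)
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$method, " | scale: ", x$scale,
      if (!is.na(x$timepoint)) paste0(" | timepoint: ", x$timepoint) else "",
      "\n  estimate ", signif(x$estimate, 4), " (95% ",
      substr(x$interval_type, 1, 4), ". interval ", signif(x$lower, 4), " to ",
      signif(x$upper, 4), ")\n", sep = "")
  invisible(x)
}

check_combinable <- function(index, comparator) {
  stopifnot(inherits(index, "relative_effect"),
            inherits(comparator, "relative_effect"))
  if (index$scale != comparator$scale)
    stop_maic("scale mismatch: ", index$scale, " vs ", comparator$scale)
  if (!identical(is.na(index$timepoint), is.na(comparator$timepoint)))
    stop_maic("timepoint mismatch between effects")
}

#' Anchored indirect comparison by the Bucher method
#'
#' Both treatments are compared through the common control arm: the
#' active-vs-active contrast is the difference of the two within-trial
#' relative effects, with variances summed under independence, and a normal
#' 95% confidence interval.
#'
#' @param index Weighted index-trial [relative_effect] (active vs control).
#' @param comparator Published comparator-trial [relative_effect].
#' @return A `comparison_result` with method `"anchored_bucher"`.
#' @export
bucher_combine <- function(index, comparator) {
  check_combinable(index, comparator)
  new_comparison_result(
    scale = index$scale, timepoint = index$timepoint,
    estimate = index$estimate - comparator$estimate,
    se = sqrt(index$se^2 + comparator$se^2),
    method = "anchored_bucher", interval_type = "confidence"
  )
}

#' Anchored comparison by conjugate Bayesian fixed-effects meta-analysis
#'
#' Two-trial fixed-effects network with a shared anchor: each trial's
#' relative effect gets a normal likelihood around its basic parameter, the
#' basic parameters get independent `N(0, prior_sd^2)` priors, and the
#' active-vs-active contrast is the difference of the two (conjugate normal)
#' posteriors. The closed-form posterior is always computed; with
#' `draws > 0` an independent posterior sampler is run as a check and its
#' summaries attached (`sampler_mean`, `sampler_lower`, `sampler_upper`,
#' `sampler_mc_se`). With a vague prior the posterior reproduces the Bucher
#' estimate and SE.
#'
#' @param index,comparator [relative_effect] objects on the same scale.
#' @param prior_sd Prior standard deviation for both basic parameters.
#' @param draws Number of posterior draws for the sampler check (0 = none).
#' @param seed Seed for the sampler.
#' @return A `comparison_result` with method `"anchored_bayes"` and a 95%
#'   credible interval.
#' @export
bayes_fe_nma <- function(index, comparator, prior_sd = 100, draws = 0,
                         seed = NULL) {
  check_combinable(index, comparator)
  if (!is_number(prior_sd) || prior_sd <= 0)
    stop_maic("prior_sd must be positive")
  post <- function(eff) {
    prec <- 1 / eff$se^2 + 1 / prior_sd^2
    list(mean = (eff$estimate / eff$se^2) / prec, var = 1 / prec)
  }
  p1 <- post(index)
  p2 <- post(comparator)
  est <- p1$mean - p2$mean
  sd_post <- sqrt(p1$var + p2$var)
  extra <- list(prior_sd = prior_sd)
  if (draws > 0) {
    if (!is.null(seed)) set.seed(seed)
    d <- stats::rnorm(draws, p1$mean, sqrt(p1$var)) -
      stats::rnorm(draws, p2$mean, sqrt(p2$var))
    extra <- c(extra, list(
      sampler_mean = mean(d),
      sampler_lower = unname(stats::quantile(d, 0.025)),
      sampler_upper = unname(stats::quantile(d, 0.975)),
      sampler_mc_se = sd_post / sqrt(draws),
      draws = draws
    ))
  }
  new_comparison_result(
    scale = index$scale, timepoint = index$timepoint,
    estimate = est, se = sd_post,
    method = "anchored_bayes", interval_type = "credible", extra = extra
  )
}

#' Unanchored arm-level indirect comparison
#'
#' Difference of two arm-level effects (index weighted active arm vs the
#' comparator's published active arm) with SEs combined in quadrature and a
#' normal 95% confidence interval. Relies entirely on the covariate
#' adjustment; no common comparator is used.
#'
#' @param index_arm,comparator_arm Lists or [relative_effect]-like objects
#'   with `estimate` and `se` on the same analysis scale.
#' @param scale Analysis scale of both effects.
#' @param timepoint Canonical timepoint label.
#' @return A `comparison_result` with method `"unanchored"`.
#' @export
unanchored_contrast <- function(index_arm, comparator_arm,
                                scale = c("mean_difference", "log_gmr",
                                          "log_hr"),
                                timepoint = NA_real_) {
  scale <- match.arg(scale)
  for (e in list(index_arm, comparator_arm)) {
    if (!is_number(e$estimate) || !is_number(e$se) || e$se <= 0)
      stop_maic("arm effects need finite estimate and positive se")
    if (!is.null(e$scale) && e$scale != scale)
      stop_maic("scale mismatch: ", e$scale, " vs ", scale)
  }
  new_comparison_result(
    scale = scale, timepoint = as.numeric(timepoint),
    estimate = index_arm$estimate - comparator_arm$estimate,
    se = sqrt(index_arm$se^2 + comparator_arm$se^2),
    method = "unanchored", interval_type = "confidence"
  )
}

#' Back-transform a comparison to its reporting scale
#'
#' Log-scale ratio results are exponentiated to geometric-mean ratios or
#' hazard ratios (optionally `100 * (exp(x) - 1)` percent change for GMRs);
#' mean differences pass through unchanged. The mapping is monotone, so
#' interval ordering is preserved.
#'
#' @param result A `comparison_result`.
#' @param as_percent For `log_gmr`, report percent change instead of the
#'   ratio.
#' @return A `comparison_result` on the reporting scale (`"gmr"`, `"hr"`,
#'   `"percent_change"` or unchanged `"mean_difference"`).
#' @export
back_transform <- function(result, as_percent = FALSE) {
  stopifnot(inherits(result, "comparison_result"))
  if (result$scale == "mean_difference") return(result)
  if (!result$scale %in% c("log_gmr", "log_hr"))
    stop_maic("cannot back-transform scale ", result$scale)
  f <- if (result$scale == "log_gmr" && as_percent)
    function(x) 100 * (expm1(x)) else exp
  out <- result
  out$scale <- if (result$scale == "log_hr") "hr"
    else if (as_percent) "percent_change" else "gmr"
  out$estimate <- f(result$estimate)
  out$lower <- f(result$lower)
  out$upper <- f(result$upper)
  out$se <- NA_real_  # SE does not transform; intervals carry the uncertainty
  out
}
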