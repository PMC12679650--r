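ENDPOINT_SCALES <- c(egfr = "mean_difference", upcr = "log_gmr",
                     uacr = "log_gmr", composite = "log_hr")

# Fit the index trial's weighted relative effects for one endpoint.
index_relative_effects <- function(ipd, endpoint, weights) {
  if (endpoint == "composite") {
    cx <- fit_weighted_cox(derive_composite_events(ipd), weights)
    return(data.frame(endpoint = "composite", timepoint = NA_real_,
                      scale = "log_hr", estimate = cx$log_hr, se = cx$se,
                      stringsAsFactors = FALSE))
  }
  fit <- fit_mmrm(build_change_outcomes(ipd, endpoint), weights,
                  scale = if (endpoint == "egfr") "absolute_change" else "log_ratio")
  data.frame(endpoint = endpoint, timepoint = fit$contrasts$visit,
             scale = ENDPOINT_SCALES[[endpoint]],
             estimate = fit$contrasts$estimate, se = fit$contrasts$se,
             stringsAsFactors = FALSE)
}

comparison_to_row <- function(endpoint, timepoint, cr) {
  data.frame(endpoint = endpoint, timepoint = timepoint, method = cr$method,
             estimate = cr$estimate, lower = cr$lower, upper = cr$upper,
             scale = cr$scale, interval_type = cr$interval_type,
             stringsAsFactors = FALSE)
}

#' Run the full indirect-comparison pipeline
#'
#' Executes read/validate, matching, weighted outcome models and cross-trial
#' synthesis for the requested endpoints. In anchored mode both index arms
#' enter one weight fit against the overall comparator targets; each
#' endpoint's weighted within-trial contrast is combined with the published
#' comparator contrast by the conjugate Bayesian fixed-effects model (and
#' optionally the Bucher closed form). In unanchored mode each index arm is
#' reweighted to the corresponding comparator arm's targets and the two
#' reweighted arms are contrasted directly through the weighted outcome
#' models; no anchor enters.
#'
#' @param ipd A [maic_ipd] object or CSV path ([read_ipd]).
#' @param targets An [aggregate_targets] object, a JSON/YAML path
#'   ([read_targets]), or a `read_targets()` result list; for anchored mode
#'   the overall-population targets.
#' @param summaries A [comparator_summary] of published relative effects
#'   (required for anchored mode; timepoints in comparator weeks).
#' @param mode `"anchored"` or `"unanchored"`.
#' @param endpoints Subset of `c("egfr", "upcr", "uacr", "composite")`.
#' @param targets_active,targets_control Arm-specific targets for unanchored
#'   mode (default: `targets`). The arm-specific threshold conventions (e.g.
#'   a lower UACR cutoff for the active-vs-active match) live in these
#'   target sets.
#' @param prior_sd,draws,seed Options for [bayes_fe_nma].
#' @param include_bucher Also emit Bucher rows in anchored mode.
#' @param out_dir Optional directory; when given, writes `weights.csv`,
#'   `baseline_table.csv`, `forest_table.csv` and `manifest.json`.
#' @return List of class `maic_run`: `mode`, `weights` (one or two
#'   `maic_weights`), `baseline_table`, `index_effects`, `forest`
#'   (data.frame), `manifest`.
#' @export
run_pipeline <- function(ipd, targets, summaries = NULL,
                         mode = c("anchored", "unanchored"),
                         endpoints = c("egfr", "upcr", "uacr", "composite"),
                         targets_active = NULL, targets_control = NULL,
                         prior_sd = 100, draws = 0, seed = 1L,
                         include_bucher = FALSE, out_dir = NULL) {
  mode <- match.arg(mode)
  bad <- setdiff(endpoints, names(ENDPOINT_SCALES))
  if (length(bad) > 0) stop_maic("unknown endpoint(s): ", paste(bad, collapse = ", "))
  input_files <- character(0)
  if (is.character(ipd)) {
    input_files <- c(input_files, ipd = ipd)
    ipd <- read_ipd(ipd)
  }
  if (is.character(targets)) {
    input_files <- c(input_files, targets = targets)
    targets <- read_targets(targets)
  }
  if (is.list(targets) && !inherits(targets, "aggregate_targets")) {
    if (is.null(summaries)) summaries <- targets$summaries
    targets <- targets$targets
  }

  stage <- "matching"
  res <- tryCatch({
    if (mode == "anchored") {
      wts <- estimate_weights(ipd, targets, mode = "anchored")
      baseline <- weighted_baseline_table(ipd, wts, targets)
      w_named <- stats::setNames(wts$weights_raw, wts$subject_id)
      weights_out <- list(anchored = wts)
    } else {
      ta <- targets_active %||% targets
      tc <- targets_control %||% targets
      wa <- estimate_weights(ipd, ta, mode = "unanchored_active")
      wc <- estimate_weights(ipd, tc, mode = "unanchored_control")
      baseline <- rbind(
        cbind(arm = "active", weighted_baseline_table(ipd, wa, ta)),
        cbind(arm = "control", weighted_baseline_table(ipd, wc, tc))
      )
      w_named <- c(stats::setNames(wa$weights_raw, wa$subject_id),
                   stats::setNames(wc$weights_raw, wc$subject_id))
      weights_out <- list(active = wa, control = wc)
    }

    stage <- "outcome_models"
    idx <- do.call(rbind, lapply(endpoints, function(ep)
      index_relative_effects(ipd, ep, w_named)))

    stage <- "indirect_comparison"
    forest <- list()
    for (r in seq_len(nrow(idx))) {
      ep <- idx$endpoint[r]
      tp <- idx$timepoint[r]
      ie <- relative_effect(idx$scale[r], idx$estimate[r], idx$se[r],
                            timepoint = tp, source = "index_weighted")
      if (mode == "anchored") {
        if (is.null(summaries)) stop_maic("anchored mode needs comparator summaries")
        tp_match <- if (is.na(tp)) is.na(summaries$timepoint)
          else !is.na(summaries$timepoint) &
            summaries$timepoint == map_timepoint(tp, "month")
        sm <- summaries[summaries$endpoint == ep & is.na(summaries$arm) &
                          tp_match, , drop = FALSE]
        if (nrow(sm) != 1)
          stop_maic("no unique comparator summary for ", ep, " at timepoint ", tp)
        # comparator_summary stores bounds on the analysis scale already
        ce <- relative_effect(sm$scale, sm$estimate,
                              (sm$upper - sm$lower) / (2 * Z95),
                              timepoint = tp, source = "comparator_published")
        forest[[length(forest) + 1]] <- comparison_to_row(
          ep, tp, bayes_fe_nma(ie, ce, prior_sd = prior_sd, draws = draws,
                               seed = child_seed(seed, length(forest) + 1)))
        if (include_bucher)
          forest[[length(forest) + 1]] <-
            comparison_to_row(ep, tp, bucher_combine(ie, ce))
      } else {
        cr <- new_comparison_result(ie$scale, tp, ie$estimate, ie$se,
                                    method = "unanchored",
                                    interval_type = "confidence")
        forest[[length(forest) + 1]] <- comparison_to_row(ep, tp, cr)
      }
    }
    forest <- do.call(rbind, forest)
    list(weights = weights_out, baseline = baseline, idx = idx,
         forest = forest)
  }, error = function(e) {
    stop_maic("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })

  ess <- vapply(res$weights, function(w) w$ess, 0)
  manifest <- list(
    package = "maickit",
    version = as.character(utils::packageVersion("maickit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = mode, endpoints = endpoints,
    options = list(prior_sd = prior_sd, draws = draws, seed = seed,
                   z_multiplier = Z95, solver_tol = 1e-10,
                   ties_method = "efron", mmrm_covariance = "unstructured"),
    counts = list(
      subjects_read = n_subjects(ipd),
      excluded = lapply(res$weights, function(w) w$excluded_subjects),
      ess = as.list(ess)
    ),
    input_md5 = if (length(input_files) > 0)
      as.list(tools::md5sum(input_files)) else list(),
    timepoint_map = timepoint_map()
  )

  out <- list(mode = mode, weights = res$weights,
              baseline_table = res$baseline, index_effects = res$idx,
              forest = res$forest, manifest = manifest)
  class(out) <- "maic_run"
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.maic_run <- function(x, ...) {
  cat("<maic_run> mode:", x$mode, "| ESS:",
      paste(names(x$weights), round(vapply(x$weights, function(w) w$ess, 0), 1),
            collapse = ", "), "\n")
  print(x$forest, row.names = FALSE)
  invisible(x)
}

# Write the run's tabular outputs and manifest to a directory.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wdf <- do.call(rbind, lapply(names(run$weights), function(nm) {
    w <- run$weights[[nm]]
    data.frame(fit = nm, subject_id = w$subject_id, weight = w$weights,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(wdf, file.path(out_dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(run$baseline_table,
                   file.path(out_dir, "baseline_table.csv"), row.names = FALSE)
  export_forest_table(run$forest, file.path(out_dir, "forest_table.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Export a forest table to CSV
#'
#' One row per (endpoint, timepoint, method) in canonical order, written at
#' full double precision so a re-read reproduces the estimates exactly.
#'
#' @param forest data.frame with columns `endpoint`, `timepoint`, `method`,
#'   `estimate`, `lower`, `upper`, `scale`, `interval_type`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_forest_table <- function(forest, path) {
  need <- c("endpoint", "timepoint", "method", "estimate", "lower", "upper",
            "scale", "interval_type")
  miss <- setdiff(need, names(forest))
  if (nrow(forest) == 0) stop_maic("empty forest table")
  if (length(miss) > 0)
    stop_maic("forest table missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(forest$endpoint, forest$timepoint, forest$method)
  if (anyDuplicated(key))
    stop_maic("duplicate forest rows: ", key[duplicated(key)][1])
  ord <- order(match(forest$endpoint, names(ENDPOINT_SCALES)),
               forest$timepoint, forest$method)
  out <- forest[ord, need]
  for (col in c("timepoint", "estimate", "lower", "upper")) {
    s <- sprintf("%.17g", out[[col]])
    s[is.na(out[[col]])] <- NA_character_
    out[[col]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back an exported forest table
#'
#' @param path CSV written by [export_forest_table].
#' @return data.frame with numeric estimate columns restored.
#' @export
read_forest_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("timepoint", "estimate", "lower", "upper"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
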