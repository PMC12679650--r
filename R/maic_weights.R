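#' Center a covariate matrix on its aggregate targets
#'
#' Subtracts each target value from its covariate column, the standard MAIC
#' preprocessing step: with centered columns `C`, weights `exp(C %*% beta)`
#' balance the weighted sample moments onto the targets. Each target is
#' checked for feasibility — it must lie strictly inside the observed range
#' of its column (and both levels of a binary column must be present) unless
#' the column is already exactly balanced, in which case it is flagged.
#'
#' @param mat Covariate matrix from [derive_threshold_indicators].
#' @param targets Matching [aggregate_targets] (same column count/order).
#' @return Centered matrix with a logical `"balanced"` attribute per column.
#' @export
center_covariates <- function(mat, targets) {
  stopifnot(is.matrix(mat), inherits(targets, "aggregate_targets"))
  if (ncol(mat) != nrow(targets))
    stop_maic("covariate matrix has ", ncol(mat), " columns but ",
              nrow(targets), " targets")
  centered <- mat
  balanced <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    t <- targets$value[j]
    centered[, j] <- x - t
    if (all(abs(centered[, j]) < 1e-12)) {
      balanced[j] <- TRUE  # constant column equal to its target
      next
    }
    rng <- range(x)
    binary <- all(x %in% c(0, 1))
    feasible <- if (binary) {
      any(x == 0) && any(x == 1) && t > 0 && t < 1
    } else {
      t > rng[1] && t < rng[2]
    }
    if (!feasible)
      stop_maic("infeasible target for '", targets$name[j], "': value ",
                t, " not strictly inside observed range [",
                signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
  }
  attr(centered, "balanced") <- balanced
  centered
}

#' Solve for method-of-moments MAIC weights on a centered matrix
#'
#' Minimizes the convex objective `sum_i exp(c_i' beta)` by damped Newton
#' iteration with step-halving, starting at `beta = 0`. At the optimum the
#' gradient `sum_i w_i c_i` vanishes, i.e. the weighted mean of every matched
#' covariate equals its target exactly. Collinear or already-balanced columns
#' are dropped before solving (their coefficients are reported as `NA`).
#'
#' @param centered Centered covariate matrix from [center_covariates].
#' @param tol Gradient-norm tolerance, scaled by the row count.
#' @param max_iter Iteration cap.
#' @return List with `beta` (per input column), `weights_raw`
#'   (`exp(centered %*% beta)` with dropped columns contributing 0),
#'   `converged`, `iterations`, `gradient_norm`, `dropped` (column indices).
#' @export
solve_weights <- function(centered, tol = 1e-10, max_iter = 200) {
  stopifnot(is.matrix(centered))
  n <- nrow(centered)
  if (n == 0) stop_maic("no subjects to weight")
  balanced <- attr(centered, "balanced") %||%
    apply(centered, 2, function(x) all(abs(x) < 1e-12))
  keep <- which(!balanced)
  # drop collinear centered columns (e.g. coincident threshold indicators)
  if (length(keep) > 1) {
    drop <- integer(0)
    for (a in seq_along(keep)[-1]) {
      for (b in seq_len(a - 1)) {
        if (keep[b] %in% drop) next
        r <- suppressWarnings(stats::cor(centered[, keep[a]], centered[, keep[b]]))
        if (is.finite(r) && abs(r) > 1 - 1e-10) { drop <- c(drop, keep[a]); break }
      }
    }
    if (length(drop) > 0) {
      warning("dropping collinear matching column(s): ",
              paste(colnames(centered)[drop], collapse = ", "), call. = FALSE)
      keep <- setdiff(keep, drop)
    }
  }
  beta_full <- rep(NA_real_, ncol(centered))
  if (length(keep) == 0) {
    return(list(beta = beta_full, weights_raw = rep(1, n), converged = TRUE,
                iterations = 0L, gradient_norm = 0,
                dropped = seq_len(ncol(centered))))
  }
  # solve on sd-scaled columns for conditioning; rescale beta afterwards
  scl <- pmax(apply(centered[, keep, drop = FALSE], 2, stats::sd), 1e-12)
  C <- sweep(centered[, keep, drop = FALSE], 2, scl, `/`)
  beta <- rep(0, ncol(C))
  f_of <- function(b) sum(exp(C %*% b))
  f <- f_of(beta)
  iter <- 0L
  gnorm <- Inf
  repeat {
    eta <- drop(C %*% beta)
    w <- exp(eta)
    g_scaled <- drop(crossprod(C, w))
    # convergence is judged on the unscaled gradient
    gnorm <- sqrt(sum((g_scaled * scl)^2))
    if (gnorm <= tol * n || iter >= max_iter) break
    H <- crossprod(C * w, C)
    step <- tryCatch(solve(H, g_scaled), error = function(e) g_scaled / max(diag(H)))
    lambda <- 1
    repeat {
      cand <- beta - lambda * step
      fc <- f_of(cand)
      # tolerate rounding-level non-decrease so Newton steps are not
      # rejected once the objective is flat at machine precision
      if (is.finite(fc) && fc <= f + 1e-9 * (abs(f) + 1)) break
      lambda <- lambda / 2
      if (lambda < 1e-12) { cand <- beta; fc <- f; break }
    }
    beta <- cand; f <- fc
    iter <- iter + 1L
  }
  beta_full[keep] <- beta / scl
  list(beta = beta_full,
       weights_raw = drop(exp(C %*% beta)),
       converged = gnorm <= tol * n,
       iterations = iter,
       gradient_norm = gnorm,
       dropped = setdiff(seq_len(ncol(centered)), keep))
}

#' Effective sample size of a weight vector
#'
#' `(sum w)^2 / sum(w^2)`: the notional number of equally weighted subjects
#' carrying the same information. Invariant to rescaling; at most `n`, with
#' equality exactly for uniform weights.
#'
#' @param weights Positive weights.
#' @return Effective count (dimensionless).
#' @export
effective_sample_size <- function(weights) {
  if (length(weights) == 0) stop_maic("empty weight vector")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop_maic("weights must be positive and finite")
  sum(weights)^2 / sum(weights^2)
}

#' Estimate MAIC weights for a trial against aggregate targets
#'
#' Anchored matching pools both arms into one weight fit (the whole index
#' population is matched to the whole comparator population); unanchored
#' matching fits the named arm alone against the corresponding comparator
#' arm's targets. Subjects with a missing matching covariate are excluded
#' (complete-case) with a message. Reported weights are rescaled to sum to
#' the number of weighted subjects; the raw relative weights are retained and
#' all downstream results are invariant to the rescaling.
#'
#' @param ipd A [maic_ipd] object.
#' @param targets An [aggregate_targets] object.
#' @param mode `"anchored"`, `"unanchored_active"` or `"unanchored_control"`.
#' @param covariate_subset Optional character vector of target covariate
#'   names to match on (per-endpoint subsets); default uses all targets.
#' @param tol,max_iter Passed to [solve_weights].
#' @return Object of class `maic_weights`: `subject_id`, `weights` (sum n),
#'   `weights_raw`, `beta`, `ess`, `converged`, `iterations`,
#'   `gradient_norm`, `excluded_subjects`, `mode`, `targets`.
#' @export
estimate_weights <- function(ipd, targets,
                             mode = c("anchored", "unanchored_active",
                                      "unanchored_control"),
                             covariate_subset = NULL,
                             tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(ipd, "maic_ipd"))
  mode <- match.arg(mode)
  if (!is.null(covariate_subset)) {
    keep <- targets$name %in% covariate_subset
    if (!any(keep)) stop_maic("covariate_subset matches no targets")
    targets <- targets[keep, , drop = FALSE]
    class(targets) <- c("aggregate_targets", "data.frame")
  }
  sub <- switch(mode,
    anchored = ipd,
    unanchored_active = subset_arm(ipd, "active"),
    unanchored_control = subset_arm(ipd, "control"))
  mat <- derive_threshold_indicators(sub, targets, na_action = "exclude")
  centered <- center_covariates(mat, targets)
  sol <- solve_weights(centered, tol = tol, max_iter = max_iter)
  if (!sol$converged)
    stop_maic("weight solver failed to converge; gradient norm ",
              signif(sol$gradient_norm, 4))
  n <- nrow(mat)
  w_raw <- sol$weights_raw
  res <- list(
    subject_id = rownames(mat),
    weights = w_raw * n / sum(w_raw),
    weights_raw = w_raw,
    beta = stats::setNames(sol$beta, target_labels(targets)),
    ess = effective_sample_size(w_raw),
    converged = sol$converged,
    iterations = sol$iterations,
    gradient_norm = sol$gradient_norm,
    dropped_columns = target_labels(targets)[sol$dropped],
    excluded_subjects = attr(mat, "excluded_subjects"),
    mode = mode,
    targets = targets
  )
  class(res) <- "maic_weights"
  res
}

# Restrict an IPD object to one arm.
subset_arm <- function(ipd, arm) {
  keep <- ipd$subjects$arm == arm
  maic_ipd(ipd$subjects[keep, , drop = FALSE],
           ipd$visits[ipd$visits$subject_id %in%
                        ipd$subjects$subject_id[keep], , drop = FALSE])
}

#' @export
print.maic_weights <- function(x, ...) {
  cat("<maic_weights> mode:", x$mode, "\n")
  cat("  subjects weighted:", length(x$weights),
      " excluded:", length(x$excluded_subjects), "\n")
  cat("  ESS:", round(x$ess, 1), " (", round(100 * x$ess / length(x$weights)),
      "% of weighted n)\n", sep = "")
  cat("  converged:", x$converged, "in", x$iterations,
      "iterations; gradient norm", signif(x$gradient_norm, 3), "\n")
  invisible(x)
}

# Align a maic_weights object with an IPD object, returning the per-subject
# weight vector (NA-excluded subjects get weight 0 rows dropped).
weights_for <- function(ipd, wts) {
  if (is.null(wts)) return(stats::setNames(rep(1, n_subjects(ipd)),
                                           ipd$subjects$subject_id))
  if (inherits(wts, "maic_weights"))
    return(stats::setNames(wts$weights_raw, wts$subject_id))
  if (is.numeric(wts)) {
    if (is.null(names(wts))) {
      if (length(wts) != n_subjects(ipd))
        stop_maic("weight vector length ", length(wts),
                  " does not match ", n_subjects(ipd), " subjects")
      return(stats::setNames(wts, ipd$subjects$subject_id))
    }
    return(wts)
  }
  stop_maic("weights must be NULL, numeric, or a maic_weights object")
}

#' Baseline table before and after weighting
#'
#' Reproduces the published three-column matching table: the unweighted
#' sample moment, the aggregate target, and the MAIC-weighted moment for each
#' matched characteristic, with proportions on the percentage scale. The
#' weighted column equals the target column at solver precision.
#'
#' @param ipd A [maic_ipd] object.
#' @param weights A `maic_weights` object fitted on `ipd` and `targets`.
#' @param targets The [aggregate_targets] used in the fit.
#' @return data.frame: `parameter`, `unweighted`, `target`, `weighted`.
#' @export
weighted_baseline_table <- function(ipd, weights, targets) {
  stopifnot(inherits(weights, "maic_weights"))
  sub <- switch(weights$mode,
    anchored = ipd,
    unanchored_active = subset_arm(ipd, "active"),
    unanchored_control = subset_arm(ipd, "control"))
  mat <- derive_threshold_indicators(sub, targets, na_action = "exclude")
  if (nrow(mat) != length(weights$weights_raw))
    stop_maic("weights were not fitted on these records (", nrow(mat),
              " vs ", length(weights$weights_raw), " subjects)")
  w <- weights$weights_raw
  pct <- ifelse(targets$kind == "mean", 1, 100)
  data.frame(
    parameter = target_labels(targets),
    unweighted = colMeans(mat) * pct,
    target = targets$value * pct,
    weighted = drop(crossprod(mat, w) / sum(w)) * pct,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Summarize a weight distribution
#'
#' Deterministic, permutation-invariant summary of the (rescaled) weights:
#' quantiles, dispersion, and a fixed-bin histogram whose edges are recorded
#' for the run manifest.
#'
#' @param weights Numeric weights or a `maic_weights` object.
#' @param n_bins Number of equal-width histogram bins over `[0, max]`.
#' @return List: `quantiles`, `max_min_ratio`, `cv`, `ess`, `bin_edges`,
#'   `bin_counts`.
#' @export
weight_distribution_summary <- function(weights, n_bins = 20) {
  if (inherits(weights, "maic_weights")) weights <- weights$weights
  if (length(weights) == 0 || any(weights <= 0))
    stop_maic("weights must be positive")
  w <- weights * length(weights) / sum(weights)
  edges <- seq(0, max(w), length.out = n_bins + 1)
  counts <- as.vector(table(cut(w, breaks = edges, include.lowest = TRUE)))
  list(
    quantiles = stats::quantile(w, c(0, 0.25, 0.5, 0.75, 1), names = TRUE),
    max_min_ratio = max(w) / min(w),
    cv = stats::sd(w) / mean(w),
    ess = effective_sample_size(w),
    bin_edges = edges,
    bin_counts = counts
  )
}
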