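# Shared fixture builders and independent oracles for the test suite.

# Minimal valid subject table; covariates can be overridden per subject.
toy_subjects <- function(n, arm = rep(c("active", "control"), length.out = n),
                         ...) {
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    trial_id = "TOY",
    arm = arm,
    age = 45,
    male = 1L,
    white = 1L,
    egfr_baseline = 60,
    upcr_baseline = 1.2,
    uacr_baseline = 0.9,
    uprot24h_baseline = 1.5,
    event_time = NA_real_,
    event_type = NA_character_,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

# One visit row per subject-timepoint; egfr defaults to a flat series.
toy_visits <- function(subject_id, timepoints = c(9, 12, 24), egfr = 58,
                       upcr = 1.0, uacr = 0.8) {
  expand <- expand.grid(timepoint = timepoints, subject_id = subject_id,
                        stringsAsFactors = FALSE)
  data.frame(subject_id = expand$subject_id, timepoint = expand$timepoint,
             egfr = egfr, upcr = upcr, uacr = uacr,
             stringsAsFactors = FALSE)
}

toy_ipd <- function(n = 4, ...) {
  s <- toy_subjects(n, ...)
  maic_ipd(s, toy_visits(s$subject_id))
}

# The standard seven-moment target layout with arbitrary values.
toy_targets <- function(age = 46, male = 0.698, white = 0.6733, egfr = 56.95,
                        upcr = 1.44, uacr_gt = 0.5, uprot_gt = 0.5) {
  aggregate_targets(
    name = c("age", "male", "white", "egfr", "upcr", "uacr", "uprot24h"),
    kind = c("mean", "proportion", "proportion", "mean", "mean",
             "threshold_proportion", "threshold_proportion"),
    value = c(age, male, white, egfr, upcr, uacr_gt, uprot_gt),
    threshold = c(NA, NA, NA, NA, NA, 1.1, 1.8)
  )
}

# Random feasible weighting instance: n rows, k columns (mix of continuous
# and binary), target strictly inside the convex hull via a random convex
# combination of the rows.
random_instance <- function(n, k) {
  X <- sapply(seq_len(k), function(j) {
    if (j %% 2 == 0) stats::rbinom(n, 1, 0.5) else stats::runif(n, -1, 1)
  })
  X <- matrix(X, n, k)
  # retry until binary columns have both levels
  for (j in seq_len(k)) {
    while (length(unique(X[, j])) < 2) {
      X[, j] <- if (j %% 2 == 0) stats::rbinom(n, 1, 0.5)
        else stats::runif(n, -1, 1)
    }
  }
  a <- stats::rgamma(n, 1)
  target <- drop(crossprod(X, a / sum(a)))
  list(X = X, target = target, centered = sweep(X, 2, target))
}

# Independent oracle: nested grid search for the beta minimizing
# sum(exp(C beta)), refined until the grid step is below `step_tol`.
grid_search_beta <- function(C, span = 5, step_tol = 1e-6) {
  k <- ncol(C)
  center <- rep(0, k)
  width <- span
  pts_1d <- 13
  repeat {
    grids <- lapply(seq_len(k), function(j)
      seq(center[j] - width, center[j] + width, length.out = pts_1d))
    G <- as.matrix(expand.grid(grids))
    vals <- colSums(exp(C %*% t(G)))
    center <- as.numeric(G[which.min(vals), ])
    step <- 2 * width / (pts_1d - 1)
    if (step < step_tol) return(center)
    width <- 2 * step  # keep a neighborhood around the current best
  }
}

# Independent oracle: bisection on the 1-D weighted-moment equation
# sum(w x)/sum(w) = target with w = exp((x - target) beta).
bisect_beta <- function(x, target, lo = -50, hi = 50, tol = 1e-12) {
  h <- function(b) {
    w <- exp((x - target) * b)
    sum(w * x) / sum(w) - target
  }
  stats::uniroot(h, c(lo, hi), tol = tol)$root
}

# Independent oracle: weighted Cox partial likelihood (no ties assumed),
# maximized by 1-D grid refinement over the log hazard ratio.
cox_partial_loglik <- function(beta, time, status, x, w) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; x <- x[ord]; w <- w[ord]
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (x[i] * beta -
                         log(sum(w[risk] * exp(x[risk] * beta))))
  }
  ll
}

grid_search_cox <- function(time, status, x, w, span = 5, step_tol = 1e-6) {
  center <- 0
  width <- span
  repeat {
    grid <- seq(center - width, center + width, length.out = 41)
    vals <- vapply(grid, cox_partial_loglik, 0, time, status, x, w)
    center <- grid[which.max(vals)]
    step <- 2 * width / 40
    if (step < step_tol) return(center)
    width <- 2 * step
  }
}

# Calibrated 364-subject index trial plus the shipped comparator targets,
# reused across weighting tests.
calibrated_index_trial <- function(seed = 11) {
  cfg <- index_like_config(seed = seed)
  list(ipd = calibrate_trial_moments(generate_trial(cfg), attr(cfg, "targets")),
       own_targets = attr(cfg, "targets"),
       match_targets = read_targets(
         system.file("extdata", "comparator_targets.json",
                     package = "maickit"))$targets)
}
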