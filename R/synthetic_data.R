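COVARIATE_ORDER <- c("age", "male", "white", "egfr", "upcr", "uacr", "uprot24h")

#' Default marginal family hints for the covariate generator
#'
#' Distribution family and spread for each baseline covariate; location
#' parameters are filled in by [calibrate_marginals] from target moments.
#' Ages and eGFR are truncated normals (both are bounded in trial
#' populations), the binary covariates Bernoulli, and the three proteinuria
#' measures log-normal with fixed log-scale SDs.
#'
#' @return Named list of marginal hint lists.
#' @export
default_marginal_hints <- function() {
  list(
    age = list(dist = "truncnorm", sd = 12, lower = 18, upper = 85),
    male = list(dist = "bernoulli"),
    white = list(dist = "bernoulli"),
    egfr = list(dist = "truncnorm", sd = 13, lower = 15, upper = 105),
    upcr = list(dist = "lognormal", sdlog = 0.55),
    uacr = list(dist = "lognormal", sdlog = 0.70),
    uprot24h = list(dist = "lognormal", sdlog = 0.60)
  )
}

#' Default Gaussian-copula correlation among baseline covariates
#'
#' The three proteinuria measures are strongly positively correlated with
#' one another, and moderately negatively correlated with eGFR; age is
#' mildly negatively correlated with eGFR. The joint distribution of the
#' real trials is unpublished, so this matrix is an explicit modeling
#' assumption recorded in run manifests.
#'
#' @return 7x7 correlation matrix over `age, male, white, egfr, upcr, uacr,
#'   uprot24h`.
#' @export
default_copula_correlation <- function() {
  K <- length(COVARIATE_ORDER)
  R <- diag(K)
  dimnames(R) <- list(COVARIATE_ORDER, COVARIATE_ORDER)
  set_cor <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_cor("age", "egfr", -0.30)
  set_cor("egfr", "upcr", -0.25)
  set_cor("egfr", "uacr", -0.20)
  set_cor("egfr", "uprot24h", -0.25)
  set_cor("upcr", "uacr", 0.80)
  set_cor("upcr", "uprot24h", 0.85)
  set_cor("uacr", "uprot24h", 0.75)
  R
}

# mean of a normal truncated to [lower, upper]
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# inverse CDF of the truncated normal
truncnorm_q <- function(u, mu, sd, lower, upper) {
  pa <- stats::pnorm(lower, mu, sd)
  pb <- stats::pnorm(upper, mu, sd)
  stats::qnorm(pa + u * (pb - pa), mu, sd)
}

#' Calibrate covariate marginals to aggregate target moments
#'
#' Returns marginal parameters whose analytic moments equal the targets:
#' Bernoulli `p` is the target proportion; a truncated normal's location is
#' solved so the truncated mean equals the target mean at the hinted SD; a
#' log-normal's `meanlog` is `log(target) - sdlog^2 / 2` for a mean target,
#' or `log(threshold) - sdlog * qnorm(1 - p)` for a threshold-proportion
#' target (so e.g. `P(X > t) = 0.5` pins the median at `t`). When a
#' covariate carries both a mean and a threshold target the threshold takes
#' precedence, with a message.
#'
#' @param targets An [aggregate_targets] object (one moment per covariate,
#'   plus optional threshold constraints).
#' @param hints Marginal family hints; see [default_marginal_hints].
#' @return Named list of fully parameterized marginals, in canonical
#'   covariate order.
#' @export
calibrate_marginals <- function(targets, hints = default_marginal_hints()) {
  stopifnot(inherits(targets, "aggregate_targets"))
  out <- list()
  for (nm in intersect(COVARIATE_ORDER, unique(targets$name))) {
    rows <- targets[targets$name == nm, , drop = FALSE]
    h <- hints[[nm]]
    if (is.null(h)) stop_maic("no marginal hint for covariate '", nm, "'")
    thr <- rows[rows$kind == "threshold_proportion", , drop = FALSE]
    mn <- rows[rows$kind == "mean", , drop = FALSE]
    pr <- rows[rows$kind == "proportion", , drop = FALSE]
    m <- h
    if (h$dist == "bernoulli") {
      if (nrow(pr) != 1) stop_maic("covariate '", nm, "' needs one proportion target")
      m$p <- pr$value[1]
    } else if (h$dist == "truncnorm") {
      if (nrow(mn) != 1) stop_maic("covariate '", nm, "' needs one mean target")
      tgt <- mn$value[1]
      if (tgt <= h$lower || tgt >= h$upper)
        stop_maic("mean target for '", nm, "' outside truncation bounds")
      m$mean <- stats::uniroot(
        function(mu) truncnorm_mean(mu, h$sd, h$lower, h$upper) - tgt,
        interval = c(h$lower - 6 * h$sd, h$upper + 6 * h$sd), tol = 1e-12
      )$root
    } else if (h$dist == "lognormal") {
      if (nrow(thr) >= 1) {
        if (nrow(mn) >= 1)
          message("covariate '", nm,
                  "': threshold target takes precedence over mean target")
        if (nrow(thr) > 1)
          stop_maic("multiple threshold targets for '", nm,
                    "' cannot be satisfied by a two-parameter log-normal")
        p <- thr$value[1]
        if (p <= 0 || p >= 1)
          stop_maic("threshold proportion for '", nm, "' must be in (0, 1)")
        p_above <- if (thr$direction[1] == "greater") p else 1 - p
        m$meanlog <- log(thr$threshold[1]) - h$sdlog * stats::qnorm(1 - p_above)
      } else if (nrow(mn) == 1) {
        if (mn$value[1] <= 0) stop_maic("log-normal mean target must be positive")
        m$meanlog <- log(mn$value[1]) - h$sdlog^2 / 2
      } else stop_maic("covariate '", nm, "' needs a mean or threshold target")
    } else stop_maic("unknown marginal family '", h$dist, "'")
    out[[nm]] <- m
  }
  out
}

default_trajectory <- function(endpoint, role = c("index", "comparator")) {
  role <- match.arg(role)
  # per-arm mean changes at months 9/12/24 (eGFR: ml/min/1.73m^2; ratios: log)
  traj <- switch(endpoint,
    egfr = if (role == "index")
      list(active = c(1.0, -0.5, -3.0), control = c(-4.0, -5.5, -9.0))
    else
      list(active = c(-1.0, -2.0, -5.0), control = c(-4.0, -6.0, -10.0)),
    upcr = if (role == "index")
      list(active = c(-0.35, -0.45, -0.35), control = c(-0.05, -0.08, -0.10))
    else
      list(active = c(-0.45, -0.50, -0.55), control = c(-0.10, -0.12, -0.15)),
    uacr = if (role == "index")
      list(active = c(-0.45, -0.55, -0.40), control = c(-0.05, -0.08, -0.10))
    else
      list(active = c(-0.50, -0.55, -0.60), control = c(-0.10, -0.12, -0.15))
  )
  noise <- switch(endpoint,
    egfr = list(intercept_sd = 4, resid_sd = c(5, 6, 8), resid_corr = 0.5),
    upcr = list(intercept_sd = 0.25, resid_sd = c(0.30, 0.32, 0.35),
                resid_corr = 0.5),
    uacr = list(intercept_sd = 0.30, resid_sd = c(0.35, 0.38, 0.42),
                resid_corr = 0.5)
  )
  c(traj, noise)
}

default_event_model <- function() {
  # Weibull PH baseline; terminal (ESKD/death) events are uncommon over the
  # 24-month window, matching a slowly progressing nephropathy
  list(shape = 1.2, rate = 0.0035, log_hr_active = -0.3,
       beta_egfr = -0.02, beta_log_upcr = 0.40, eskd_prob = 0.6)
}

#' Build a validated generator configuration
#'
#' @param trial_id Trial label stamped on every subject.
#' @param n Number of subjects.
#' @param marginals Calibrated covariate marginals ([calibrate_marginals]).
#' @param allocation Active-arm allocation fraction in (0, 1).
#' @param correlation Copula correlation matrix
#'   ([default_copula_correlation]).
#' @param visit_schedule Post-baseline visit months.
#' @param egfr,upcr,uacr Trajectory settings: per-arm mean changes per visit
#'   (`active`, `control`), `intercept_sd`, per-visit `resid_sd`, and
#'   exchangeable `resid_corr`.
#' @param events Weibull proportional-hazards terminal-event model: `shape`,
#'   `rate`, `log_hr_active`, `beta_egfr`, `beta_log_upcr`, `eskd_prob`.
#' @param seed Integer seed; all randomness in [generate_trial] flows from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(trial_id, n, marginals, allocation = 0.5,
                             correlation = default_copula_correlation(),
                             visit_schedule = c(9, 12, 24),
                             egfr = default_trajectory("egfr"),
                             upcr = default_trajectory("upcr"),
                             uacr = default_trajectory("uacr"),
                             events = default_event_model(),
                             seed = 1L) {
  if (!is_number(n) || n < 2) stop_maic("n must be at least 2")
  if (!is_number(allocation) || allocation <= 0 || allocation >= 1)
    stop_maic("allocation must be in (0, 1)")
  miss <- setdiff(names(marginals), COVARIATE_ORDER)
  if (length(miss) > 0) stop_maic("unknown marginal(s): ", paste(miss, collapse = ", "))
  if (length(setdiff(COVARIATE_ORDER, names(marginals))) > 0)
    stop_maic("marginals must cover all of: ", paste(COVARIATE_ORDER, collapse = ", "))
  K <- length(COVARIATE_ORDER)
  if (!is.matrix(correlation) || any(dim(correlation) != K) ||
      any(abs(diag(correlation) - 1) > 1e-12) ||
      any(abs(correlation - t(correlation)) > 1e-12))
    stop_maic("correlation must be a symmetric unit-diagonal ", K, "x", K, " matrix")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_maic("correlation matrix is not positive definite")
  V <- length(visit_schedule)
  for (ep in list(egfr = egfr, upcr = upcr, uacr = uacr)) {
    if (length(ep$active) != V || length(ep$control) != V)
      stop_maic("trajectory effect vectors must match the visit schedule")
    if (ep$intercept_sd < 0 || any(ep$resid_sd < 0))
      stop_maic("trajectory SDs must be non-negative")
    if (ep$resid_corr <= -1 / max(V - 1, 1) || ep$resid_corr >= 1)
      stop_maic("resid_corr outside the exchangeable-correlation range")
    if (!is.null(ep$modifier)) {
      if (is.null(ep$modifier$name) || is.null(ep$modifier$coef) ||
          !ep$modifier$name %in% COVARIATE_ORDER)
        stop_maic("trajectory modifier needs a covariate 'name' and 'coef'")
    }
  }
  structure(list(trial_id = trial_id, n = as.integer(n),
                 allocation = allocation,
                 marginals = marginals[COVARIATE_ORDER],
                 correlation = correlation,
                 visit_schedule = visit_schedule,
                 egfr = egfr, upcr = upcr, uacr = uacr,
                 events = events, seed = as.integer(seed)),
            class = "generator_config")
}

marginal_q <- function(u, m) {
  switch(m$dist,
    truncnorm = truncnorm_q(u, m$mean, m$sd, m$lower, m$upper),
    bernoulli = as.numeric(u <= m$p),
    lognormal = stats::qlnorm(u, m$meanlog, m$sdlog),
    stop_maic("unknown marginal family '", m$dist, "'"))
}

# n x V draws from MVN(0, Sigma) with exchangeable correlation rho and
# per-visit SDs
resid_draws <- function(n, sd, rho) {
  V <- length(sd)
  R <- (1 - rho) * diag(V) + rho
  Z <- matrix(stats::rnorm(n * V), n, V) %*% chol(R)
  sweep(Z, 2, sd, `*`)  # a zero SD silences that visit's residual
}

#' Generate a synthetic parallel-arm trial
#'
#' Baseline covariates are drawn through a Gaussian copula with the
#' configured marginals; eGFR visits are baseline plus the arm-by-visit mean
#' change, a subject random intercept and correlated residuals; UPCR/UACR
#' visits are baseline times the exponential of the analogous log-scale
#' process; terminal ESKD/death events come from a Weibull
#' proportional-hazards model with administrative censoring at the last
#' scheduled visit. Identical seeds give identical trials.
#'
#' @param config A [generator_config].
#' @return A [maic_ipd] object.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n
  K <- length(COVARIATE_ORDER)
  n_active <- round(n * config$allocation)
  arm <- sample(rep(c("active", "control"), c(n_active, n - n_active)))

  Z <- matrix(stats::rnorm(n * K), n, K) %*% chol(config$correlation)
  U <- stats::pnorm(Z)
  cov <- stats::setNames(vector("list", K), COVARIATE_ORDER)
  for (k in seq_len(K)) {
    nm <- COVARIATE_ORDER[k]
    cov[[nm]] <- marginal_q(U[, k], config$marginals[[nm]])
  }

  sched <- config$visit_schedule
  V <- length(sched)
  active <- as.numeric(arm == "active")
  visit_mat <- function(ep, baseline, log_scale) {
    eff <- outer(active, ep$active) + outer(1 - active, ep$control)
    if (!is.null(ep$modifier)) {
      # treatment-effect modification: the active-arm effect shifts by
      # coef * z_i, z a raw covariate or a strict threshold indicator
      m <- ep$modifier
      z <- cov[[m$name]]
      if (!is.null(m$threshold)) z <- as.numeric(z > m$threshold)
      eff <- eff + outer(active * z, rep_len(m$coef, V))
    }
    b <- stats::rnorm(n, 0, ep$intercept_sd)
    E <- resid_draws(n, ep$resid_sd, ep$resid_corr)
    if (log_scale) baseline * exp(eff + b + E)
    else pmax(baseline + eff + b + E, 1)
  }
  egfr_v <- visit_mat(config$egfr, cov$egfr, FALSE)
  upcr_v <- visit_mat(config$upcr, cov$upcr, TRUE)
  uacr_v <- visit_mat(config$uacr, cov$uacr, TRUE)

  em <- config$events
  lp <- em$log_hr_active * active +
    em$beta_egfr * (cov$egfr - 60) +
    em$beta_log_upcr * (log(pmax(cov$upcr, 1e-6)) - log(1.5))
  u_ev <- stats::runif(n)
  t_ev <- (-log(u_ev) / (em$rate * exp(lp)))^(1 / em$shape)
  admin <- max(sched)
  is_event <- t_ev <= admin
  comp <- ifelse(stats::runif(n) <= em$eskd_prob, "eskd", "death")
  event_time <- ifelse(is_event, t_ev, admin)
  event_type <- ifelse(is_event, comp, "censored")

  ids <- sprintf("%s-%04d", config$trial_id, seq_len(n))
  subjects <- data.frame(
    subject_id = ids, trial_id = config$trial_id, arm = arm,
    age = cov$age, male = as.integer(cov$male), white = as.integer(cov$white),
    egfr_baseline = cov$egfr, upcr_baseline = cov$upcr,
    uacr_baseline = cov$uacr, uprot24h_baseline = cov$uprot24h,
    event_time = event_time, event_type = event_type,
    stringsAsFactors = FALSE
  )
  visits <- data.frame(
    subject_id = rep(ids, each = V),
    timepoint = rep(sched, n),
    egfr = as.vector(t(egfr_v)),
    upcr = as.vector(t(upcr_v)),
    uacr = as.vector(t(uacr_v)),
    stringsAsFactors = FALSE
  )
  maic_ipd(subjects, visits)
}

#' Calibrate a generated trial's sample moments exactly onto targets
#'
#' Deterministic post-draw adjustment so the finite sample reproduces a
#' printed baseline column exactly (up to the integer resolution of count
#' targets): continuous mean targets are met by shifting (age, eGFR) or
#' rescaling (positive proteinuria measures) the covariate, proportion
#' targets by flipping the minimal number of indicators (last subjects
#' first), and threshold-proportion targets by rescaling so that exactly
#' `round(n * p)` subjects lie strictly beyond the threshold. Visit
#' measurements are shifted/rescaled together with their baselines, so
#' change scores and ratios stay coherent.
#'
#' @param ipd A [maic_ipd] object.
#' @param targets [aggregate_targets] describing the moments to reproduce.
#' @return The adjusted [maic_ipd].
#' @export
calibrate_trial_moments <- function(ipd, targets) {
  stopifnot(inherits(ipd, "maic_ipd"), inherits(targets, "aggregate_targets"))
  subj <- ipd$subjects
  vis <- ipd$visits
  n <- nrow(subj)
  for (j in seq_len(nrow(targets))) {
    nm <- targets$name[j]
    col <- COVARIATE_COLUMNS[[nm]]
    x <- subj[[col]]
    if (anyNA(x)) stop_maic("cannot calibrate '", nm, "' with missing values")
    kind <- targets$kind[j]
    if (kind == "mean") {
      tgt <- targets$value[j]
      if (nm %in% c("age", "egfr")) {
        delta <- tgt - mean(x)
        subj[[col]] <- x + delta
        if (nm == "egfr") vis$egfr <- vis$egfr + delta
      } else {
        if (any(x <= 0)) stop_maic("cannot rescale non-positive '", nm, "'")
        cfac <- tgt / mean(x)
        subj[[col]] <- x * cfac
        if (nm %in% c("upcr", "uacr")) vis[[nm]] <- vis[[nm]] * cfac
      }
    } else if (kind == "proportion") {
      k <- round(n * targets$value[j])
      ones <- which(x == 1)
      if (length(ones) > k) {
        subj[[col]][rev(ones)[seq_len(length(ones) - k)]] <- 0L
      } else if (length(ones) < k) {
        zeros <- which(x == 0)
        subj[[col]][rev(zeros)[seq_len(k - length(ones))]] <- 1L
      }
    } else {  # threshold_proportion
      if (targets$direction[j] != "greater")
        stop_maic("calibration implemented for 'greater' thresholds only")
      k <- round(n * targets$value[j])
      if (k < 1 || k >= n)
        stop_maic("threshold target for '", nm, "' needs 0 < count < n")
      s <- sort(x, decreasing = TRUE)
      cfac <- targets$threshold[j] / sqrt(s[k] * s[k + 1])
      subj[[col]] <- x * cfac
      if (nm %in% c("upcr", "uacr")) vis[[nm]] <- vis[[nm]] * cfac
    }
  }
  maic_ipd(subj, vis)
}

read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  tl <- doc$targets
  targets <- aggregate_targets(
    name = vapply(tl, function(e) e$name, ""),
    kind = vapply(tl, function(e) e$kind, ""),
    value = vapply(tl, function(e) as.numeric(e$value), 0),
    threshold = vapply(tl, function(e) as.numeric(e$threshold %||% NA_real_), 0),
    direction = vapply(tl, function(e) e$direction %||% NA_character_, ""),
    source = vapply(tl, function(e) e$source %||% NA_character_, "")
  )
  list(trial_id = doc$trial_id, n = doc$n_subjects,
       allocation = doc$allocation %||% 0.5, targets = targets)
}

#' Generator configuration for the bundled index-trial scenario
#'
#' Reads the shipped `index_like.yaml` scenario (synthetic marginals matching
#' the index trial's printed baseline column) and returns a ready
#' [generator_config].
#'
#' @param seed Integer seed.
#' @param n Optional override of the scenario's sample size.
#' @return A [generator_config]; its `targets` attribute holds the printed
#'   column as an [aggregate_targets] object.
#' @export
index_like_config <- function(seed = 1L, n = NULL) {
  scenario_config("index_like.yaml", seed, n, role = "index")
}

#' Generator configuration for the bundled comparator-trial scenario
#'
#' As [index_like_config], for the shipped `comparator_like.yaml` scenario
#' (marginals matching the comparator trial's printed baseline column).
#'
#' @param seed Integer seed.
#' @param n Optional override of the scenario's sample size.
#' @return A [generator_config] with a `targets` attribute.
#' @export
comparator_like_config <- function(seed = 1L, n = NULL) {
  scenario_config("comparator_like.yaml", seed, n, role = "comparator")
}

scenario_config <- function(file, seed, n, role) {
  path <- system.file("extdata", file, package = "maickit", mustWork = TRUE)
  sc <- read_scenario(path)
  cfg <- generator_config(
    trial_id = sc$trial_id, n = n %||% sc$n, allocation = sc$allocation,
    marginals = calibrate_marginals(sc$targets),
    egfr = default_trajectory("egfr", role),
    upcr = default_trajectory("upcr", role),
    uacr = default_trajectory("uacr", role),
    seed = seed
  )
  attr(cfg, "targets") <- sc$targets
  cfg
}

empirical_targets <- function(ipd, template) {
  mat <- derive_threshold_indicators(ipd, template)
  tg <- template
  tg$value <- unname(colMeans(mat))
  tg$value_raw <- ifelse(tg$kind == "mean", tg$value, tg$value * 100)
  tg$source <- "synthetic comparator IPD"
  tg
}

apply_effects <- function(cfg, eff) {
  for (ep in c("egfr", "upcr", "uacr")) {
    if (!is.null(eff[[ep]])) {
      for (a in c("active", "control", "modifier"))
        if (!is.null(eff[[ep]][[a]])) cfg[[ep]][[a]] <- eff[[ep]][[a]]
    }
  }
  if (!is.null(eff$log_hr)) cfg$events$log_hr_active <- eff$log_hr
  cfg
}

#' Generate a paired two-trial scenario for end-to-end testing
#'
#' Reproduces the information regime of an anchored MAIC: the index trial is
#' returned as IPD; the comparator trial is generated, summarized into
#' aggregate baseline targets (its empirical moments, in the standard
#' seven-moment layout) and within-trial relative effects (repeated-measures
#' contrasts per visit and a composite log hazard ratio, fitted on its own
#' IPD), and its IPD is then discarded.
#'
#' @param true_effects Optional overrides, a list with elements `index` and
#'   `comparator`, each holding per-endpoint per-arm visit effects (e.g.
#'   `list(egfr = list(active = c(5, 4, 3)))`) and optionally `log_hr`.
#' @param seed Master seed; the two trials use derived child seeds.
#' @param n_index,n_comparator Trial sizes.
#' @param endpoints Endpoints summarized for the comparator.
#' @return List: `index_ipd`, `targets` (comparator [aggregate_targets]);
#'   `true_difference` reports the base arm-effect differences and ignores
#'   any configured effect modifiers (whose population truth depends on the
#'   covariate distribution);
#'   `summaries` ([comparator_summary] of relative effects, week labels),
#'   `true_difference` (active-vs-active truth per endpoint/visit implied by
#'   the configured effects, on the analysis scale).
#' @export
make_paired_scenario <- function(true_effects = NULL, seed = 1L,
                                 n_index = 364, n_comparator = 404,
                                 endpoints = c("egfr", "upcr", "uacr",
                                               "composite")) {
  cfg_i <- index_like_config(seed = child_seed(seed, 1), n = n_index)
  cfg_c <- comparator_like_config(seed = child_seed(seed, 2), n = n_comparator)
  if (!is.null(true_effects$index)) cfg_i <- apply_effects(cfg_i, true_effects$index)
  if (!is.null(true_effects$comparator))
    cfg_c <- apply_effects(cfg_c, true_effects$comparator)

  index_ipd <- generate_trial(cfg_i)
  comp_ipd <- generate_trial(cfg_c)
  targets <- empirical_targets(comp_ipd, attr(cfg_c, "targets"))

  rows <- list()
  for (ep in setdiff(endpoints, "composite")) {
    fit <- fit_mmrm(build_change_outcomes(comp_ipd, ep),
                    scale = if (ep == "egfr") "absolute_change" else "log_ratio")
    sc <- if (ep == "egfr") "mean_difference" else "log_gmr"
    rows[[ep]] <- data.frame(
      endpoint = ep, timepoint = map_timepoint(fit$contrasts$visit, "month"),
      scale = sc, estimate = fit$contrasts$estimate,
      lower = fit$contrasts$estimate - Z95 * fit$contrasts$se,
      upper = fit$contrasts$estimate + Z95 * fit$contrasts$se,
      stringsAsFactors = FALSE
    )
  }
  if ("composite" %in% endpoints) {
    cx <- fit_weighted_cox(derive_composite_events(comp_ipd))
    rows$composite <- data.frame(
      endpoint = "composite", timepoint = NA_real_, scale = "log_hr",
      estimate = cx$log_hr, lower = cx$log_hr - Z95 * cx$se,
      upper = cx$log_hr + Z95 * cx$se, stringsAsFactors = FALSE
    )
  }
  fr <- do.call(rbind, rows)
  summaries <- comparator_summary(
    endpoint = fr$endpoint, timepoint = fr$timepoint, scale = fr$scale,
    estimate = fr$estimate, lower = fr$lower, upper = fr$upper,
    interval_type = "confidence"
  )

  truth <- list()
  for (ep in setdiff(endpoints, "composite"))
    truth[[ep]] <- (cfg_i[[ep]]$active - cfg_i[[ep]]$control) -
      (cfg_c[[ep]]$active - cfg_c[[ep]]$control)
  if ("composite" %in% endpoints)
    truth$composite <- cfg_i$events$log_hr_active - cfg_c$events$log_hr_active

  list(index_ipd = index_ipd, targets = targets, summaries = summaries,
       true_difference = truth, visit_schedule = cfg_i$visit_schedule)
}
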