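#' Build longitudinal change outcomes for one endpoint
#'
#' eGFR is analyzed as the absolute change from baseline at each visit;
#' UPCR and UACR as the log of the post-baseline to baseline ratio, with the
#' log-transformed baseline carried as the model covariate. Missing visit
#' values stay missing. Subjects with a zero baseline on a ratio endpoint
#' cannot form a ratio and are excluded with a message.
#'
#' @param ipd A [maic_ipd] object.
#' @param endpoint `"egfr"`, `"upcr"` or `"uacr"`.
#' @return data.frame: `subject_id`, `arm`, `timepoint`, `baseline` (eGFR, or
#'   log baseline for ratio endpoints), `value` (change or log ratio).
#' @export
build_change_outcomes <- function(ipd, endpoint = c("egfr", "upcr", "uacr")) {
  stopifnot(inherits(ipd, "maic_ipd"))
  endpoint <- match.arg(endpoint)
  subj <- ipd$subjects
  base_col <- paste0(endpoint, "_baseline")
  base <- stats::setNames(subj[[base_col]], subj$subject_id)
  if (endpoint != "egfr") {
    zero <- !is.na(base) & base == 0
    if (any(zero)) {
      message(sum(zero), " subject(s) excluded from ", endpoint,
              " log-ratio analysis (zero baseline)")
      base[zero] <- NA
    }
  }
  v <- ipd$visits
  out <- data.frame(
    subject_id = v$subject_id,
    arm = subj$arm[match(v$subject_id, subj$subject_id)],
    timepoint = v$timepoint,
    stringsAsFactors = FALSE
  )
  b <- base[out$subject_id]
  raw <- v[[endpoint]]
  if (endpoint == "egfr") {
    out$baseline <- b
    out$value <- raw - b
  } else {
    out$baseline <- log(b)
    out$value <- log(raw) - log(b)
  }
  out <- out[!is.na(base[out$subject_id]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Build the MMRM fixed-effects design: treatment, visit, baseline,
# baseline-by-visit and treatment-by-visit. With one visit the interactions
# are dropped and the model is the baseline-adjusted ANCOVA.
mmrm_design <- function(dat) {
  dat$arm <- factor(dat$arm, levels = ARM_LEVELS)
  dat$visit <- factor(dat$timepoint, levels = sort(unique(dat$timepoint)))
  form <- if (nlevels(dat$visit) > 1) ~ arm + visit + baseline +
    baseline:visit + arm:visit else ~ arm + baseline
  X <- stats::model.matrix(form, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_maic("singular MMRM design; aliased term(s): ",
              paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                    collapse = ", "))
  list(X = X, dat = dat, visits = levels(dat$visit))
}

#' Fit a weighted mixed-effects model for repeated measures
#'
#' Longitudinal fixed-effects model with treatment group, visit, baseline,
#' baseline-by-visit and treatment-by-visit terms and an unstructured
#' within-subject residual covariance, estimated by iterative generalized
#' least squares on the weighted restricted likelihood. Observations carry
#' the subject's MAIC weight (treated as fixed); contrast standard errors use
#' a robust sandwich estimator. Least-squares means are evaluated at the
#' weighted mean baseline. Missing visits enter through the likelihood of the
#' observed visits only (no imputation). If the unstructured covariance fails
#' to stay positive definite the fit falls back to compound symmetry with a
#' warning.
#'
#' @param outcomes Long table from [build_change_outcomes].
#' @param weights Per-subject weights: `NULL` (uniform), a named numeric
#'   vector, or a `maic_weights` object.
#' @param scale Label stored on the fit: `"absolute_change"` or `"log_ratio"`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap for the covariance update.
#' @return Object of class `mmrm_fit`: `coefficients`, `vcov` (sandwich),
#'   `ls_means` (arm x visit with SE), `contrasts` (active minus control per
#'   visit with SE), `residual_covariance`, `scale`, `n_used`, `converged`,
#'   `iterations`, `covariance_structure`.
#' @export
fit_mmrm <- function(outcomes, weights = NULL,
                     scale = c("absolute_change", "log_ratio"),
                     tol = 1e-8, max_iter = 100) {
  scale <- match.arg(scale)
  dat <- outcomes[!is.na(outcomes$value) & !is.na(outcomes$baseline), ,
                  drop = FALSE]
  if (nrow(dat) == 0) stop_maic("no usable outcome rows")
  for (a in ARM_LEVELS)
    if (length(unique(dat$subject_id[dat$arm == a])) < 2)
      stop_maic("need at least 2 subjects with post-baseline data per arm")

  if (inherits(weights, "maic_weights"))
    weights <- stats::setNames(weights$weights_raw, weights$subject_id)
  sid <- unique(dat$subject_id)
  if (is.null(weights)) {
    w_subj <- stats::setNames(rep(1, length(sid)), sid)
  } else {
    if (is.null(names(weights)))
      stop_maic("weights must be named by subject_id (or a maic_weights object)")
    w_subj <- weights[sid]
    if (anyNA(w_subj)) {
      dat <- dat[dat$subject_id %in% names(weights)[!is.na(weights)], ,
                 drop = FALSE]
      sid <- unique(dat$subject_id)
      w_subj <- weights[sid]
    }
  }
  w_subj <- w_subj * length(w_subj) / sum(w_subj)  # mean-1 normalization

  des <- mmrm_design(dat)
  X <- des$X
  dat <- des$dat
  V <- length(des$visits)
  p <- ncol(X)
  y <- dat$value
  vis_idx <- as.integer(dat$visit)
  subj_rows <- split(seq_len(nrow(dat)), dat$subject_id)
  subj_rows <- subj_rows[sid]
  n <- length(sid)
  q <- p / V  # per-visit parameter count (saturated-by-visit design)

  # initial covariance: pooled residual variance from weighted OLS
  w_obs <- w_subj[dat$subject_id]
  beta <- stats::lm.wfit(X, y, w_obs)$coefficients
  r <- y - drop(X %*% beta)
  s2_init <- max(sum(w_obs * r^2) / sum(w_obs), 1e-10)
  Sigma <- diag(V) * s2_init

  pattern_key <- vapply(subj_rows, function(ix)
    paste(vis_idx[ix], collapse = ","), "")
  loglik <- -Inf
  converged <- FALSE
  structure_used <- "unstructured"
  iter <- 0L

  gls_pass <- function(Sigma) {
    inv_cache <- list()
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (i in seq_len(n)) {
      ix <- subj_rows[[i]]
      key <- pattern_key[i]
      Oi <- inv_cache[[key]]
      if (is.null(Oi)) {
        Oi <- solve(Sigma[vis_idx[ix], vis_idx[ix], drop = FALSE])
        inv_cache[[key]] <- Oi
      }
      Xi <- X[ix, , drop = FALSE]
      wXO <- w_subj[i] * crossprod(Xi, Oi)
      A <- A + wXO %*% Xi
      b <- b + drop(wXO %*% y[ix])
    }
    beta <- solve(A, b)
    r <- y - drop(X %*% beta)
    # weighted log-likelihood and meat of the sandwich
    ll <- 0
    B <- matrix(0, p, p)
    S_new <- matrix(0, V, V)
    W_pair <- matrix(0, V, V)
    for (i in seq_len(n)) {
      ix <- subj_rows[[i]]
      vi <- vis_idx[ix]
      Oi <- inv_cache[[pattern_key[i]]]
      ri <- r[ix]
      ll <- ll + w_subj[i] * (determinant(Oi)$modulus -
                                drop(crossprod(ri, Oi %*% ri)))
      ui <- w_subj[i] * drop(crossprod(X[ix, , drop = FALSE], Oi %*% ri))
      B <- B + tcrossprod(ui)
      S_new[vi, vi] <- S_new[vi, vi] + w_subj[i] * tcrossprod(ri)
      W_pair[vi, vi] <- W_pair[vi, vi] + w_subj[i]
    }
    # pairwise moment update with a residual degrees-of-freedom correction
    denom <- pmax(W_pair * (1 - q / n), 1e-8)
    list(beta = beta, A = A, B = B, ll = ll / 2,
         Sigma_new = S_new / denom, r = r)
  }

  for (iter in seq_len(max_iter)) {
    fit <- tryCatch(gls_pass(Sigma), error = function(e) NULL)
    if (is.null(fit)) break
    S_cand <- fit$Sigma_new
    # degenerate (near-perfect) fits: floor the residual variance
    diag(S_cand) <- pmax(diag(S_cand), 1e-10)
    if (inherits(tryCatch(chol(S_cand), error = function(e) e), "error")) {
      # fall back to compound symmetry
      v_bar <- mean(diag(S_cand))
      off <- S_cand[upper.tri(S_cand)]
      rho <- if (length(off) > 0) mean(off) / v_bar else 0
      rho <- max(min(rho, 0.99), -1 / max(V - 1, 1) + 0.01)
      S_cand <- v_bar * ((1 - rho) * diag(V) + rho)
      if (structure_used != "compound_symmetry")
        warning("unstructured covariance not positive definite; ",
                "falling back to compound symmetry", call. = FALSE)
      structure_used <- "compound_symmetry"
    }
    if (is.finite(loglik) &&
        abs(fit$ll - loglik) <= tol * (abs(loglik) + 1e-8)) {
      converged <- TRUE
      Sigma <- S_cand
      loglik <- fit$ll
      break
    }
    Sigma <- S_cand
    loglik <- fit$ll
  }
  fit <- gls_pass(Sigma)
  beta <- fit$beta
  Ainv <- solve(fit$A)
  vc <- Ainv %*% fit$B %*% Ainv
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  # least-squares means at the weighted mean baseline of the analysis set
  first <- !duplicated(dat$subject_id)
  b_bar <- sum(w_subj[dat$subject_id[first]] * dat$baseline[first]) /
    sum(w_subj[dat$subject_id[first]])
  grid <- expand.grid(arm = ARM_LEVELS, visit = des$visits,
                      stringsAsFactors = FALSE)
  Lrows <- t(vapply(seq_len(nrow(grid)), function(k) {
    nd <- dat[1, , drop = FALSE]
    nd$arm <- factor(grid$arm[k], levels = ARM_LEVELS)
    nd$visit <- factor(grid$visit[k], levels = des$visits)
    nd$baseline <- b_bar
    form <- if (V > 1) ~ arm + visit + baseline + baseline:visit + arm:visit
      else ~ arm + baseline
    drop(stats::model.matrix(form, nd))
  }, numeric(p)))
  ls_means <- data.frame(
    arm = grid$arm,
    visit = as.numeric(grid$visit),
    estimate = drop(Lrows %*% beta),
    se = sqrt(rowSums((Lrows %*% vc) * Lrows)),
    stringsAsFactors = FALSE
  )
  contrasts <- do.call(rbind, lapply(des$visits, function(v) {
    La <- Lrows[grid$arm == "active" & grid$visit == v, ]
    Lc <- Lrows[grid$arm == "control" & grid$visit == v, ]
    L <- La - Lc
    data.frame(visit = as.numeric(v), estimate = drop(L %*% beta),
               se = sqrt(drop(t(L) %*% vc %*% L)))
  }))
  res <- list(
    coefficients = beta, vcov = vc, ls_means = ls_means,
    contrasts = contrasts, residual_covariance = Sigma,
    scale = scale, n_used = n, n_obs = nrow(dat),
    converged = converged, iterations = iter, loglik = loglik,
    covariance_structure = structure_used, baseline_mean = b_bar,
    visits = as.numeric(des$visits)
  )
  class(res) <- "mmrm_fit"
  res
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat("<mmrm_fit> scale:", x$scale, "| covariance:", x$covariance_structure,
      "|", x$n_used, "subjects,", x$n_obs, "observations\n")
  cat("Active - control contrasts:\n")
  print(transform(x$contrasts,
                  lower = estimate - Z95 * se,
                  upper = estimate + Z95 * se), row.names = FALSE)
  invisible(x)
}

#' Derive composite kidney-failure events
#'
#' Composite of the first of: confirmed 40% eGFR reduction (a visit value at
#' or below 60% of baseline, confirmed at the next scheduled visit, with the
#' event dated at the first qualifying visit), end-stage kidney disease, or
#' all-cause death. Subjects with none of these are censored at their last
#' visit; subjects with no post-baseline data are censored at time 0 with a
#' warning.
#'
#' @param ipd A [maic_ipd] object (ESKD/death carried in `event_time` /
#'   `event_type`).
#' @return data.frame of class `composite_events`: `subject_id`, `arm`,
#'   `time` (months), `status` (`"event"`/`"censored"`), `component`.
#' @export
derive_composite_events <- function(ipd) {
  stopifnot(inherits(ipd, "maic_ipd"))
  subj <- ipd$subjects
  vis <- split(ipd$visits, ipd$visits$subject_id)
  no_data <- character(0)
  rows <- lapply(seq_len(nrow(subj)), function(i) {
    id <- subj$subject_id[i]
    v <- vis[[id]]
    cand_time <- numeric(0)
    cand_comp <- character(0)
    # confirmed 40% eGFR reduction from the visit series
    if (!is.null(v)) {
      ev <- v[!is.na(v$egfr), , drop = FALSE]
      if (nrow(ev) >= 2) {
        thr <- 0.6 * subj$egfr_baseline[i]
        qual <- ev$egfr <= thr
        hit <- which(qual[-nrow(ev)] & qual[-1])
        if (length(hit) > 0) {
          cand_time <- c(cand_time, ev$timepoint[hit[1]])
          cand_comp <- c(cand_comp, "egfr40_confirmed")
        }
      }
    }
    if (!is.na(subj$event_type[i]) &&
        subj$event_type[i] %in% c("eskd", "death")) {
      cand_time <- c(cand_time, subj$event_time[i])
      cand_comp <- c(cand_comp, subj$event_type[i])
    }
    last_visit <- if (is.null(v) || nrow(v) == 0) NA_real_ else max(v$timepoint)
    if (is.na(last_visit)) {
      no_data <<- c(no_data, id)
      last_visit <- 0
    }
    if (length(cand_time) > 0) {
      k <- which.min(cand_time)  # earliest component wins
      data.frame(subject_id = id, arm = subj$arm[i], time = cand_time[k],
                 status = "event", component = cand_comp[k],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = id, arm = subj$arm[i], time = last_visit,
                 status = "censored", component = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  if (length(no_data) > 0)
    warning(length(no_data), " subject(s) with no post-baseline data ",
            "censored at time 0", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("composite_events", "data.frame")
  out
}

#' Fit a weighted Cox proportional-hazards model
#'
#' Maximizes the MAIC-weighted partial likelihood for the active-vs-control
#' hazard ratio with Efron tie handling and a robust (sandwich) standard
#' error, via [survival::coxph]. If one arm has no events the log hazard
#' ratio diverges; the fit is returned with `infinite_interval = TRUE` and an
#' infinite standard error rather than an error.
#'
#' @param events [derive_composite_events] output (columns `subject_id`,
#'   `arm`, `time`, `status`).
#' @param weights Per-subject weights: `NULL`, a named numeric vector, or a
#'   `maic_weights` object.
#' @return Object of class `cox_fit`: `log_hr` (active vs control), `se`,
#'   `n_events`, `n`, `ties_method`, `infinite_interval`.
#' @export
fit_weighted_cox <- function(events, weights = NULL) {
  stopifnot(is.data.frame(events))
  if (inherits(weights, "maic_weights"))
    weights <- stats::setNames(weights$weights_raw, weights$subject_id)
  dat <- events
  dat$arm <- factor(dat$arm, levels = ARM_LEVELS)
  if (nlevels(droplevels(dat$arm)) < 2) stop_maic("need two arms")
  dat$d <- as.integer(dat$status == "event")
  if (sum(dat$d) < 1) stop_maic("need at least one event")
  w <- if (is.null(weights)) rep(1, nrow(dat)) else {
    if (is.null(names(weights))) stop_maic("weights must be named by subject_id")
    ww <- weights[dat$subject_id]
    if (anyNA(ww)) stop_maic("missing weight for subject(s): ",
                             paste(utils::head(dat$subject_id[is.na(ww)], 3),
                                   collapse = ", "))
    unname(ww)
  }
  ev_by_arm <- tapply(dat$d, dat$arm, sum)
  infinite <- any(ev_by_arm == 0)
  dat$w <- w
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, d) ~ arm, data = dat, weights = w,
                    ties = "efron", robust = TRUE)
  )
  log_hr <- unname(stats::coef(fit)[1])
  se <- unname(sqrt(fit$var[1, 1]))
  if (infinite) se <- Inf
  res <- list(log_hr = log_hr, se = se, n_events = sum(dat$d), n = nrow(dat),
              events_per_arm = as.list(ev_by_arm), ties_method = "efron",
              infinite_interval = infinite)
  class(res) <- "cox_fit"
  res
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> log HR (active vs control):", signif(x$log_hr, 4),
      "robust SE:", signif(x$se, 4), "\n")
  cat("  HR:", signif(exp(x$log_hr), 4), "95% CI:",
      signif(exp(x$log_hr - Z95 * x$se), 4), "-",
      signif(exp(x$log_hr + Z95 * x$se), 4), "\n")
  cat("  events:", x$n_events, "of", x$n, "subjects; ties:", x$ties_method,
      if (x$infinite_interval) "(one arm event-free: infinite interval)" else "",
      "\n")
  invisible(x)
}
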