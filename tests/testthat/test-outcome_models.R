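test_that("change outcomes use absolute eGFR and log proteinuria ratios", {
  s <- toy_subjects(2, egfr_baseline = c(60, 70), upcr_baseline = c(1.0, 2.0))
  ipd <- maic_ipd(s, toy_visits(s$subject_id, 9, egfr = c(58, 72),
                                upcr = c(0.5, 4.0)))
  eg <- build_change_outcomes(ipd, "egfr")
  expect_equal(eg$value, c(-2, 2))
  expect_equal(eg$baseline, c(60, 70))
  up <- build_change_outcomes(ipd, "upcr")
  expect_equal(up$value, c(log(0.5), log(2)), tolerance = 1e-12)
  expect_equal(up$baseline, log(c(1, 2)))
  # ratios 0.5 and 2.0: geometric mean of ratios is 1 (0% change)
  expect_equal(mean(up$value), 0)
})

test_that("log-ratio outcomes are invariant to a subject-level unit change", {
  s <- toy_subjects(1, arm = "active", upcr_baseline = 1.3)
  ipd1 <- maic_ipd(s, toy_visits(s$subject_id, c(9, 12), upcr = c(0.9, 0.7)))
  s2 <- s; s2$upcr_baseline <- s$upcr_baseline * 1000  # g/g -> mg/g
  ipd2 <- maic_ipd(s2, toy_visits(s$subject_id, c(9, 12),
                                  upcr = c(0.9, 0.7) * 1000))
  expect_equal(build_change_outcomes(ipd1, "upcr")$value,
               build_change_outcomes(ipd2, "upcr")$value, tolerance = 1e-12)
})

test_that("zero baselines on ratio endpoints are excluded with a message", {
  s <- toy_subjects(3, upcr_baseline = c(1, 0, 2))
  ipd <- maic_ipd(s, toy_visits(s$subject_id, 9))
  expect_message(out <- build_change_outcomes(ipd, "upcr"), "zero baseline")
  expect_false("S002" %in% out$subject_id)
})

test_that("single-visit MMRM collapses to the weighted ANCOVA contrast", {
  set.seed(501)
  n <- 60
  arm <- rep(c("active", "control"), each = n / 2)
  base <- rnorm(n, 60, 10)
  y <- 2 * (arm == "active") + 0.3 * base + rnorm(n)
  out <- data.frame(subject_id = sprintf("P%02d", 1:n), arm = arm,
                    timepoint = 9, baseline = base, value = y)
  w <- stats::setNames(rgamma(n, 2), out$subject_id)
  fit <- fit_mmrm(out, weights = w)
  lmfit <- lm(y ~ arm + base, weights = unname(w))
  expect_equal(fit$contrasts$estimate,
               -unname(coef(lmfit)["armcontrol"]), tolerance = 1e-8)
})

test_that("MMRM agrees with an independent REML fit on complete data", {
  set.seed(502)
  n <- 80
  arm <- rep(c("active", "control"), each = n / 2)
  base <- rnorm(n, 60, 8)
  Sig <- matrix(c(9, 4, 4, 16), 2)
  E <- matrix(rnorm(n * 2), n) %*% chol(Sig)
  y <- cbind(1.5 * (arm == "active") + 0.2 * base + E[, 1],
             3.0 * (arm == "active") + 0.1 * base + E[, 2])
  out <- data.frame(
    subject_id = rep(sprintf("P%02d", 1:n), each = 2),
    arm = rep(arm, each = 2),
    timepoint = rep(c(9, 12), n),
    baseline = rep(base, each = 2),
    value = as.vector(t(y))
  )
  fit <- fit_mmrm(out)
  g <- nlme::gls(
    value ~ arm * visit + baseline * visit,
    data = transform(out, visit = factor(timepoint), arm = factor(arm, ARM <- c("control", "active"))),
    correlation = nlme::corSymm(form = ~ 1 | subject_id),
    weights = nlme::varIdent(form = ~ 1 | visit),
    method = "REML"
  )
  # same contrast at each visit (different parameterizations)
  cg <- coef(g)
  gls_contrast_v1 <- unname(cg["armactive"])
  gls_contrast_v2 <- unname(cg["armactive"] + cg["armactive:visit12"])
  expect_equal(fit$contrasts$estimate[1], gls_contrast_v1, tolerance = 1e-4)
  expect_equal(fit$contrasts$estimate[2], gls_contrast_v2, tolerance = 1e-4)
  # residual covariance close to the independent REML estimate
  sg2 <- g$sigma^2
  vf <- coef(g$modelStruct$varStruct, unconstrained = FALSE, allCoef = TRUE)
  rho <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(diag(fit$residual_covariance),
               sg2 * unname(vf[c("9", "12")])^2, tolerance = 1e-2)
  expect_equal(fit$residual_covariance[1, 2],
               sg2 * prod(unname(vf)) * unname(rho), tolerance = 1e-2)
})

test_that("identical outcomes across arms give zero contrasts", {
  s <- toy_subjects(6, arm = rep(c("active", "control"), 3),
                    egfr_baseline = rep(c(55, 60, 65), each = 2))
  v <- toy_visits(s$subject_id, c(9, 12))
  v$egfr <- s$egfr_baseline[match(v$subject_id, s$subject_id)] +
    ifelse(v$timepoint == 9, -5, -8)
  fit <- fit_mmrm(build_change_outcomes(maic_ipd(s, v), "egfr"))
  expect_equal(fit$contrasts$estimate, c(0, 0), tolerance = 1e-10)
})

test_that("MMRM recovers known treatment-by-visit effects", {
  set.seed(503)
  truth <- c(5, 3, 2)
  cfg <- index_like_config(seed = 91, n = 400)
  cfg$egfr$active <- truth
  cfg$egfr$control <- c(0, 0, 0)
  ipd <- generate_trial(cfg)
  fit <- fit_mmrm(build_change_outcomes(ipd, "egfr"))
  expect_true(fit$converged)
  expect_equal(fit$covariance_structure, "unstructured")
  for (v in 1:3)
    expect_lt(abs(fit$contrasts$estimate[v] - truth[v]),
              3 * fit$contrasts$se[v])
  # residual covariance is symmetric positive definite
  S <- fit$residual_covariance
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE)$values > 0))
  # contrast equals the difference of that visit's LS means
  lm9 <- fit$ls_means[fit$ls_means$visit == 9, ]
  expect_equal(fit$contrasts$estimate[1],
               lm9$estimate[lm9$arm == "active"] -
                 lm9$estimate[lm9$arm == "control"], tolerance = 1e-10)
})

test_that("MMRM interval coverage is near nominal (smoke replication)", {
  set.seed(504)
  reps <- 50
  covered <- logical(reps)
  for (k in 1:reps) {
    cfg <- index_like_config(seed = 7000 + k, n = 120)
    cfg$egfr$active <- c(4, 3, 2)
    cfg$egfr$control <- c(0, 0, 0)
    fit <- fit_mmrm(build_change_outcomes(generate_trial(cfg), "egfr"))
    est <- fit$contrasts$estimate[1]
    se <- fit$contrasts$se[1]
    covered[k] <- (est - 1.959964 * se <= 4) && (4 <= est + 1.959964 * se)
  }
  # 50-rep smoke check: binomial 3-SE band around the nominal 95%
  expect_gte(mean(covered), 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("composite events follow the confirmed-reduction rule", {
  mk <- function(egfr_series, months = c(3, 6, 9), event_time = NA_real_,
                 event_type = NA_character_) {
    s <- toy_subjects(1, arm = "active", egfr_baseline = 60,
                      event_time = event_time, event_type = event_type)
    maic_ipd(s, toy_visits(s$subject_id, months, egfr = egfr_series))
  }
  # 40% reduction at month 6 (threshold 36), confirmed at month 9
  ev <- derive_composite_events(mk(c(50, 34, 33)))
  expect_equal(ev$status, "event")
  expect_equal(ev$component, "egfr40_confirmed")
  expect_equal(ev$time, 6)
  # qualifying value not confirmed at the next visit -> censored at last visit
  ev2 <- derive_composite_events(mk(c(34, 50), months = c(3, 6)))
  expect_equal(ev2$status, "censored")
  expect_equal(ev2$time, 6)
  # death before any eGFR qualification wins as earliest component
  ev3 <- derive_composite_events(mk(c(50, 34, 33), event_time = 5,
                                    event_type = "death"))
  expect_equal(ev3$component, "death")
  expect_equal(ev3$time, 5)
})

test_that("weighted Cox matches a brute-force partial-likelihood oracle", {
  events <- data.frame(
    subject_id = sprintf("S%d", 1:4),
    arm = c("active", "active", "control", "control"),
    time = c(1, 3, 2, 4),
    status = "event",
    stringsAsFactors = FALSE
  )
  fit <- fit_weighted_cox(events)
  x <- as.numeric(events$arm == "active")
  oracle <- grid_search_cox(events$time, rep(1, 4), x, rep(1, 4))
  expect_equal(fit$log_hr, oracle, tolerance = 1e-4)
  # weighted case against the same oracle
  w <- c(2, 1, 1.5, 0.5)
  names(w) <- events$subject_id
  fitw <- fit_weighted_cox(events, w)
  oraclew <- grid_search_cox(events$time, rep(1, 4), x, unname(w))
  expect_equal(fitw$log_hr, oraclew, tolerance = 1e-4)
})

test_that("Cox estimates respect symmetry and invariances", {
  events <- data.frame(
    subject_id = sprintf("S%d", 1:6),
    arm = rep(c("active", "control"), each = 3),
    time = rep(c(2, 5, 9), 2),   # identical event times across arms
    status = "event", stringsAsFactors = FALSE
  )
  expect_equal(fit_weighted_cox(events)$log_hr, 0, tolerance = 1e-10)
  ipd <- generate_trial(index_like_config(seed = 31, n = 150))
  ev <- derive_composite_events(ipd)
  f1 <- fit_weighted_cox(ev)
  w <- stats::setNames(rep(2, nrow(ev)), ev$subject_id)
  f2 <- fit_weighted_cox(ev, w)  # doubling all weights
  expect_equal(f1$log_hr, f2$log_hr, tolerance = 1e-10)
  ev_days <- ev; ev_days$time <- ev$time * 30.4375  # months -> days
  f3 <- fit_weighted_cox(ev_days)
  expect_equal(f1$log_hr, f3$log_hr, tolerance = 1e-10)
})

test_that("an event-free arm yields an infinite-interval flag, not an error", {
  events <- data.frame(
    subject_id = sprintf("S%d", 1:6),
    arm = rep(c("active", "control"), each = 3),
    time = c(3, 6, 9, 10, 12, 24),
    status = c("event", "event", "event", "censored", "censored", "censored"),
    stringsAsFactors = FALSE
  )
  fit <- fit_weighted_cox(events)
  expect_true(fit$infinite_interval)
  expect_equal(fit$se, Inf)
})
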