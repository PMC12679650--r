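test_that("generation is deterministic in the seed", {
  cfg <- index_like_config(seed = 5, n = 60)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a, b)
  c_ <- generate_trial(index_like_config(seed = 6, n = 60))
  expect_false(identical(a$subjects$age, c_$subjects$age))
})

test_that("large-sample moments converge to the calibrated targets", {
  cfg <- comparator_like_config(seed = 8, n = 1e5)
  ipd <- generate_trial(cfg)
  s <- ipd$subjects
  se3 <- function(x) 3 * sd(x) / sqrt(length(x))
  expect_lt(abs(mean(s$age) - 46.00), se3(s$age))
  expect_lt(abs(mean(s$egfr_baseline) - 56.95), se3(s$egfr_baseline))
  expect_lt(abs(mean(s$upcr_baseline) - 1.44), se3(s$upcr_baseline))
  expect_lt(abs(mean(s$male) - 0.698), se3(s$male))
  expect_lt(abs(mean(s$uacr_baseline > 1.1) - 0.50),
            se3(as.numeric(s$uacr_baseline > 1.1)))
  expect_lt(abs(mean(s$uprot24h_baseline > 1.8) - 0.50),
            se3(as.numeric(s$uprot24h_baseline > 1.8)))
})

test_that("zero noise and zero effects give flat eGFR trajectories", {
  cfg <- index_like_config(seed = 9, n = 20)
  cfg$egfr$active <- cfg$egfr$control <- c(0, 0, 0)
  cfg$egfr$intercept_sd <- 0
  cfg$egfr$resid_sd <- c(0, 0, 0)
  ipd <- generate_trial(cfg)
  base <- ipd$subjects$egfr_baseline[match(ipd$visits$subject_id,
                                           ipd$subjects$subject_id)]
  expect_equal(ipd$visits$egfr, base, tolerance = 1e-12)
})

test_that("marginal calibration reproduces target moments analytically", {
  tg <- aggregate_targets(
    name = c("male", "upcr", "uacr", "age"),
    kind = c("proportion", "mean", "threshold_proportion", "mean"),
    value = c(0.698, 1.44, 0.5, 46),
    threshold = c(NA, NA, 1.1, NA)
  )
  hints <- default_marginal_hints()
  hints$upcr$sdlog <- 0.6
  m <- calibrate_marginals(tg, hints)
  expect_equal(m$male$p, 0.698)
  # log-normal mean identity: E = exp(mu + sigma^2/2)
  expect_equal(m$upcr$meanlog, log(1.44) - 0.18, tolerance = 1e-12)
  expect_equal(exp(m$upcr$meanlog + m$upcr$sdlog^2 / 2), 1.44)
  # P(X > t) = 0.5 pins the median at the threshold
  expect_equal(qlnorm(0.5, m$uacr$meanlog, m$uacr$sdlog), 1.1)
  # truncated-normal location solved so the truncated mean hits the target
  expect_equal(maickit:::truncnorm_mean(m$age$mean, m$age$sd, m$age$lower,
                                        m$age$upper), 46, tolerance = 1e-9)
})

test_that("inconsistent marginal targets are rejected with a diagnostic", {
  tg <- aggregate_targets("uacr", c("threshold_proportion", "threshold_proportion"),
                          c(0.5, 0.6), threshold = c(1.1, 2.0))
  expect_error(calibrate_marginals(tg), "cannot be satisfied")
  tg2 <- aggregate_targets("age", "mean", 10)
  expect_error(calibrate_marginals(tg2), "outside truncation bounds")
})

test_that("exact moment calibration pins the finite sample", {
  tr <- calibrated_index_trial(seed = 13)
  s <- tr$ipd$subjects
  expect_equal(mean(s$age), 42.70, tolerance = 1e-10)
  expect_equal(mean(s$egfr_baseline), 57.87, tolerance = 1e-10)
  expect_equal(mean(s$upcr_baseline), 1.48, tolerance = 1e-10)
  expect_equal(sum(s$male), round(0.6593 * 364))
  expect_equal(sum(s$uacr_baseline > 1.1), round(0.4066 * 364))
  expect_equal(sum(s$uprot24h_baseline > 1.8), round(0.6566 * 364))
  # visits were rescaled coherently: log-ratios unaffected by calibration
  cfg <- index_like_config(seed = 13)
  raw <- generate_trial(cfg)
  expect_equal(build_change_outcomes(tr$ipd, "upcr")$value,
               build_change_outcomes(raw, "upcr")$value, tolerance = 1e-12)
})

test_that("a null paired scenario covers zero and shifted moments cut ESS", {
  eff <- list(egfr = list(active = c(2, 2, 2), control = c(0, 0, 0)))
  sc <- make_paired_scenario(true_effects = list(index = eff, comparator = eff),
                             seed = 23, endpoints = "egfr")
  expect_equal(sc$true_difference$egfr, c(0, 0, 0))
  run <- run_pipeline(sc$index_ipd, sc$targets, sc$summaries,
                      mode = "anchored", endpoints = "egfr")
  f <- run$forest[run$forest$timepoint == 9, ]
  expect_true(f$lower <= 0 && 0 <= f$upper)
  # index and comparator populations differ, so weights are non-uniform
  expect_lt(run$weights$anchored$ess, n_subjects(sc$index_ipd))
})

test_that("MAIC removes effect-modification bias that Bucher alone keeps", {
  # the active effect is 4 units stronger in subjects with uprot24h > 1.8;
  # the index population has ~66% such subjects, the comparator ~50%
  reps <- 100
  te <- list(
    index = list(egfr = list(
      active = c(1, 1, 1), control = c(0, 0, 0),
      modifier = list(name = "uprot24h", threshold = 1.8, coef = 4))),
    comparator = list(egfr = list(
      active = c(1, 1, 1), control = c(0, 0, 0),
      modifier = list(name = "uprot24h", threshold = 1.8, coef = 4)))
  )
  adj <- una <- numeric(reps)
  for (k in 1:reps) {
    sc <- make_paired_scenario(te, seed = 40000 + k, n_index = 300,
                               n_comparator = 300, endpoints = "egfr")
    run <- run_pipeline(sc$index_ipd, sc$targets, sc$summaries,
                        mode = "anchored", endpoints = "egfr",
                        include_bucher = TRUE)
    adj[k] <- run$forest$estimate[run$forest$timepoint == 9 &
                                    run$forest$method == "anchored_bucher"]
    # unadjusted comparison: unweighted index contrast minus comparator's
    fit <- fit_mmrm(build_change_outcomes(sc$index_ipd, "egfr"))
    cs <- sc$summaries[sc$summaries$timepoint == 36, ]
    una[k] <- fit$contrasts$estimate[1] - cs$estimate
  }
  # truth: equal effects in the comparator population -> difference 0
  mc <- sd(una) / sqrt(reps)
  expect_gt(abs(mean(una)), 3 * mc)          # unadjusted is biased
  expect_lt(abs(mean(adj)), 3 * sd(adj) / sqrt(reps))  # MAIC is not
  expect_lt(abs(mean(adj)), abs(mean(una)))  # and strictly less biased
})
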