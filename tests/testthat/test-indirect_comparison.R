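test_that("standard errors recover from published 95% intervals", {
  # symmetric interval of half-width 1.96 on the difference scale
  expect_equal(se_from_interval(-1.959964, 1.959964, "mean_difference"), 1,
               tolerance = 1e-9)
  # published mean-difference interval 3.14 to 8.20
  expect_equal(se_from_interval(3.14, 8.20, "mean_difference"), 1.2908,
               tolerance = 1e-3)
  # published hazard-ratio interval 0.31 to 2.28, log scale
  expect_equal(se_from_interval(0.31, 2.28, "log_hr"), 0.5089,
               tolerance = 1e-3)
  expect_error(se_from_interval(2, 1, "mean_difference"), "lower < upper")
  expect_error(se_from_interval(-0.5, 2, "log_hr"), "strictly positive")
})

test_that("the Bucher combination is the difference of independent normals", {
  a <- relative_effect("mean_difference", 5, 1, timepoint = 9)
  b <- relative_effect("mean_difference", 2, 1, timepoint = 9,
                       source = "comparator_published")
  res <- bucher_combine(a, b)
  expect_equal(res$estimate, 3)
  expect_equal(res$se, sqrt(2), tolerance = 1e-9)
  expect_equal(c(res$lower, res$upper), c(0.228, 5.772), tolerance = 1e-3)
  expect_equal(res$method, "anchored_bucher")
  expect_equal(res$interval_type, "confidence")
  # a near-degenerate anchor returns the index effect
  b0 <- relative_effect("mean_difference", 0, 1e-8, timepoint = 9)
  expect_equal(bucher_combine(a, b0)$estimate, 5)
  expect_equal(bucher_combine(a, b0)$se, 1, tolerance = 1e-6)
  # scale mismatch refuses
  expect_error(bucher_combine(a, relative_effect("log_hr", 0.1, 0.2,
                                                 timepoint = 9)), "scale")
})

test_that("Bucher intervals match a Monte-Carlo difference of normals", {
  set.seed(601)
  for (rep in 1:5) {
    e1 <- rnorm(1); s1 <- runif(1, 0.2, 2)
    e2 <- rnorm(1); s2 <- runif(1, 0.2, 2)
    res <- bucher_combine(relative_effect("mean_difference", e1, s1),
                          relative_effect("mean_difference", e2, s2))
    draws <- rnorm(1e6, e1, s1) - rnorm(1e6, e2, s2)
    mc_se <- sd(draws) / sqrt(1e6)
    expect_lt(abs(res$estimate - mean(draws)), 4 * mc_se)
    expect_equal(res$se, sd(draws), tolerance = 5e-3)
    expect_equal(unname(quantile(draws, c(0.025, 0.975))),
                 c(res$lower, res$upper), tolerance = 2e-2)
  }
})

test_that("the conjugate posterior equals Bucher under a vague prior", {
  set.seed(602)
  for (rep in 1:100) {
    e1 <- rnorm(1, 0, 2); s1 <- runif(1, 0.1, 2)
    e2 <- rnorm(1, 0, 2); s2 <- runif(1, 0.1, 2)
    idx <- relative_effect("mean_difference", e1, s1)
    cmp <- relative_effect("mean_difference", e2, s2)
    bay <- bayes_fe_nma(idx, cmp, prior_sd = 100)
    buc <- bucher_combine(idx, cmp)
    scale_ref <- max(abs(buc$estimate), buc$se)
    expect_lt(abs(bay$estimate - buc$estimate), 1e-3 * scale_ref)
    expect_lt(abs(bay$se - buc$se), 1e-3 * buc$se)
    expect_equal(bay$interval_type, "credible")
  }
})

test_that("a dominating prior shrinks the contrast to zero", {
  idx <- relative_effect("mean_difference", 5, 1)
  cmp <- relative_effect("mean_difference", 2, 1)
  res <- bayes_fe_nma(idx, cmp, prior_sd = 1e-6)
  expect_lt(abs(res$estimate), 1e-8)
  expect_error(bayes_fe_nma(idx, cmp, prior_sd = 0), "prior_sd")
})

test_that("the posterior sampler agrees with the closed form", {
  idx <- relative_effect("mean_difference", 5, 1)
  cmp <- relative_effect("mean_difference", 2, 1)
  res <- bayes_fe_nma(idx, cmp, prior_sd = 100, draws = 40000, seed = 99)
  expect_lt(abs(res$sampler_mean - res$estimate), 3 * res$sampler_mc_se)
  # tail quantiles: allow 3 asymptotic MC SEs of the 2.5% normal quantile
  q_se <- res$se * sqrt(0.025 * 0.975) / (dnorm(1.959964) * sqrt(40000))
  expect_lt(abs(res$sampler_lower - res$lower), 3 * q_se)
  expect_lt(abs(res$sampler_upper - res$upper), 3 * q_se)
})

test_that("unanchored contrasts difference arm-level effects in quadrature", {
  res <- unanchored_contrast(list(estimate = -2, se = 0.5),
                             list(estimate = -5, se = 0.5),
                             scale = "mean_difference", timepoint = 9)
  expect_equal(res$estimate, 3)
  expect_equal(res$se, sqrt(0.5), tolerance = 1e-9)
  expect_equal(res$method, "unanchored")
  same <- unanchored_contrast(list(estimate = -2, se = 0.5),
                              list(estimate = -2, se = 0.5),
                              scale = "mean_difference")
  expect_equal(same$estimate, 0)
  expect_true(is.finite(same$lower) && is.finite(same$upper))
})

test_that("unanchored equals Bucher when both anchors are a shared constant", {
  set.seed(603)
  a1 <- rnorm(1); a2 <- rnorm(1); anchor <- rnorm(1)
  s1 <- runif(1, 0.2, 1); s2 <- runif(1, 0.2, 1)
  buc <- bucher_combine(
    relative_effect("mean_difference", a1 - anchor, s1),
    relative_effect("mean_difference", a2 - anchor, s2))
  una <- unanchored_contrast(list(estimate = a1, se = s1),
                             list(estimate = a2, se = s2),
                             scale = "mean_difference")
  expect_equal(buc$estimate, una$estimate, tolerance = 1e-12)
  expect_equal(buc$se, una$se, tolerance = 1e-12)
})

test_that("back-transformation maps log scales monotonically", {
  r <- maickit:::new_comparison_result("log_gmr", 9, -0.3, 0.1,
                                       "anchored_bucher", "confidence")
  g <- back_transform(r)
  expect_equal(g$estimate, exp(-0.3), tolerance = 1e-4)
  expect_equal(g$scale, "gmr")
  expect_lt(g$lower, g$estimate)
  expect_gt(g$upper, g$estimate)
  p <- back_transform(r, as_percent = TRUE)
  expect_equal(p$estimate, 100 * (exp(-0.3) - 1))
  expect_equal(p$scale, "percent_change")
  h <- maickit:::new_comparison_result("log_hr", NA_real_, 0, 0.2,
                                       "anchored_bayes", "credible")
  hb <- back_transform(h)
  expect_equal(hb$estimate, 1.0)
  expect_equal(hb$scale, "hr")
  expect_true(hb$lower < 1 && hb$upper > 1)
  md <- maickit:::new_comparison_result("mean_difference", 9, 2, 1,
                                        "unanchored", "confidence")
  expect_identical(back_transform(md), md)
})

test_that("positive eGFR mean differences denote index-active benefit", {
  # index active preserves eGFR strongly; comparator active does not
  sc <- make_paired_scenario(true_effects = list(
    index = list(egfr = list(active = c(8, 8, 8), control = c(0, 0, 0))),
    comparator = list(egfr = list(active = c(0, 0, 0), control = c(0, 0, 0)))),
    seed = 17, endpoints = "egfr")
  run <- run_pipeline(sc$index_ipd, sc$targets, sc$summaries,
                      mode = "anchored", endpoints = "egfr")
  expect_true(all(run$forest$estimate > 0))
})
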