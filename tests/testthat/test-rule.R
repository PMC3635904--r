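mk_features <- function(vmax, amax, level = NULL) {
  f <- tibble::tibble(trial_index = seq_along(vmax), vmax = vmax, amax = amax)
  if (!is.null(level)) f$speed_level <- level
  f
}

test_that("the rule scatter pairs consecutive trials with carried labels", {
  f <- mk_features(c(0.5, 2), c(6.5, NA))
  sc <- build_rule_scatter(f)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$x, log(6.5))
  expect_equal(sc$y, log(6.5))               # ln(2 + 9 * 0.5)
  # T trials -> T - 1 points
  s <- generate_vmax_sequence(40, eps_sd = 0, seed = 2)
  sc2 <- build_rule_scatter(mk_features(s$vmax, s$amax))
  expect_equal(nrow(sc2), 39)
  # rule-consistent noise-free m = 1, b = 0 sits exactly on y = x
  s3 <- generate_vmax_sequence(60, m = 1, b = 0, eps_sd = 0, seed = 3)
  sc3 <- build_rule_scatter(mk_features(s3$vmax, s3$amax))
  expect_equal(sc3$y, sc3$x, tolerance = 1e-12)
  expect_error(build_rule_scatter(mk_features(c(1, -1, 2), c(1, 1, NA))),
               "non-positive")
  expect_error(build_rule_scatter(mk_features(c(1, 2), c(1, NA))[c(1, 1, 2), ]),
               "duplicated")
})

test_that("context breaks are excluded from the scatter by default", {
  s <- generate_vmax_sequence(10, eps_sd = 0, seed = 5)
  f <- mk_features(s$vmax, s$amax)
  f$context <- rep(c("dark", "mirror"), each = 5)
  expect_equal(nrow(build_rule_scatter(f)), 8)
  expect_equal(nrow(build_rule_scatter(f, drop_context_breaks = FALSE)), 9)
})

test_that("noise-free fits recover the generating line exactly", {
  for (par in list(c(0.9, 0.3), c(1.03, 0.87))) {
    s <- generate_vmax_sequence(100, m = par[1], b = par[2], eps_sd = 0,
                                seed = 6)
    fit <- fit_rule(build_rule_scatter(mk_features(s$vmax, s$amax)))
    expect_equal(fit$coef$m, par[1], tolerance = 1e-9)
    expect_equal(fit$coef$b, par[2], tolerance = 1e-9)
    expect_equal(fit$coef$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("noisy fits cover the generating parameters and keep diagnostics consistent", {
  # session-wide speed spread (the levels merged), where the inversion's
  # errors-in-x attenuation is negligible relative to the CI width
  s <- generate_vmax_sequence(100, meanlog = log(1.5), sdlog = 0.9,
                              m = 0.95, b = 1.4, eps_sd = 0.05, seed = 8)
  fit <- fit_rule(build_rule_scatter(mk_features(s$vmax, s$amax)))
  cf <- fit$coef
  expect_true(cf$ci_m_low < 0.95 && 0.95 < cf$ci_m_high)
  expect_true(cf$ci_b_low < 1.4 && 1.4 < cf$ci_b_high)
  # RMSE = sqrt(SSE / (n - 2)) on every fit
  expect_equal(cf$rmse, sqrt(cf$sse / (cf$n - 2)), tolerance = 1e-12)
  expect_equal(cf$delta + cf$m, 1, tolerance = 1e-12)
})

test_that("per-level fits disentangle level-specific rules", {
  s1 <- generate_vmax_sequence(80, meanlog = log(2), m = 0.85, b = 1.7,
                               eps_sd = 0.02, seed = 9)
  s2 <- generate_vmax_sequence(80, meanlog = log(4), m = 1.0, b = 1.1,
                               eps_sd = 0.02, seed = 10)
  f <- dplyr::bind_rows(
    mk_features(s1$vmax, s1$amax, "slow"),
    mk_features(s2$vmax, s2$amax, "fast") %>%
      dplyr::mutate(trial_index = trial_index + 80))
  sc <- build_rule_scatter(f)
  sc <- sc[sc$trial_t != 80, ]               # drop the splice pair
  per <- fit_rule(sc, "per_level")
  slow <- per$coef[per$coef$level == "slow", ]
  fast <- per$coef[per$coef$level == "fast", ]
  expect_equal(slow$m, 0.85, tolerance = 0.05)
  expect_equal(fast$m, 1.0, tolerance = 0.05)
  single <- fit_rule(sc, "single")
  expect_gt(single$coef$rmse, max(per$coef$rmse))
  dec <- split_decision(sc)
  expect_equal(dec$decision, "per_level")
  expect_lt(dec$p_value, 0.01)
})

test_that("identical level rules yield a single-line decision", {
  s <- generate_vmax_sequence(120, m = 0.95, b = 1.4, eps_sd = 0.05, seed = 12)
  f <- mk_features(s$vmax, s$amax, rep(c("slow", "fast"), 60))
  dec <- split_decision(build_rule_scatter(f))
  expect_equal(dec$decision, "single")
  expect_gt(dec$p_value, 0.05)
})

test_that("permuted level labels on a split scatter reject at about the test level", {
  s1 <- generate_vmax_sequence(50, meanlog = log(2), m = 0.85, b = 1.7,
                               eps_sd = 0.05, seed = 13)
  s2 <- generate_vmax_sequence(50, meanlog = log(4), m = 1.0, b = 1.1,
                               eps_sd = 0.05, seed = 14)
  f <- dplyr::bind_rows(
    mk_features(s1$vmax, s1$amax, "slow"),
    mk_features(s2$vmax, s2$amax, "fast") %>%
      dplyr::mutate(trial_index = trial_index + 50))
  sc <- build_rule_scatter(f)
  sc <- sc[sc$trial_t != 50, ]               # drop the splice pair
  rej <- withr::with_seed(15, {
    mean(replicate(200, {
      sc$speed_level <- sample(sc$speed_level)
      split_decision(sc)$p_value < 0.05
    }))
  })
  expect_lt(rej, 0.12)                       # ~ alpha = 0.05 under the null
})

test_that("the power form reports delta and its quadratic remainder", {
  # exact scatter on the printed novice fast line: slope 1.03, intercept 0.87
  x <- seq(0.5, 2, length.out = 6)
  sc <- structure(tibble::tibble(x = x, y = 1.03 * x + 0.87),
                  class = c("rule_scatter", class(tibble::tibble())),
                  upsilon = 10)
  pf <- power_form(fit_rule(sc))
  expect_equal(pf$terms$delta, -0.03, tolerance = 1e-12)
  expect_equal(pf$terms$delta_squared, 9.0e-4, tolerance = 1e-12)
  # slope of the expert slow intended line
  sc2 <- structure(tibble::tibble(x = x, y = 0.6918 * x + 1.844),
                   class = c("rule_scatter", class(tibble::tibble())),
                   upsilon = 10)
  pf2 <- power_form(fit_rule(sc2))
  expect_equal(pf2$terms$delta, 0.3082, tolerance = 1e-12)
  # m = 1: expansion exact, remainder bound zero
  sc3 <- structure(tibble::tibble(x = x, y = x),
                   class = c("rule_scatter", class(tibble::tibble())),
                   upsilon = 10)
  pf3 <- power_form(fit_rule(sc3))
  expect_equal(pf3$terms$delta, 0)
  expect_equal(pf3$terms$remainder_bound, 0)
})

test_that("one-step predictions invert the rule", {
  sc <- structure(tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 2)),
                  class = c("rule_scatter", class(tibble::tibble())),
                  upsilon = 10)
  fit <- fit_rule(sc)                        # m = 1, b = 0
  expect_equal(predict_next_vmax(fit, 0.5, 6.5), 2.0, tolerance = 1e-12)
  # noise-free generated session: predictions match realized speeds
  s <- generate_vmax_sequence(100, m = 0.95, b = 1.4, eps_sd = 0, seed = 16)
  fit2 <- fit_rule(build_rule_scatter(mk_features(s$vmax, s$amax)))
  pred <- predict_next_vmax(fit2, head(s$vmax, -2), head(s$amax, -2))
  expect_equal(pred, s$vmax[2:99], tolerance = 1e-9)
  # eps_sd = 0.05: log-residual sd close to the generator's noise
  s3 <- generate_vmax_sequence(500, m = 0.95, b = 1.4, eps_sd = 0.05,
                               seed = 17)
  fit3 <- fit_rule(build_rule_scatter(mk_features(s3$vmax, s3$amax)))
  expect_equal(fit3$coef$rmse, 0.05, tolerance = 0.15)
  expect_warning(predict_next_vmax(fit2, 100, 1), "out-of-regime")
})
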