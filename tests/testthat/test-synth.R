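test_that("rule inversion generates exactly rule-consistent sequences", {
  # m = 1, b = 0: amax(t) must equal vmax(t+1) + 9 vmax(t) identically
  s <- generate_vmax_sequence(50, m = 1, b = 0, eps_sd = 0, seed = 7)
  expect_equal(head(s$amax, -1),
               s$vmax[-1] + 9 * head(s$vmax, -1), tolerance = 1e-12)
  # generic (m, b): least squares on the log-log scatter recovers them exactly
  for (par in list(c(0.9, 0.3), c(1.03, 0.87), c(0.6918, 1.844))) {
    s <- generate_vmax_sequence(100, m = par[1], b = par[2], eps_sd = 0,
                                seed = 11)
    y <- log(s$vmax[-1] + 9 * head(s$vmax, -1))
    x <- log(head(s$amax, -1))
    f <- lm(y ~ x)
    expect_equal(unname(coef(f)[2]), par[1], tolerance = 1e-9)
    expect_equal(unname(coef(f)[1]), par[2], tolerance = 1e-9)
  }
})

test_that("residual noise enters the generated sequences at the requested sd", {
  s <- generate_vmax_sequence(2000, m = 0.95, b = 1.4, eps_sd = 0.05, seed = 3)
  y <- log(s$vmax[-1] + 9 * head(s$vmax, -1))
  x <- log(head(s$amax, -1))
  expect_equal(sd(residuals(lm(y ~ x))), 0.05, tolerance = 0.1)
})

test_that("generators are bit-identical under the same seed", {
  a <- generate_vmax_sequence(50, seed = 123)
  b <- generate_vmax_sequence(50, seed = 123)
  expect_identical(a, b)
  cfg <- small_config(trials_per_condition = 4)
  s1 <- generate_session(cfg, seed = 9)
  s2 <- generate_session(cfg, seed = 9)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth, s2$truth)
})

test_that("degenerate rule parameters are rejected", {
  expect_error(generate_vmax_sequence(10, m = 0), "m")
  expect_error(generate_vmax_sequence(1), "n >= 2")
})

test_that("speed profiles are unimodal bells with the programmed maximum", {
  p <- generate_speed_profile(3, 1, 240, 0.5)
  expect_length(p, 240)
  expect_equal(max(p), 3, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_equal(p[1], 0); expect_equal(p[length(p)], 0)
  # exactly one sign change of the discrete derivative
  expect_equal(sum(diff(sign(diff(p))) != 0), 1)
  # symmetric template peaks at mid-duration
  expect_equal((which.max(p) - 1) / 240, 0.5, tolerance = 1 / 240)
  # asymmetric template peaks at the requested fraction
  p2 <- generate_speed_profile(2, 1, 240, 0.3)
  expect_equal((which.max(p2) - 1) / 240, 0.3, tolerance = 2 / 240)
  expect_error(generate_speed_profile(-1, 1), "vmax")
})

test_that("trajectories integrate the speed profile on a bent planar path", {
  p <- generate_speed_profile(3, 1, 240)
  L <- sum((p[-1] + p[-length(p)]) / 2) / 240
  # bend = 0: exactly colinear
  tr <- generate_trajectory(p, 240, c(0, 0, 0), c(1, 0, 0), bend = 0)
  lp <- linearity_profile(tr, 50)
  expect_lt(max(lp$deviation), 1e-9)
  # bend = r: max perpendicular deviation = r within 1%, arc length matches
  for (r in c(0.05, 0.1)) {
    tr <- generate_trajectory(p, 240, c(0, 0, 0), c(1, 0, 0), bend = r)
    dev <- sqrt(tr[, 2]^2 + tr[, 3]^2)
    expect_equal(max(dev), r, tolerance = 0.01)
    arc <- sum(sqrt(rowSums(apply(tr, 2, diff)^2)))
    expect_equal(arc, L, tolerance = 0.01)
  }
  # monotone in bend
  d1 <- max(abs(generate_trajectory(p, 240, bend = 0.03)[, 2]))
  d2 <- max(abs(generate_trajectory(p, 240, bend = 0.08)[, 2]))
  expect_lt(d1, d2)
  expect_error(generate_trajectory(p, 240, c(0, 0, 0), c(0, 0, 0), 0),
               "distinct")
})

test_that("sessions have the configured layout and labels", {
  cfg <- synth_config(subjects = list(subject_profile("N1", "novice")),
                      contexts = "no_bag", trials_per_condition = 10)
  s <- generate_session(cfg, seed = 2)
  expect_equal(nrow(s$truth), 2 * 10 * 2)        # 2 levels x 10 trials x 2 segments
  expect_equal(length(unique(s$truth$trial_index)), 20)
  expect_setequal(unique(s$truth$segment), c("strike", "retraction"))
  # blocked design: contiguous single-level blocks
  lv <- s$truth$speed_level[s$truth$segment == "strike"]
  expect_equal(sum(lv[-1] != lv[-length(lv)]), 1)
  # random design interleaves (seeded draw, exact per-level counts)
  cfg_r <- synth_config(subjects = list(subject_profile("N1", "novice")),
                        contexts = "no_bag", design = "random",
                        trials_per_condition = 10)
  sr <- generate_session(cfg_r, seed = 2)
  lvr <- sr$truth$speed_level[sr$truth$segment == "strike"]
  expect_equal(unname(table(lvr)["slow"]), 10)
  expect_gt(sum(lvr[-1] != lvr[-length(lvr)]), 1)
})

test_that("generated peak speeds follow the configured log-normal law", {
  s <- generate_vmax_sequence(1000, meanlog = log(2), sdlog = 0.2, seed = 5)
  expect_gt(shapiro.test(log(s$vmax))$p.value, 0.01)
  lf <- fit_lognormal(s$vmax)
  expect_equal(lf$meanlog, log(2), tolerance = 0.05)
  expect_equal(lf$sdlog, 0.2, tolerance = 0.1)
})

test_that("expert profiles spread condition means wider and fluctuate less than novice", {
  demo <- demo_study()
  tr <- demo$session$truth %>% dplyr::filter(segment == "strike")
  spread <- tr %>%
    dplyr::group_by(class, context, speed_level) %>%
    dplyr::summarise(m = mean(vmax), cv = sd(vmax) / mean(vmax),
                     .groups = "drop") %>%
    dplyr::group_by(class) %>%
    dplyr::summarise(bw = max(m) / min(m), cv = mean(cv))
  expect_gt(spread$bw[spread$class == "expert"],
            spread$bw[spread$class == "novice"])
  expect_lt(spread$cv[spread$class == "expert"],
            spread$cv[spread$class == "novice"])
})

test_that("noise-free sessions obey the configured rule exactly (closed loop)", {
  cfg <- small_config(trials_per_condition = 10,
                      rule = list(m = 0.9, b = 1.5, eps_sd = 0),
                      rule_retraction = list())
  s <- generate_session(cfg, seed = 20)
  tr <- s$truth %>% dplyr::filter(segment == "strike") %>%
    dplyr::arrange(trial_index)
  y <- log(tr$vmax[-1] + 9 * head(tr$vmax, -1))
  x <- log(head(tr$amax, -1))
  expect_equal(y, 0.9 * x + 1.5, tolerance = 1e-9)
})
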