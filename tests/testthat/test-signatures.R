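test_that("signature trajectories recover block-wise Gamma truths", {
  truths <- list(c(3, 0.2), c(6, 0.12), c(10, 0.08), c(16, 0.05))
  feats <- withr::with_seed(30, {
    purrr::imap(truths, function(p, i)
      tibble::tibble(block = paste0("ctx", i), trial_index = 1:110,
                     vmax = rgamma(110, p[1], scale = p[2]))) %>%
      dplyr::bind_rows()
  })
  tr <- signature_trajectory(feats, group = "block")
  expect_equal(nrow(tr), 4)
  expect_equal(tr$block, paste0("ctx", 1:4))       # chronological order
  for (i in 1:4) {
    expect_true(tr$ci_shape_low[i] < truths[[i]][1] &&
                truths[[i]][1] < tr$ci_shape_high[i])
    expect_true(tr$ci_scale_low[i] < truths[[i]][2] &&
                truths[[i]][2] < tr$ci_scale_high[i])
  }
  # monotone rightward drift classified as positive gains
  expect_equal(tr$shift[-1], rep("positive_gain", 3))
  # single block: length-1 trajectory, no classification
  tr1 <- signature_trajectory(feats[feats$block == "ctx1", ], group = "block")
  expect_equal(nrow(tr1), 1)
  expect_true(is.na(tr1$shift))
  # permuting trials within a block leaves its signature unchanged
  sh <- withr::with_seed(31, {
    f2 <- feats[sample(nrow(feats)), ] %>% dplyr::arrange(block)
    signature_trajectory(f2, group = "block")$shape
  })
  expect_equal(sh, tr$shape, tolerance = 1e-9)
})

test_that("gain shifts follow the shape axis and are antisymmetric", {
  expect_equal(classify_shift(2, 5), "positive_gain")
  expect_equal(classify_shift(5, 2), "negative_gain")
  expect_equal(classify_shift(3, 3), "neutral")
  expect_equal(classify_shift(3, 3.1), "neutral")    # within 5% tolerance
  withr::with_seed(32, {
    for (i in 1:20) {
      a <- runif(2, 0.5, 20)
      f <- classify_shift(a[1], a[2]); r <- classify_shift(a[2], a[1])
      if (f == "neutral") expect_equal(r, "neutral")
      else expect_setequal(c(f, r), c("positive_gain", "negative_gain"))
    }
  })
})

test_that("condition comparisons reproduce exact rank-test results", {
  f <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
                      g = rep(c("a", "b"), each = 3))
  res <- compare_conditions(f, "v", "g", test = "ranksum")
  expect_equal(res$p_value, 0.1)             # exact: 2 / C(6,3)
  expect_equal(res$summary$median, c(2, 11))
  # identical samples: central statistic, p = 1
  f2 <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(suppressWarnings(
    compare_conditions(f2, "v", "g", test = "ranksum")$p_value), 1)
  # rank tests are invariant under monotone transformations
  demo <- demo_study()
  st <- demo$features %>% dplyr::filter(session_id == "S2_no_bag",
                                        segment == "strike")
  p1 <- compare_conditions(st, "vmax", "speed_level")$p_value
  st$vmax <- exp(st$vmax)
  p2 <- compare_conditions(st, "vmax", "speed_level")$p_value
  expect_equal(p1, p2)
  expect_lt(p1, 1e-6)                        # well-separated synthetic laws
})

test_that("kruskal-wallis and friedman layouts are supported", {
  withr::with_seed(33, {
    f <- tibble::tibble(v = c(rnorm(20), rnorm(20, 3), rnorm(20, 6)),
                        g = rep(c("a", "b", "c"), each = 20))
    res <- compare_conditions(f, "v", "g", test = "kruskal_wallis")
    expect_lt(res$p_value, 1e-6)
    fr <- tibble::tibble(v = rnorm(30), g = rep(c("a", "b", "c"), 10),
                         s = rep(1:10, each = 3))
    resf <- compare_conditions(fr, "v", "g", test = "friedman", block = "s")
    expect_gt(resf$p_value, 0.01)
    expect_error(compare_conditions(fr[1:29, ], "v", "g", test = "friedman",
                                    block = "s"), "one observation")
  })
})

test_that("fatigue checks flag injected late-block duration inflation only", {
  demo <- demo_study()
  block <- demo$features %>%
    dplyr::filter(session_id == "S1_no_bag", segment == "retraction",
                  speed_level == "fast") %>%
    dplyr::arrange(trial_index)
  # stationary block: no effect in either measure
  fc0 <- fatigue_check(block, k = 10)
  expect_true(all(fc0$p_value > 0.05))
  # inflate the last 10 durations by 20%: duration flagged, vmax untouched
  fatigued <- block
  late <- seq.int(nrow(block) - 9, nrow(block))
  fatigued$duration[late] <- fatigued$duration[late] * 1.2
  fc1 <- fatigue_check(fatigued, k = 10)
  expect_lt(fc1$p_value[fc1$measure == "duration"], 0.01)
  expect_gt(fc1$p_value[fc1$measure == "vmax"], 0.05)
  # k at the half-block boundary is valid, beyond it errors
  expect_s3_class(fatigue_check(block, k = nrow(block) %/% 2), "tbl_df")
  expect_error(fatigue_check(block, k = nrow(block) %/% 2 + 1), "too short")
})

test_that("expertise profiles separate the generator's expert from its novice", {
  demo <- demo_study()
  sigs <- gamma_signatures(demo$features %>% dplyr::filter(segment == "strike"),
                           subject_id, class, context, speed_level,
                           value = "vmax") %>%
    dplyr::mutate(condition = paste(context, speed_level, sep = "_"))
  prof <- split(sigs, sigs$subject_id) %>% purrr::map(expertise_profile)
  expert <- prof$S1; novice <- prof$S2
  expect_true(expert$expert_like)
  expect_false(novice$expert_like)
  expect_true(all(expert$separability$separable))
  nb <- novice$separability %>%
    dplyr::filter(grepl("slow", cond_a), grepl("slow", cond_b))
  expect_false(any(nb$separable))            # slow bag vs slow no-bag confused
  expect_lt(expert$max_fano, novice$max_fano)
  # duplicated condition signatures: bandwidth collapses to 1
  dup <- sigs[c(1, 1), ] %>% dplyr::mutate(condition = c("x", "y"))
  expect_equal(expertise_profile(dup)$bandwidth, 1)
  # bandwidth is invariant under rescaling all condition means
  sc <- sigs %>% dplyr::mutate(scale = scale * 3)
  expect_equal(expertise_profile(sc[sc$subject_id == "S1", ])$bandwidth,
               expert$bandwidth, tolerance = 1e-12)
})
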