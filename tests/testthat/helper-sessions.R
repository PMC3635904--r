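# shared fixtures, generated once per run and cached
.fixture_cache <- new.env(parent = emptyenv())

# the demo study: 2 subjects (expert, novice) x 2 contexts x 2 blocked speed
# levels x 100 trials, generator defaults
demo_study <- function() {
  if (is.null(.fixture_cache$demo)) {
    cfg <- synth_config()
    session <- generate_session(cfg, seed = 1)
    features <- suppressWarnings(trial_features(session$trials))
    .fixture_cache$demo <- list(config = cfg, session = session,
                                features = features)
  }
  .fixture_cache$demo
}

small_config <- function(trials_per_condition = 16, ...) {
  synth_config(subjects = list(subject_profile("E1", "expert")),
               contexts = "no_bag",
               trials_per_condition = trials_per_condition, ...)
}

# two concatenated bell profiles with a zero-speed junction sample
two_bell_speed <- function(v1 = 2, v2 = 3, n1 = 120, n2 = 150) {
  b1 <- generate_speed_profile(v1, n1 / 240, 240)
  b2 <- generate_speed_profile(v2, n2 / 240, 240)
  c(b1, 0, b2)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
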