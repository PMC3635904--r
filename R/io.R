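trial_schema <- c("session_id", "subject_id", "trial_index", "segment",
                  "speed_level", "context", "design", "t_s", "x_m", "y_m",
                  "z_m")

#' Write a tidy trial table (with JSON metadata sidecar)
#'
#' @param session A `session_record` or a tidy trial tibble.
#' @param path CSV output path; the metadata sidecar is written next to it
#'   as `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(session, path) {
  trials <- if (inherits(session, "session_record")) session$trials else session
  miss <- setdiff(trial_schema, names(trials))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  readr::write_csv(trials, path)
  meta <- list(
    n_rows = nrow(trials),
    sessions = unique(trials$session_id),
    design = unique(trials$design),
    sampling_rate = if (inherits(session, "session_record"))
      session$config$sampling_rate else 1 / median(diff(trials$t_s[1:50])))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and validate a tidy trial table
#'
#' Checks the schema (every required column present), the segment labels,
#' and the uniformity of the time step within each (session, trial,
#' segment) series; violations are reported with the offending column or
#' row.
#'
#' @param path CSV path written by [write_trials()] or of the same schema.
#' @param tol Relative tolerance on time-step uniformity.
#' @return Tidy trial tibble.
#' @export
read_trials <- function(path, tol = 1e-6) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(trial_schema, names(trials))
  if (length(miss))
    abort(paste("schema error: missing column(s):", paste(miss, collapse = ", ")))
  bad_seg <- setdiff(unique(trials$segment), c("strike", "retraction"))
  if (length(bad_seg))
    abort(paste("unknown segment label(s):", paste(bad_seg, collapse = ", ")))
  trials %>%
    group_by(.data$session_id, .data$trial_index, .data$segment) %>%
    group_split() %>%
    purrr::walk(function(g) {
      dts <- diff(g$t_s)
      if (any(dts <= 0))
        abort(sprintf("time not strictly increasing in session %s trial %d (%s)",
                      g$session_id[1], g$trial_index[1], g$segment[1]))
      if (max(dts) - min(dts) > tol * median(dts)) {
        bad <- which.max(abs(dts - median(dts)))
        abort(sprintf(
          "non-uniform time step in session %s trial %d (%s) near row %d",
          g$session_id[1], g$trial_index[1], g$segment[1], bad + 1L))
      }
    })
  trials
}

#' Write / read a feature table
#'
#' @param features Feature tibble from [trial_features()].
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  feats <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("session_id", "trial_index", "segment", "vmax")
  miss <- setdiff(need, names(feats))
  if (length(miss))
    abort(paste("schema error: missing column(s):", paste(miss, collapse = ", ")))
  feats
}

#' Write a report bundle to a directory
#'
#' Emits the signature table and rule fits as JSON, and the condition
#' comparisons, fatigue checks and linearity summaries as CSV.
#'
#' @param report A `speedsig_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "speedsig_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report$signatures, file.path(dir, "signatures.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rule_json <- purrr::map(report$rule_fits, function(rf) list(
    mode = rf$decision$decision, f_statistic = rf$decision$f_statistic,
    p_value = rf$decision$p_value,
    lines = purrr::pmap(rf$per_level$coef, function(level, m, b, delta,
                                                    ci_m_low, ci_m_high,
                                                    ci_b_low, ci_b_high, sse,
                                                    r_squared, adj_r_squared,
                                                    rmse, n, ...)
      list(level = level, p1 = m, p2 = b,
           p1_ci = c(ci_m_low, ci_m_high), p2_ci = c(ci_b_low, ci_b_high),
           SSE = sse, `R-square` = r_squared,
           `Adjusted R-square` = adj_r_squared, RMSE = rmse, n = n)),
    pooled = as.list(rf$single$coef[1, c("m", "b", "sse", "r_squared",
                                         "adj_r_squared", "rmse")])))
  jsonlite::write_json(rule_json, file.path(dir, "rule_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"))
  readr::write_csv(report$fatigue, file.path(dir, "fatigue.csv"))
  readr::write_csv(report$linearity, file.path(dir, "linearity.csv"))
  jsonlite::write_json(
    list(seed = report$seed,
         dip = purrr::map(report$dip, function(d)
           list(statistic = d$statistic, p_value = d$p_value, n = d$n)),
         gamma_plane = if (!is.null(report$gamma_plane))
           as.list(tidy(report$gamma_plane)),
         expertise = purrr::map(report$expertise, function(e) as.list(tidy(e))),
         log = report$log),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline on a synthetic configuration
#'
#' Orchestrates simulate -> features -> distributions -> rule -> signatures
#' -> fatigue -> linearity. Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed controlling every stochastic stage.
#' @param out_dir Optional directory for [write_report()].
#' @param n_boot Dip-test bootstrap draws.
#' @param verbose Emit per-stage messages.
#' @return A `speedsig_report` list: `features`, `signatures` (per subject x
#'   context x speed level, strike segment), `dip` (merged-block unimodality
#'   tests per session), `gamma_plane` power fit, `rule_fits` (per session x
#'   segment: single, per-level and the split decision), `trajectories`
#'   (per-subject signature trajectories), `expertise` (per subject),
#'   `comparisons`, `fatigue`, `linearity`, `log`.
#' @export
run_pipeline <- function(config = synth_config(), seed = 1L, out_dir = NULL,
                         n_boot = 2000, verbose = TRUE) {
  say <- function(...) if (verbose) inform(sprintf(...))
  log <- list(seed = seed)
  say("stage simulate: %d subjects x %d contexts x %d levels x %d trials",
      length(config$subjects), length(config$contexts),
      length(config$speed_levels), config$trials_per_condition)
  session <- generate_session(config, seed = seed)
  say("stage features: %d segments", nrow(session$truth))
  features <- trial_features(session$trials)
  strike <- features %>% filter(.data$segment == "strike")

  say("stage distributions: dip tests and Gamma signatures")
  dip <- withr::with_seed(seed + 1L, {
    sessions <- split(strike, strike$session_id)
    purrr::map(sessions, function(g) dip_test(g$vmax, n_boot = n_boot))
  })
  signatures <- gamma_signatures(strike, .data$subject_id, .data$class,
                                 .data$context, .data$speed_level,
                                 value = "vmax")
  gamma_plane <- if (nrow(signatures) >= 3) gamma_plane_power_fit(signatures)
                 else NULL

  say("stage rule: scatters and fits per session x segment")
  rule_fits <- features %>%
    group_by(.data$session_id, .data$segment) %>% group_split() %>%
    purrr::map(function(g) {
      sc <- build_rule_scatter(g, upsilon = config$upsilon)
      list(session_id = g$session_id[1], segment = g$segment[1],
           single = fit_rule(sc, "single"),
           per_level = fit_rule(sc, "per_level"),
           decision = split_decision(sc))
    })
  names(rule_fits) <- purrr::map_chr(rule_fits, function(rf)
    paste(rf$session_id, rf$segment, sep = "."))

  say("stage signatures: trajectories and expertise")
  trajectories <- strike %>%
    mutate(block = paste(.data$context, .data$speed_level, sep = "_")) %>%
    group_by(.data$subject_id) %>% group_split() %>%
    purrr::map(function(g) signature_trajectory(g, group = "block"))
  names(trajectories) <- purrr::map_chr(
    strike %>% group_by(.data$subject_id) %>% group_split(),
    function(g) g$subject_id[1])
  expertise <- signatures %>%
    mutate(condition = paste(.data$context, .data$speed_level, sep = "_")) %>%
    group_by(.data$subject_id) %>% group_split() %>%
    purrr::map(expertise_profile)
  names(expertise) <- names(trajectories)

  say("stage comparisons: strike vs retraction, fast vs slow")
  comparisons <- purrr::map(split(features, features$session_id), function(g) {
    sv <- compare_conditions(g, "vmax", "segment", test = "ranksum")
    fs <- compare_conditions(g %>% filter(.data$segment == "strike"),
                             "vmax", "speed_level", test = "ranksum")
    tibble(session_id = g$session_id[1],
           comparison = c("strike_vs_retraction", "fast_vs_slow"),
           statistic = c(sv$statistic, fs$statistic),
           p_value = c(sv$p_value, fs$p_value))
  }) %>% list_rbind()

  say("stage fatigue: first vs last %d trials per block",
      min(10, config$trials_per_condition %/% 2))
  k <- min(10, config$trials_per_condition %/% 2)
  fatigue <- features %>%
    group_by(.data$session_id, .data$speed_level) %>% group_split() %>%
    purrr::map(function(g)
      fatigue_check(g, k = k) %>%
        mutate(session_id = g$session_id[1],
               speed_level = g$speed_level[1])) %>%
    list_rbind()

  say("stage linearity: per-segment deviation profiles")
  linearity <- session$trials %>%
    group_by(.data$session_id, .data$trial_index, .data$segment,
             .data$speed_level, .data$context) %>%
    group_split() %>%
    purrr::map(function(g) {
      lp <- linearity_profile(cbind(g$x_m, g$y_m, g$z_m), n_frames = 50)
      s <- attr(lp, "summary")
      tibble(session_id = g$session_id[1], trial_index = g$trial_index[1],
             segment = g$segment[1], speed_level = g$speed_level[1],
             context = g$context[1], max_deviation = s[["max"]],
             mean_deviation = s[["mean"]])
    }) %>% list_rbind()

  report <- structure(
    list(features = features, signatures = signatures, dip = dip,
         gamma_plane = gamma_plane, rule_fits = rule_fits,
         trajectories = trajectories, expertise = expertise,
         comparisons = comparisons, fatigue = fatigue,
         linearity = linearity, seed = seed, log = log,
         config = config),
    class = "speedsig_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.speedsig_report <- function(x, ...) {
  cat("<speedsig_report>\n")
  cat("  features:", nrow(x$features), "segments;",
      nrow(x$signatures), "Gamma signatures;",
      length(x$rule_fits), "rule fits\n")
  cat("  dip p-values:",
      paste(sprintf("%s=%.3g", names(x$dip),
                    purrr::map_dbl(x$dip, "p_value")), collapse = ", "), "\n")
  invisible(x)
}
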