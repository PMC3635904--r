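#' Subject profile for the session generator
#'
#' Describes one simulated performer. The two classes encode the qualitative
#' contrast reported for trained and untrained performers: an expert spans a
#' broad bandwidth of condition-wise peak-speed levels with small relative
#' fluctuation (low noise-to-signal), a novice a narrow bandwidth with large
#' fluctuation.
#'
#' @param subject_id Character id.
#' @param class `"expert"` or `"novice"`.
#' @param base_means Named numeric, median peak speed (m/s) per speed level.
#' @param sdlog Log-scale standard deviation of the per-trial peak-speed law.
#' @param context_spread Total multiplicative spread of condition means across
#'   contexts (the ratio between the most and least demanding context).
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            class = c("novice", "expert"),
                            base_means = NULL,
                            sdlog = NULL,
                            context_spread = NULL) {
  class <- match.arg(class)
  if (is.null(base_means)) {
    base_means <- if (class == "expert") c(slow = 1.15, fast = 4.5) else c(slow = 2.0, fast = 3.3)
  }
  if (is.null(sdlog)) sdlog <- if (class == "expert") 0.08 else 0.25
  if (is.null(context_spread)) context_spread <- if (class == "expert") 1.75 else 1.04
  stopifnot(sdlog > 0, all(base_means > 0), context_spread >= 1)
  structure(list(subject_id = subject_id, class = class,
                 base_means = base_means, sdlog = sdlog,
                 context_spread = context_spread),
            class = "subject_profile")
}

#' Configuration of a synthetic kinematic session
#'
#' Bundles everything the generator needs: subject profiles, the per-condition
#' log-normal peak-speed laws, the first-order trial-to-trial rule that ties
#' the peak acceleration of trial t to the peak speeds of trials t and t+1,
#' the speed design (blocked or randomly interleaved), and the geometry of the
#' simulated strikes and retractions.
#'
#' The trial-to-trial rule is
#' \deqn{\ln(v_{t+1} + \nu v_t) = m \ln(a_t) + b + \varepsilon_t,}
#' with \eqn{\nu = \upsilon - 1} and \eqn{\upsilon = 10} by default; the
#' generator draws the peak-speed sequence from the condition's log-normal law
#' and derives each trial's peak acceleration by inverting the rule, so the
#' configured slope and intercept are recovered exactly when `eps_sd = 0`.
#'
#' @param subjects List of [subject_profile()] objects.
#' @param speed_levels Character vector of instructed speed levels.
#' @param contexts Character vector of training contexts.
#' @param design `"blocked"` (contiguous single-level blocks) or `"random"`
#'   (levels interleaved by a seeded draw).
#' @param trials_per_condition Trials per (subject, speed level, context).
#' @param sampling_rate Sampling rate in Hz.
#' @param duration_range Allowed segment duration range in seconds.
#' @param peak_fraction Mean relative time of the speed peak within a segment.
#' @param peak_fraction_sd Per-trial jitter of `peak_fraction`.
#' @param upsilon Scaling constant of the rule (\eqn{\nu = \upsilon - 1}).
#' @param rule Strike rule, `list(m, b, eps_sd)`.
#' @param rule_retraction Per-speed-level retraction rules,
#'   `list(<level> = list(m, b, eps_sd), ...)`. Levels absent from the list
#'   fall back on `rule`.
#' @param retraction_scale Multiplier of the peak-speed law for retractions.
#' @param retraction_curvature Named numeric, lateral bend (m) of the
#'   retraction path per speed level.
#' @param strike_curvature Lateral bend (m) of the strike path.
#' @param loads_curvature_factor Bend multiplier applied in the `"loads"`
#'   context.
#' @param fatigue `list(k, duration_factor, segment)`: inflate the durations
#'   of the last `k` trials of each block by `duration_factor` (1 = none).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(subjects = list(subject_profile("S1", "expert"),
                                         subject_profile("S2", "novice")),
                         speed_levels = c("slow", "fast"),
                         contexts = c("no_bag", "bag"),
                         design = c("blocked", "random"),
                         trials_per_condition = 100,
                         sampling_rate = 240,
                         duration_range = c(0.8, 2.1),
                         peak_fraction = 0.45,
                         peak_fraction_sd = 0.03,
                         upsilon = 10,
                         rule = list(m = 0.95, b = 1.4, eps_sd = 0.05),
                         rule_retraction = list(
                           slow = list(m = 0.88, b = 1.7, eps_sd = 0.05),
                           fast = list(m = 0.98, b = 1.2, eps_sd = 0.05)),
                         retraction_scale = 0.85,
                         retraction_curvature = c(slow = 0.05, fast = 0.12),
                         strike_curvature = 0.005,
                         loads_curvature_factor = 1.5,
                         fatigue = list(k = 0, duration_factor = 1,
                                        segment = "retraction")) {
  design <- match.arg(design)
  stopifnot(sampling_rate > 0,
            length(duration_range) == 2, diff(duration_range) > 0,
            duration_range[1] > 0.3, duration_range[2] < 3.0,
            trials_per_condition >= 2,
            peak_fraction > 0, peak_fraction < 1,
            upsilon > 1,
            rule$m != 0, rule$eps_sd >= 0)
  if (!all(vapply(subjects, inherits, logical(1), "subject_profile")))
    abort("`subjects` must be a list of subject_profile() objects")
  laws <- purrr::map(subjects, function(sp) {
    mult <- if (length(contexts) == 1) 1 else
      exp(seq(-log(sp$context_spread) / 2, log(sp$context_spread) / 2,
              length.out = length(contexts)))
    tidyr::expand_grid(speed_level = speed_levels, context = contexts) %>%
      mutate(subject_id = sp$subject_id, class = sp$class,
             meanlog = log(sp$base_means[.data$speed_level]) +
               log(mult[match(.data$context, contexts)]),
             sdlog = sp$sdlog)
  }) %>% list_rbind() %>%
    select("subject_id", "class", "speed_level", "context", "meanlog", "sdlog")
  structure(list(subjects = subjects, speed_levels = speed_levels,
                 contexts = contexts, design = design,
                 trials_per_condition = trials_per_condition,
                 sampling_rate = sampling_rate,
                 duration_range = duration_range,
                 peak_fraction = peak_fraction,
                 peak_fraction_sd = peak_fraction_sd,
                 upsilon = upsilon, rule = rule,
                 rule_retraction = rule_retraction,
                 retraction_scale = retraction_scale,
                 retraction_curvature = retraction_curvature,
                 strike_curvature = strike_curvature,
                 loads_curvature_factor = loads_curvature_factor,
                 fatigue = fatigue,
                 speed_laws = laws),
            class = "synth_config")
}

#' Generate a rule-consistent sequence of peak speeds and accelerations
#'
#' Draws `n + 1` peak speeds from a log-normal law and derives the peak
#' acceleration of each trial by inverting the first-order rule
#' \eqn{\ln(v_{t+1} + \nu v_t) = m \ln(a_t) + b + \varepsilon_t}, so that a
#' log-log regression of the combined velocity on the acceleration recovers
#' `(m, b)` exactly when `eps_sd = 0`. Inversion is the only workable
#' generation direction: propagating speeds forward through the rule is
#' dynamically unstable, because the map \eqn{v_{t+1} = a_t^m e^b - \nu v_t}
#' amplifies fluctuations by \eqn{\nu = 9} per trial. A side effect of the
#' inversion is that a non-zero residual enters the regressor, so ordinary
#' least squares on noisy sequences is mildly attenuated (see the package
#' vignette).
#'
#' @param n Number of trials (>= 2).
#' @param meanlog,sdlog Log-normal law of the peak speed (m/s).
#' @param m,b Slope and intercept of the rule (`m != 0`).
#' @param eps_sd Standard deviation of the Gaussian residual on the log scale.
#' @param upsilon Scaling constant; \eqn{\nu = \upsilon - 1}.
#' @param seed Optional integer seed (reproducible draws).
#' @return Tibble with columns `trial`, `vmax`, `amax` (`amax` is `NA` for the
#'   last trial, which has no successor).
#' @export
generate_vmax_sequence <- function(n, meanlog = log(2), sdlog = 0.2,
                                   m = 0.95, b = 1.4, eps_sd = 0.05,
                                   upsilon = 10, seed = NULL) {
  stopifnot(n >= 2, sdlog > 0, eps_sd >= 0)
  if (m == 0) abort("`m` must be non-zero: the rule inversion is degenerate at m = 0")
  run <- function() {
    nu <- upsilon - 1
    eps <- if (eps_sd > 0) rnorm(n, 0, eps_sd) else numeric(n)
    v <- rlnorm(n + 1, meanlog, sdlog)
    a <- exp((log(v[-1] + nu * v[-(n + 1)]) - b - eps) / m)
    tibble(trial = seq_len(n), vmax = v[seq_len(n)],
           amax = c(a[seq_len(n - 1)], NA_real_))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# template exponents: peak of tau^a (1-tau)^b at a/(a+b) = f with b = 2
profile_exponents <- function(peak_fraction) {
  b <- 2
  a <- b * peak_fraction / (1 - peak_fraction)
  c(a = a, b = b)
}

# peak |d speed / d tau| of the unit-peak template, used to convert a
# programmed peak acceleration into a segment duration
template_amax_const <- function(peak_fraction) {
  e <- profile_exponents(peak_fraction)
  tau <- seq(1e-4, 1 - 1e-4, length.out = 2001)
  s <- tau^e[1] * (1 - tau)^e[2]
  peak <- max(s)
  ds <- tau^(e[1] - 1) * (1 - tau)^(e[2] - 1) * (e[1] * (1 - tau) - e[2] * tau)
  max(abs(ds)) / peak
}

#' Bell-shaped (single-peak) speed profile
#'
#' Minimum-jerk-like template \eqn{\tau^a (1-\tau)^b} scaled so the sampled
#' maximum equals `vmax` exactly; `peak_fraction` sets the relative time of
#' the peak (0.5 gives the symmetric template).
#'
#' @param vmax Peak speed (m/s), > 0.
#' @param duration Segment duration (s), > 0.
#' @param sampling_rate Hz.
#' @param peak_fraction Relative peak time in (0, 1).
#' @return Numeric vector of `round(duration * sampling_rate)` speeds.
#' @export
generate_speed_profile <- function(vmax, duration, sampling_rate = 240,
                                   peak_fraction = 0.5) {
  stopifnot(vmax > 0, duration > 0, sampling_rate > 0,
            peak_fraction > 0, peak_fraction < 1)
  n <- max(5L, as.integer(round(duration * sampling_rate)))
  e <- profile_exponents(peak_fraction)
  tau <- seq(0, 1, length.out = n)
  s <- tau^e[1] * (1 - tau)^e[2]
  s * (vmax / max(s))
}

#' Place a speed profile on a (possibly bent) 3D path
#'
#' Builds a planar path from `start` towards `end`: a straight chord plus a
#' sine-shaped lateral bump of amplitude `bend`, then walks it at the arc
#' lengths implied by the speed profile (trapezoidal integration). The chord
#' length is solved so that the path length matches the integrated profile;
#' `end` therefore fixes the direction and the bending plane, while the
#' realized endpoint distance follows from the profile. `bend = 0` yields
#' exactly colinear points.
#'
#' @param profile Speed series (m/s).
#' @param sampling_rate Hz.
#' @param start,end Numeric length-3 positions (m); must differ.
#' @param bend Lateral bump amplitude (m), >= 0.
#' @return Matrix `length(profile)` x 3 of positions (m).
#' @export
generate_trajectory <- function(profile, sampling_rate = 240,
                                start = c(0, 0, 0), end = c(1, 0, 0),
                                bend = 0) {
  stopifnot(length(start) == 3, length(end) == 3, bend >= 0,
            all(profile >= 0), length(profile) >= 2)
  chord <- end - start
  if (sqrt(sum(chord^2)) < 1e-12) abort("`start` and `end` must be distinct")
  dir <- chord / sqrt(sum(chord^2))
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  perp <- c(dir[2] * ref[3] - dir[3] * ref[2],
            dir[3] * ref[1] - dir[1] * ref[3],
            dir[1] * ref[2] - dir[2] * ref[1])
  perp <- perp / sqrt(sum(perp^2))
  dt <- 1 / sampling_rate
  svals <- c(0, cumsum((profile[-1] + profile[-length(profile)]) / 2 * dt))
  L <- svals[length(svals)]
  if (L <= 0) abort("speed profile has zero integrated path length")
  if (bend == 0) {
    pts <- outer(svals, dir)
    return(sweep(pts, 2, start, "+"))
  }
  u <- seq(0, 1, length.out = 1501)
  du <- u[2] - u[1]
  seg_len <- function(C) {
    integrand <- sqrt(C^2 + (bend * pi * cos(pi * u))^2)
    sum((integrand[-1] + integrand[-length(u)]) / 2 * du)
  }
  if (seg_len(1e-9) > L)
    abort("`bend` too large for the path length implied by the profile")
  C <- stats::uniroot(function(cc) seg_len(cc) - L,
                      lower = 1e-9, upper = L, tol = 1e-10)$root
  integrand <- sqrt(C^2 + (bend * pi * cos(pi * u))^2)
  cl <- c(0, cumsum((integrand[-1] + integrand[-length(u)]) / 2 * du))
  cl[length(cl)] <- L                      # guard rounding at the end
  uu <- approx(cl, u, xout = pmin(svals, L), ties = "ordered")$y
  pts <- outer(uu * C, dir) + outer(bend * sin(pi * uu), perp)
  sweep(pts, 2, start, "+")
}

resolve_rule <- function(config, segment, level) {
  if (segment == "retraction" && !is.null(config$rule_retraction[[level]])) {
    r <- config$rule_retraction[[level]]
  } else {
    r <- config$rule
  }
  if (is.null(r$eps_sd)) r$eps_sd <- config$rule$eps_sd
  r
}

# peak speeds and rule-consistent accelerations for one ordered block of
# trials with per-trial (level-specific) rule parameters
chain_vmax_amax <- function(levels, laws, rules, nu) {
  T <- length(levels)
  v <- unname(vapply(c(levels, levels[T]), function(lv)
    rlnorm(1, laws[[lv]]$meanlog, laws[[lv]]$sdlog), numeric(1)))
  a <- vapply(seq_len(T), function(t) {
    r <- rules[[levels[t]]]
    eps <- if (r$eps_sd > 0) rnorm(1, 0, r$eps_sd) else 0
    exp((log(v[t + 1] + nu * v[t]) - r$b - eps) / r$m)
  }, numeric(1))
  list(vmax = v[seq_len(T)], amax = a)
}

#' Generate a full synthetic session
#'
#' One session per (subject, context): an ordered sequence of trials, each a
#' strike followed by a retraction, with speed levels either blocked or
#' randomly interleaved. Peak speeds follow the configured log-normal laws,
#' peak accelerations are rule-consistent (see [generate_vmax_sequence()]),
#' segment durations are derived from the programmed peak acceleration and
#' clamped to `duration_range`, and retraction paths bend laterally by the
#' speed-level-specific curvature.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; identical seeds give identical sessions.
#' @return A list of class `session_record` with elements `trials` (tidy
#'   per-sample tibble: session_id, subject_id, class, trial_index, segment,
#'   speed_level, context, design, t_s, x_m, y_m, z_m), `truth` (programmed
#'   per-segment scalars: vmax, amax, duration, bend) and `config`.
#' @export
generate_session <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (length(config$contexts) == 0) abort("empty condition set")
  withr::with_seed(seed, generate_session_impl(config))
}

generate_session_impl <- function(config) {
  nu <- config$upsilon - 1
  fs <- config$sampling_rate
  tpc <- config$trials_per_condition
  const_cache <- list()
  amax_const <- function(f) {
    key <- sprintf("%.4f", f)
    if (is.null(const_cache[[key]])) const_cache[[key]] <<- template_amax_const(f)
    const_cache[[key]]
  }
  trials_out <- list()
  truth_out <- list()
  for (sp in config$subjects) {
    for (ctx in config$contexts) {
      session_id <- paste(sp$subject_id, ctx, sep = "_")
      levels <- if (config$design == "blocked") {
        rep(config$speed_levels, each = tpc)
      } else {
        sample(rep(config$speed_levels, times = tpc))
      }
      T <- length(levels)
      laws <- lapply(setNames(config$speed_levels, config$speed_levels),
                     function(lv) {
        row <- config$speed_laws %>%
          filter(.data$subject_id == sp$subject_id,
                 .data$speed_level == lv, .data$context == ctx)
        list(meanlog = row$meanlog, sdlog = row$sdlog)
      })
      seg_chain <- function(segment) {
        rules <- lapply(setNames(config$speed_levels, config$speed_levels),
                        function(lv) resolve_rule(config, segment, lv))
        lw <- laws
        if (segment == "retraction")
          lw <- lapply(lw, function(l) {
            l$meanlog <- l$meanlog + log(config$retraction_scale); l
          })
        chain_vmax_amax(levels, lw, rules, nu)
      }
      chains <- list(strike = seg_chain("strike"),
                     retraction = seg_chain("retraction"))
      pf <- pmin(0.8, pmax(0.2, rnorm(2 * T, config$peak_fraction,
                                      config$peak_fraction_sd)))
      bends <- list(
        strike = rep(config$strike_curvature, T),
        retraction = unname(config$retraction_curvature[levels]))
      if (ctx == "loads")
        bends <- lapply(bends, `*`, config$loads_curvature_factor)
      for (seg in c("strike", "retraction")) {
        ch <- chains[[seg]]
        idx <- if (seg == "strike") seq_len(T) else T + seq_len(T)
        dur <- vapply(seq_len(T), function(t)
          amax_const(pf[idx[t]]) * ch$vmax[t] / ch$amax[t], numeric(1))
        dur <- pmin(config$duration_range[2], pmax(config$duration_range[1], dur))
        if (config$fatigue$duration_factor != 1 && config$fatigue$k > 0 &&
            seg == config$fatigue$segment) {
          late <- seq.int(T - config$fatigue$k + 1L, T)
          dur[late] <- pmin(config$duration_range[2],
                            dur[late] * config$fatigue$duration_factor)
        }
        chains[[seg]]$duration <- dur
        chains[[seg]]$pf <- pf[idx]
      }
      per_trial <- purrr::map(seq_len(T), function(t) {
        out_tr <- list(); out_th <- list()
        strike_end <- NULL
        for (seg in c("strike", "retraction")) {
          ch <- chains[[seg]]
          prof <- generate_speed_profile(ch$vmax[t], ch$duration[t], fs, ch$pf[t])
          if (seg == "strike") {
            pts <- generate_trajectory(prof, fs, start = c(0, 0, 0),
                                       end = c(1, 0, 0), bend = bends[[seg]][t])
            strike_end <- pts[nrow(pts), ]
          } else {
            pts <- generate_trajectory(prof, fs, start = strike_end,
                                       end = c(0, 0, 0), bend = bends[[seg]][t])
          }
          nseg <- nrow(pts)
          out_tr[[seg]] <- tibble(
            session_id = session_id, subject_id = sp$subject_id,
            class = sp$class, trial_index = t, segment = seg,
            speed_level = levels[t], context = ctx, design = config$design,
            t_s = (seq_len(nseg) - 1) / fs,
            x_m = pts[, 1], y_m = pts[, 2], z_m = pts[, 3])
          out_th[[seg]] <- tibble(
            session_id = session_id, subject_id = sp$subject_id,
            class = sp$class, trial_index = t, segment = seg,
            speed_level = levels[t], context = ctx, design = config$design,
            vmax = ch$vmax[t], amax = ch$amax[t], duration = ch$duration[t],
            bend = bends[[seg]][t])
        }
        list(trials = list_rbind(out_tr), truth = list_rbind(out_th))
      })
      trials_out[[session_id]] <- list_rbind(purrr::map(per_trial, "trials"))
      truth_out[[session_id]] <- list_rbind(purrr::map(per_trial, "truth"))
    }
  }
  structure(list(trials = list_rbind(trials_out),
                 truth = list_rbind(truth_out),
                 config = config),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  n_tr <- nrow(distinct(x$trials, .data$session_id, .data$trial_index))
  cat("<session_record>\n")
  cat("  sessions:", length(unique(x$trials$session_id)),
      " trials:", n_tr, " segments:", nrow(x$truth),
      " samples:", nrow(x$trials), "\n")
  cat("  design:", x$config$design,
      " sampling:", x$config$sampling_rate, "Hz\n")
  invisible(x)
}
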