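#' Smooth a position series and differentiate it
#'
#' Savitzky-Golay (polynomial-window) smoothing of each coordinate followed by
#' central finite differences. Speed is the Euclidean norm of the velocity
#' vector; acceleration is the (signed) time derivative of the speed, i.e. the
#' tangential acceleration, the component that the bell-shaped profile
#' controls. Jerk is deliberately never computed: third derivatives of
#' smoothed position data amplify instrumentation error.
#'
#' @param position Numeric matrix (n x 3) of positions in meters.
#' @param sampling_rate Hz.
#' @param smoothing_window Odd window length in samples (>= 5).
#' @param polyorder Polynomial order of the smoother (< window).
#' @return List with `speed` (m/s, >= 0), `acceleration` (m/s^2, signed) and
#'   `velocity` (n x 3 matrix).
#' @export
differentiate_smooth <- function(position, sampling_rate,
                                 smoothing_window = 11, polyorder = 3) {
  position <- as.matrix(position)
  n <- nrow(position)
  if (n < 5) abort("position series too short (need >= 5 samples)")
  if (smoothing_window %% 2 == 0 || smoothing_window < 5)
    abort("`smoothing_window` must be odd and >= 5")
  if (n <= smoothing_window)
    abort(sprintf("position series too short (%d samples) for window %d",
                  n, smoothing_window))
  stopifnot(polyorder < smoothing_window)
  dt <- 1 / sampling_rate
  sm <- apply(position, 2, signal::sgolayfilt, p = polyorder,
              n = smoothing_window)
  vel <- apply(sm, 2, central_diff, dt = dt)
  speed <- sqrt(rowSums(vel^2))
  accel <- central_diff(speed, dt)
  list(speed = speed, acceleration = accel, velocity = vel)
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Split a two-peak speed series into strike and retraction
#'
#' The split index is the deepest interior minimum between the two largest
#' local maxima (earliest sample on ties). A series without two separated
#' peaks is returned as a single flagged segment.
#'
#' @param speed Numeric speed series.
#' @return List with `split` (index, `NA` if degenerate), `strike` and
#'   `retraction` index ranges (`retraction` is `NULL` when degenerate).
#' @export
segment_strike_retraction <- function(speed, min_valley = 0.5) {
  n <- length(speed)
  stopifnot(n >= 3)
  # light running-mean smoothing so measurement noise does not fragment peaks
  sm <- if (n >= 15) {
    f <- as.numeric(stats::filter(speed, rep(1 / 7, 7), sides = 2))
    ifelse(is.na(f), speed, f)
  } else speed
  d <- diff(sm)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  pair <- NULL
  if (length(peaks) >= 2) {
    ord <- peaks[order(sm[peaks], decreasing = TRUE)]
    # the second peak must be separated from the first by a real valley
    for (i in 2:length(ord)) {
      p1 <- min(ord[1], ord[i]); p2 <- max(ord[1], ord[i])
      if (min(sm[p1:p2]) < min_valley * min(sm[p1], sm[p2])) {
        pair <- c(p1, p2); break
      }
    }
  }
  if (is.null(pair)) {
    warn("no two separated peaks found: returning a single segment")
    return(list(split = NA_integer_, strike = seq_len(n), retraction = NULL))
  }
  k <- pair[1] - 1L + which.min(sm[pair[1]:pair[2]])   # earliest on ties
  list(split = k, strike = seq_len(k), retraction = seq.int(k + 1L, n))
}

#' Scalar kinematic features of one segment
#'
#' @param time Time stamps (s), uniformly spaced.
#' @param speed Speed series (m/s).
#' @param acceleration Acceleration series (m/s^2); may be `NULL`, in which
#'   case `amax` is `NA`.
#' @return One-row tibble: `vmax`, `amax`, `t_peak` (s from segment start),
#'   `duration`, `mean_speed`, `norm_vmax` = vmax / (vmax + mean speed).
#' @export
extract_features <- function(time, speed, acceleration = NULL) {
  n <- length(speed)
  if (n < 5) abort("segment too short (need >= 5 samples)")
  if (all(speed == 0)) abort("all-zero speed segment")
  i <- which.max(speed)
  vmax <- speed[i]
  mean_speed <- mean(speed)
  tibble(vmax = vmax,
         amax = if (is.null(acceleration)) NA_real_ else max(acceleration),
         t_peak = time[i] - time[1],
         duration = time[n] - time[1],
         mean_speed = mean_speed,
         norm_vmax = vmax / (vmax + mean_speed))
}

#' Per-segment features of a tidy trial table
#'
#' Differentiates and smooths each (session, trial, segment) position series
#' and extracts its scalar features. This is the bridge between raw
#' trajectories and every distributional analysis.
#'
#' @param trials Tidy trial tibble (columns `session_id`, `subject_id`,
#'   `trial_index`, `segment`, `speed_level`, `context`, `design`, `t_s`,
#'   `x_m`, `y_m`, `z_m`; a `class` column is carried through if present), as
#'   produced by [generate_session()] or [read_trials()].
#' @param smoothing_window,polyorder Passed to [differentiate_smooth()].
#' @return Feature tibble, one row per segment, in chronological order.
#' @export
trial_features <- function(trials, smoothing_window = 11, polyorder = 3) {
  req <- c("session_id", "subject_id", "trial_index", "segment",
           "speed_level", "context", "design", "t_s", "x_m", "y_m", "z_m")
  miss <- setdiff(req, names(trials))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  keys <- intersect(c("session_id", "subject_id", "class", "trial_index",
                      "segment", "speed_level", "context", "design"),
                    names(trials))
  trials %>%
    arrange(.data$session_id, .data$trial_index,
            match(.data$segment, c("strike", "retraction"))) %>%
    group_by(across(all_of(keys))) %>%
    group_split() %>%
    purrr::map(function(g) {
      fs <- 1 / median(diff(g$t_s))
      ks <- differentiate_smooth(cbind(g$x_m, g$y_m, g$z_m), fs,
                                 smoothing_window, polyorder)
      feat <- extract_features(g$t_s, ks$speed, ks$acceleration)
      dplyr::bind_cols(g[1, keys], feat)
    }) %>%
    list_rbind() %>%
    arrange(.data$session_id, .data$trial_index,
            match(.data$segment, c("strike", "retraction")))
}

#' Linearity profile of a 3D trajectory
#'
#' The trajectory is resampled to `n_frames` points equally spaced in
#' normalized time and each resampled point is projected at a right angle
#' onto the straight start-end chord; the deviation is the length of that
#' perpendicular. A superposition check (the largest distance between the
#' original samples and the resampled polyline, relative to the chord) is
#' attached so that resampling artefacts are visible.
#'
#' @param position Numeric matrix (n x 3), n >= 3, endpoints distinct.
#' @param n_frames Number of resampled frames M (>= 3).
#' @return Tibble of class `linearity_profile` with columns `frame`, `frac`
#'   and `deviation` (m); attributes `summary` (max/mean/median),
#'   `chord_length` and `resample_error`.
#' @export
linearity_profile <- function(position, n_frames = 100) {
  position <- as.matrix(position)
  n <- nrow(position)
  if (n < 3) abort("need at least 3 points")
  stopifnot(n_frames >= 3)
  chord <- position[n, ] - position[1, ]
  clen <- sqrt(sum(chord^2))
  if (clen < 1e-12) abort("coincident endpoints: chord undefined")
  u <- chord / clen
  frac <- seq(0, 1, length.out = n_frames)
  t0 <- seq(0, 1, length.out = n)
  res <- vapply(1:3, function(j) approx(t0, position[, j], xout = frac)$y,
                numeric(n_frames))
  rel <- sweep(res, 2, position[1, ])
  along <- as.vector(rel %*% u)
  perp <- rel - outer(along, u)
  dev <- sqrt(rowSums(perp^2))
  dev[c(1, n_frames)] <- 0
  rs_err <- max(vapply(seq_len(n), function(i)
    point_polyline_dist(position[i, ], res), numeric(1)))
  out <- tibble(frame = seq_len(n_frames), frac = frac, deviation = dev)
  structure(out,
            class = c("linearity_profile", class(out)),
            summary = c(max = max(dev), mean = mean(dev),
                        median = median(dev)),
            chord_length = clen,
            resample_error = rs_err / clen)
}

point_polyline_dist <- function(p, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, p, "+")
  len2 <- rowSums(ab^2)
  t <- pmin(1, pmax(0, ifelse(len2 > 0, rowSums(ap * ab) / len2, 0)))
  proj <- a + ab * t
  sqrt(min(rowSums(sweep(proj, 2, p)^2)))
}
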