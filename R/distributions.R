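#' Scott's optimal bin width
#'
#' \eqn{W = 3.49 \, s \, N^{-1/3}} with `s` the sample standard deviation and
#' `N` the sample size.
#'
#' @param s Sample standard deviation (> 0).
#' @param n Sample size (>= 1).
#' @return Bin width in the units of the variable.
#' @export
scott_bin_width <- function(s, n) {
  stopifnot(s > 0, n >= 1)
  3.49 * s * n^(-1 / 3)
}

#' Normalized frequency histogram with Scott bin widths
#'
#' @param values Numeric sample.
#' @param bin_width Optional width; defaults to [scott_bin_width()] of the
#'   sample.
#' @return Tibble with `mid`, `lower`, `upper` and `frequency` (sums to 1);
#'   attribute `bin_width`.
#' @export
normalized_histogram <- function(values, bin_width = NULL) {
  stopifnot(length(values) >= 1)
  if (is.null(bin_width)) bin_width <- scott_bin_width(sd(values), length(values))
  stopifnot(bin_width > 0)
  lo <- min(values)
  edges <- seq(lo, max(values) + bin_width, by = bin_width)
  cnt <- graphics::hist(values, breaks = edges, plot = FALSE)$counts
  out <- tibble(lower = edges[-length(edges)], upper = edges[-1],
                mid = (edges[-1] + edges[-length(edges)]) / 2,
                frequency = cnt / length(values))
  attr(out, "bin_width") <- bin_width
  out
}

#' Gamma probability density
#'
#' \eqn{f(x \mid a, b) = x^{a-1} e^{-x/b} / (b^a \Gamma(a))} with shape `a`
#' and scale `b`.
#'
#' @param x Non-negative values.
#' @param shape,scale Gamma parameters (> 0).
#' @return Density values.
#' @export
gamma_pdf <- function(x, shape, scale) {
  stopifnot(all(x >= 0), shape > 0, scale > 0)
  dgamma(x, shape = shape, scale = scale)
}

#' Gamma-plane stochastic signature by maximum likelihood
#'
#' Fits shape and scale of the Gamma family to a positive sample and attaches
#' the derived moments (mean = a b, variance = a b^2) and the noise-to-signal
#' (Fano) ratio variance/mean = b. Confidence intervals are Wald intervals
#' from the observed information. The fitted point (a, b) is the sample's
#' stochastic signature on the Gamma plane: small shapes sit in the
#' memoryless Exponential range, large shapes in the symmetric Gaussian-like
#' range.
#'
#' @param values Positive sample, n >= 10.
#' @param conf_level Confidence level of the Wald intervals.
#' @return Object of class `gamma_signature`: shape, scale, standard errors,
#'   CIs, n, mean, variance, fano.
#' @export
fit_gamma <- function(values, conf_level = 0.95) {
  n <- length(values)
  if (n < 10) abort("need at least 10 values for a stable Gamma MLE")
  if (any(values <= 0)) abort("Gamma support violation: all values must be > 0")
  fit <- tryCatch({
    f <- fitdistrplus::fitdist(values, "gamma", method = "mle",
                               keepdata = FALSE)
    v <- vcov(f)
    list(shape = unname(f$estimate["shape"]), rate = unname(f$estimate["rate"]),
         var_shape = v["shape", "shape"], var_rate = v["rate", "rate"],
         loglik = f$loglik, method = "fitdistrplus")
  }, error = function(e) NULL)
  if (is.null(fit)) fit <- gamma_mle_newton(values)
  shape <- fit$shape
  scale <- 1 / fit$rate
  se_shape <- sqrt(fit$var_shape)
  se_scale <- sqrt(fit$var_rate) / fit$rate^2    # delta method
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(shape = shape, scale = scale,
                 se_shape = se_shape, se_scale = se_scale,
                 ci_shape = shape + c(-1, 1) * z * se_shape,
                 ci_scale = scale + c(-1, 1) * z * se_scale,
                 conf_level = conf_level, n = n,
                 mean = shape * scale, variance = shape * scale^2,
                 fano = scale, loglik = fit$loglik, method = fit$method),
            class = "gamma_signature")
}

# analytic fallback: Newton on log(a) - digamma(a) = log(mean) - mean(log)
gamma_mle_newton <- function(values) {
  n <- length(values)
  s <- log(mean(values)) - mean(log(values))
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * a) { a <- a_new; break }
    a <- a_new
  }
  b <- mean(values) / a
  rate <- 1 / b
  # observed (= expected, at the MLE) information for (shape, rate)
  info <- n * matrix(c(trigamma(a), -1 / rate, -1 / rate, a / rate^2), 2)
  v <- solve(info)
  ll <- sum(dgamma(values, shape = a, rate = rate, log = TRUE))
  list(shape = a, rate = rate, var_shape = v[1, 1], var_rate = v[2, 2],
       loglik = ll, method = "newton")
}

#' @export
print.gamma_signature <- function(x, ...) {
  cat(sprintf("<gamma_signature> shape %.4g [%.4g, %.4g], scale %.4g [%.4g, %.4g], n = %d\n",
              x$shape, x$ci_shape[1], x$ci_shape[2],
              x$scale, x$ci_scale[1], x$ci_scale[2], x$n))
  cat(sprintf("  mean %.4g  variance %.4g  Fano (noise-to-signal) %.4g\n",
              x$mean, x$variance, x$fano))
  invisible(x)
}

#' @export
tidy.gamma_signature <- function(x, ...) {
  tibble(shape = x$shape, scale = x$scale,
         se_shape = x$se_shape, se_scale = x$se_scale,
         ci_shape_low = x$ci_shape[1], ci_shape_high = x$ci_shape[2],
         ci_scale_low = x$ci_scale[1], ci_scale_high = x$ci_scale[2],
         mean = x$mean, variance = x$variance, fano = x$fano, n = x$n)
}

#' @export
glance.gamma_signature <- function(x, ...) {
  tibble(logLik = x$loglik, n = x$n, method = x$method,
         conf_level = x$conf_level)
}

#' Per-group Gamma signatures of a feature table
#'
#' @param features Feature tibble (e.g. from [trial_features()]).
#' @param value Column to fit (default `"vmax"`).
#' @param ... Grouping columns (tidy-select), e.g. `subject_id, speed_level`.
#' @param min_n Groups smaller than this are skipped with a warning.
#' @return Tibble with one signature row per group (shape, scale, CIs, mean,
#'   fano, n).
#' @export
gamma_signatures <- function(features, ..., value = "vmax", min_n = 10) {
  grouped <- features %>% group_by(...)
  keys <- dplyr::group_keys(grouped)
  groups <- grouped %>% group_split(.keep = TRUE)
  out <- purrr::imap(groups, function(g, i) {
    v <- g[[value]]
    if (length(v) < min_n) {
      warn(sprintf("group with %d trials skipped (min_n = %d)", length(v), min_n))
      return(NULL)
    }
    dplyr::bind_cols(keys[i, ], tidy(fit_gamma(v)))
  })
  list_rbind(out[!vapply(out, is.null, logical(1))])
}

#' Noise-to-signal (Fano) ratio of a Gamma signature
#'
#' Variance-to-mean ratio; for a Gamma(a, b) this equals the scale b
#' identically.
#'
#' @param sig A `gamma_signature` or a tibble with `mean` and `variance`
#'   columns.
#' @return Numeric Fano factor(s).
#' @export
fano_factor <- function(sig) {
  if (inherits(sig, "gamma_signature")) return(sig$variance / sig$mean)
  stopifnot(all(c("mean", "variance") %in% names(sig)))
  sig$variance / sig$mean
}

#' Log-normal fit with a log-scale normality check
#'
#' MLE on the log values (n-divisor variance); the goodness-of-fit p-value is
#' a Shapiro-Wilk test of the log values (Kolmogorov-Smirnov beyond n = 5000).
#'
#' @param values Positive sample.
#' @return List: `meanlog`, `sdlog`, `gof_p`, `n`, `degenerate` flag.
#' @export
fit_lognormal <- function(values) {
  stopifnot(length(values) >= 3)
  if (any(values <= 0)) abort("log-normal support violation: values must be > 0")
  lx <- log(values)
  n <- length(lx)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))
  if (sdlog < 1e-12) {
    warn("constant sample: degenerate log-normal fit (sdlog = 0)")
    return(list(meanlog = meanlog, sdlog = 0, gof_p = NA_real_, n = n,
                degenerate = TRUE))
  }
  gof_p <- if (n <= 5000) shapiro.test(lx)$p.value
           else stats::ks.test(lx, "pnorm", meanlog, sdlog)$p.value
  list(meanlog = meanlog, sdlog = sdlog, gof_p = gof_p, n = n,
       degenerate = FALSE)
}

#' Hartigan's dip test of unimodality
#'
#' The dip statistic is the smallest sup-norm distance between the empirical
#' CDF and any unimodal CDF, computed exactly by a convex/concave hull scan
#' over candidate modes. The p-value is calibrated by bootstrap from the
#' uniform null distribution (Hartigan's calibration).
#'
#' @param values Sample, n >= 30.
#' @param n_boot Bootstrap draws (>= 500).
#' @param seed Optional seed for the bootstrap.
#' @return List of class `dip_test`: `statistic`, `p_value`, `n`, `n_boot`.
#' @export
dip_test <- function(values, n_boot = 2000, seed = NULL) {
  n <- length(values)
  if (n < 30) abort("sample too small for the dip test (need n >= 30)")
  stopifnot(n_boot >= 500)
  stat <- dip_stat_cpp(as.numeric(values))
  boot <- if (is.null(seed)) dip_boot_cpp(n, n_boot)
          else withr::with_seed(seed, dip_boot_cpp(n, n_boot))
  p <- (1 + sum(boot >= stat)) / (n_boot + 1)
  structure(list(statistic = stat, p_value = p, n = n, n_boot = n_boot),
            class = "dip_test")
}

#' Dip statistic only
#'
#' @param values Numeric sample (n >= 2).
#' @return The dip statistic.
#' @export
dip_statistic <- function(values) {
  stopifnot(length(values) >= 2)
  dip_stat_cpp(as.numeric(values))
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("<dip_test> dip = %.5g, p = %.4g (n = %d, %d bootstrap draws)\n",
              x$statistic, x$p_value, x$n, x$n_boot))
  invisible(x)
}

#' @export
tidy.dip_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
         n_boot = x$n_boot)
}

#' Power-law fit of the Gamma plane
#'
#' Least squares of log scale on log shape across a set of signatures:
#' \eqn{b = n \, a^m}. On the log-log plane a slope of 1 is the line of
#' unity.
#'
#' @param signatures Tibble with `shape` and `scale` columns (>= 3 rows).
#' @return List of class `power_fit`: `prefactor` n, `exponent` m,
#'   `r_squared`, and the underlying `lm` fit.
#' @export
gamma_plane_power_fit <- function(signatures) {
  stopifnot(all(c("shape", "scale") %in% names(signatures)))
  if (nrow(signatures) < 3) abort("need at least 3 signatures")
  if (sd(signatures$shape) < 1e-12)
    abort("degenerate scatter: all shapes equal")
  fit <- lm(log(scale) ~ log(shape), data = signatures)
  structure(list(prefactor = unname(exp(coef(fit)[1])),
                 exponent = unname(coef(fit)[2]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 fit = fit),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> scale = %.4g * shape^%.4g  (R^2 = %.4f)\n",
              x$prefactor, x$exponent, x$r_squared))
  invisible(x)
}

#' @export
tidy.power_fit <- function(x, ...) {
  tibble(prefactor = x$prefactor, exponent = x$exponent,
         r_squared = x$r_squared)
}
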