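#' Build the trial-to-trial rule scatter
#'
#' For consecutive trials t, t+1 of one ordered segment stream, the scatter
#' point is \eqn{(x, y) = (\ln a_t, \ln(v_{t+1} + \nu v_t))} with
#' \eqn{\nu = \upsilon - 1}. Condition labels are carried from trial t. When
#' the feature table holds several sessions or segments the scatter is built
#' within each (session, segment) stream; pairs spanning a context change are
#' excluded by default, since the rule is stated per task context.
#'
#' @param features Feature tibble with `trial_index`, `vmax`, `amax` and
#'   optionally `session_id`, `segment`, `speed_level`, `context` columns, in
#'   acquisition order.
#' @param upsilon Scaling constant (default 10).
#' @param drop_context_breaks Exclude pairs whose context changes.
#' @return Tibble of class `rule_scatter` with columns `x`, `y`, `vmax_t`,
#'   `vmax_next`, `amax_t` and the carried labels; attribute `upsilon`.
#' @export
build_rule_scatter <- function(features, upsilon = 10,
                               drop_context_breaks = TRUE) {
  stopifnot(all(c("trial_index", "vmax", "amax") %in% names(features)))
  nu <- upsilon - 1
  keys <- intersect(c("session_id", "segment"), names(features))
  grouped <- if (length(keys)) features %>% group_by(across(all_of(keys)))
             else features %>% group_by()
  out <- grouped %>% group_split() %>% purrr::map(function(g) {
    g <- g %>% arrange(.data$trial_index)
    if (anyDuplicated(g$trial_index))
      abort("duplicated trial indices in one segment stream")
    if (nrow(g) < 2) abort("need at least 2 trials in acquisition order")
    ok <- !is.na(g$amax)
    if (any(g$vmax <= 0) || any(g$amax[ok] <= 0))
      abort("non-positive kinematics: vmax and amax must be > 0")
    t_idx <- seq_len(nrow(g) - 1)
    pair <- tibble(
      trial_t = g$trial_index[t_idx],
      x = log(g$amax[t_idx]),
      y = log(g$vmax[t_idx + 1] + nu * g$vmax[t_idx]),
      vmax_t = g$vmax[t_idx], vmax_next = g$vmax[t_idx + 1],
      amax_t = g$amax[t_idx])
    for (cl in intersect(c("session_id", "subject_id", "segment",
                           "speed_level", "context", "design"), names(g)))
      pair[[cl]] <- g[[cl]][t_idx]
    if (drop_context_breaks && "context" %in% names(g))
      pair <- pair[g$context[t_idx] == g$context[t_idx + 1], ]
    pair[stats::complete.cases(pair$x, pair$y), ]
  }) %>% list_rbind()
  structure(out, class = c("rule_scatter", class(out)), upsilon = upsilon)
}

rule_diagnostics <- function(fit) {
  sm <- suppressWarnings(summary(fit))   # exact fits trip a perfect-fit warning
  res <- stats::residuals(fit)
  n <- length(res)
  sse <- sum(res^2)
  ci <- suppressWarnings(confint(fit))
  tibble(m = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         delta = 1 - unname(coef(fit)[2]),
         ci_m_low = ci[2, 1], ci_m_high = ci[2, 2],
         ci_b_low = ci[1, 1], ci_b_high = ci[1, 2],
         sse = sse, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         rmse = sqrt(sse / (n - 2)), n = n)
}

#' Fit the first-order stochastic rule
#'
#' Ordinary least squares of y on x over the rule scatter, either pooled
#' (`"single"`) or one line per speed level (`"per_level"`). Diagnostics
#' follow the usual regression vocabulary: SSE, R-square, adjusted R-square
#' and RMSE = sqrt(SSE / (n - 2)). The slope decomposes as m = 1 - delta.
#'
#' @param scatter A [build_rule_scatter()] result.
#' @param mode `"single"` or `"per_level"`.
#' @return Object of class `rule_fit`: `$coef` tibble (one row per fitted
#'   line), `$models` (the lm fits), `$mode`, `$upsilon`, `$x_range`.
#' @export
fit_rule <- function(scatter, mode = c("single", "per_level")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scatter, "rule_scatter"))
  if (mode == "per_level" && !"speed_level" %in% names(scatter))
    abort("per_level fitting needs a `speed_level` column")
  pieces <- if (mode == "single") list(all = scatter)
            else split(scatter, scatter$speed_level)
  fits <- purrr::map(pieces, function(p) {
    if (nrow(p) < 3) abort("need at least 3 points per fitted line")
    if (sd(p$x) < 1e-12) abort("zero variance in x: slope unidentifiable")
    lm(y ~ x, data = p)
  })
  coefs <- purrr::imap(fits, function(f, lv)
    dplyr::bind_cols(tibble(level = lv), rule_diagnostics(f))) %>% list_rbind()
  structure(list(coef = coefs, models = fits, mode = mode,
                 upsilon = attr(scatter, "upsilon"),
                 x_range = range(scatter$x)),
            class = "rule_fit")
}

#' @export
print.rule_fit <- function(x, ...) {
  cat(sprintf("<rule_fit> mode = %s, upsilon = %g\n", x$mode, x$upsilon))
  print(as.data.frame(x$coef %>% select("level", "m", "b", "delta",
                                        "r_squared", "rmse", "n")),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.rule_fit <- function(x, ...) x$coef

#' @export
glance.rule_fit <- function(x, ...) {
  tibble(mode = x$mode, upsilon = x$upsilon, n_lines = nrow(x$coef),
         total_n = sum(x$coef$n))
}

#' Single line or one line per speed level?
#'
#' Nested-model F-test of a pooled line against level-specific slopes and
#' intercepts, at level `alpha`.
#'
#' @param scatter A [build_rule_scatter()] result with a `speed_level`
#'   column; every level needs >= 3 points.
#' @param alpha Test level.
#' @return List: `decision` (`"single"` or `"per_level"`), `f_statistic`,
#'   `p_value`, `alpha`.
#' @export
split_decision <- function(scatter, alpha = 0.05) {
  stopifnot(inherits(scatter, "rule_scatter"),
            "speed_level" %in% names(scatter))
  cnt <- table(scatter$speed_level)
  if (length(cnt) < 2) abort("need at least two speed levels")
  if (any(cnt < 3)) abort("every speed level needs at least 3 points")
  m0 <- lm(y ~ x, data = scatter)
  m1 <- lm(y ~ x * speed_level, data = scatter)
  a <- anova(m0, m1)
  fstat <- a$F[2]
  p <- a$`Pr(>F)`[2]
  list(decision = if (p < alpha) "per_level" else "single",
       f_statistic = fstat, p_value = p, alpha = alpha)
}

#' Power form and leading-order expansion of a rule fit
#'
#' Exponentiating the fitted log-log line gives
#' \eqn{v_{t+1} + \nu v_t = a_t^m e^{b + \varepsilon}}. Writing m = 1 - delta
#' and expanding \eqn{a^m = a(1 - \delta \ln a) + O(\delta^2)} yields the
#' anticipatory updating form; the reported remainder bound is the worst
#' value of \eqn{|e^{-\delta u} - (1 + \delta u)| \le (\delta u)^2
#' e^{|\delta u|} / 2} over the scatter's \eqn{u = \ln a} range (a relative
#' bound on the \eqn{a^m} term).
#'
#' @param fit A [fit_rule()] result.
#' @return List: `terms` tibble (level, m, delta, delta_squared,
#'   remainder_bound) and `form`, the expansion written out.
#' @export
power_form <- function(fit) {
  stopifnot(inherits(fit, "rule_fit"))
  umax <- max(abs(fit$x_range))
  terms <- fit$coef %>%
    mutate(delta_squared = .data$delta^2,
           remainder_bound = (.data$delta * umax)^2 *
             exp(abs(.data$delta) * umax) / 2) %>%
    select("level", "m", "delta", "delta_squared", "remainder_bound")
  list(terms = terms,
       form = paste("vmax[t+1] = amax[t] * (1 - delta*ln amax[t]) *",
                    "exp(b + eps) - nu*vmax[t] + O(delta^2)"))
}

#' One-step-ahead prediction of the next peak speed
#'
#' \eqn{\hat v_{t+1} = a_t^m e^b - \nu v_t} with the fitted (m, b) and the
#' residual set to zero. Non-positive predictions are flagged as
#' out-of-regime.
#'
#' @param fit A [fit_rule()] result (its first line is used unless `level`
#'   is given).
#' @param vmax_t,amax_t Current-trial peak speed and acceleration
#'   (vectorized).
#' @param level Optional level name selecting a per-level line.
#' @return Numeric predictions (NA where non-positive, with a warning).
#' @export
predict_next_vmax <- function(fit, vmax_t, amax_t, level = NULL) {
  stopifnot(inherits(fit, "rule_fit"), all(amax_t > 0))
  row <- if (is.null(level)) fit$coef[1, ]
         else fit$coef[fit$coef$level == level, ]
  if (nrow(row) != 1) abort("unknown `level`")
  nu <- fit$upsilon - 1
  pred <- amax_t^row$m * exp(row$b) - nu * vmax_t
  if (any(pred <= 0)) {
    warn(sprintf("%d non-positive predictions flagged as out-of-regime (NA)",
                 sum(pred <= 0)))
    pred[pred <= 0] <- NA_real_
  }
  pred
}
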