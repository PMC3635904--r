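#' Stochastic-signature trajectory across blocks or windows
#'
#' Fits one Gamma signature per chronological group of trials (a condition
#' block, or a sliding window of fixed size) and classifies each transition
#' as a positive gain (shift towards the symmetric, predictive range: larger
#' shape), a negative gain (towards the memoryless Exponential range) or
#' neutral.
#'
#' @param features Feature tibble in chronological order.
#' @param group Name of the column defining blocks (ignored when `window` is
#'   given).
#' @param value Feature column to fit (default `"vmax"`).
#' @param window Optional window size in trials; consecutive non-overlapping
#'   windows are used.
#' @param min_n Minimum trials per group; undersized groups are skipped with
#'   a warning.
#' @param neutral_tol Relative shape-change tolerance of the neutral class.
#' @return Tibble of class `signature_trajectory`, one row per block in
#'   chronological order (block, n, shape, scale, CIs, mean, fano, shift
#'   from the previous block).
#' @export
signature_trajectory <- function(features, group = "speed_level",
                                 value = "vmax", window = NULL,
                                 min_n = 10, neutral_tol = 0.05) {
  if (!is.null(window)) {
    stopifnot(window >= min_n)
    features$...block <- paste0("window_",
                                (seq_len(nrow(features)) - 1) %/% window + 1)
    group <- "...block"
  }
  stopifnot(group %in% names(features))
  blocks <- split(seq_len(nrow(features)),
                  factor(features[[group]], levels = unique(features[[group]])))
  rows <- purrr::imap(blocks, function(ix, label) {
    v <- features[[value]][ix]
    if (length(v) < min_n) {
      warn(sprintf("block '%s' with %d trials skipped (min_n = %d)",
                   label, length(v), min_n))
      return(NULL)
    }
    dplyr::bind_cols(tibble(block = label), tidy(fit_gamma(v)))
  })
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) >= 2) {
    out$shift <- c(NA_character_,
                   purrr::map_chr(seq_len(nrow(out) - 1), function(i)
                     classify_shift(out$shape[i], out$shape[i + 1],
                                    tol = neutral_tol)))
  } else {
    out$shift <- NA_character_
  }
  structure(out, class = c("signature_trajectory", class(out)),
            value = value)
}

#' Classify a Gamma-plane shift as positive or negative gain
#'
#' A shift to the right (larger shape, towards the symmetric Gaussian-like
#' range) is a positive gain; a shift to the left (towards the memoryless
#' Exponential range) a negative gain. Shape changes below `tol` of the
#' smaller shape are neutral.
#'
#' @param from,to `gamma_signature` objects or plain shape values.
#' @param tol Relative neutral tolerance.
#' @return `"positive_gain"`, `"negative_gain"` or `"neutral"`.
#' @export
classify_shift <- function(from, to, tol = 0.05) {
  a1 <- if (inherits(from, "gamma_signature")) from$shape else from
  a2 <- if (inherits(to, "gamma_signature")) to$shape else to
  stopifnot(a1 > 0, a2 > 0)
  if (abs(a2 - a1) < tol * min(a1, a2)) return("neutral")
  if (a2 > a1) "positive_gain" else "negative_gain"
}

#' Nonparametric comparison of conditions
#'
#' Rank-based tests on a per-trial feature across condition groups: Wilcoxon
#' rank-sum for two groups, Kruskal-Wallis for several, Friedman for a
#' paired (blocked) layout. The output mirrors the usual reporting format:
#' per-group median and min-max range plus the test statistic and p-value.
#'
#' @param features Feature tibble.
#' @param value Feature column name.
#' @param group Grouping column name.
#' @param test `"ranksum"`, `"kruskal_wallis"` or `"friedman"`.
#' @param block Block column name (required for `"friedman"`).
#' @return List: `summary` tibble (group, n, median, min, max), `statistic`,
#'   `p_value`, `test`.
#' @export
compare_conditions <- function(features, value, group,
                               test = c("ranksum", "kruskal_wallis",
                                        "friedman"),
                               block = NULL) {
  test <- match.arg(test)
  stopifnot(value %in% names(features), group %in% names(features))
  v <- features[[value]]
  g <- factor(features[[group]])
  if (any(table(g) == 0) || nlevels(g) < 2) abort("need >= 2 non-empty groups")
  smry <- features %>% group_by(.group = g) %>%
    summarise(n = dplyr::n(), median = median(.data[[value]]),
              min = min(.data[[value]]), max = max(.data[[value]]),
              .groups = "drop") %>%
    rename(group = ".group")
  res <- switch(test,
    ranksum = {
      if (nlevels(g) != 2) abort("ranksum compares exactly 2 groups")
      wilcox.test(v ~ g)
    },
    kruskal_wallis = kruskal.test(v, g),
    friedman = {
      if (is.null(block)) abort("friedman needs a `block` column")
      b <- factor(features[[block]])
      tab <- table(b, g)
      if (any(tab != 1))
        abort("friedman needs exactly one observation per (block, group)")
      friedman.test(v, g, b)
    })
  list(summary = smry, statistic = unname(res$statistic),
       p_value = res$p.value, test = test)
}

#' Fatigue check: first k vs last k trials
#'
#' Compares peak speed and duration between the first `k` and last `k`
#' trials of a block (strike and retraction separately when a `segment`
#' column is present), with Wilcoxon rank-sum tests. Stationary blocks
#' should show no effect; fatigue typically surfaces as inflated durations
#' late in the block.
#'
#' @param features Feature tibble of one block in chronological order.
#' @param k Number of trials at each end (block must hold >= 2k trials).
#' @param measures Feature columns to compare.
#' @return Tibble: segment, measure, medians of the early and late trials,
#'   statistic, p_value.
#' @export
fatigue_check <- function(features, k = 10,
                          measures = c("vmax", "duration")) {
  stopifnot(all(measures %in% names(features)))
  segs <- if ("segment" %in% names(features))
    split(features, features$segment) else list(all = features)
  purrr::imap(segs, function(g, seg) {
    g <- g %>% arrange(.data$trial_index)
    T <- nrow(g)
    if (T < 2 * k) abort(sprintf("block too short (%d trials) for k = %d", T, k))
    early <- g[seq_len(k), ]
    late <- g[seq.int(T - k + 1L, T), ]
    purrr::map(measures, function(ms) {
      wt <- wilcox.test(early[[ms]], late[[ms]], exact = FALSE)
      tibble(segment = seg, measure = ms,
             median_first = median(early[[ms]]),
             median_last = median(late[[ms]]),
             statistic = unname(wt$statistic), p_value = wt$p.value)
    }) %>% list_rbind()
  }) %>% list_rbind()
}

#' Expertise profile from per-condition Gamma signatures
#'
#' Expertise combines (1) a broad bandwidth of condition-wise distribution
#' locations and (2) low noise-to-signal ratios. Bandwidth is the ratio of
#' the largest to the smallest condition-wise Gamma mean; separability of a
#' condition pair is non-overlap of the central 95% probability intervals of
#' the fitted Gamma pdfs.
#'
#' @param signatures Tibble with one row per condition: `shape`, `scale` and
#'   a condition label column (the first non-numeric column, or `condition`).
#' @param theta_bw Bandwidth threshold.
#' @param theta_f Maximal acceptable Fano (noise-to-signal) ratio.
#' @param prob Central probability mass of the separability intervals.
#' @return List of class `expertise_profile`: `bandwidth`, `max_fano`,
#'   `separability` (pairwise tibble), `expert_like`, thresholds.
#' @export
expertise_profile <- function(signatures, theta_bw = 3, theta_f = 0.1,
                              prob = 0.95) {
  stopifnot(all(c("shape", "scale") %in% names(signatures)))
  if (nrow(signatures) < 2) abort("need >= 2 conditions")
  lab_col <- if ("condition" %in% names(signatures)) "condition"
             else names(signatures)[!vapply(signatures, is.numeric, logical(1))][1]
  if (is.na(lab_col)) {
    signatures$condition <- paste0("cond_", seq_len(nrow(signatures)))
    lab_col <- "condition"
  }
  mu <- signatures$shape * signatures$scale
  bw <- max(mu) / min(mu)
  max_fano <- max(signatures$scale)
  alpha <- (1 - prob) / 2
  lo <- qgamma(alpha, shape = signatures$shape, scale = signatures$scale)
  hi <- qgamma(1 - alpha, shape = signatures$shape, scale = signatures$scale)
  pairs <- utils::combn(nrow(signatures), 2)
  sep <- tibble(
    cond_a = signatures[[lab_col]][pairs[1, ]],
    cond_b = signatures[[lab_col]][pairs[2, ]],
    separable = purrr::map_lgl(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      hi[i1] < lo[i2] || hi[i2] < lo[i1]
    }))
  structure(list(bandwidth = bw, max_fano = max_fano, separability = sep,
                 expert_like = bw >= theta_bw && max_fano <= theta_f,
                 theta_bw = theta_bw, theta_f = theta_f, prob = prob,
                 conditions = signatures[[lab_col]]),
            class = "expertise_profile")
}

#' @export
print.expertise_profile <- function(x, ...) {
  cat(sprintf("<expertise_profile> bandwidth %.3g (theta %.3g), max Fano %.3g (theta %.3g)\n",
              x$bandwidth, x$theta_bw, x$max_fano, x$theta_f))
  cat(sprintf("  separable pairs: %d / %d; expert-like: %s\n",
              sum(x$separability$separable), nrow(x$separability),
              x$expert_like))
  invisible(x)
}

#' @export
tidy.expertise_profile <- function(x, ...) {
  tibble(bandwidth = x$bandwidth, max_fano = x$max_fano,
         n_separable = sum(x$separability$separable),
         n_pairs = nrow(x$separability), expert_like = x$expert_like)
}
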