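#' Baseline trend as mean of first differences
#'
#' Estimates the baseline linear trend as the average of the differenced
#' baseline measurements, `mean(y[i] - y[i-1])` over the baseline phase: the
#' average change from one baseline session to the next. By telescoping this
#' equals `(y[n_pre] - y[1]) / (n_pre - 1)` exactly.
#'
#' @param series A [two_phase_series()] with at least 2 baseline sessions.
#' @return The trend in score units per session.
#' @export
baseline_trend <- function(series) {
  series <- validate_series(series, min_pre = 2L)
  mean(diff(pre_scores(series)))
}

#' Remove a linear trend positionally from a whole series
#'
#' Corrects each score according to its position in the session sequence:
#' `y*[t] = y[t] - (t - 1) * trend`, so the first session is unmoved. With the
#' baseline trend this turns a linearly-trending baseline into a flat one and
#' expresses every later score net of the trend's continuation.
#'
#' @param series A [two_phase_series()].
#' @param trend Slope to remove, in score units per session; defaults to
#'   [baseline_trend()] of the series.
#' @return A [two_phase_series()] with the corrected scores (same phase split
#'   and aim).
#' @export
detrend <- function(series, trend = baseline_trend(series)) {
  series <- validate_series(series)
  corrected <- series$score - (series$time - 1) * trend
  two_phase_series(corrected[series$phase == "pre"],
                   corrected[series$phase == "post"],
                   aim = series_aim(series), label = series_label(series))
}

#' Slope change after baseline detrending
#'
#' After removing the baseline trend from the whole series, the remaining
#' trend in the intervention phase is attributed to the intervention. It is
#' estimated the same way as the baseline trend: the average of the
#' differenced, already-detrended intervention measurements — the average
#' per-session change during the intervention net of the baseline trend's
#' continuation (a progressive effect).
#'
#' @param series A [two_phase_series()] with at least 2 sessions per phase.
#' @return Slope change in score units per intervention session.
#' @export
slope_change <- function(series) {
  series <- validate_series(series, min_pre = 2L, min_post = 2L)
  mean(diff(post_scores(detrend(series))))
}

#' Net level change after trend and slope correction
#'
#' Removes the baseline trend from all sessions, then removes the slope
#' change positionally within the intervention phase
#' (`y**[j] = y*[n_pre + j] - (j - 1) * slope_change`), and returns the
#' difference between the mean corrected intervention score and the mean
#' corrected baseline score: an abrupt-and-maintained effect in raw score
#' units. The sign follows the score scale; interpret it against the series'
#' improvement direction.
#'
#' @inheritParams slope_change
#' @return Net level change in score units.
#' @export
level_change <- function(series) {
  slc(series)$level_change
}

#' Slope and Level Change (SLC) decomposition
#'
#' Composes the three descriptive estimates — baseline trend, slope change,
#' and net level change — and keeps the intermediate corrected series for
#' plotting. The outputs deliberately stay in raw score units (unstandardised),
#' so a slope change of −1.6 on a T-score scale reads as an average reduction
#' of 1.6 T-score points per intervention session.
#'
#' @inheritParams slope_change
#' @return An `slc_result` list: `baseline_trend`, `slope_change`,
#'   `level_change` (all in score units), `detrended` (a [two_phase_series()]
#'   after baseline-trend removal), `post_doubly_corrected` (intervention
#'   scores after additional slope-change removal), and `short_baseline`
#'   (flag: fewer than 5 baseline sessions, below the usual design standard —
#'   reported, never blocking). [generics::tidy()] returns the three
#'   estimates as a tibble.
#' @examples
#' s <- two_phase_series(c(0, 2, 4), c(10, 10, 10), aim = "increase")
#' slc(s)
#' @export
slc <- function(series) {
  series <- validate_series(series, min_pre = 2L, min_post = 2L)
  b <- baseline_trend(series)
  star <- detrend(series, b)
  sc <- mean(diff(post_scores(star)))
  post_star <- post_scores(star)
  post_dd <- post_star - (seq_along(post_star) - 1) * sc
  lc <- mean(post_dd) - mean(pre_scores(star))
  structure(
    list(
      baseline_trend = b,
      slope_change = sc,
      level_change = lc,
      detrended = star,
      post_doubly_corrected = post_dd,
      short_baseline = n_pre(series) < 5L,
      aim = series_aim(series)
    ),
    class = "slc_result"
  )
}

#' @export
print.slc_result <- function(x, ...) {
  cat(sprintf(
    paste0("Slope and Level Change (raw score units)\n",
           "  baseline trend: %8.4f per session\n",
           "  slope change:   %8.4f per session (after baseline detrending)\n",
           "  level change:   %8.4f (corrected phase-mean difference)\n"),
    x$baseline_trend, x$slope_change, x$level_change))
  if (x$short_baseline) {
    cat("  note: baseline shorter than 5 sessions; trend estimate is fragile\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slc_result <- function(x, ...) {
  tibble::tibble(
    term = c("baseline_trend", "slope_change", "level_change"),
    estimate = c(x$baseline_trend, x$slope_change, x$level_change),
    units = c("score/session", "score/session", "score")
  )
}

#' @exportS3Method generics::glance
glance.slc_result <- function(x, ...) {
  tibble::tibble(baseline_trend = x$baseline_trend,
                 slope_change = x$slope_change,
                 level_change = x$level_change,
                 short_baseline = x$short_baseline)
}

#' @exportS3Method ggplot2::autoplot
autoplot.slc_result <- function(object, ...) {
  orig <- object$detrended
  df <- dplyr::bind_rows(
    tibble::tibble(time = orig$time, score = orig$score,
                   phase = orig$phase, stage = "detrended"),
    tibble::tibble(time = orig$time[orig$phase == "post"],
                   score = object$post_doubly_corrected,
                   phase = factor("post", levels = c("pre", "post")),
                   stage = "doubly corrected")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$score,
                                   linetype = .data$stage,
                                   shape = .data$stage)) +
    ggplot2::geom_vline(xintercept = sum(df$phase == "pre" & df$stage == "detrended") + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Session", y = "Corrected score",
                  title = "SLC corrected series",
                  linetype = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
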