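#' Per-phase range lines
#'
#' The coarsest visual aid: the minimum and maximum of each phase, drawn as
#' horizontal lines spanning the phase. Two disjoint ranges are a crude
#' statement of complete non-overlap; intersecting ranges mean some scores
#' are shared between phases.
#'
#' @param series A [two_phase_series()].
#' @return A tibble with one row per phase (`phase`, `n`, `minimum`,
#'   `maximum`) and a logical column `ranges_overlap`, TRUE when the two
#'   phase ranges intersect.
#' @export
range_lines <- function(series) {
  series <- validate_series(series)
  rng <- series |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(n = dplyr::n(), minimum = min(.data$score),
                     maximum = max(.data$score), .groups = "drop")
  overlap <- rng$minimum[1] <= rng$maximum[2] && rng$minimum[2] <= rng$maximum[1]
  dplyr::mutate(rng, ranges_overlap = overlap)
}

#' Two-standard-deviation band
#'
#' Computes the baseline mean and standard deviation, draws limits at
#' `center ± k * sd`, and projects the band across the intervention phase.
#' For normally distributed stable behaviour, few intervention points (under
#' 5% in the long run) should fall outside a 2-SD band when nothing changed;
#' many outside points suggest change beyond baseline variability. The band
#' is a visual aid, not a formal test: behavioural series are rarely normal,
#' continuous, or serially independent, and with short baselines the
#' estimated band is too narrow (see the methods vignette).
#'
#' Points exactly on a limit count as inside (the conservative, no-change
#' reading); "outside" means strictly beyond a limit.
#'
#' @param series A [two_phase_series()] with at least 2 baseline sessions.
#' @param k Band half-width in baseline standard deviations (default 2).
#' @param center `"mean"` (default) or `"median"` of the baseline.
#' @param sd_type Sample (n − 1, default) or population SD convention.
#' @return An `sd_band` list: `center`, `sd`, `k`, `lower`, `upper`,
#'   `outside_post` (1-based indices within the intervention phase of points
#'   strictly outside), `outside_fraction`, and `direction` (`"above"`,
#'   `"below"`, `"mixed"`, or `"none"` for the outside points).
#' @export
sd_band <- function(series, k = 2, center = c("mean", "median"),
                    sd_type = c("sample", "population")) {
  center <- match.arg(center)
  sd_type <- match.arg(sd_type)
  series <- validate_series(series, min_pre = 2L)
  pre <- pre_scores(series)
  post <- post_scores(series)
  ctr <- if (center == "mean") mean(pre) else stats::median(pre)
  s <- phase_sd(pre, sd_type)
  lower <- ctr - k * s
  upper <- ctr + k * s
  outside <- which(post < lower | post > upper)
  structure(
    list(
      center = ctr, sd = s, k = k, lower = lower, upper = upper,
      center_type = center,
      n_post = length(post),
      outside_post = outside,
      outside_fraction = length(outside) / length(post),
      direction = outside_direction(post[outside], lower, upper)
    ),
    class = "sd_band"
  )
}

outside_direction <- function(values, lower, upper) {
  if (length(values) == 0) return("none")
  above <- any(values > upper)
  below <- any(values < lower)
  if (above && below) "mixed" else if (above) "above" else "below"
}

#' @export
print.sd_band <- function(x, ...) {
  cat(sprintf(
    "%s +/- %g SD band: [%.4f, %.4f] (center %.4f, sd %.4f)\n%d/%d post points outside (%.1f%%), direction: %s\n",
    x$center_type, x$k, x$lower, x$upper, x$center, x$sd,
    length(x$outside_post), x$n_post,
    100 * x$outside_fraction, x$direction))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sd_band <- function(x, ...) {
  tibble::tibble(center = x$center, sd = x$sd, k = x$k,
                 lower = x$lower, upper = x$upper,
                 outside_fraction = x$outside_fraction,
                 direction = x$direction)
}

#' Straight trend lines for one phase
#'
#' `ols_trend()` fits an ordinary least-squares line through the
#' (session, score) points of a phase. `split_middle()` fits the resistant
#' split-middle line: the phase is split into two halves, each half is
#' summarised by its (median session, median score) point, and the line is
#' drawn through those two points. For odd phase lengths the middle
#' observation belongs to both halves by default; `middle = "drop"` excludes
#' it instead.
#'
#' Both return a `trend_line` whose `predict()` method extrapolates to any
#' session, which is how a baseline trend is projected into the intervention
#' phase.
#'
#' @param scores Numeric scores of one phase.
#' @param offset Session index of the last point *before* this phase (0 for a
#'   phase that starts at session 1), so the phase occupies sessions
#'   `offset + 1, ..., offset + length(scores)`.
#' @return A `trend_line` with fields `slope` (score units per session),
#'   `intercept` (score units at session 0), `method`, and the fitted session
#'   range.
#' @examples
#' predict(ols_trend(c(1, 3, 5)), 1:5)
#' split_middle(c(2, 4, 6, 8, 10))
#' @export
ols_trend <- function(scores, offset = 0) {
  if (length(scores) < 2) abort_scedab("need at least 2 points to fit a trend", "phase-too-short")
  t <- offset + seq_along(scores)
  fit <- stats::lm(scores ~ t)
  new_trend_line(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
                 "ols", range(t))
}

#' @rdname ols_trend
#' @param middle For odd phase lengths, whether the middle observation is
#'   `"both"` halves (default) or `"drop"`ped.
#' @export
split_middle <- function(scores, offset = 0, middle = c("both", "drop")) {
  middle <- match.arg(middle)
  n <- length(scores)
  if (n < 2) abort_scedab("need at least 2 points to fit a trend", "phase-too-short")
  t <- offset + seq_len(n)
  if (n %% 2 == 0) {
    first <- seq_len(n / 2)
    second <- seq(n / 2 + 1, n)
  } else if (middle == "both") {
    first <- seq_len((n + 1) / 2)
    second <- seq((n + 1) / 2, n)
  } else {
    first <- seq_len((n - 1) / 2)
    second <- seq((n + 3) / 2, n)
  }
  p1 <- c(stats::median(t[first]), stats::median(scores[first]))
  p2 <- c(stats::median(t[second]), stats::median(scores[second]))
  if (p1[1] == p2[1]) abort_scedab("the two half-phase median sessions coincide", "degenerate-split")
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  new_trend_line(slope, p1[2] - slope * p1[1], "split-middle", range(t))
}

new_trend_line <- function(slope, intercept, method, t_range) {
  structure(list(slope = slope, intercept = intercept, method = method,
                 t_range = t_range),
            class = "trend_line")
}

#' @export
predict.trend_line <- function(object, t, ...) {
  object$intercept + object$slope * t
}

#' @export
print.trend_line <- function(x, ...) {
  cat(sprintf("<trend_line> %s: score = %.4f %+.4f * session (fitted over sessions %g..%g)\n",
              x$method, x$intercept, x$slope, x$t_range[1], x$t_range[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trend_line <- function(x, ...) {
  tibble::tibble(method = x$method, slope = x$slope, intercept = x$intercept,
                 t_min = x$t_range[1], t_max = x$t_range[2])
}

#' Split-middle trend with projected stability envelope
#'
#' Fits the split-middle trend to the baseline, projects it across the
#' intervention phase, and surrounds it with an envelope whose half-width is
#' a fraction (default 25%) of the baseline median: the lower limit sits that
#' distance below the trend line and the upper limit the same distance above.
#' Two containment fractions are reported: the baseline points inside their
#' own envelope (trend stability of the baseline itself) and the intervention
#' points inside the *projected* envelope (a change assessment — points
#' escaping the envelope behave differently from the continued baseline
#' trend). The stability verdict applies the criterion (default 80%) to the
#' intervention-phase containment; the baseline containment is reported
#' alongside so an unstable baseline can be flagged.
#'
#' Points exactly on a limit count as inside. Projection is unbounded in
#' time, so a trending envelope can leave the plausible measurement range;
#' [analyze()] warns when it does.
#'
#' @param series A [two_phase_series()] with at least 2 baseline sessions
#'   (4 or more recommended for a meaningful split).
#' @param fraction Envelope half-width as a fraction of the baseline median
#'   (default 0.25).
#' @param criterion Containment proportion at or above which a phase counts
#'   as trend-stable (default 0.80).
#' @param middle Odd-length halving rule, see [split_middle()].
#' @return An `envelope_result` list: `trend` (a `trend_line`), `half_width`,
#'   `baseline_within_fraction`, `post_within_fraction`, `stable`,
#'   `criterion`, and `direction` of the escaping intervention points
#'   (`"above"`, `"below"`, `"mixed"`, `"none"`).
#' @export
stability_envelope <- function(series, fraction = 0.25, criterion = 0.80,
                               middle = c("both", "drop")) {
  middle <- match.arg(middle)
  series <- validate_series(series, min_pre = 2L)
  pre <- pre_scores(series)
  post <- post_scores(series)
  trend <- split_middle(pre, offset = 0, middle = middle)
  hw <- fraction * stats::median(pre)
  inside <- function(values, t) abs(values - predict(trend, t)) <= hw
  pre_in <- inside(pre, seq_along(pre))
  t_post <- length(pre) + seq_along(post)
  post_in <- inside(post, t_post)
  resid_out <- (post - predict(trend, t_post))[!post_in]
  structure(
    list(
      trend = trend,
      half_width = hw,
      fraction = fraction,
      baseline_within_fraction = mean(pre_in),
      post_within_fraction = mean(post_in),
      stable = mean(post_in) >= criterion,
      baseline_stable = mean(pre_in) >= criterion,
      criterion = criterion,
      direction = outside_direction(resid_out, 0, 0)
    ),
    class = "envelope_result"
  )
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf(
    paste0("Split-middle trend: slope %.4f, intercept %.4f; envelope half-width %.4f\n",
           "baseline containment %.0f%%, projected post containment %.0f%% ",
           "(criterion %.0f%%) -> %s\n"),
    x$trend$slope, x$trend$intercept, x$half_width,
    100 * x$baseline_within_fraction, 100 * x$post_within_fraction,
    100 * x$criterion,
    if (x$stable) "trend-stable (no slope change suggested)"
    else sprintf("not stable (post points escape %s)", x$direction)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.envelope_result <- function(x, ...) {
  tibble::tibble(slope = x$trend$slope, intercept = x$trend$intercept,
                 half_width = x$half_width,
                 baseline_within_fraction = x$baseline_within_fraction,
                 post_within_fraction = x$post_within_fraction,
                 criterion = x$criterion, stable = x$stable,
                 direction = x$direction)
}

#' Immediacy of change at the phase boundary
#'
#' Contrasts the sessions just around the intervention's introduction: the
#' mean of the first `window` intervention scores minus the mean of the last
#' `window` baseline scores. A change in the improvement direction right at
#' the boundary strengthens the reading that the behaviour changed when — not
#' merely after — the intervention started.
#'
#' @param series A [two_phase_series()].
#' @param window Number of sessions on each side of the boundary (default 3);
#'   must not exceed either phase length.
#' @return A one-row tibble with `window`, `change` (score units, post minus
#'   pre), and `label` (`"improvement"`, `"deterioration"`, `"no change"`
#'   judged against the series' aim).
#' @export
immediacy <- function(series, window = 3) {
  series <- validate_series(series)
  if (window < 1 || window > min(n_pre(series), n_post(series))) {
    abort_scedab("window must be between 1 and the shorter phase length", "window-too-large")
  }
  pre <- pre_scores(series)
  post <- post_scores(series)
  change <- mean(post[seq_len(window)]) - mean(utils::tail(pre, window))
  improving <- if (series_aim(series) == "decrease") change < 0 else change > 0
  tibble::tibble(
    window = as.integer(window),
    change = change,
    label = if (change == 0) "no change" else if (improving) "improvement" else "deterioration"
  )
}
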