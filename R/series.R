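#' Construct a two-phase (AB) series
#'
#' A two-phase series is the basic data object of the package: a single
#' behavioural measure recorded over consecutive sessions, split into a
#' baseline (pre-intervention) phase and an intervention (post-intervention)
#' phase. The object is a tibble with columns `time` (1-based consecutive
#' session index), `score`, and `phase` (`"pre"` or `"post"`), carrying the
#' improvement direction and an optional label as attributes.
#'
#' @param pre_scores Numeric vector of baseline-phase scores (at least 1).
#' @param post_scores Numeric vector of intervention-phase scores (at least 1).
#' @param aim Improvement direction: `"decrease"` if lower scores are better
#'   (e.g., problem-behaviour counts, ECBI Intensity T-scores), `"increase"`
#'   otherwise. Every directional statistic in the package consumes it.
#' @param label Optional free-text identifier for the case or measure.
#'
#' @return A `two_phase_series` tibble with `n_pre + n_post` rows and columns
#'   `time`, `score`, `phase`.
#'
#' @examples
#' s <- two_phase_series(c(82, 73, 70, 75, 80), c(62, 59, 63, 58, 55,
#'                       52, 50, 48, 45, 44), aim = "decrease")
#' s
#' phase_descriptives(s)
#' @export
two_phase_series <- function(pre_scores, post_scores, aim = c("decrease", "increase"),
                             label = NULL) {
  aim <- match.arg(aim)
  pre_scores <- check_scores(pre_scores, "pre")
  post_scores <- check_scores(post_scores, "post")
  n_pre <- length(pre_scores)
  n_post <- length(post_scores)
  out <- tibble::tibble(
    time = seq_len(n_pre + n_post),
    score = c(pre_scores, post_scores),
    phase = factor(rep(c("pre", "post"), c(n_pre, n_post)),
                   levels = c("pre", "post"))
  )
  new_two_phase_series(out, aim = aim, label = label)
}

new_two_phase_series <- function(df, aim, label = NULL) {
  structure(df,
            aim = aim,
            label = label,
            class = c("two_phase_series", class(tibble::tibble())))
}

check_scores <- function(x, which) {
  if (length(x) == 0) {
    abort_scedab(sprintf("the %s phase has no scores", which), "phase-empty")
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_scedab(
      sprintf("all %s-phase scores must be finite numbers (missing values are not imputed)", which),
      "invalid-score"
    )
  }
  as.numeric(x)
}

abort_scedab <- function(message, code) {
  rlang::abort(message, class = c(paste0("scedab_", code), "scedab_error"),
               code = code)
}

#' Coerce a long data frame to a two-phase series
#'
#' Accepts the "long" layout: one row per session with columns `Time`
#' (1..n, consecutive), `Score`, and `Phase` (a block of 0s for the baseline
#' followed by a block of 1s for the intervention). Column names are matched
#' case-insensitively.
#'
#' @param df A data frame with columns `Time`, `Score`, `Phase`.
#' @inheritParams two_phase_series
#' @return A [two_phase_series()].
#' @export
as_two_phase_series <- function(df, aim = c("decrease", "increase"), label = NULL) {
  aim <- match.arg(aim)
  if (inherits(df, "two_phase_series")) return(df)
  nm <- tolower(names(df))
  need <- c("time", "score", "phase")
  if (!all(need %in% nm)) {
    abort_scedab("expected columns Time, Score, Phase", "phase-empty")
  }
  df <- stats::setNames(df[match(need, nm)], need)
  if (nrow(df) == 0) abort_scedab("no rows in input", "phase-empty")
  if (!all(df$time == seq_len(nrow(df)))) {
    abort_scedab("Time must be consecutive integers 1..n in order", "bad-time-index")
  }
  ph <- as.integer(df$phase)
  if (!all(ph %in% c(0L, 1L))) {
    abort_scedab("Phase must be 0 (baseline) or 1 (intervention)", "non-contiguous-phases")
  }
  if (is.unsorted(ph)) {
    abort_scedab("Phase must be a block of 0s followed by a block of 1s", "non-contiguous-phases")
  }
  two_phase_series(df$score[ph == 0L], df$score[ph == 1L], aim = aim, label = label)
}

#' @export
print.two_phase_series <- function(x, ...) {
  lbl <- series_label(x)
  cat(sprintf("<two_phase_series>%s  n_pre = %d, n_post = %d, aim = %s\n",
              if (is.null(lbl)) "" else paste0(" ", lbl),
              n_pre(x), n_post(x), series_aim(x)))
  NextMethod()
}

#' Series accessors
#'
#' Small helpers reading the phase split and improvement direction off a
#' two-phase series.
#'
#' @param series A [two_phase_series()].
#' @return `n_pre()`/`n_post()` return counts, `series_aim()` the improvement
#'   direction, `pre_scores()`/`post_scores()` the per-phase score vectors,
#'   `series_label()` the label (or `NULL`).
#' @export
n_pre <- function(series) sum(series$phase == "pre")

#' @rdname n_pre
#' @export
n_post <- function(series) sum(series$phase == "post")

#' @rdname n_pre
#' @export
series_aim <- function(series) attr(series, "aim") %||% "decrease"

#' @rdname n_pre
#' @export
series_label <- function(series) attr(series, "label")

#' @rdname n_pre
#' @export
pre_scores <- function(series) series$score[series$phase == "pre"]

#' @rdname n_pre
#' @export
post_scores <- function(series) series$score[series$phase == "post"]

validate_series <- function(series, min_pre = 1L, min_post = 1L,
                            code_pre = "baseline-too-short",
                            code_post = "post-too-short") {
  series <- as_series_strict(series)
  if (n_pre(series) < min_pre) {
    abort_scedab(sprintf("baseline phase needs at least %d sessions", min_pre), code_pre)
  }
  if (n_post(series) < min_post) {
    abort_scedab(sprintf("intervention phase needs at least %d sessions", min_post), code_post)
  }
  series
}

as_series_strict <- function(series) {
  if (!inherits(series, "two_phase_series")) {
    abort_scedab("expected a two_phase_series (see two_phase_series() or as_two_phase_series())",
                 "invalid-score")
  }
  series
}

#' Per-phase descriptive statistics
#'
#' Summarises each phase with the quantities behind the simplest visual aids:
#' range lines (minimum/maximum), central-tendency lines (mean and median),
#' and the standard deviation used by the two-standard-deviation band.
#'
#' @param series A [two_phase_series()].
#' @param sd_type `"sample"` (n − 1 denominator, the default) or
#'   `"population"` (n). Downstream SD bands are wider, hence more
#'   conservative, with the sample convention.
#' @return A tibble with one row per phase and columns `phase`, `n`,
#'   `minimum`, `maximum`, `mean`, `median`, `sd`, `sd_defined`. For a
#'   single-session phase the standard deviation is undefined; it is reported
#'   as 0 with `sd_defined = FALSE`.
#' @export
phase_descriptives <- function(series, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  series <- validate_series(series)
  series |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      n = dplyr::n(),
      minimum = min(.data$score),
      maximum = max(.data$score),
      mean = mean(.data$score),
      median = stats::median(.data$score),
      sd = phase_sd(.data$score, sd_type),
      sd_defined = dplyr::n() > 1L,
      .groups = "drop"
    )
}

phase_sd <- function(x, sd_type = "sample") {
  if (length(x) < 2) return(0)
  s <- stats::sd(x)
  if (identical(sd_type, "population")) s * sqrt((length(x) - 1) / length(x)) else s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
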