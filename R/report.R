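#' Full three-part analysis of an AB series
#'
#' Runs every analysis in the package on one two-phase series and assembles
#' the results into a single report covering the three complementary
#' assessments: visual (range lines, central tendency, two-SD band,
#' split-middle trend with projected stability envelope, immediacy),
#' quantitative (NAP and the SLC decomposition), and substantive (a clinical
#' cut-off check, when a cut-off is supplied). The report never aggregates
#' the components into a single verdict: when they disagree — which happens
#' with delayed effects or unstable baselines — the disagreement pattern is
#' flagged and adjudication is left to the analyst. Narrative labels speak of
#' behavioural change, not of intervention effects in causal terms: a
#' two-phase design alone cannot establish causality.
#'
#' @param series A [two_phase_series()] (or a long data frame accepted by
#'   [as_two_phase_series()]).
#' @param cutoff Optional clinical cut-off in score units (e.g., an ECBI
#'   Intensity T-score of 60); scores strictly on the improvement side of it
#'   are in the functional range.
#' @param final_k The cut-off check also asks whether the *last* `final_k`
#'   intervention sessions are all functional (default 3).
#' @param sd_k Two-SD-band multiplier (default 2).
#' @param envelope_fraction,stability_criterion Envelope half-width fraction
#'   and containment criterion, see [stability_envelope()].
#' @param immediacy_window Sessions on each side of the phase boundary for
#'   the immediacy contrast (default 3, clamped to the shorter phase length).
#' @param bands NAP interpretive bands, see [nap_bands()].
#' @param tie_tol NAP tie tolerance, see [pairwise_counts()].
#' @param scale_range Optional length-2 numeric giving the plausible
#'   measurement range; a projected envelope leaving it triggers a warning
#'   entry (trend projections into impossible values should not be read
#'   literally).
#' @param aim Improvement direction; only consulted when `series` is a plain
#'   data frame, otherwise the series' own aim is used.
#' @return An `ab_report` list with elements `series`, `descriptives`, `nap`,
#'   `slc`, `sd_band`, `envelope`, `immediacy`, `cutoff` (or NULL),
#'   `components` (per-component statements with the direction each
#'   suggests), `disagreement`, `warnings`, and `config`. Deterministic: the
#'   same series and configuration always produce the identical report.
#' @examples
#' s <- simulate_ab(simulation_spec(n_pre = 5, n_post = 10, level = 70,
#'                                  level_change = -15, phi = 0.3,
#'                                  noise_sd = 3, seed = 7))
#' rep <- analyze(s, cutoff = 60)
#' rep$components
#' @export
analyze <- function(series, cutoff = NULL, final_k = 3, sd_k = 2,
                    envelope_fraction = 0.25, stability_criterion = 0.80,
                    immediacy_window = 3, bands = nap_bands(), tie_tol = 0,
                    scale_range = NULL, aim = c("decrease", "increase")) {
  if (!inherits(series, "two_phase_series")) {
    series <- as_two_phase_series(series, aim = match.arg(aim))
  }
  series <- validate_series(series, min_pre = 2L, min_post = 2L)
  aim <- series_aim(series)
  window <- min(immediacy_window, n_pre(series), n_post(series))

  desc <- with_module("core", phase_descriptives(series))
  nap_res <- with_module("nonoverlap", nap(series, tie_tol = tie_tol, bands = bands))
  slc_res <- with_module("slc", slc(series))
  band <- with_module("visual_aids", sd_band(series, k = sd_k))
  env <- with_module("visual_aids",
                     stability_envelope(series, fraction = envelope_fraction,
                                        criterion = stability_criterion))
  imm <- with_module("visual_aids", immediacy(series, window = window))
  cut_res <- if (!is.null(cutoff)) {
    with_module("report", cutoff_assessment(series, cutoff, k = final_k))
  }

  warnings <- report_warnings(series, env, scale_range)
  components <- component_statements(nap_res, slc_res, band, env, imm, cut_res, aim)

  structure(
    list(
      series = list(label = series_label(series), n_pre = n_pre(series),
                    n_post = n_post(series), aim = aim,
                    scores = series$score),
      descriptives = desc,
      nap = nap_res,
      slc = slc_res,
      sd_band = band,
      envelope = env,
      immediacy = imm,
      cutoff = cut_res,
      components = components,
      disagreement = component_disagreement(components),
      warnings = warnings,
      config = list(cutoff = cutoff, final_k = final_k, sd_k = sd_k,
                    envelope_fraction = envelope_fraction,
                    stability_criterion = stability_criterion,
                    immediacy_window = window, tie_tol = tie_tol,
                    bands = as.list(bands),
                    scale_range = scale_range)
    ),
    class = "ab_report"
  )
}

with_module <- function(module, expr) {
  tryCatch(expr, scedab_error = function(e) {
    rlang::abort(sprintf("[%s] %s", module, conditionMessage(e)),
                 class = class(e), parent = e)
  })
}

report_warnings <- function(series, env, scale_range) {
  w <- character(0)
  if (n_pre(series) < 5) {
    w <- c(w, "short-baseline: fewer than 5 baseline sessions, below the usual design standard")
  }
  if (env$baseline_within_fraction < env$criterion) {
    w <- c(w, "unstable-baseline: baseline points escape their own split-middle envelope")
  }
  if (!is.null(scale_range)) {
    t_post <- n_pre(series) + seq_len(n_post(series))
    lim <- range(predict(env$trend, t_post) + c(-1, 1) * env$half_width)
    if (lim[1] < scale_range[1] || lim[2] > scale_range[2]) {
      w <- c(w, "projection-out-of-range: the projected envelope leaves the plausible measurement range; do not read the projection literally")
    }
  }
  w
}

component_statements <- function(nap_res, slc_res, band, env, imm, cut_res, aim) {
  sign_improves <- function(x) {
    if (x == 0) return(NA)
    if (aim == "decrease") x < 0 else x > 0
  }
  rows <- list(
    tibble::tibble(
      component = "nap",
      statement = sprintf("NAP %.2f%% (%s): %s the 50%% chance level",
                          nap_res$nap_percent, nap_res$category,
                          if (nap_res$nap > 0.5) "above" else if (nap_res$nap < 0.5) "below" else "at"),
      suggests_improvement = if (nap_res$nap == 0.5) NA else nap_res$nap > 0.5
    ),
    tibble::tibble(
      component = "slc_level",
      statement = sprintf("net level change %.4f score units", slc_res$level_change),
      suggests_improvement = sign_improves(slc_res$level_change)
    ),
    tibble::tibble(
      component = "slc_slope",
      statement = sprintf("slope change %.4f score units per session", slc_res$slope_change),
      suggests_improvement = sign_improves(slc_res$slope_change)
    ),
    tibble::tibble(
      component = "sd_band",
      statement = sprintf("%.0f%% of intervention points outside the %g-SD band (%s)",
                          100 * band$outside_fraction, band$k, band$direction),
      suggests_improvement = if (band$direction == "none" || band$direction == "mixed") NA
        else (band$direction == "below") == (aim == "decrease")
    ),
    tibble::tibble(
      component = "envelope",
      statement = sprintf("projected-trend containment %.0f%%: %s",
                          100 * env$post_within_fraction,
                          if (env$stable) "trend-stable" else paste0("points escape ", env$direction)),
      suggests_improvement = if (env$stable || env$direction == "mixed") NA
        else (env$direction == "below") == (aim == "decrease")
    ),
    tibble::tibble(
      component = "immediacy",
      statement = sprintf("boundary contrast %.4f (%s)", imm$change, imm$label),
      suggests_improvement = if (imm$label == "no change") NA else imm$label == "improvement"
    )
  )
  if (!is.null(cut_res)) {
    rows <- c(rows, list(tibble::tibble(
      component = "cutoff",
      statement = sprintf("%d/%d intervention sessions in the functional range; final %d all functional: %s",
                          length(cut_res$functional_sessions), cut_res$n_post,
                          cut_res$k, cut_res$final_k_functional),
      suggests_improvement = if (length(cut_res$functional_sessions) == 0) FALSE
        else cut_res$final_k_functional
    )))
  }
  dplyr::bind_rows(rows)
}

component_disagreement <- function(components) {
  s <- components$suggests_improvement
  s <- s[!is.na(s)]
  length(unique(s)) > 1
}

#' Clinical cut-off assessment
#'
#' Substantive check against an external threshold separating clinically
#' significant from functional scores (for instance an ECBI Intensity T-score
#' of 60). An intervention session is in the functional range when its score
#' is *strictly* on the improvement side of the cut-off — below it under
#' `aim = "decrease"`, above it under `aim = "increase"`; a score exactly at
#' the cut-off does not qualify. The check also reports whether the last `k`
#' intervention sessions are all functional, reading a maintained,
#' practically significant change at the end of the phase.
#'
#' @param series A [two_phase_series()].
#' @param cutoff Finite cut-off in score units.
#' @param k How many final sessions must all be functional (default 3).
#' @return A `cutoff_assessment` list: `cutoff`, `k`, `n_post`,
#'   `functional_sessions` (1-based indices within the intervention phase),
#'   `final_k_functional`.
#' @examples
#' s <- two_phase_series(c(70, 72), c(65, 58, 55), aim = "decrease")
#' cutoff_assessment(s, cutoff = 60, k = 2)
#' @export
cutoff_assessment <- function(series, cutoff, k = 3) {
  series <- validate_series(series)
  if (!is.numeric(cutoff) || !is.finite(cutoff)) {
    abort_scedab("cutoff must be a finite number", "invalid-score")
  }
  post <- post_scores(series)
  functional <- if (series_aim(series) == "decrease") post < cutoff else post > cutoff
  k_eff <- min(k, length(post))
  structure(
    list(cutoff = cutoff, k = as.integer(k_eff), n_post = length(post),
         functional_sessions = which(functional),
         final_k_functional = all(utils::tail(functional, k_eff))),
    class = "cutoff_assessment"
  )
}

#' @export
print.ab_report <- function(x, ...) {
  cat(sprintf("== AB-series analysis%s ==\n",
              if (is.null(x$series$label)) "" else paste0(": ", x$series$label)))
  cat(sprintf("%d baseline + %d intervention sessions, aim = %s\n\n",
              x$series$n_pre, x$series$n_post, x$series$aim))
  print(x$nap)
  cat("\n")
  print(x$slc)
  cat("\n")
  print(x$sd_band)
  cat("\n")
  print(x$envelope)
  cat(sprintf("\nImmediacy (window %d): %.4f (%s)\n",
              x$immediacy$window, x$immediacy$change, x$immediacy$label))
  if (!is.null(x$cutoff)) {
    cat(sprintf("Cut-off %.4g: sessions %s functional; final %d all functional: %s\n",
                x$cutoff$cutoff,
                if (length(x$cutoff$functional_sessions) == 0) "none"
                else paste(x$cutoff$functional_sessions, collapse = ","),
                x$cutoff$k, x$cutoff$final_k_functional))
  }
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  cat(sprintf("\nComponents %s\n",
              if (x$disagreement) "disagree; adjudication is left to the analyst:"
              else "agree:"))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  [%s] %s\n", x$components$component[i], x$components$statement[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ab_report <- function(x, ...) x$components

#' @exportS3Method generics::glance
glance.ab_report <- function(x, ...) {
  tibble::tibble(
    n_pre = x$series$n_pre, n_post = x$series$n_post, aim = x$series$aim,
    nap = x$nap$nap, nap_category = x$nap$category,
    baseline_trend = x$slc$baseline_trend,
    slope_change = x$slc$slope_change, level_change = x$slc$level_change,
    sd_band_outside_fraction = x$sd_band$outside_fraction,
    envelope_stable = x$envelope$stable,
    immediacy = x$immediacy$change,
    final_k_functional = if (is.null(x$cutoff)) NA else x$cutoff$final_k_functional,
    disagreement = x$disagreement,
    n_warnings = length(x$warnings)
  )
}

#' Serialise an analysis report as JSON
#'
#' Writes the report with a stable key order and fixed number formatting
#' (floats rounded to 4 decimals), so repeated runs on the same input produce
#' byte-identical files.
#'
#' @param report An [analyze()] report.
#' @param path Output path; when NULL the JSON text is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ab_report"))
  r4 <- function(x) round(x, 4)
  obj <- list(
    series = list(label = report$series$label, n_pre = report$series$n_pre,
                  n_post = report$series$n_post, aim = report$series$aim,
                  scores = r4(report$series$scores)),
    descriptives = dplyr::mutate(report$descriptives,
                                 dplyr::across(dplyr::where(is.numeric), r4)),
    nap = list(comparisons = report$nap$n_comparisons,
               improving = report$nap$n_improving,
               ties = report$nap$n_ties,
               deteriorating = report$nap$n_deteriorating,
               nap = r4(report$nap$nap),
               nap_percent = round(report$nap$nap_percent, 2),
               category = report$nap$category),
    slc = list(baseline_trend = r4(report$slc$baseline_trend),
               slope_change = r4(report$slc$slope_change),
               level_change = r4(report$slc$level_change),
               detrended = r4(report$slc$detrended$score),
               post_doubly_corrected = r4(report$slc$post_doubly_corrected)),
    sd_band = list(center = r4(report$sd_band$center), sd = r4(report$sd_band$sd),
                   k = report$sd_band$k, lower = r4(report$sd_band$lower),
                   upper = r4(report$sd_band$upper),
                   outside_post = report$sd_band$outside_post,
                   outside_fraction = r4(report$sd_band$outside_fraction),
                   direction = report$sd_band$direction),
    envelope = list(slope = r4(report$envelope$trend$slope),
                    intercept = r4(report$envelope$trend$intercept),
                    half_width = r4(report$envelope$half_width),
                    baseline_within_fraction = r4(report$envelope$baseline_within_fraction),
                    post_within_fraction = r4(report$envelope$post_within_fraction),
                    criterion = report$envelope$criterion,
                    stable = report$envelope$stable,
                    direction = report$envelope$direction),
    immediacy = list(window = report$immediacy$window,
                     change = r4(report$immediacy$change),
                     label = report$immediacy$label),
    cutoff = if (is.null(report$cutoff)) NULL else
      list(cutoff = report$cutoff$cutoff, k = report$cutoff$k,
           functional_sessions = report$cutoff$functional_sessions,
           final_k_functional = report$cutoff$final_k_functional),
    components = report$components,
    disagreement = report$disagreement,
    warnings = report$warnings,
    config = report$config
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
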