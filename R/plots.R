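base_series_plot <- function(series, cutoff = NULL, title = NULL) {
  boundary <- n_pre(series) + 0.5
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = .data$score)) +
    ggplot2::geom_vline(xintercept = boundary, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 2) +
    ggplot2::scale_colour_manual(values = c(pre = "#1b6ca8", post = "#c1403d")) +
    ggplot2::labs(x = "Session", y = "Score", title = title, colour = "Phase") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dotdash",
                                 colour = "darkorange")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.two_phase_series <- function(object, cutoff = NULL, ...) {
  base_series_plot(object, cutoff = cutoff, title = series_label(object))
}

#' Visual-aid panels
#'
#' One ggplot per visual aid, each overlaying the raw series with the
#' construction it illustrates: per-phase range and median lines
#' (`plot_range_median()`), the baseline two-SD band projected across the
#' intervention phase (`plot_sd_band()`), the split-middle baseline trend
#' with its projected stability envelope (`plot_envelope()`), and per-phase
#' ordinary least-squares trend lines (`plot_ols_trends()`).
#' `plot_visual_aids()` arranges all four in a 2-by-2 grid.
#'
#' @param series A [two_phase_series()].
#' @param cutoff Optional clinical cut-off drawn as a horizontal reference.
#' @param k,fraction Band and envelope parameters, as in [sd_band()] and
#'   [stability_envelope()].
#' @return A ggplot (or, for `plot_visual_aids()`, a patchwork of four).
#' @export
plot_range_median <- function(series, cutoff = NULL) {
  series <- validate_series(series)
  desc <- phase_descriptives(series)
  seg <- dplyr::mutate(
    desc,
    x = c(1, n_pre(series) + 1),
    xend = c(n_pre(series), n_pre(series) + n_post(series))
  )
  base_series_plot(series, cutoff, "Range and median lines") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$minimum, yend = .data$minimum),
                          inherit.aes = FALSE, linetype = "dotted") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$maximum, yend = .data$maximum),
                          inherit.aes = FALSE, linetype = "dotted") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$median, yend = .data$median),
                          inherit.aes = FALSE, linewidth = 0.8)
}

#' @rdname plot_range_median
#' @export
plot_sd_band <- function(series, k = 2, cutoff = NULL) {
  band <- sd_band(series, k = k)
  n <- n_pre(series) + n_post(series)
  base_series_plot(series, cutoff, sprintf("Baseline mean %s %g SD band", "±", k)) +
    ggplot2::annotate("rect", xmin = 1, xmax = n, ymin = band$lower,
                      ymax = band$upper, alpha = 0.12, fill = "#1b6ca8") +
    ggplot2::geom_hline(yintercept = band$center, linetype = "solid",
                        colour = "#1b6ca8") +
    ggplot2::geom_hline(yintercept = c(band$lower, band$upper),
                        linetype = "dashed", colour = "#1b6ca8")
}

#' @rdname plot_range_median
#' @export
plot_envelope <- function(series, fraction = 0.25, cutoff = NULL) {
  env <- stability_envelope(series, fraction = fraction)
  n <- n_pre(series) + n_post(series)
  t_grid <- seq(1, n, length.out = 50)
  ribbon <- tibble::tibble(time = t_grid,
                           fit = predict(env$trend, t_grid),
                           lo = .data$fit - env$half_width,
                           hi = .data$fit + env$half_width)
  base_series_plot(series, cutoff, "Split-middle trend and stability envelope") +
    ggplot2::geom_ribbon(data = ribbon,
                         ggplot2::aes(x = .data$time, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.12, fill = "#2a7d46") +
    ggplot2::geom_line(data = ribbon,
                       ggplot2::aes(x = .data$time, y = .data$fit),
                       inherit.aes = FALSE, colour = "#2a7d46")
}

#' @rdname plot_range_median
#' @export
plot_ols_trends <- function(series, cutoff = NULL) {
  series <- validate_series(series, min_pre = 2L, min_post = 2L)
  pre_fit <- ols_trend(pre_scores(series), offset = 0)
  post_fit <- ols_trend(post_scores(series), offset = n_pre(series))
  lines <- dplyr::bind_rows(
    tibble::tibble(time = seq_len(n_pre(series)),
                   fit = predict(pre_fit, .data$time), phase = "pre"),
    tibble::tibble(time = n_pre(series) + seq_len(n_post(series)),
                   fit = predict(post_fit, .data$time), phase = "post")
  )
  base_series_plot(series, cutoff, "Per-phase OLS trend lines") +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$time, y = .data$fit,
                                    group = .data$phase),
                       inherit.aes = FALSE, linewidth = 0.8, colour = "grey20")
}

#' @rdname plot_range_median
#' @export
plot_visual_aids <- function(series, cutoff = NULL, k = 2, fraction = 0.25) {
  patchwork::wrap_plots(
    plot_range_median(series, cutoff), plot_sd_band(series, k, cutoff),
    plot_envelope(series, fraction, cutoff), plot_ols_trends(series, cutoff),
    ncol = 2
  )
}

#' Write the report figures to disk
#'
#' Renders the four visual-aid panels and one combined figure with
#' deterministic filenames (`01_range_median`, `02_sd_band`, `03_envelope`,
#' `04_ols_trends`, `00_combined`, plus the format extension). The phase
#' boundary is drawn in every panel; the clinical cut-off is drawn only when
#' the report was configured with one.
#'
#' @param report An [analyze()] report.
#' @param series The analysed [two_phase_series()].
#' @param dir Output directory (created if missing).
#' @param format `"png"` or `"svg"`.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the written file paths.
#' @export
render_plots <- function(report, series, dir, format = c("png", "svg"),
                         width = 7, height = 5, dpi = 120) {
  format <- match.arg(format)
  stopifnot(inherits(report, "ab_report"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort_scedab(paste("cannot write to", dir), "io-error")
  }
  cutoff <- report$config$cutoff
  k <- report$config$sd_k
  fraction <- report$config$envelope_fraction
  panels <- list(
    "01_range_median" = plot_range_median(series, cutoff),
    "02_sd_band" = plot_sd_band(series, k, cutoff),
    "03_envelope" = plot_envelope(series, fraction, cutoff),
    "04_ols_trends" = plot_ols_trends(series, cutoff),
    "00_combined" = plot_visual_aids(series, cutoff, k, fraction)
  )
  paths <- character(0)
  for (nm in names(panels)) {
    path <- file.path(dir, paste0(nm, ".", format))
    is_combined <- nm == "00_combined"
    dev <- if (format == "svg") grDevices::svg else format
    ggplot2::ggsave(path, panels[[nm]], device = dev,
                    width = if (is_combined) 2 * width else width,
                    height = if (is_combined) 2 * height else height,
                    dpi = dpi)
    paths <- c(paths, path)
  }
  invisible(paths)
}
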