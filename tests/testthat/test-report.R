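fixture_series <- function() {
  # delayed-improvement pattern on a T-score-like scale
  two_phase_series(c(62, 58, 65, 60, 66),
                   c(64, 63, 65, 61, 60, 58, 57, 55, 54, 52),
                   aim = "decrease", label = "fixture")
}

test_that("cutoff assessment lists strictly-functional sessions", {
  s <- two_phase_series(c(70, 72), c(65, 58, 55), aim = "decrease")
  a <- cutoff_assessment(s, cutoff = 60, k = 2)
  expect_equal(a$functional_sessions, c(2L, 3L))
  expect_true(a$final_k_functional)

  none <- cutoff_assessment(two_phase_series(c(70, 72), c(65, 61, 63),
                                             aim = "decrease"), 60)
  expect_equal(length(none$functional_sessions), 0)
  expect_false(none$final_k_functional)

  # a score exactly at the cut-off is not functional
  at <- cutoff_assessment(two_phase_series(c(70, 72), c(60, 59),
                                           aim = "decrease"), 60, k = 2)
  expect_equal(at$functional_sessions, 2L)
  expect_false(at$final_k_functional)

  up <- cutoff_assessment(two_phase_series(c(1, 2), c(5, 7), aim = "increase"),
                          4, k = 2)
  expect_true(up$final_k_functional)
  expect_error(cutoff_assessment(s, NA_real_), class = "scedab_invalid-score")
})

test_that("analyze assembles every component and echoes its configuration", {
  rep <- analyze(fixture_series(), cutoff = 60)
  expect_s3_class(rep, "ab_report")
  expect_equal(rep$nap$n_comparisons, 50)
  expect_equal(rep$series$n_pre, 5)
  expect_equal(nrow(rep$descriptives), 2)
  expect_equal(rep$config$cutoff, 60)
  expect_setequal(
    c("nap", "slc_level", "slc_slope", "sd_band", "envelope", "immediacy",
      "cutoff"),
    rep$components$component
  )
  expect_type(rep$disagreement, "logical")

  no_cut <- analyze(fixture_series())
  expect_null(no_cut$cutoff)
  expect_false("cutoff" %in% no_cut$components$component)

  # long data frames are accepted directly
  df <- data.frame(Time = 1:6, Score = c(5, 6, 4, 1, 2, 1),
                   Phase = c(0, 0, 0, 1, 1, 1))
  expect_equal(analyze(df, aim = "decrease")$series$n_pre, 3)
})

test_that("report warnings follow their documented rules", {
  short <- analyze(two_phase_series(c(5, 6), c(1, 2, 1), aim = "decrease"))
  expect_true(any(grepl("short-baseline", short$warnings)))

  long_stable <- analyze(two_phase_series(c(5, 5, 6, 5, 6, 5),
                                          c(5, 5, 6, 5), aim = "decrease"))
  expect_false(any(grepl("short-baseline", long_stable$warnings)))
  expect_false(any(grepl("unstable-baseline", long_stable$warnings)))

  # an alternating, widely varying baseline escapes its own envelope
  unstable <- analyze(two_phase_series(c(1, 30, 2, 28, 2, 31),
                                       c(3, 4, 3, 2), aim = "decrease"))
  expect_true(any(grepl("unstable-baseline", unstable$warnings)))

  # steep downward trend projects the envelope below a 0-100 scale
  steep <- analyze(two_phase_series(c(90, 70, 50, 30), c(20, 15, 12, 9),
                                    aim = "decrease"), scale_range = c(0, 100))
  expect_true(any(grepl("projection-out-of-range", steep$warnings)))
})

test_that("module errors are propagated with the originating module named", {
  err <- tryCatch(analyze(fixture_series(), immediacy_window = 0),
                  error = function(e) e)
  expect_s3_class(err, "scedab_window-too-large")
  expect_match(conditionMessage(err), "\\[visual_aids\\]")
})

test_that("report JSON is deterministic and round-trips its key numbers", {
  rep <- analyze(fixture_series(), cutoff = 60)
  j1 <- write_report_json(rep)
  j2 <- write_report_json(analyze(fixture_series(), cutoff = 60))
  expect_identical(as.character(j1), as.character(j2))

  parsed <- jsonlite::fromJSON(j1)
  expect_equal(parsed$nap$nap_percent, round(rep$nap$nap_percent, 2))
  expect_equal(parsed$slc$baseline_trend, round(rep$slc$baseline_trend, 4))
  expect_equal(parsed$cutoff$cutoff, 60)
})

test_that("plot files are rendered with deterministic names", {
  dir <- withr::local_tempdir()
  s <- fixture_series()
  rep <- analyze(s, cutoff = 60)
  paths <- render_plots(rep, s, dir, format = "png")
  expect_length(paths, 5)  # 4 aid panels + 1 combined
  expect_true(all(file.exists(paths)))
  expect_equal(basename(paths)[1], "01_range_median.png")

  svg_paths <- render_plots(rep, s, file.path(dir, "svg"), format = "svg")
  xml <- xml2::read_xml(svg_paths[1])  # vector output parses as XML
  expect_equal(xml2::xml_name(xml), "svg")

  expect_error(render_plots(rep, s, "/proc/scedab-cannot-write-here"),
               class = "scedab_io-error")
})

test_that("autoplot and panel builders return ggplot objects", {
  s <- fixture_series()
  expect_s3_class(ggplot2::autoplot(s), "gg")
  expect_s3_class(plot_range_median(s), "gg")
  expect_s3_class(plot_sd_band(s), "gg")
  expect_s3_class(plot_envelope(s), "gg")
  expect_s3_class(plot_ols_trends(s), "gg")
  expect_s3_class(ggplot2::autoplot(slc(s)), "gg")
  expect_s3_class(plot_visual_aids(s, cutoff = 60), "patchwork")
})

test_that("tidy and glance methods return well-formed tibbles", {
  s <- fixture_series()
  rep <- analyze(s, cutoff = 60)
  expect_named(glance(nap(s)), c("nap", "nap_percent", "category"))
  expect_equal(nrow(tidy(slc(s))), 3)
  expect_equal(nrow(tidy(rep)), nrow(rep$components))
  g <- glance(rep)
  expect_equal(g$n_pre, 5)
  expect_s3_class(tidy(sd_band(s)), "tbl_df")
  expect_s3_class(tidy(stability_envelope(s)), "tbl_df")
  expect_s3_class(tidy(ols_trend(pre_scores(s))), "tbl_df")
})
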