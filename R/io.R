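#' Read and write two-phase series files
#'
#' The package supports two plain-text layouts plus a JSON serialization.
#'
#' * Long CSV: header `Time,Score,Phase`, one row per session, `Phase` a block
#'   of 0s (baseline) followed by a block of 1s (intervention), `Time`
#'   consecutive 1..n. This is the layout used by common single-case analysis
#'   scripts.
#' * Phases CSV: header `pre,post`, the two score columns padded with blanks
#'   to equal length when the phases differ in length.
#'
#' The time axis is validated on read but the internal representation derives
#' session times from row position, so a round trip reproduces the numeric
#' content exactly for decimal inputs.
#'
#' @param path File path.
#' @param aim Improvement direction, `"decrease"` or `"increase"`.
#' @param sep Field separator; `","` by default, `";"` tolerated.
#' @param label Optional series label.
#' @return `read_long_csv()` and `read_phases_csv()` return a
#'   [two_phase_series()]; the writers return `path` invisibly.
#' @export
read_long_csv <- function(path, aim = c("decrease", "increase"), sep = ",",
                          label = NULL) {
  aim <- match.arg(aim)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE),
    error = function(e) abort_scedab(paste0("could not parse ", path, ": ", conditionMessage(e)),
                                     "phase-empty")
  )
  as_two_phase_series(df, aim = aim, label = label %||% basename(path))
}

#' @rdname read_long_csv
#' @param series A [two_phase_series()].
#' @export
write_long_csv <- function(series, path, sep = ",") {
  series <- as_series_strict(series)
  df <- data.frame(Time = series$time,
                   Score = format_plain(series$score),
                   Phase = as.integer(series$phase == "post"))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_long_csv
#' @export
read_phases_csv <- function(path, aim = c("decrease", "increase"), sep = ",",
                            label = NULL) {
  aim <- match.arg(aim)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE,
                      na.strings = c("", "NA")),
    error = function(e) abort_scedab(paste0("could not parse ", path, ": ", conditionMessage(e)),
                                     "phase-empty")
  )
  nm <- tolower(names(df))
  if (!all(c("pre", "post") %in% nm)) {
    abort_scedab("phases CSV needs columns pre,post", "phase-empty")
  }
  pre <- df[[which(nm == "pre")[1]]]
  post <- df[[which(nm == "post")[1]]]
  two_phase_series(pre[!is.na(pre)], post[!is.na(post)], aim = aim,
                   label = label %||% basename(path))
}

#' @rdname read_long_csv
#' @export
write_phases_csv <- function(series, path, sep = ",") {
  series <- as_series_strict(series)
  pre <- pre_scores(series)
  post <- post_scores(series)
  n <- max(length(pre), length(post))
  pad <- function(x) c(format_plain(x), rep("", n - length(x)))
  df <- data.frame(pre = pad(pre), post = pad(post))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# plain decimal formatting (no exponent notation) so CSV round trips are
# bit-identical for decimal inputs
format_plain <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15),
         character(1))
}

#' @rdname read_long_csv
#' @export
series_to_json <- function(series, path = NULL) {
  series <- as_series_strict(series)
  obj <- list(
    label = series_label(series),
    aim = series_aim(series),
    pre_scores = pre_scores(series),
    post_scores = post_scores(series)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    invisible(path)
  } else {
    json
  }
}

#' @rdname read_long_csv
#' @param json JSON text or a path to a JSON file produced by
#'   `series_to_json()`.
#' @export
series_from_json <- function(json) {
  if (length(json) == 1 && !grepl("\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  obj <- jsonlite::fromJSON(json)
  two_phase_series(obj$pre_scores, obj$post_scores, aim = obj$aim,
                   label = obj$label)
}
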