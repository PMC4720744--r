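#' Pairwise phase comparisons behind NAP
#'
#' Compares every baseline score with every intervention score: with
#' `n_pre` baseline and `n_post` intervention sessions there are
#' `n_pre * n_post` ordered pairs. A pair is *improving* when the
#' intervention value improves the baseline value (is smaller under
#' `aim = "decrease"`, larger under `aim = "increase"`), a *tie* when the two
#' values are equal (exactly, or within `tie_tol`), and *deteriorating*
#' otherwise.
#'
#' @param series A [two_phase_series()].
#' @param tie_tol Absolute tolerance within which two scores count as tied.
#'   The default 0 demands exact equality; a small positive value suits
#'   instrument-rounded data.
#' @return A one-row tibble with columns `n_comparisons`, `n_improving`,
#'   `n_ties`, `n_deteriorating`. The three counts always sum to
#'   `n_comparisons`.
#' @examples
#' s <- two_phase_series(c(3, 1, 4), c(2, 5), aim = "decrease")
#' pairwise_counts(s)
#' @export
pairwise_counts <- function(series, tie_tol = 0) {
  series <- validate_series(series)
  pre <- pre_scores(series)
  post <- post_scores(series)
  # exhaustive enumeration of all ordered (pre, post) pairs
  d <- outer(pre, post, `-`)     # pre - post
  if (series_aim(series) == "increase") d <- -d
  ties <- sum(abs(d) <= tie_tol)
  improving <- sum(d > tie_tol)  # post improves pre
  tibble::tibble(
    n_comparisons = length(d),
    n_improving = improving,
    n_ties = ties,
    n_deteriorating = length(d) - improving - ties
  )
}

#' Non-overlap of All Pairs (NAP)
#'
#' NAP is the proportion of all ordered baseline-by-intervention score pairs
#' in which the intervention value improves the baseline value, with ties
#' counting as half an improvement:
#' `nap = (n_improving + 0.5 * n_ties) / (n_pre * n_post)`.
#' It is an ordinal measure, identical to the nonparametric probability of
#' superiority: the probability that a randomly chosen intervention
#' measurement improves a randomly chosen baseline measurement. Under a
#' no-change null its expectation is 0.5 (50%).
#'
#' @inheritParams pairwise_counts
#' @param bands Interpretive category boundaries, see [nap_bands()].
#' @return A `nap_result` object: a list with the pairwise counts, `nap`
#'   (proportion in `[0, 1]`), `nap_percent`, and the interpretive `category`.
#'   [generics::tidy()] returns it as a one-row tibble.
#' @examples
#' s <- two_phase_series(c(5, 5), c(1, 1), aim = "decrease")
#' nap(s)
#' @export
nap <- function(series, tie_tol = 0, bands = nap_bands()) {
  series <- validate_series(series)
  counts <- pairwise_counts(series, tie_tol = tie_tol)
  value <- (counts$n_improving + 0.5 * counts$n_ties) / counts$n_comparisons
  structure(
    list(
      n_comparisons = counts$n_comparisons,
      n_improving = counts$n_improving,
      n_ties = counts$n_ties,
      n_deteriorating = counts$n_deteriorating,
      nap = value,
      nap_percent = 100 * value,
      category = classify_nap(value, bands = bands),
      aim = series_aim(series)
    ),
    class = "nap_result"
  )
}

#' Interpretive bands for NAP
#'
#' Default effect-size categories for the NAP percentage, closed on the upper
#' end of each band: small 0--65%, medium 66--92%, large 93--100%. Only the
#' small band's upper edge (65%) is fixed by the interpretive convention this
#' package follows; all boundaries are configurable.
#'
#' @param upper Named numeric vector of band upper bounds on the proportion
#'   scale, increasing, last element 1.
#' @return A named numeric vector usable as the `bands` argument of [nap()]
#'   and [classify_nap()].
#' @export
nap_bands <- function(upper = c(small = 0.65, medium = 0.92, large = 1)) {
  if (is.null(names(upper)) || any(!nzchar(names(upper))) ||
      is.unsorted(upper, strictly = TRUE) || utils::tail(upper, 1) != 1 ||
      any(upper < 0) || any(upper > 1)) {
    abort_scedab("bands must be named, strictly increasing, within [0,1], ending at 1",
                 "invalid-bands")
  }
  upper
}

#' @rdname nap_bands
#' @param nap_value A NAP proportion in `[0, 1]`.
#' @param bands Band upper bounds as produced by [nap_bands()].
#' @export
classify_nap <- function(nap_value, bands = nap_bands()) {
  bands <- nap_bands(bands)
  if (!is.numeric(nap_value) || anyNA(nap_value) ||
      any(nap_value < 0 | nap_value > 1)) {
    abort_scedab("NAP must lie in [0, 1]", "invalid-bands")
  }
  # each band is closed on its upper end; first band starts at 0 inclusive
  idx <- vapply(nap_value, function(v) which(v <= bands)[1], integer(1))
  names(bands)[idx]
}

#' Build a series realising prescribed pairwise counts
#'
#' Constructs a two-phase series whose pairwise comparison decomposition has
#' exactly `n_improving` improving pairs and no ties, for fixtures and worked
#' examples (e.g., 5 baseline and 10 intervention sessions with 31 improving
#' pairs out of 50, giving NAP = 62%).
#'
#' The baseline scores are fixed at `base + 10, base + 20, ...`; each
#' intervention score is placed between two baseline values (or past the
#' extremes) so that it improves exactly the required number of baseline
#' scores. All values are distinct, so no pair is tied.
#'
#' @param n_pre,n_post Phase lengths.
#' @param n_improving Required number of improving pairs, between 0 and
#'   `n_pre * n_post`.
#' @inheritParams two_phase_series
#' @param base Offset added to all scores (keeps them in a plausible range).
#' @return A [two_phase_series()] with `pairwise_counts()` equal to
#'   `(n_improving, 0, n_pre * n_post - n_improving)`.
#' @examples
#' s <- series_from_pair_counts(5, 10, n_improving = 31, aim = "decrease")
#' nap(s)
#' @export
series_from_pair_counts <- function(n_pre, n_post, n_improving,
                                    aim = c("decrease", "increase"),
                                    base = 30) {
  aim <- match.arg(aim)
  if (n_improving < 0 || n_improving > n_pre * n_post) {
    abort_scedab("n_improving must lie in [0, n_pre * n_post]", "invalid-score")
  }
  # greedy: give each post point as many improved baseline points as remain
  per_post <- integer(n_post)
  left <- n_improving
  for (j in seq_len(n_post)) {
    per_post[j] <- min(left, n_pre)
    left <- left - per_post[j]
  }
  pre <- base + 10 * seq_len(n_pre)
  # a post score improving k baseline points sits just beyond the k-th most
  # extreme baseline value on the improving side; offsets avoid ties
  place <- function(k, j) {
    eps <- j / (n_post + 1)  # distinct within each slot
    if (aim == "decrease") base + 10 * (n_pre - k) + 5 + eps
    else base + 10 * k + 5 + eps
  }
  post <- vapply(seq_len(n_post), function(j) place(per_post[j], j), numeric(1))
  two_phase_series(pre, post, aim = aim)
}

#' @export
print.nap_result <- function(x, ...) {
  cat(sprintf(
    "NAP = %.2f%% (%s effect)\n%d comparisons: %d improving, %d tied, %d deteriorating (aim = %s)\n",
    x$nap_percent, x$category, x$n_comparisons, x$n_improving, x$n_ties,
    x$n_deteriorating, x$aim
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nap_result <- function(x, ...) {
  tibble::tibble(
    n_comparisons = x$n_comparisons,
    n_improving = x$n_improving,
    n_ties = x$n_ties,
    n_deteriorating = x$n_deteriorating,
    nap = x$nap,
    nap_percent = x$nap_percent,
    category = x$category
  )
}

#' @exportS3Method generics::glance
glance.nap_result <- function(x, ...) {
  tibble::tibble(nap = x$nap, nap_percent = x$nap_percent,
                 category = x$category)
}
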