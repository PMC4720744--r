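#' Specification of a synthetic AB series
#'
#' Bundles and validates the generative parameters for [simulate_ab()]. The
#' deterministic part mirrors the Slope-and-Level-Change decomposition —
#' baseline level and linear trend, plus an additive level change and an extra
#' per-session slope change in the intervention phase — so that the SLC
#' estimator recovers the generating triple exactly when `noise_sd = 0`. The
#' stochastic part is a zero-mean AR(1) process, the standard assumption for
#' serially dependent behavioural measurements from one individual.
#'
#' @param n_pre,n_post Phase lengths (at least 1 each).
#' @param level Baseline intercept at the first session, score units.
#' @param trend Baseline slope, score units per session.
#' @param level_change Additive shift applied to every intervention session.
#' @param slope_change Extra slope per intervention session (on top of the
#'   continued baseline trend).
#' @param phi AR(1) coefficient, strictly inside (−1, 1). Behavioural series
#'   typically show mild positive autocorrelation.
#' @param noise_sd Standard deviation of the AR(1) *innovations* (not of the
#'   marginal noise, which is `noise_sd / sqrt(1 - phi^2)`); 0 gives a
#'   noiseless series.
#' @param aim Improvement direction attached to the generated series.
#' @param seed Optional integer seed; equal specs with equal seeds yield
#'   bit-identical series.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_pre = 5, n_post = 10, level = 0, trend = 0,
                            level_change = 0, slope_change = 0, phi = 0,
                            noise_sd = 1, aim = c("decrease", "increase"),
                            seed = NULL) {
  aim <- match.arg(aim)
  bad <- function(ok, what) if (!ok) abort_scedab(paste("invalid spec:", what), "invalid-spec")
  bad(is.numeric(n_pre) && n_pre >= 1 && n_pre == round(n_pre), "n_pre must be a count >= 1")
  bad(is.numeric(n_post) && n_post >= 1 && n_post == round(n_post), "n_post must be a count >= 1")
  bad(is.numeric(phi) && is.finite(phi) && abs(phi) < 1, "|phi| must be < 1")
  bad(is.numeric(noise_sd) && is.finite(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  for (v in c(level, trend, level_change, slope_change)) {
    bad(is.numeric(v) && is.finite(v), "effect parameters must be finite")
  }
  structure(list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 level = level, trend = trend, level_change = level_change,
                 slope_change = slope_change, phi = phi, noise_sd = noise_sd,
                 aim = aim, seed = seed),
            class = "simulation_spec")
}

#' Simulate a two-phase AB series
#'
#' Generates scores `y[t] = mu[t] + e[t]` where the deterministic mean is
#' `mu[t] = level + trend * (t - 1)` during the baseline and
#' `mu[n_pre + j] = level + trend * (n_pre + j - 1) + level_change +
#' slope_change * (j - 1)` during the intervention, and `e[t]` is an AR(1)
#' noise process `e[t] = phi * e[t-1] + innovation` with normal innovations of
#' standard deviation `noise_sd`, started from 100 burn-in steps so the
#' process is effectively stationary at the first session.
#'
#' @param spec A [simulation_spec()], or arguments to build one passed via
#'   `...`.
#' @param ... Passed to [simulation_spec()] when `spec` is missing.
#' @return A [two_phase_series()].
#' @examples
#' simulate_ab(simulation_spec(n_pre = 3, n_post = 3, trend = 2,
#'                             level_change = 4, slope_change = -2,
#'                             noise_sd = 0))
#' @export
simulate_ab <- function(spec = simulation_spec(...), ...) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_pre + spec$n_post
  t_all <- seq_len(n)
  mu <- spec$level + spec$trend * (t_all - 1)
  j <- seq_len(spec$n_post)
  mu[spec$n_pre + j] <- mu[spec$n_pre + j] + spec$level_change +
    spec$slope_change * (j - 1)
  e <- ar1_noise(n, spec$phi, spec$noise_sd)
  y <- mu + e
  two_phase_series(y[seq_len(spec$n_pre)], y[spec$n_pre + j], aim = spec$aim,
                   label = "simulated AB series")
}

ar1_noise <- function(n, phi, noise_sd, burn_in = 100) {
  if (noise_sd == 0) return(rep(0, n))
  innov <- stats::rnorm(burn_in + n, sd = noise_sd)
  e <- stats::filter(innov, phi, method = "recursive")
  as.numeric(e[burn_in + seq_len(n)])
}

#' Monte Carlo chance level of NAP
#'
#' Simulates `reps` no-effect series (no trend, no level or slope change,
#' i.i.d. normal scores) and returns the Monte Carlo mean of NAP with its
#' standard error. Under this null every ordering of the pooled scores is
#' equally likely, so the expected NAP is 0.5 — the 50% chance level against
#' which an observed NAP is read.
#'
#' @param n_pre,n_post Phase lengths per replicate.
#' @param reps Number of replicates (at least 1).
#' @param seed Integer seed for reproducibility.
#' @param aim Improvement direction used in each NAP computation (the null
#'   mean is 0.5 either way).
#' @return A one-row tibble: `reps`, `mean_nap`, `se` (NA with a flag when
#'   `reps = 1`), `mean_nap_percent`.
#' @export
null_nap_calibration <- function(n_pre = 5, n_post = 10, reps = 1000,
                                 seed = NULL,
                                 aim = c("decrease", "increase")) {
  aim <- match.arg(aim)
  if (reps < 1) abort_scedab("reps must be >= 1", "invalid-spec")
  if (!is.null(seed)) set.seed(seed)
  spec <- simulation_spec(n_pre = n_pre, n_post = n_post, noise_sd = 1,
                          aim = aim)
  vals <- vapply(seq_len(reps), function(i) nap(simulate_ab(spec))$nap,
                 numeric(1))
  tibble::tibble(
    reps = as.integer(reps),
    mean_nap = mean(vals),
    se = if (reps > 1) stats::sd(vals) / sqrt(reps) else NA_real_,
    se_defined = reps > 1,
    mean_nap_percent = 100 * mean(vals)
  )
}

#' Monte Carlo exceedance of the two-standard-deviation band
#'
#' Simulates no-change series with i.i.d. normal scores in both phases, fits
#' the `k`-SD band to each baseline, and returns the long-run fraction of
#' intervention points falling strictly outside the projected band. With the
#' band estimated from a long stable baseline this fraction approaches the
#' normal-theory exceedance (about 4.6% for `k = 2`), the "fewer than 5%"
#' reading of the band; with short baselines the estimated band is too narrow
#' and the fraction is substantially larger (see the methods vignette).
#'
#' @param n_pre Baseline length per replicate. The default 500 probes the
#'   long-baseline regime in which the normal-theory expectation applies.
#' @param n_post Intervention length per replicate.
#' @param reps Number of simulated series.
#' @param k Band half-width in SDs.
#' @param seed Integer seed.
#' @return A one-row tibble: `reps`, `n_pre`, `n_post`, `k`,
#'   `outside_fraction` (pooled over all replicates and intervention points),
#'   `se`.
#' @export
sd_band_null_calibration <- function(n_pre = 500, n_post = 10, reps = 1000,
                                     k = 2, seed = NULL) {
  if (reps < 1) abort_scedab("reps must be >= 1", "invalid-spec")
  if (!is.null(seed)) set.seed(seed)
  spec <- simulation_spec(n_pre = n_pre, n_post = n_post, noise_sd = 1)
  outside <- vapply(seq_len(reps), function(i) {
    length(sd_band(simulate_ab(spec), k = k)$outside_post)
  }, numeric(1))
  total <- reps * n_post
  frac <- sum(outside) / total
  tibble::tibble(
    reps = as.integer(reps), n_pre = as.integer(n_pre),
    n_post = as.integer(n_post), k = k,
    outside_fraction = frac,
    se = sqrt(frac * (1 - frac) / total)
  )
}
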