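# fixtures built in code; no stored data files

random_series <- function(n_pre = NULL, n_post = NULL, ties = FALSE,
                          aim = "decrease") {
  n_pre <- n_pre %||% sample(2:12, 1)
  n_post <- n_post %||% sample(2:12, 1)
  draw <- function(n) {
    if (ties) sample(0:10, n, replace = TRUE) else rnorm(n)
  }
  two_phase_series(draw(n_pre), draw(n_post), aim = aim)
}

# independent rank-based probability of superiority (midrank ties):
# P(pre > post) from the rank-sum statistic, the Mann-Whitney route
rank_prob_superiority <- function(pre, post, aim = "decrease") {
  r <- rank(c(pre, post))
  n1 <- length(pre)
  n2 <- length(post)
  if (aim == "decrease") {
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2    # #(pre > post) + 0.5 ties
  } else {
    u <- sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2  # #(post > pre) + 0.5 ties
  }
  u / (n1 * n2)
}

linear_series <- function(n_pre, n_post, slope, intercept, aim = "decrease") {
  t <- seq_len(n_pre + n_post)
  y <- intercept + slope * t
  two_phase_series(y[seq_len(n_pre)], y[-seq_len(n_pre)], aim = aim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
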