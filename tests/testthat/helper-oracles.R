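# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with the plainest possible R code so they stay
# independent of the package's implementation paths.

# Exhaustive O(N^2) ordered-pair template scan for sample entropy.
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1
      }
    }
  }
  list(A = A, B = B)
}

oracle_sampen <- function(x, m = 2, r_frac = 0.2, r_abs = NULL) {
  if (is.null(r_abs)) r_abs <- r_frac * sd(x)
  cnt <- oracle_sampen_counts(x, m, r_abs)
  if (cnt$A == 0 || cnt$B == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

# From-scratch covariance/SD Pearson correlation.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Mixed test-series generator: white noise, AR(1), noisy periodic.
random_series <- function(n, kind = c("white", "ar", "periodic")) {
  kind <- match.arg(kind)
  switch(kind,
    white = rnorm(n),
    ar = as.numeric(stats::arima.sim(list(ar = runif(1, 0.3, 0.9)), n)),
    periodic = sin(2 * pi * seq_len(n) / sample(3:12, 1)) +
      rnorm(n, sd = runif(1, 0.05, 0.4)))
}

# Small in-memory recording with distinguishable integer-valued channels.
toy_recording <- function(n = 2000, fs = 500, labels = ectmse:::MONTAGE) {
  data <- t(sapply(seq_along(labels), function(k) {
    round(10 * sin(2 * pi * 7 * seq_len(n) / fs + k) + k)
  }))
  recording(data, labels, fs, session_id = "toy")
}

# Tiny-but-complete generator configuration for pipeline-level tests:
# 4 s segments (two 2 s FFT epochs), one session per condition.
tiny_config <- function(seed = 7L) {
  generator_config(seed = seed,
                   n_sessions = c(pre_ect = 1L, during_ect = 1L,
                                  after_ect = 1L, lorazepam = 1L),
                   segment_s = 4)
}
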