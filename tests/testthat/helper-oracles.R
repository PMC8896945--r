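# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Raw periodogram ordinates (no taper), frequencies in Hz.
periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  k <- 0:(floor(n / 2))
  data.frame(freq = k * fs / n, power = p[k + 1])
}

# Dense Toeplitz solve of the Yule-Walker system: the brute-force
# counterpart of the Levinson-Durbin recursion.
dense_yule_walker <- function(r, p) {
  phi <- solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
  sigma2 <- r[1] - sum(phi * r[2:(p + 1)])
  list(phi = as.numeric(phi), sigma2 = sigma2)
}

# A positive-definite autocorrelation sequence: the biased sample ACF of a
# random series is positive semidefinite; random data make it strictly
# definite almost surely.
random_pd_acf <- function(max_lag, n = 200) {
  x <- stats::rnorm(n)
  autocorrelation(x, max_lag)
}

# Random-search oracle with the same evaluation budget as a CSA run.
random_search_best <- function(fn, d, lower, upper, n_evals, seed) {
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_evals)) {
    best <- min(best, fn(stats::runif(d, lower, upper)))
  }
  best
}

# Tiny single-subject trial set generated straight from templates.
make_subject_features <- function(trials_per_task, seed, mode = "psd",
                                  config = synth_config(seed = seed)) {
  rows <- list()
  feats <- list()
  k <- 0
  for (task in c("FORWARD", "RIGHT", "LEFT", "STOP")) {
    for (tr in seq_len(trials_per_task)) {
      k <- k + 1
      trial <- generate_trial(task, config, "S1", tr)
      feats[[k]] <- extract_features(notch_filter(trial), mode = mode)
      rows[[k]] <- task
    }
  }
  list(x = do.call(rbind, feats), task = unlist(rows))
}
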