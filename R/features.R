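# Yule-Walker autoregressive feature extraction.
#
# A trial is reduced to 22 numbers: the two channels' biased
# autocorrelation sequences are averaged, an order-21 AR model is fitted by
# the Levinson-Durbin recursion on the Yule-Walker (Toeplitz) system, and
# the features are either the model's parametric power spectral density on
# a 22-point frequency grid spanning [0, fs/2] (default) or the raw
# coefficients plus log noise variance.

#' Sample autocorrelation sequence
#'
#' Mean-removed autocovariances `gamma_0 .. gamma_max_lag`. The biased
#' estimator divides every lag by `N`, which guarantees a positive
#' semidefinite sequence (the standard Yule-Walker choice); the unbiased
#' estimator divides by `N - m`. For real signals `gamma_{-m} = gamma_m`.
#'
#' @param x Numeric vector of samples.
#' @param max_lag Largest lag to compute.
#' @param estimator `"biased"` (default) or `"unbiased"`.
#' @param demean Subtract the sample mean first (default `TRUE`).
#' @return Numeric vector of length `max_lag + 1`; element 1 is lag 0
#'   (the biased sample variance when demeaned).
#' @examples
#' autocorrelation(c(1, -1, 1, -1), 1)  # gamma_0 = 1, gamma_1 = -0.75
#' @export
autocorrelation <- function(x, max_lag, estimator = c("biased", "unbiased"),
                            demean = TRUE) {
  estimator <- match.arg(estimator)
  if (!all(is.finite(x))) stopf("autocorrelation: non-finite samples")
  n <- length(x)
  if (max_lag >= n) {
    stopf("autocorrelation: max_lag (%d) must be smaller than the series length (%d)",
          max_lag, n)
  }
  g <- as.numeric(stats::acf(x, lag.max = max_lag, type = "covariance",
                             demean = demean, plot = FALSE)$acf)
  if (estimator == "unbiased") g <- g * n / (n - 0:max_lag)
  g
}

#' Fit an AR model by solving the Yule-Walker equations
#'
#' Solves the order-`p` Toeplitz system relating the AR coefficients to the
#' autocorrelation sequence, via the Levinson-Durbin recursion (O(p^2));
#' the driving-noise variance is the final prediction-error energy,
#' `gamma_0 - sum_k phi_k gamma_k`.
#'
#' @param acf_values Autocorrelations `gamma_0 .. gamma_p` (at least
#'   `order + 1` values), e.g. from [autocorrelation()].
#' @param order AR order `p >= 1`.
#' @return An `ar_model` with `coefficients` (phi) and `noise_variance`.
#' @examples
#' # true ACF of AR(1), phi = 0.6, sigma^2 = 1
#' g <- 0.6^(0:3) / (1 - 0.36)
#' solve_yule_walker(g, 1)
#' @export
solve_yule_walker <- function(acf_values, order) {
  stopifnot(order >= 1)
  if (length(acf_values) < order + 1) {
    stopf("solve_yule_walker: need %d autocorrelation values, got %d",
          order + 1, length(acf_values))
  }
  r <- as.numeric(acf_values)
  if (!all(is.finite(r))) stopf("solve_yule_walker: non-finite autocorrelations")
  if (r[1] <= 0) {
    stopf("solve_yule_walker: gamma_0 = %g is not positive (constant or empty input?)", r[1])
  }
  a <- numeric(0)
  err <- r[1]
  for (k in seq_len(order)) {
    if (err <= 0) {
      stopf("solve_yule_walker: prediction-error energy vanished at recursion step %d (autocorrelation sequence not positive definite)", k)
    }
    refl <- if (k == 1) r[2] / err else (r[k + 1] - sum(a * r[k:2])) / err
    if (!is.finite(refl) || abs(refl) >= 1) {
      stopf("solve_yule_walker: reflection coefficient %.4g out of (-1, 1) at recursion step %d (autocorrelation sequence not positive definite)", refl, k)
    }
    a <- c(a - refl * rev(a), refl)
    err <- err * (1 - refl^2)
  }
  new_ar_model(a, err)
}

#' Parametric power spectral density of an AR model
#'
#' One-sided PSD of the fitted process on `[0, fs/2]`:
#' `S(f) = c(f) * sigma^2 / (fs * |1 - sum_k phi_k exp(-i 2 pi k f / fs)|^2)`
#' with `c(f) = 2` except at 0 and Nyquist where `c = 1`, so that the
#' trapezoid integral of `S` over `[0, fs/2]` recovers the process
#' variance.
#'
#' @param model A stationary `ar_model`.
#' @param n_freqs Number of equispaced frequencies on `[0, fs/2]`
#'   (ignored when `freqs` is given).
#' @param fs Sampling rate in Hz.
#' @param freqs Optional explicit frequency grid in Hz.
#' @return Data frame with columns `freq` and `psd` (all `psd >= 0`).
#' @export
yule_walker_psd <- function(model, n_freqs = 22, fs = 200, freqs = NULL) {
  stopifnot(inherits(model, "ar_model"))
  if (!ar_is_stationary(model)) {
    stopf("yule_walker_psd: model is non-stationary")
  }
  if (is.null(freqs)) {
    stopifnot(n_freqs >= 2)
    freqs <- seq(0, fs / 2, length.out = n_freqs)
  }
  k <- seq_len(model$order)
  psd <- vapply(freqs, function(f) {
    denom <- if (model$order == 0) 1 else
      Mod(1 - sum(model$coefficients * exp(-1i * 2 * pi * k * f / fs)))^2
    scale <- if (isTRUE(all.equal(f, 0)) || isTRUE(all.equal(f, fs / 2))) 1 else 2
    scale * model$noise_variance / (fs * denom)
  }, numeric(1))
  data.frame(freq = freqs, psd = psd)
}

#' Extract the 22-dimensional feature vector of a trial
#'
#' The active channels' biased autocorrelation sequences are averaged
#' (`channels = "average"`, default) and an order-`order` AR model is
#' fitted by [solve_yule_walker()]. In `"psd"` mode (default) the features
#' are the model's Yule-Walker PSD sampled at `n_features` equispaced
#' frequencies on `[0, fs/2]`; in `"ar"` mode they are
#' `[phi_1 .. phi_order, log sigma^2]` (requiring
#' `n_features == order + 1`). With `channels = "concatenate"` each channel
#' is fitted separately and the per-channel features concatenated.
#'
#' @param trial An `eeg_trial` (preprocessed) or a numeric matrix with one
#'   column per channel.
#' @param order AR model order.
#' @param mode `"psd"` or `"ar"`.
#' @param n_features Length of the emitted vector per channel group.
#' @param channels `"average"` or `"concatenate"`.
#' @param fs Sampling rate (taken from the trial when available).
#' @return Numeric feature vector (length `n_features`, or
#'   `n_channels * n_features` when concatenating), all finite.
#' @export
extract_features <- function(trial, order = 21, mode = c("psd", "ar"),
                             n_features = 22,
                             channels = c("average", "concatenate"),
                             fs = NULL) {
  mode <- match.arg(mode)
  channels <- match.arg(channels)
  if (inherits(trial, "eeg_trial")) {
    samples <- trial$samples
    fs <- trial$fs
  } else {
    samples <- as.matrix(trial)
    if (is.null(fs)) fs <- 200
  }
  n <- nrow(samples)
  if (order >= n) stopf("extract_features: order %d >= trial length %d", order, n)
  if (mode == "ar" && n_features != order + 1) {
    stopf("extract_features: 'ar' mode emits order + 1 = %d features, not %d",
          order + 1, n_features)
  }
  if (any(apply(samples, 2, stats::sd) == 0)) {
    stopf("extract_features: constant channel (zero variance)")
  }
  feat_of <- function(acfseq) {
    model <- solve_yule_walker(acfseq, order)
    if (mode == "ar") {
      c(model$coefficients, log(model$noise_variance))
    } else {
      yule_walker_psd(model, n_freqs = n_features, fs = fs)$psd
    }
  }
  acfs <- apply(samples, 2, autocorrelation, max_lag = order)
  out <- if (channels == "average") {
    feat_of(rowMeans(acfs))
  } else {
    as.numeric(apply(acfs, 2, feat_of))
  }
  if (!all(is.finite(out))) stopf("extract_features: non-finite feature values")
  out
}

#' Feature matrix of a dataset
#'
#' Applies [extract_features()] to every trial and returns one row per
#' trial with feature columns `f01, f02, ...` plus provenance labels.
#'
#' @param dataset An `eeg_dataset` (typically after [notch_filter()]).
#' @inheritParams extract_features
#' @return Data frame: `subject`, `age_group`, `task`, `trial_index`,
#'   then the feature columns.
#' @export
extract_feature_matrix <- function(dataset, order = 21, mode = c("psd", "ar"),
                                   n_features = 22,
                                   channels = c("average", "concatenate")) {
  mode <- match.arg(mode)
  channels <- match.arg(channels)
  feats <- t(vapply(dataset$trials, extract_features,
                    numeric(if (channels == "average") n_features
                            else n_features * ncol(dataset$trials[[1]]$samples)),
                    order = order, mode = mode, n_features = n_features,
                    channels = channels))
  colnames(feats) <- sprintf("f%02d", seq_len(ncol(feats)))
  meta <- do.call(rbind, lapply(dataset$trials, function(tr) {
    data.frame(subject = tr$subject_id, age_group = tr$age_group,
               task = tr$task, trial_index = tr$trial_index,
               stringsAsFactors = FALSE)
  }))
  cbind(meta, as.data.frame(feats))
}

#' @noRd
feature_columns <- function(df) grep("^f[0-9]+$", names(df), value = TRUE)
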