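# Power-line interference removal.
#
# A second-order constrained IIR notch (zeros on the unit circle at the
# mains frequency, poles pulled inside at a radius set by the quality
# factor) applied forward-backward so the net phase response is zero. The
# ends are extended by point reflection over one filter-settling length
# before filtering to limit edge transients.

#' Specification of the mains notch filter
#'
#' @param frequency Notch centre frequency in Hz (the mains line).
#' @param q Quality factor: `frequency / bandwidth` of the -3 dB notch.
#'   Larger values give a narrower notch.
#' @param fs Sampling rate in Hz.
#' @return An object of class `notch_spec`.
#' @export
notch_spec <- function(frequency = 50, q = 30, fs = 200) {
  stopifnot(q > 0, fs > 0)
  if (!(frequency > 0 && frequency < fs / 2)) {
    stopf("notch frequency %g Hz must lie in (0, fs/2) = (0, %g) Hz",
          frequency, fs / 2)
  }
  structure(list(frequency = frequency, q = q, fs = fs), class = "notch_spec")
}

#' Biquad coefficients of the notch filter
#'
#' Zeros at `exp(+-i w0)` (exact null at the notch frequency), poles at
#' radius `1 - bw/2` with `bw = w0 / q`, and gain normalised to 1 at DC.
#'
#' @param spec A [notch_spec()].
#' @return List with numerator `b` and denominator `a` (both length 3,
#'   `a[1] == 1`).
#' @export
notch_coefficients <- function(spec) {
  w0 <- 2 * pi * spec$frequency / spec$fs
  r <- 1 - (w0 / spec$q) / 2
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b)  # unit gain in the passband (evaluated at DC)
  list(b = b, a = a)
}

#' Frequency response of the notch filter
#'
#' @param spec A [notch_spec()].
#' @param freqs Frequencies in Hz at which to evaluate.
#' @param passes Number of filtering passes (2 for the forward-backward
#'   application used by [notch_filter()]).
#' @return Magnitude response (per pass raised to `passes`).
#' @export
notch_response <- function(spec, freqs, passes = 2) {
  co <- notch_coefficients(spec)
  sapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / spec$fs * (0:2))
    (Mod(sum(co$b * z)) / Mod(sum(co$a * z)))^passes
  })
}

#' @noRd
iir_pass <- function(x, b, a) {
  # Direct-form I: FIR stage then the recursive stage. stats::filter's
  # convolution pass leaves NA for the first taps, so prepend zeros.
  nb <- length(b)
  fir <- as.numeric(stats::filter(c(rep(0, nb - 1), x), b, sides = 1))[-seq_len(nb - 1)]
  as.numeric(stats::filter(fir, -a[-1], method = "recursive"))
}

#' Remove mains interference from a trial
#'
#' Applies the notch forward and backward (zero net phase). Ends are
#' extended by point reflection over three pole time constants before
#' filtering, then trimmed. Note that a narrow notch cannot annihilate a
#' finite-length sinusoid entirely: the segment boundaries leak energy just
#' outside the notch band, so a short residual transient remains near the
#' edges even though the filter's response at the notch frequency is
#' exactly zero.
#'
#' @param x An `eeg_trial`, an `eeg_dataset`, or a numeric vector.
#' @param spec A [notch_spec()]; its `fs` must match the trial's.
#' @return Same type as `x`, filtered per channel.
#' @export
notch_filter <- function(x, spec = notch_spec()) {
  UseMethod("notch_filter")
}

#' @export
notch_filter.default <- function(x, spec = notch_spec()) {
  stopifnot(is.numeric(x))
  if (!all(is.finite(x))) stopf("notch_filter: input contains non-finite samples")
  n <- length(x)
  if (n < 4) stopf("notch_filter: input too short (%d samples)", n)
  co <- notch_coefficients(spec)
  w0 <- 2 * pi * spec$frequency / spec$fs
  r <- 1 - (w0 / spec$q) / 2
  pad <- min(n - 1, 3 * ceiling(1 / (1 - r)))  # ~3 settling time constants
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_pass(xp, co$b, co$a)
  y <- rev(iir_pass(rev(y), co$b, co$a))
  y[(pad + 1):(pad + n)]
}

#' @export
notch_filter.eeg_trial <- function(x, spec = notch_spec(fs = x$fs)) {
  if (!isTRUE(all.equal(x$fs, spec$fs))) {
    stopf("sampling-rate mismatch: trial %g Hz vs filter %g Hz", x$fs, spec$fs)
  }
  x$samples <- apply(x$samples, 2, notch_filter.default, spec = spec)
  x
}

#' @export
notch_filter.eeg_dataset <- function(x, spec = notch_spec(fs = x$config$fs)) {
  x$trials <- lapply(x$trials, notch_filter, spec = spec)
  x
}
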