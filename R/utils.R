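# Internal helpers shared across modules.

TASKS <- c("FORWARD", "RIGHT", "LEFT", "STOP")

#' @noRd
fnv1a32 <- function(s) {
  # 32-bit FNV-1a over the UTF-8 bytes of a string, done in double arithmetic
  # (exact below 2^53). Used to derive per-trial RNG substreams and to stamp
  # output files with a configuration fingerprint; not cryptographic.
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' @noRd
bitwXor_dbl <- function(a, b) {
  # bitwXor() works on 32-bit signed ints; keep everything in [0, 2^32).
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Derive a reproducible 31-bit seed from a base seed and a string tag
#' @noRd
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "|")
  as.integer(fnv1a32(tag) %% 2147483647) + 1L
}

#' @noRd
config_fingerprint <- function(x) {
  h <- fnv1a32(yaml::as.yaml(x))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @noRd
round_half_up <- function(x, digits = 2) {
  # The reports quote percentages like 94.00; round half away from zero so
  # printed values match conventional table rounding rather than banker's.
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)
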