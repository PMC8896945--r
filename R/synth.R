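# Synthetic EEG generator.
#
# Each mental task is tied to a stationary AR template; a trial is the
# template-filtered white noise plus 50 Hz line interference and broadband
# measurement noise, cut to 5 s at 200 Hz after a burn-in. The protocol
# dimensions (2 x 10 subjects, 4 tasks, 10 trials/task, 1000 samples) mirror
# the acquisition design the classifier was developed for.

#' Build an autoregressive task template from spectral peak positions
#'
#' Constructs a stationary AR model whose power spectral density peaks at the
#' requested frequencies, by placing one conjugate pole pair per entry of
#' `peak_freqs` at radius `radii` inside the unit circle. The sign convention
#' throughout the package is `x_t = sum_k phi_k x_{t-k} + e_t`.
#'
#' @param peak_freqs Peak frequencies in Hz (one pole pair each).
#' @param radii Pole radii in (0, 1), recycled to `length(peak_freqs)`;
#'   closer to 1 gives a sharper resonance.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Standard deviation of the driving white noise.
#' @return An object of class `ar_model` (fields `order`, `coefficients`,
#'   `noise_variance`).
#' @examples
#' tpl <- ar_template(10, radii = 0.95)
#' tpl$coefficients
#' @export
ar_template <- function(peak_freqs, radii = 0.95, fs = 200, noise_sd = 1) {
  stopifnot(length(peak_freqs) >= 1, all(peak_freqs > 0), all(peak_freqs < fs / 2))
  radii <- rep_len(radii, length(peak_freqs))
  if (any(radii <= 0) || any(radii >= 1)) {
    stopf("pole radii must lie strictly inside (0, 1); got %s",
          paste(radii, collapse = ", "))
  }
  a <- 1 + 0i
  for (k in seq_along(peak_freqs)) {
    th <- 2 * pi * peak_freqs[k] / fs
    for (p in complex(modulus = radii[k], argument = c(th, -th))) {
      a <- c(a, 0) - c(0, a * p)  # multiply characteristic polynomial by (1 - p z^-1)
    }
  }
  new_ar_model(-Re(a[-1]), noise_sd^2)
}

#' @noRd
new_ar_model <- function(phi, sigma2) {
  structure(list(order = length(phi),
                 coefficients = as.numeric(phi),
                 noise_variance = as.numeric(sigma2)),
            class = "ar_model")
}

#' Test stationarity of an AR model
#'
#' An AR model under the convention `x_t = sum_k phi_k x_{t-k} + e_t` is
#' stationary iff all roots of `1 - sum_k phi_k z^-k` lie inside the unit
#' circle, equivalently all roots of `1 - phi_1 z - ... - phi_p z^p` lie
#' outside it.
#'
#' @param model An `ar_model`.
#' @return `TRUE` or `FALSE`.
#' @export
ar_is_stationary <- function(model) {
  if (model$order == 0) return(TRUE)
  roots <- polyroot(c(1, -model$coefficients))
  all(Mod(roots) > 1 + 1e-10)
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("AR(%d) model, noise variance %.4g\n", x$order, x$noise_variance))
  if (x$order > 0) cat("  phi:", paste(signif(x$coefficients, 4), collapse = " "), "\n")
  invisible(x)
}

#' Default task templates
#'
#' Four AR(4) templates with dominant spectral peaks at 6, 10, 14 and 18 Hz,
#' inside the EEG band and well away from the 50 Hz mains line. Each template
#' stacks two conjugate pole pairs at the task frequency (radii 0.95 and
#' 0.75): a sharp resonance over a broader shoulder, so the four tasks carry
#' clearly distinct spectral signatures.
#'
#' @param peak_freqs Peak frequency per task, named or in task order
#'   (FORWARD, RIGHT, LEFT, STOP).
#' @param radii Two pole radii shared by all tasks.
#' @param fs Sampling rate in Hz.
#' @return Named list of `ar_model` templates.
#' @export
default_task_templates <- function(peak_freqs = c(FORWARD = 6, RIGHT = 10,
                                                  LEFT = 14, STOP = 18),
                                   radii = c(0.95, 0.75), fs = 200) {
  if (is.null(names(peak_freqs))) names(peak_freqs) <- TASKS
  stopifnot(setequal(names(peak_freqs), TASKS))
  lapply(peak_freqs[TASKS], function(f) ar_template(c(f, f), radii, fs = fs))
}

#' Configuration of the synthetic EEG generator
#'
#' @param n_subjects_per_group Subjects per age group; the generator emits
#'   two groups, `young` (ages 20-28, subjects S1...) and `adult` (29-40).
#' @param trials_per_task Trials recorded per task per subject.
#' @param fs Sampling rate in Hz.
#' @param duration Trial duration in seconds.
#' @param task_templates Named list (FORWARD/RIGHT/LEFT/STOP) of stationary
#'   `ar_model` generators.
#' @param line_amplitude Amplitude of the 50 Hz mains interference.
#' @param line_frequency Mains frequency in Hz.
#' @param broadband_noise_sd Standard deviation of additive white
#'   measurement noise.
#' @param burn_in Samples discarded before the retained segment, removing
#'   AR filter transients.
#' @param channels Active channel labels.
#' @param seed Master seed; every trial draws from a substream derived
#'   deterministically from (seed, subject, task, trial).
#' @return A validated object of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_group = 10, trials_per_task = 10,
                         fs = 200, duration = 5,
                         task_templates = default_task_templates(fs = fs),
                         line_amplitude = 0.5, line_frequency = 50,
                         broadband_noise_sd = 0.2, burn_in = 500,
                         channels = c("T3", "T4"), seed = 1) {
  cfg <- structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                        trials_per_task = as.integer(trials_per_task),
                        fs = fs, duration = duration,
                        task_templates = task_templates,
                        line_amplitude = line_amplitude,
                        line_frequency = line_frequency,
                        broadband_noise_sd = broadband_noise_sd,
                        burn_in = as.integer(burn_in),
                        channels = channels,
                        seed = as.integer(seed)),
                   class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' @noRd
validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_subjects_per_group >= 1, cfg$trials_per_task >= 1,
            cfg$fs > 0, cfg$duration > 0, cfg$burn_in >= 0,
            length(cfg$channels) >= 1)
  missing <- setdiff(TASKS, names(cfg$task_templates))
  if (length(missing)) {
    stopf("synth_config: no template for task(s) %s", paste(missing, collapse = ", "))
  }
  for (task in TASKS) {
    tpl <- cfg$task_templates[[task]]
    if (!inherits(tpl, "ar_model")) stopf("template for %s is not an ar_model", task)
    if (!ar_is_stationary(tpl)) {
      stopf("template for task %s is non-stationary (characteristic root on or outside the unit circle)", task)
    }
  }
  invisible(cfg)
}

#' Simulate one AR realization under the package sign convention
#' @noRd
simulate_ar <- function(model, n, burn_in) {
  e <- stats::rnorm(n + burn_in, sd = sqrt(model$noise_variance))
  if (model$order == 0) return(e[(burn_in + 1):(burn_in + n)])
  x <- stats::filter(e, model$coefficients, method = "recursive")
  as.numeric(x)[(burn_in + 1):(burn_in + n)]
}

#' Generate a single synthetic trial
#'
#' The trial is an AR realization from the task template plus a 50 Hz
#' sinusoid at random phase and independent broadband noise, per channel.
#' Both channels share the template but draw independent noise. The RNG
#' substream is derived from `(config$seed, subject_id, task, trial_index)`,
#' so a trial is reproducible in isolation and independent of generation
#' order.
#'
#' @param task One of `"FORWARD"`, `"RIGHT"`, `"LEFT"`, `"STOP"`.
#' @param config A [synth_config()].
#' @param subject_id Subject label, e.g. `"S3"`.
#' @param trial_index Trial number within (subject, task), 1-based.
#' @param age_group `"young"` (20-28) or `"adult"` (29-40).
#' @return An object of class `eeg_trial`: fields `subject_id`, `age_group`,
#'   `task`, `trial_index`, `fs`, and `samples` (matrix, one column per
#'   channel).
#' @export
generate_trial <- function(task, config, subject_id, trial_index,
                           age_group = "young") {
  if (!task %in% TASKS) {
    stopf("unknown task '%s'; expected one of %s", task, paste(TASKS, collapse = ", "))
  }
  validate_synth_config(config)
  tpl <- config$task_templates[[task]]
  n <- round(config$fs * config$duration)
  tt <- (seq_len(n) - 1) / config$fs
  samples <- matrix(0, n, length(config$channels),
                    dimnames = list(NULL, config$channels))
  for (ch in seq_along(config$channels)) {
    set.seed(derive_seed(config$seed, subject_id, task, trial_index,
                         config$channels[ch]))
    x <- simulate_ar(tpl, n, config$burn_in)
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + config$line_amplitude *
      sin(2 * pi * config$line_frequency * tt + phase)
    x <- x + stats::rnorm(n, sd = config$broadband_noise_sd)
    samples[, ch] <- x
  }
  new_eeg_trial(subject_id, age_group, task, trial_index, config$fs, samples)
}

#' @noRd
new_eeg_trial <- function(subject_id, age_group, task, trial_index, fs, samples) {
  structure(list(subject_id = subject_id, age_group = age_group, task = task,
                 trial_index = as.integer(trial_index), fs = fs,
                 samples = samples),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("EEG trial %s/%s #%d: %d samples x %d channel(s) at %g Hz\n",
              x$subject_id, x$task, x$trial_index, nrow(x$samples),
              ncol(x$samples), x$fs))
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' Emits `2 * n_subjects_per_group` subjects x 4 tasks x `trials_per_task`
#' trials (800 with defaults) together with a manifest recording provenance.
#' Identical configurations (including seed) produce bit-identical datasets.
#'
#' @param config A [synth_config()].
#' @return An object of class `eeg_dataset`: `$trials` (list of `eeg_trial`)
#'   and `$manifest` (data.frame: subject, age_group, task, trial_index,
#'   seed).
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  n_young <- config$n_subjects_per_group
  subjects <- paste0("S", seq_len(2 * n_young))
  groups <- rep(c("young", "adult"), each = n_young)
  trials <- vector("list", length(subjects) * 4 * config$trials_per_task)
  rows <- vector("list", length(trials))
  k <- 0
  for (s in seq_along(subjects)) {
    for (task in TASKS) {
      for (tr in seq_len(config$trials_per_task)) {
        k <- k + 1
        trials[[k]] <- generate_trial(task, config, subjects[s], tr,
                                      age_group = groups[s])
        rows[[k]] <- data.frame(subject = subjects[s], age_group = groups[s],
                                task = task, trial_index = tr,
                                seed = derive_seed(config$seed, subjects[s],
                                                   task, tr, config$channels[1]),
                                stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(trials = trials, manifest = do.call(rbind, rows),
                 config = config),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("EEG dataset: %d trials, %d subjects, %d tasks\n",
              length(x$trials), length(unique(x$manifest$subject)),
              length(unique(x$manifest$task))))
  invisible(x)
}
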