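# Rhythm classes, in the fixed order used throughout (N, A, O, ~)
AF_CLASSES <- c("N", "A", "O", "~")

#' Synthetic ECG generation parameters
#'
#' Bundles the knobs of the synthetic single-lead ECG generator. Defaults are
#' class-specific and encode the canonical phenotype of each rhythm class:
#' regular RR with visible P waves for normal rhythm (`"N"`); irregular RR
#' (coefficient of variation >= 0.2), absent P waves and a low-amplitude
#' fibrillatory baseline oscillation for atrial fibrillation (`"A"`); a
#' normal-like rhythm with a fraction of premature beats and PR-interval
#' jitter for other rhythm (`"O"`); and a noise-dominated trace for the noisy
#' class (`"~"`).
#'
#' @param class_label one of `"N"`, `"A"`, `"O"`, `"~"`.
#' @param duration_s record duration in seconds, in \[9, 61\].
#' @param fs sampling frequency in Hz.
#' @param rr_mean_s mean RR interval in seconds, in \[0.3, 2\].
#' @param rr_cv coefficient of variation of the RR intervals.
#' @param p_amplitude P-wave amplitude in mV (0 suppresses the P wave).
#' @param qrs_amplitude R-wave amplitude in mV.
#' @param t_amplitude T-wave amplitude in mV.
#' @param noise_sigma standard deviation of additive white noise in mV.
#' @param fib_wave_hz fibrillatory-wave frequency in Hz (class `"A"` only),
#'   in \[4, 9\].
#' @param fib_amplitude fibrillatory-wave amplitude in mV.
#' @param premature_frac fraction of premature beats (class `"O"` only).
#' @param pr_jitter_s half-width of the uniform PR-interval jitter in seconds
#'   (class `"O"` only).
#' @param baseline_wander_mv amplitude of a 0.3 Hz baseline-wander sinusoid in
#'   mV (class `"~"` only).
#' @param seed integer seed for the record's random draws.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(class_label,
                         duration_s = 30,
                         fs = 300,
                         rr_mean_s = NULL,
                         rr_cv = NULL,
                         p_amplitude = NULL,
                         qrs_amplitude = 1.0,
                         t_amplitude = 0.3,
                         noise_sigma = NULL,
                         fib_wave_hz = 6,
                         fib_amplitude = 0.05,
                         premature_frac = 0.2,
                         pr_jitter_s = 0.04,
                         baseline_wander_mv = 0.3,
                         seed = 1L) {
  if (!class_label %in% AF_CLASSES) {
    stop("unknown class_label '", class_label, "'; must be one of ",
         paste(AF_CLASSES, collapse = ", "))
  }
  if (fs <= 0) stop("fs must be positive")
  if (duration_s < 9) stop("duration_s must be >= 9 s")
  # class-specific defaults
  if (is.null(rr_mean_s)) {
    rr_mean_s <- switch(class_label, N = 0.8, A = 0.7, O = 0.8, "~" = 0.8)
  }
  if (is.null(rr_cv)) {
    rr_cv <- switch(class_label, N = 0.03, A = 0.25, O = 0.04, "~" = 0.03)
  }
  if (is.null(p_amplitude)) {
    p_amplitude <- if (class_label == "A") 0 else 0.15
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- switch(class_label, N = 0.02, A = 0.03, O = 0.02, "~" = 0.8)
  }
  if (rr_mean_s < 0.3 || rr_mean_s > 2.0) stop("rr_mean_s must be in [0.3, 2.0]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (class_label == "A" && (fib_wave_hz < 4 || fib_wave_hz > 9)) {
    stop("fib_wave_hz must be in [4, 9] Hz")
  }
  structure(list(
    class_label = class_label, duration_s = duration_s, fs = fs,
    rr_mean_s = rr_mean_s, rr_cv = rr_cv,
    p_amplitude = p_amplitude, qrs_amplitude = qrs_amplitude,
    t_amplitude = t_amplitude, noise_sigma = noise_sigma,
    fib_wave_hz = fib_wave_hz, fib_amplitude = fib_amplitude,
    premature_frac = premature_frac, pr_jitter_s = pr_jitter_s,
    baseline_wander_mv = baseline_wander_mv, seed = as.integer(seed)
  ), class = "synth_params")
}

# Morphology constants (seconds, relative to the R peak).  Widths are Gaussian
# standard deviations.  The P-wave onset used for ground truth is taken two
# standard deviations before the P-bump centre; the QRS onset 40 ms before the
# R peak, giving a resting PR interval of 160 ms.
BEAT_GEOM <- list(
  p_center = -0.150, p_sigma = 0.025,
  q_center = -0.030, q_sigma = 0.010, q_rel_amp = -0.10,
  r_center = 0.000, r_sigma = 0.012,
  s_center = 0.030, s_sigma = 0.010, s_rel_amp = -0.15,
  t_center = 0.300, t_sigma = 0.060
)

#' Single PQRST beat template
#'
#' Builds one cardiac cycle as a sum of Gaussian bumps (P, Q, R, S, T) sampled
#' at `fs`. The template spans \[-0.25, 0.45\] s around the R peak; the R bump
#' is the global maximum whenever `qrs_amplitude` exceeds the other
#' amplitudes.
#'
#' @param p_amplitude,qrs_amplitude,t_amplitude bump amplitudes in mV.
#' @param fs sampling frequency in Hz.
#' @param widths optional named list overriding the Gaussian standard
#'   deviations (seconds) of the P, QRS and T bumps
#'   (`p_sigma`, `r_sigma`, `t_sigma`).
#' @return list with `samples` (mV), `t` (seconds relative to the R peak) and
#'   `r_index` (sample index of the R centre).
#' @export
pqrst_template <- function(p_amplitude = 0.15, qrs_amplitude = 1.0,
                           t_amplitude = 0.3, fs = 300, widths = list()) {
  g <- utils::modifyList(BEAT_GEOM, widths)
  if (fs <= 0) stop("fs must be positive")
  if (any(unlist(g[grepl("sigma", names(g))]) <= 0)) {
    stop("all bump widths must be positive")
  }
  t <- seq(-0.25, 0.45, by = 1 / fs)
  bump <- function(a, c, s) a * exp(-(t - c)^2 / (2 * s^2))
  x <- bump(p_amplitude, g$p_center, g$p_sigma) +
    bump(g$q_rel_amp * qrs_amplitude, g$q_center, g$q_sigma) +
    bump(qrs_amplitude, g$r_center, g$r_sigma) +
    bump(g$s_rel_amp * qrs_amplitude, g$s_center, g$s_sigma) +
    bump(t_amplitude, g$t_center, g$t_sigma)
  list(samples = x, t = t, r_index = which.min(abs(t)))
}

# Add a Gaussian bump centred at time tc (s) to x in place, evaluated only on
# a +-4 sigma support window for speed.
add_bump <- function(x, fs, tc, amp, sigma) {
  if (amp == 0) return(x)
  n <- length(x)
  i0 <- max(1L, floor((tc - 4 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((tc + 4 * sigma) * fs) + 1L)
  if (i0 > i1) return(x)
  tt <- (seq(i0, i1) - 1) / fs
  x[i0:i1] <- x[i0:i1] + amp * exp(-(tt - tc)^2 / (2 * sigma^2))
  x
}

#' Generate one labeled synthetic ECG recording
#'
#' Draws a beat train with class-specific RR statistics, renders PQRST
#' morphology, applies class-specific modifiers (fibrillatory wave, premature
#' beats, PR jitter, heavy noise plus baseline wander) and returns the trace
#' together with its fiducial ground truth.
#'
#' @param params a [synth_params()] object.
#' @return list with `recording` (fields `record_id`, `samples` in mV, `fs`,
#'   `label`) and `truth` (fields `r_peak_times`, `p_onset_times`,
#'   `qrs_onset_times` in seconds, `class_label`).
#' @export
generate_recording <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  n <- round(p$duration_s * p$fs)
  g <- BEAT_GEOM

  # lognormal RR with requested mean/cv
  sdlog <- sqrt(log(1 + p$rr_cv^2))
  meanlog <- log(p$rr_mean_s) - sdlog^2 / 2
  n_draw <- ceiling(p$duration_s / p$rr_mean_s * 2) + 10
  rr <- stats::rlnorm(n_draw, meanlog, sdlog)
  rr <- pmax(rr, 0.25)
  if (p$class_label == "O" && p$premature_frac > 0) {
    prem <- stats::runif(n_draw) < p$premature_frac
    rr[prem] <- rr[prem] / 2
  }
  t_first <- 0.3
  beat_t <- t_first + cumsum(c(0, rr))
  beat_t <- beat_t[beat_t < p$duration_s - 0.25]

  # PR jitter shifts the P bump beat-by-beat (class O)
  pr_shift <- if (p$class_label == "O" && p$pr_jitter_s > 0) {
    stats::runif(length(beat_t), -p$pr_jitter_s, p$pr_jitter_s)
  } else {
    rep(0, length(beat_t))
  }

  x <- numeric(n)
  for (i in seq_along(beat_t)) {
    tc <- beat_t[i]
    x <- add_bump(x, p$fs, tc + g$p_center - pr_shift[i], p$p_amplitude, g$p_sigma)
    x <- add_bump(x, p$fs, tc + g$q_center, g$q_rel_amp * p$qrs_amplitude, g$q_sigma)
    x <- add_bump(x, p$fs, tc + g$r_center, p$qrs_amplitude, g$r_sigma)
    x <- add_bump(x, p$fs, tc + g$s_center, g$s_rel_amp * p$qrs_amplitude, g$s_sigma)
    x <- add_bump(x, p$fs, tc + g$t_center, p$t_amplitude, g$t_sigma)
  }

  tt <- (seq_len(n) - 1) / p$fs
  if (p$class_label == "A" && p$fib_amplitude > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + p$fib_amplitude * sin(2 * pi * p$fib_wave_hz * tt + phase)
  }
  if (p$class_label == "~" && p$baseline_wander_mv > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + p$baseline_wander_mv * sin(2 * pi * 0.3 * tt + phase)
  }
  if (p$noise_sigma > 0) x <- x + stats::rnorm(n, 0, p$noise_sigma)

  p_onsets <- if (p$p_amplitude > 0) {
    sort(beat_t + g$p_center - pr_shift - 2 * g$p_sigma)
  } else {
    numeric(0)
  }
  truth <- list(
    r_peak_times = beat_t,
    p_onset_times = p_onsets,
    qrs_onset_times = beat_t - 0.040,
    class_label = p$class_label
  )
  rec <- list(record_id = sprintf("SYN%06d", p$seed %% 1000000L),
              samples = x, fs = p$fs, label = p$class_label)
  class(rec) <- "ecg_recording"
  list(recording = rec, truth = truth)
}

#' Generate a labeled synthetic dataset
#'
#' @param counts named integer vector/list of recordings per class, names in
#'   `c("N","A","O","~")`.
#' @param seed master seed; per-record seeds are derived from it
#'   deterministically.
#' @param length_law function `n -> durations` drawing record durations in
#'   seconds from \[9, 61\]; default is uniform, mirroring the variable-length
#'   short recordings the pipeline must unify.
#' @param fs sampling frequency in Hz.
#' @param ... further arguments forwarded to [synth_params()].
#' @return list of `list(recording, truth)` pairs, classes in block order.
#' @export
generate_dataset <- function(counts, seed = 1L,
                             length_law = function(n) stats::runif(n, 9, 61),
                             fs = 300, ...) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || !all(names(counts) %in% AF_CLASSES)) {
    stop("counts must be named with classes among N, A, O, ~")
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  if (total == 0) return(list())
  set.seed(seed)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, total)
  durations <- pmin(61, pmax(9, length_law(total)))
  labels <- rep(names(counts), counts)
  out <- vector("list", total)
  for (i in seq_len(total)) {
    sp <- synth_params(labels[i], duration_s = durations[i], fs = fs,
                       seed = rec_seeds[i], ...)
    out[[i]] <- generate_recording(sp)
    out[[i]]$recording$record_id <- sprintf("SYN%05d", i)
  }
  out
}
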