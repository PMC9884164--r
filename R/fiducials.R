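# Beat-level fiducial detection: R peaks (Pan-Tompkins), QRS onsets
# (derivative back-search) and P onsets (dyadic spline-wavelet modulus maxima).

# Zero-phase 5-15 Hz band-pass used by the Pan-Tompkins chain.
pt_bandpass <- function(x, fs) {
  ny <- fs / 2
  bp <- signal::butter(3, c(5, 15) / ny, type = "pass")
  as.numeric(signal::filtfilt(bp, x - mean(x)))
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic chain: zero-phase 5-15 Hz band-pass, five-point derivative,
#' squaring, 150-ms moving-window integration, then adaptive dual-threshold
#' peak picking with search-back and a 200-ms refractory period. Detected
#' integration peaks are refined to the nearest band-passed-signal extremum so
#' the returned indices sit on the R wave of the original trace. All
#' thresholds are relative, so detection is invariant to positive rescaling
#' of the input.
#'
#' @param x numeric trace in mV.
#' @param fs sampling frequency in Hz.
#' @return integer vector of R-peak sample indices (1-based, strictly
#'   increasing, gaps >= 0.2 s); empty when fewer than one credible peak is
#'   found.
#' @export
detect_r_peaks <- function(x, fs) {
  n <- length(x)
  if (n < 2 * fs) stop("need at least 2 s of samples")
  if (all(x == x[1])) return(integer(0))
  xf <- pt_bandpass(x, fs)
  # five-point derivative (zero-phase form), squaring, 150-ms integration
  der <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(3L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate local maxima of the integrated signal
  dm <- diff(mwi)
  cand <- which(dm[-length(dm)] > 0 & dm[-1] <= 0) + 1L
  if (length(cand) == 0) return(integer(0))

  refractory <- round(0.2 * fs)
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init)
  npki <- mean(init) * 0.5
  peaks <- integer(0)
  rr_avg <- fs  # running average RR in samples, init 1 s
  last_qualified <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    thr1 <- npki + 0.25 * (spki - npki)
    if (p - last_qualified < refractory) { i <- i + 1L; next }
    if (mwi[p] >= thr1) {
      peaks <- c(peaks, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(peaks) >= 2) {
        rr <- diff(utils::tail(peaks, 8))
        rr_avg <- mean(rr)
      }
      last_qualified <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      # search-back: no beat for 1.66 * average RR -> accept best candidate
      # above half threshold in the gap
      if (is.finite(last_qualified) && p - last_qualified > 1.66 * rr_avg) {
        gap <- cand[cand > last_qualified + refractory & cand <= p]
        gap <- gap[mwi[gap] >= 0.5 * thr1]
        if (length(gap) > 0) {
          best <- gap[which.max(mwi[gap])]
          peaks <- c(peaks, best)
          spki <- 0.25 * mwi[best] + 0.75 * spki
          last_qualified <- best
        }
      }
    }
    i <- i + 1L
  }
  if (length(peaks) == 0) return(integer(0))

  # refine to the band-passed extremum, then to the local |x| maximum
  half <- round(0.10 * fs)
  ref <- vapply(peaks, function(p) {
    a <- max(1L, p - half); b <- min(n, p + half)
    j <- a + which.max(abs(xf[a:b])) - 1L
    a2 <- max(1L, j - 3L); b2 <- min(n, j + 3L)
    as.integer(a2 + which.max(abs(x[a2:b2] - stats::median(x))) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory after refinement, keeping the larger peak
  keep <- rep(TRUE, length(ref))
  j <- 1L
  for (k in seq_along(ref)[-1]) {
    if (ref[k] - ref[j] < refractory) {
      if (abs(xf[ref[k]]) > abs(xf[ref[j]])) { keep[j] <- FALSE; j <- k }
      else keep[k] <- FALSE
    } else j <- k
  }
  ref[keep]
}

#' Locate QRS onsets by derivative back-search
#'
#' For each R peak, walks backward from the steepest point of the upstroke
#' within a 60-ms pre-R window until the derivative magnitude drops below 10%
#' of its window maximum; the first such sample is the onset (the initial
#' deflection of the complex). Falls back to R - 40 ms when the search
#' degenerates; indices are clamped at the segment start.
#'
#' @param x numeric trace in mV.
#' @param fs sampling frequency in Hz.
#' @param r_peaks integer R-peak indices.
#' @return integer vector of onsets, one per R peak, each in
#'   \[r - 60 ms, r\].
#' @export
detect_qrs_onsets <- function(x, fs, r_peaks) {
  if (length(r_peaks) == 0) return(integer(0))
  w <- as.integer(round(0.060 * fs))
  fallback <- as.integer(round(0.040 * fs))
  d <- abs(diff(x))
  vapply(r_peaks, function(r) {
    r <- as.integer(r)
    a <- max(1L, r - w)
    if (r - 1L < a) return(max(1L, r - fallback))
    dw <- d[a:(r - 1L)]               # d[i] = |x[i+1]-x[i]|
    mx <- max(dw)
    if (mx <= 0) return(max(1L, r - fallback))
    im <- which.max(dw)
    thr <- 0.10 * mx
    j <- im
    while (j > 1 && dw[j - 1] >= thr) j <- j - 1L
    onset <- a + j - 1L
    if (onset >= r) onset <- max(1L, r - fallback)
    as.integer(onset)
  }, integer(1))
}

# Dyadic a-trous wavelet transform with quadratic-spline-like filters
# (lowpass h = [1,3,3,1]/8, highpass g = [2,-2]).  Returns the detail
# coefficients at the requested scale 2^j, phase-aligned so that a symmetric
# positive bump yields a +/- modulus-maxima pair whose midpoint sits at the
# bump centre.  The cascade group delay per scale is calibrated numerically
# once and cached.
.atrous_cache <- new.env(parent = emptyenv())

atrous_raw <- function(x, j_scale) {
  a <- x
  h0 <- c(1, 3, 3, 1) / 8
  g0 <- c(2, -2)
  conv_same <- function(s, f, center) {
    full <- stats::convolve(s, rev(f), type = "open")
    full[center:(center + length(s) - 1)]
  }
  for (j in seq_len(j_scale)) {
    up <- 2^(j - 1)
    gj <- as.vector(rbind(g0, matrix(0, up - 1, length(g0))))
    gj <- gj[seq_len(length(gj) - (up - 1))]
    hj <- as.vector(rbind(h0, matrix(0, up - 1, length(h0))))
    hj <- hj[seq_len(length(hj) - (up - 1))]
    if (j == j_scale) {
      return(conv_same(a, gj, center = max(1L, floor(length(gj) / 2))))
    }
    a <- conv_same(a, hj, center = max(1L, floor(length(hj) / 2)))
  }
}

atrous_delay <- function(j_scale) {
  key <- paste0("d", j_scale)
  if (!is.null(.atrous_cache[[key]])) return(.atrous_cache[[key]])
  n <- 1024L
  xb <- exp(-((1:n) - 512)^2 / (2 * 8^2))
  w <- atrous_raw(xb, j_scale)
  d <- as.integer(round((which.max(w) + which.min(w)) / 2 - 512))
  .atrous_cache[[key]] <- d
  d
}

# White-noise l2 gain of the detail cascade at a given scale (for
# noise-floor transfer between scales); cached.
atrous_gain <- function(j_scale) {
  key <- paste0("g", j_scale)
  if (!is.null(.atrous_cache[[key]])) return(.atrous_cache[[key]])
  imp <- numeric(512L)
  imp[256L] <- 1
  g <- sqrt(sum(atrous_raw(imp, j_scale)^2))
  .atrous_cache[[key]] <- g
  g
}

atrous_detail <- function(x, j_scale) {
  stopifnot(j_scale >= 1)
  w <- atrous_raw(x, j_scale)
  shift <- atrous_delay(j_scale)
  if (shift > 0) w <- c(w[-seq_len(shift)], rep(0, shift))
  else if (shift < 0) w <- c(rep(0, -shift), w[seq_len(length(w) + shift)])
  w
}

#' Detect P-wave onsets by wavelet modulus maxima
#'
#' For each QRS onset, searches the window \[onset - 250 ms, onset - 50 ms\]
#' of the dyadic spline-wavelet detail signal (scale 2^4 by default; at 300 Hz
#' this responds to the 40-120 ms P deflection). A P wave is declared when the
#' window holds a modulus-maxima pair of opposite sign whose magnitudes both
#' exceed `k_mad` robust deviations of the detail signal; the onset is the
#' zero crossing preceding the first maximum of the pair. Beats with no
#' qualifying pair yield `NA` — absence is a valid outcome (AF-like or noisy
#' traces).
#'
#' A qualifying pair must satisfy three relative (scale-invariant) criteria:
#' both modulus maxima exceed `k_noise` times the segment's noise floor (the
#' fine-scale detail deviation transferred to the analysis scale through the
#' cascade's white-noise gains); the pair spans at most 120 ms; and the window
#' peak exceeds `peak_ratio` times the window's median modulus, which rejects
#' sustained oscillation (fibrillatory waves occupy the whole window, a P
#' deflection does not). The onset is the sample, left of the first maximum
#' of the pair, where the modulus falls below half that maximum.
#'
#' @param x numeric trace in mV.
#' @param fs sampling frequency in Hz.
#' @param qrs_onsets integer QRS-onset indices.
#' @param scale dyadic scale exponent (detail at 2^scale).
#' @param k_noise detection threshold in noise-floor units.
#' @param peak_ratio minimum window peak-to-median-modulus ratio.
#' @return integer vector aligned with `qrs_onsets`; `NA` where no P wave was
#'   found.
#' @export
detect_p_onsets <- function(x, fs, qrs_onsets, scale = 4, k_noise = 6,
                            peak_ratio = 1.8) {
  if (length(qrs_onsets) == 0) return(integer(0))
  w <- atrous_detail(x, scale)
  w_fine <- atrous_detail(x, 1)
  noise <- stats::mad(w_fine) / atrous_gain(1) * atrous_gain(scale)
  if (!is.finite(noise) || noise == 0) return(rep(NA_integer_, length(qrs_onsets)))
  a_off <- round(0.250 * fs); b_off <- round(0.050 * fs)
  max_span <- round(0.120 * fs)
  vapply(qrs_onsets, function(on) {
    a <- max(1L, on - a_off); b <- max(1L, on - b_off)
    if (b - a < 10) return(NA_integer_)
    ww <- w[a:b]
    imax <- which.max(ww); imin <- which.min(ww)
    if (min(ww[imax], -ww[imin]) < k_noise * noise) return(NA_integer_)
    if (abs(imax - imin) > max_span) return(NA_integer_)
    if (max(abs(ww)) < peak_ratio * stats::median(abs(ww))) return(NA_integer_)
    first <- min(imax, imin)           # opposite-sign pair; first extremum
    sgn <- sign(ww[first])
    j <- first
    while (j > 1 && sign(ww[j - 1]) == sgn && abs(ww[j - 1]) > 0.5 * abs(ww[first])) {
      j <- j - 1L
    }
    as.integer(a + j - 1L)
  }, integer(1))
}

#' Full fiducial set for a segment
#'
#' @param segment an `ecg_segment` (or any list with `samples` and `fs`).
#' @param p_scale,p_k_noise parameters forwarded to [detect_p_onsets()].
#' @return list of class `fiducial_set`: `r_peaks`, `qrs_onsets`,
#'   `p_onsets_paired` (aligned with `qrs_onsets`, `NA` = no P found),
#'   `p_onsets` (the non-missing values), `fs`.
#' @export
detect_fiducials <- function(segment, p_scale = 4, p_k_noise = 6) {
  x <- segment$samples; fs <- segment$fs
  r <- tryCatch(detect_r_peaks(x, fs), error = function(e) integer(0))
  q <- detect_qrs_onsets(x, fs, r)
  p <- detect_p_onsets(x, fs, q, scale = p_scale, k_noise = p_k_noise)
  structure(list(r_peaks = r, qrs_onsets = q,
                 p_onsets_paired = p, p_onsets = p[!is.na(p)], fs = fs),
            class = "fiducial_set")
}
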