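# The 24 artificial features: 8 waveform, 11 interval, 4 frequency-domain,
# 1 nonlinear (permutation ratio entropy).

ARTIFICIAL_FEATURE_NAMES <- c(
  "n_R", "r_max", "r_min", "r_mean", "r_median", "S", "SK", "KU",
  "rr_max", "rr_min", "rr_mean", "rr_median", "rr_std", "HR",
  "pr_max", "pr_min", "pr_mean", "pr_median", "pr_std",
  "FC", "MSF", "RMSF", "FV", "PRE"
)

# population standard deviation (the /N convention used throughout)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Waveform features of a segment
#'
#' The R-wave count, four order statistics and the standard deviation of the
#' R-peak amplitudes, plus the skewness and kurtosis of the full sample
#' series. The skewness and kurtosis use the literal printed convention: a
#' population (/N) standard deviation inside third- and fourth-moment sums
#' divided by (N-1), with 3 subtracted from the kurtosis.
#'
#' @param x numeric segment samples in mV.
#' @param r_peaks integer R-peak indices.
#' @return named numeric vector `n_R, r_max, r_min, r_mean, r_median, S, SK,
#'   KU`, with a logical `degenerate` attribute flagging values that had to
#'   fall back to 0 (no R peaks, or a constant trace).
#' @export
waveform_features <- function(x, r_peaks) {
  n <- length(x)
  stopifnot(n >= 1)
  flags <- c(r = FALSE, shape = FALSE)
  if (length(r_peaks) >= 1) {
    amp <- x[r_peaks]
    rstats <- c(max(amp), min(amp), mean(amp), stats::median(amp), sd_pop(amp))
  } else {
    rstats <- rep(0, 5)
    flags["r"] <- TRUE
  }
  m <- mean(x)
  s_full <- sd_pop(x)
  if (s_full > 0 && n > 1) {
    sk <- sum((x - m)^3) / ((n - 1) * s_full^3)
    ku <- sum((x - m)^4) / ((n - 1) * s_full^4) - 3
  } else {
    sk <- 0; ku <- 0
    flags["shape"] <- TRUE
  }
  out <- c(n_R = length(r_peaks), r_max = rstats[1], r_min = rstats[2],
           r_mean = rstats[3], r_median = rstats[4], S = rstats[5],
           SK = sk, KU = ku)
  attr(out, "degenerate") <- flags
  out
}

#' Interval features from a fiducial set
#'
#' RR intervals are successive R-peak differences in seconds; PR intervals
#' are QRS onset minus paired P onset for beats with a detected P wave. Five
#' statistics per series (standard deviations use the population /N
#' convention) plus the heart rate 60 / mean(RR) in beats per minute.
#'
#' @param fid a `fiducial_set` from [detect_fiducials()].
#' @return named numeric vector `rr_max ... rr_std, HR, pr_max ... pr_std`
#'   with a `degenerate` attribute; missing physiology (under 2 R peaks, no P
#'   onsets) yields zeros with the corresponding flag set.
#' @export
interval_features <- function(fid) {
  fs <- fid$fs
  flags <- c(rr = FALSE, pr = FALSE)
  if (length(fid$r_peaks) >= 2) {
    rr <- diff(fid$r_peaks) / fs
    rr_stats <- c(max(rr), min(rr), mean(rr), stats::median(rr), sd_pop(rr))
    hr <- 60 / mean(rr)
  } else {
    rr_stats <- rep(0, 5); hr <- 0
    flags["rr"] <- TRUE
  }
  paired <- !is.na(fid$p_onsets_paired)
  if (any(paired)) {
    pr <- (fid$qrs_onsets[paired] - fid$p_onsets_paired[paired]) / fs
    pr_stats <- c(max(pr), min(pr), mean(pr), stats::median(pr), sd_pop(pr))
  } else {
    pr_stats <- rep(0, 5)
    flags["pr"] <- TRUE
  }
  out <- c(rr_max = rr_stats[1], rr_min = rr_stats[2], rr_mean = rr_stats[3],
           rr_median = rr_stats[4], rr_std = rr_stats[5], HR = hr,
           pr_max = pr_stats[1], pr_min = pr_stats[2], pr_mean = pr_stats[3],
           pr_median = pr_stats[4], pr_std = pr_stats[5])
  attr(out, "degenerate") <- flags
  out
}

#' Spectral-moment frequency features
#'
#' Treats the one-sided periodogram of the mean-removed segment as a
#' distribution over frequency and returns its centre of gravity (FC), mean
#' square (MSF), root mean square (RMSF = sqrt(MSF)) and variance about the
#' centre (FV). The identity MSF = FV + FC^2 holds exactly.
#'
#' @param x numeric segment samples.
#' @param fs sampling frequency in Hz.
#' @return named numeric vector `FC, MSF, RMSF, FV` (Hz, Hz^2, Hz, Hz^2) with
#'   a `degenerate` attribute (constant segment -> all zero).
#' @export
frequency_features <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 2)
  xc <- x - mean(x)
  spec <- Mod(stats::fft(xc))^2 / n
  half <- floor(n / 2) + 1
  s <- spec[seq_len(half)]
  f <- (seq_len(half) - 1) * fs / n
  tot <- sum(s)
  if (tot <= 0) {
    out <- c(FC = 0, MSF = 0, RMSF = 0, FV = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fc <- sum(f * s) / tot
  msf <- sum(f^2 * s) / tot
  fv <- sum((f - fc)^2 * s) / tot
  out <- c(FC = fc, MSF = msf, RMSF = sqrt(msf), FV = fv)
  attr(out, "degenerate") <- FALSE
  out
}

#' Permutation ratio entropy
#'
#' Slides a window of m+1 samples over the series; each window is encoded as
#' the ternary signs of its m adjacent differences (with a dead-band of
#' `deadband` around zero), forming the rows of a relation matrix. Rows share
#' a pattern iff they are element-wise equal; the entropy of the pattern
#' multiplicities (in nats) is returned. The number of rows is n - m - 1.
#'
#' @param series numeric vector, length n >= m + 2.
#' @param m window order (number of adjacent differences per row).
#' @param deadband half-width around zero within which a difference counts as
#'   "equal".
#' @return entropy in nats (0 for a constant or strictly monotone series).
#' @export
pre_entropy <- function(series, m = 3, deadband = 0) {
  n <- length(series)
  if (m < 1) stop("m must be >= 1")
  if (n < m + 2) stop("series too short: need n >= m + 2")
  d <- diff(series)
  code <- ifelse(d > deadband, 1L, ifelse(d < -deadband, -1L, 0L))
  n_rows <- n - m - 1L
  # pattern id of rows code[i..i+m-1], i = 1..n_rows, base-3 encoded
  id <- numeric(n_rows)
  for (j in seq_len(m)) id <- id + (code[seq_len(n_rows) + j - 1L] + 1) * 3^(j - 1)
  counts <- table(id)
  p <- as.numeric(counts) / sum(counts)
  -sum(p * log(p))
}

#' Extract the 24 artificial features of a segment
#'
#' Concatenates waveform, interval, frequency-domain and entropy features in
#' the fixed reporting order. Degenerate physiology (no beats, constant
#' trace) produces zeros with flags, never non-finite values.
#'
#' @param segment an `ecg_segment`.
#' @param fid optional precomputed `fiducial_set`; detected if missing.
#' @param pre_m window order of the permutation ratio entropy.
#' @return named numeric vector of length 24 with a `degenerate` attribute
#'   (named logical flags).
#' @export
extract_artificial <- function(segment, fid = NULL, pre_m = 3) {
  if (is.null(fid)) fid <- detect_fiducials(segment)
  x <- segment$samples
  wf <- waveform_features(x, fid$r_peaks)
  iv <- interval_features(fid)
  fq <- frequency_features(x, segment$fs)
  pe <- pre_entropy(x, m = pre_m)
  out <- c(wf, iv, fq, PRE = pe)
  stopifnot(identical(names(out), ARTIFICIAL_FEATURE_NAMES))
  attr(out, "degenerate") <- c(attr(wf, "degenerate"), attr(iv, "degenerate"),
                               freq = attr(fq, "degenerate"))
  out
}

#' Artificial feature table for a list of segments
#'
#' @param segments list of `ecg_segment`s.
#' @param pre_m entropy window order.
#' @return data.frame with `record_id`, `label` and the 24 feature columns.
#' @export
artificial_feature_table <- function(segments, pre_m = 3) {
  rows <- lapply(segments, function(seg) {
    f <- extract_artificial(seg, pre_m = pre_m)
    c(list(record_id = seg$record_id, label = seg$label), as.list(f))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
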