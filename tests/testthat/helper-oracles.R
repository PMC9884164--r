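# Independent brute-force oracle for the permutation ratio entropy:
# enumerate every window, encode adjacent-difference relations, group equal
# rows by exhaustive pairwise comparison, evaluate the entropy directly.
pre_oracle <- function(series, m, deadband = 0) {
  n <- length(series)
  n_rows <- n - m - 1
  rows <- vector("list", n_rows)
  for (i in seq_len(n_rows)) {
    w <- series[i:(i + m)]
    r <- integer(m)
    for (j in seq_len(m)) {
      d <- w[j + 1] - w[j]
      r[j] <- if (d > deadband) 1L else if (d < -deadband) -1L else 0L
    }
    rows[[i]] <- r
  }
  assigned <- rep(FALSE, n_rows)
  counts <- integer(0)
  for (i in seq_len(n_rows)) {
    if (assigned[i]) next
    cnt <- 1L
    assigned[i] <- TRUE
    if (i < n_rows) for (j in (i + 1):n_rows) {
      if (!assigned[j] && all(rows[[j]] == rows[[i]])) {
        cnt <- cnt + 1L
        assigned[j] <- TRUE
      }
    }
    counts <- c(counts, cnt)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# short-hand: one synthetic recording unified to a 30-s segment
make_segment <- function(class_label, seed = 1, duration_s = 30, ...) {
  g <- generate_recording(synth_params(class_label, duration_s = duration_s,
                                       seed = seed, ...))
  list(segment = unify_length(g$recording, seed = seed), truth = g$truth)
}

# beat-detection F1 against ground truth at a +-25 ms tolerance
detection_f1 <- function(detected, truth_times, fs, tol_s = 0.025) {
  truth_idx <- round(truth_times * fs) + 1
  if (length(detected) == 0) return(0)
  tp <- sum(vapply(truth_idx, function(t) any(abs(detected - t) <= tol_s * fs),
                   logical(1)))
  prec <- tp / length(detected)
  rec <- tp / length(truth_idx)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
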