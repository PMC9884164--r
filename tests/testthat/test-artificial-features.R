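test_that("skewness and kurtosis follow the literal mixed-denominator forms", {
  wf <- waveform_features(c(1, 2, 3), integer(0))
  # population S = sqrt(2/3); fourth-moment sum 2 over (N-1) S^4, minus 3
  expect_equal(unname(wf["SK"]), 0)
  expect_equal(unname(wf["KU"]), -0.75)
  expect_true(attr(wf, "degenerate")["r"])

  # any series symmetric about its mean has zero skewness
  x <- c(-3, -1, 0, 1, 3) + 10
  expect_equal(unname(waveform_features(x, integer(0))["SK"]), 0)

  # constant trace: shape statistics fall back to 0 with the flag
  wf0 <- waveform_features(rep(2, 100), integer(0))
  expect_identical(unname(wf0[c("SK", "KU")]), c(0, 0))
  expect_true(attr(wf0, "degenerate")["shape"])
})

test_that("R-amplitude statistics are plain order statistics", {
  x <- rep(0, 100)
  x[c(10, 50, 90)] <- c(0.9, 1.1, 1.0)
  wf <- waveform_features(x, c(10L, 50L, 90L))
  expect_equal(unname(wf[c("n_R", "r_max", "r_min", "r_mean", "r_median")]),
               c(3, 1.1, 0.9, 1.0, 1.0))
  # S is the population standard deviation of the R amplitudes
  expect_equal(unname(wf["S"]), sqrt(mean((c(0.9, 1.1, 1.0) - 1)^2)))
})

test_that("interval features and heart rate come out in seconds and bpm", {
  fs <- 300
  fid <- structure(list(r_peaks = as.integer(1 + fs * 0:10),
                        qrs_onsets = integer(0),
                        p_onsets_paired = integer(0), p_onsets = integer(0),
                        fs = fs), class = "fiducial_set")
  iv <- interval_features(fid)
  expect_equal(unname(iv["rr_std"]), 0)
  expect_equal(unname(iv["HR"]), 60)
  expect_true(attr(iv, "degenerate")["pr"])

  fid2 <- fid
  fid2$r_peaks <- as.integer(1 + fs * c(0, 0.5, 2.0))
  iv2 <- interval_features(fid2)
  expect_equal(unname(iv2[c("rr_mean", "HR", "rr_std")]), c(1.0, 60, 0.5))

  fid3 <- fid
  fid3$qrs_onsets <- as.integer(fs * c(1.0, 2.0, 3.0))
  fid3$p_onsets_paired <- as.integer(fid3$qrs_onsets - fs * c(0.12, 0.16, 0.20))
  iv3 <- interval_features(fid3)
  expect_equal(unname(iv3[c("pr_median", "pr_max")]), c(0.16, 0.20))

  # under 2 R peaks: degenerate zeros, flagged
  fid4 <- fid
  fid4$r_peaks <- 5L
  iv4 <- interval_features(fid4)
  expect_true(all(iv4[c("rr_max", "rr_std", "HR")] == 0))
  expect_true(attr(iv4, "degenerate")["rr"])
})

test_that("a pure sinusoid collapses the spectral moments to its frequency", {
  fs <- 300
  t <- (0:8999) / fs
  fq <- frequency_features(sin(2 * pi * 10 * t), fs)
  bin <- fs / 9000
  expect_equal(unname(fq["FC"]), 10, tolerance = 2 * bin)
  expect_equal(unname(fq["RMSF"]), 10, tolerance = 2 * bin)
  expect_lt(unname(fq["FV"]), 1e-3)

  # equal-power pair at 5 and 15 Hz: two-point distribution moments
  fq2 <- frequency_features(sin(2 * pi * 5 * t) + sin(2 * pi * 15 * t), fs)
  expect_equal(unname(fq2["FC"]), 10, tolerance = 0.05)
  expect_equal(unname(fq2["FV"]), 25, tolerance = 0.5)

  fq0 <- frequency_features(rep(3, 100), fs)
  expect_true(all(fq0 == 0))
  expect_true(attr(fq0, "degenerate"))
})

test_that("the spectral variance decomposition holds everywhere", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(500) + sin(2 * pi * runif(1, 1, 40) * (1:500) / 300)
    fq <- frequency_features(x, 300)
    expect_equal(unname(fq["MSF"]), unname(fq["FV"] + fq["FC"]^2),
                 tolerance = 1e-9)
    expect_gte(unname(fq["FV"]), 0)
    expect_equal(unname(fq["RMSF"]), sqrt(unname(fq["MSF"])), tolerance = 1e-12)
  }
})

test_that("permutation ratio entropy matches hand-derived values", {
  expect_equal(pre_entropy(rep(5, 30), m = 3), 0)
  expect_equal(pre_entropy(1:50, m = 4), 0)
  expect_equal(pre_entropy(seq(100, 1, length.out = 40), m = 2), 0)
  # windows of [1,3,2,4,3,5,4] at m = 2 alternate between two sign patterns
  expect_equal(pre_entropy(c(1, 3, 2, 4, 3, 5, 4), m = 2), log(2))
  expect_error(pre_entropy(c(1, 2, 3), m = 3), "too short")
})

test_that("permutation ratio entropy equals the brute-force oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(10:50, 1)
    m <- sample(2:4, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                round(rnorm(n), 1),          # ties exercise the dead-band
                cumsum(sample(c(-1, 0, 1), n, replace = TRUE)))
    expect_equal(pre_entropy(x, m = m), pre_oracle(x, m), tolerance = 1e-12)
  }
})

test_that("white noise carries more pattern entropy than a sinusoid", {
  hits <- vapply(1:40, function(seed) {
    set.seed(seed)
    n <- 300
    noise <- rnorm(n)
    tone <- sin(2 * pi * 6 * (1:n) / 300)
    pre_entropy(noise, m = 3) > pre_entropy(tone, m = 3)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the 24-feature vector is complete, finite and deterministic", {
  for (cl in c("N", "A", "O", "~")) {
    seg <- make_segment(cl, seed = 3)$segment
    f <- extract_artificial(seg)
    expect_length(f, 24)
    expect_identical(names(f), afusion:::ARTIFICIAL_FEATURE_NAMES)
    expect_true(all(is.finite(f)))
  }
  seg <- make_segment("N", seed = 3)$segment
  expect_identical(extract_artificial(seg), extract_artificial(seg))

  flat <- structure(list(record_id = "z", samples = rep(0, 9000), fs = 300,
                         label = "~", provenance = list()),
                    class = "ecg_segment")
  f0 <- extract_artificial(flat)
  expect_true(all(f0 == 0))
  expect_true(all(attr(f0, "degenerate")))
})
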