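test_that("records round-trip through the on-disk dialect", {
  dir <- withr::local_tempdir()
  g <- generate_recording(synth_params("N", seed = 9, duration_s = 12))
  write_dataset(list(g), dir)
  recs <- read_dataset(dir)
  expect_length(recs, 1)
  rt <- recs[[1]]
  expect_identical(rt$record_id, g$recording$record_id)
  expect_identical(rt$label, "N")
  expect_equal(rt$fs, 300)
  # int16 quantization at 1000 units/mV: half an LSB
  expect_lt(max(abs(rt$samples - g$recording$samples)), 5.1e-4)
})

test_that("header gain converts raw units to mV", {
  dir <- withr::local_tempdir()
  writeLines(c("T01 1 300 3", "T01.dat 16 1000 16 0 0 0 0 ECG"),
             file.path(dir, "T01.hea"))
  con <- file(file.path(dir, "T01.dat"), "wb")
  writeBin(c(1000L, -500L, 0L), con, size = 2L, endian = "little")
  close(con)
  rec <- read_record(file.path(dir, "T01.hea"))
  expect_equal(rec$samples, c(1.0, -0.5, 0.0))
})

test_that("truncated sample files are rejected", {
  dir <- withr::local_tempdir()
  g <- generate_recording(synth_params("N", seed = 2, duration_s = 10))
  write_record(g$recording, dir)
  dat <- file.path(dir, paste0(g$recording$record_id, ".dat"))
  full <- readBin(dat, "raw", n = file.info(dat)$size)
  writeBin(full[1:(length(full) - 10)], dat)
  expect_error(read_record(file.path(dir, paste0(g$recording$record_id, ".hea"))),
               "length mismatch")
})

test_that("long recordings are cropped to a contiguous 30-s slice", {
  g <- generate_recording(synth_params("N", seed = 4, duration_s = 45))
  seg <- unify_length(g$recording, seed = 7)
  expect_length(seg$samples, 9000)
  off <- seg$provenance$crop_offset_samples
  expect_gte(off, 0)
  expect_lte(off, 4500)
  expect_identical(seg$samples, g$recording$samples[(off + 1):(off + 9000)])
  # same seed, same crop
  expect_identical(unify_length(g$recording, seed = 7)$samples, seg$samples)
})

test_that("exact-length recordings pass through unchanged", {
  g <- generate_recording(synth_params("N", seed = 4, duration_s = 30))
  seg <- unify_length(g$recording)
  expect_identical(seg$samples, g$recording$samples)
  expect_identical(seg$provenance$crop_offset_samples, 0L)
})

test_that("short recordings tile the first-to-last QRS-onset span", {
  g <- generate_recording(synth_params("N", seed = 11, duration_s = 12))
  seg <- unify_length(g$recording)
  expect_length(seg$samples, 9000)
  expect_identical(seg$provenance$mode, "tile")
  span <- seg$provenance$tile_span
  L <- span["last_qrs_onset"] - span["first_qrs_onset"]
  names(L) <- NULL
  # the output restricted to the first span equals the source span exactly
  expect_identical(seg$samples[1:L],
                   g$recording$samples[(span["first_qrs_onset"] + 1):span["last_qrs_onset"]])
  # boundary values repeat with period == span length
  idx <- seq_len(9000 - L)
  expect_identical(seg$samples[idx + L], seg$samples[idx])
})

test_that("every unified segment has exactly 9000 samples", {
  set.seed(42)
  for (dur in c(9, 12.7, 29.9, 30, 30.1, 47, 61)) {
    g <- generate_recording(synth_params("N", seed = round(dur * 10),
                                         duration_s = dur))
    expect_length(unify_length(g$recording, seed = 1)$samples, 9000)
  }
})

test_that("degenerate short recordings are refused with a clear error", {
  rec <- structure(list(record_id = "flat", samples = rep(0, 3000),
                        fs = 300, label = "~"),
                   class = "ecg_recording")
  expect_error(unify_length(rec), "degenerate")
})

test_that("the split is stratified, seeded and disjoint", {
  segs <- lapply(1:100, function(i) {
    list(label = if (i <= 70) "N" else "A")
  })
  sp <- split_dataset(segs, train_frac = 0.8, seed = 3)
  labels <- vapply(segs, `[[`, "", "label")
  expect_identical(sum(labels[sp$train] == "N"), 56L)
  expect_identical(sum(labels[sp$train] == "A"), 24L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  sp2 <- split_dataset(segs, train_frac = 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_warning(split_dataset(segs, train_frac = 1.0), "empty")
  expect_warning(split_dataset(list(list(label = "N"), list(label = "A"),
                                    list(label = "A"), list(label = "A"))),
                 "fewer than 2")
})
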