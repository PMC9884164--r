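# On-disk record dialect: per record a text header <id>.hea
#   line 1: "<id> 1 <fs> <n_samples>"
#   line 2: "<id>.dat 16 <gain> 16 0 0 0 0 ECG"
# and a little-endian int16 sample file <id>.dat (physical mV = raw / gain),
# plus one REFERENCE.csv (record_id,label) per directory.

DEFAULT_GAIN <- 1000

#' Write an ECG recording to disk
#'
#' Emits the header/binary-sample dialect that [read_record()] ingests, so
#' synthetic data round-trips through the full pipeline.
#'
#' @param rec an `ecg_recording` (fields `record_id`, `samples`, `fs`,
#'   `label`).
#' @param dir output directory (created if missing).
#' @param gain ADC units per mV.
#' @return invisibly, the header path.
#' @export
write_record <- function(rec, dir, gain = DEFAULT_GAIN) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- as.integer(round(pmin(pmax(rec$samples * gain, -32768), 32767)))
  hea <- file.path(dir, paste0(rec$record_id, ".hea"))
  dat <- file.path(dir, paste0(rec$record_id, ".dat"))
  writeLines(c(
    sprintf("%s 1 %g %d", rec$record_id, rec$fs, length(raw)),
    sprintf("%s.dat 16 %g 16 0 0 0 0 ECG", rec$record_id, gain)
  ), hea)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(raw, con, size = 2L, endian = "little")
  invisible(hea)
}

#' Write a labeled dataset and its reference file
#'
#' @param records list of `list(recording, truth)` pairs as produced by
#'   [generate_dataset()], or a bare list of `ecg_recording`s.
#' @param dir output directory.
#' @return invisibly, the path of the REFERENCE.csv label file.
#' @export
write_dataset <- function(records, dir) {
  recs <- lapply(records, function(r) if (!is.null(r$recording)) r$recording else r)
  for (r in recs) write_record(r, dir)
  ref <- data.frame(record_id = vapply(recs, `[[`, "", "record_id"),
                    label = vapply(recs, `[[`, "", "label"))
  path <- file.path(dir, "REFERENCE.csv")
  utils::write.table(ref, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one ECG record from its header file
#'
#' Samples are converted to physical units (mV) with the header gain.
#'
#' @param header_path path to the `.hea` header.
#' @param label optional class label to attach.
#' @return an `ecg_recording`.
#' @export
read_record <- function(header_path, label = NA_character_) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  lines <- readLines(header_path, n = 2)
  h1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  h2 <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  record_id <- h1[1]
  fs <- as.numeric(h1[3])
  n <- as.integer(h1[4])
  gain <- as.numeric(h2[3])
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling frequency in header")
  if (fs != 300) message("note: record ", record_id, " has fs = ", fs, " Hz")
  dat <- file.path(dirname(header_path), h2[1])
  if (!file.exists(dat)) stop("sample file not found: ", dat)
  sz <- file.info(dat)$size
  if (sz != 2 * n) {
    stop("sample file length mismatch for ", record_id,
         ": header says ", n, " samples, file holds ", sz / 2)
  }
  con <- file(dat, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  structure(list(record_id = record_id, samples = raw / gain,
                 fs = fs, label = label),
            class = "ecg_recording")
}

#' Read a directory of records with their reference labels
#'
#' @param dir directory holding `.hea`/`.dat` pairs and a REFERENCE.csv.
#' @return list of `ecg_recording`s with labels attached.
#' @export
read_dataset <- function(dir) {
  ref_path <- file.path(dir, "REFERENCE.csv")
  if (!file.exists(ref_path)) stop("REFERENCE.csv not found in ", dir)
  ref <- utils::read.table(ref_path, sep = ",", col.names = c("record_id", "label"),
                           colClasses = "character")
  lapply(seq_len(nrow(ref)), function(i) {
    read_record(file.path(dir, paste0(ref$record_id[i], ".hea")),
                label = ref$label[i])
  })
}

#' Unify a recording to an exactly 30-s segment
#'
#' Recordings longer than the target are cropped at a seeded uniformly random
#' offset; recordings at the target length pass through; shorter recordings
#' are tiled: QRS complexes are located, the span from the first QRS onset to
#' the last QRS onset is excised and copied head-to-tail until the target
#' length is reached (the final partial copy is a truncated head of the span,
#' or a mirrored copy with `pad_mode = "mirror"`).
#'
#' @param rec an `ecg_recording`.
#' @param target_s target segment length in seconds.
#' @param seed seed for the random crop offset.
#' @param pad_mode `"tile"` (default) or `"mirror"` for the final partial
#'   copy of the tiling branch.
#' @param fiducials_fn function `(samples, fs) -> list(r_peaks, qrs_onsets)`
#'   used by the tiling branch; defaults to the package's Pan-Tompkins
#'   detector and derivative-based onset search.
#' @return a `segment` list: `record_id`, `samples` (length exactly
#'   `round(target_s * fs)`), `fs`, `label`, `provenance`.
#' @export
unify_length <- function(rec, target_s = 30, seed = 1L, pad_mode = c("tile", "mirror"),
                         fiducials_fn = NULL) {
  pad_mode <- match.arg(pad_mode)
  n_target <- round(target_s * rec$fs)
  n <- length(rec$samples)
  if (n >= n_target) {
    offset <- if (n == n_target) 0L else {
      set.seed(seed)
      sample.int(n - n_target + 1L, 1L) - 1L
    }
    samples <- rec$samples[(offset + 1L):(offset + n_target)]
    prov <- list(mode = "crop", crop_offset_samples = offset)
  } else {
    if (is.null(fiducials_fn)) {
      fiducials_fn <- function(x, fs) {
        r <- detect_r_peaks(x, fs)
        list(r_peaks = r, qrs_onsets = detect_qrs_onsets(x, fs, r))
      }
    }
    fid <- fiducials_fn(rec$samples, rec$fs)
    ons <- fid$qrs_onsets
    if (length(ons) < 2) {
      stop("degenerate input: fewer than 2 QRS onsets detected in a sub-",
           target_s, "-s recording (", rec$record_id, ")")
    }
    span <- rec$samples[(ons[1] + 1L):ons[length(ons)]]  # half-open [first, last)
    if (length(span) < 1) stop("degenerate QRS span")
    n_full <- n_target %/% length(span)
    rem <- n_target - n_full * length(span)
    tail_part <- if (rem == 0) numeric(0)
                 else if (pad_mode == "tile") span[seq_len(rem)]
                 else rev(span)[seq_len(rem)]
    samples <- c(rep(span, n_full), tail_part)
    prov <- list(mode = "tile",
                 tile_span = c(first_qrs_onset = ons[1],
                               last_qrs_onset = ons[length(ons)]),
                 n_copies = n_full + (rem > 0), pad_mode = pad_mode)
  }
  structure(list(record_id = rec$record_id, samples = samples, fs = rec$fs,
                 label = rec$label, provenance = prov),
            class = "ecg_segment")
}

#' Stratified train/test split
#'
#' @param segments list of segments (or any list with a `label` field).
#' @param train_frac fraction assigned to the training set.
#' @param seed split seed.
#' @return list with `train` and `test` index vectors into `segments`.
#' @export
split_dataset <- function(segments, train_frac = 0.8, seed = 1L) {
  if (length(segments) == 0) stop("empty segment list")
  labels <- vapply(segments, `[[`, "", "label")
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2) {
      warning("class '", cl, "' has fewer than 2 members; assigned wholly to train")
      train_idx <- c(train_idx, idx)
      next
    }
    n_tr <- round(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(segments), train_idx)
  if (length(test_idx) == 0) warning("test set is empty")
  list(train = train_idx, test = test_idx)
}
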