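#' Construct an EEG recording object
#'
#' A recording is a channels-by-samples numeric matrix in microvolts with a
#' single sampling rate. Channel labels follow the 10-20 system and must be
#' unique; all channels share one length.
#'
#' @param data Numeric matrix, channels in rows, samples in columns (µV).
#' @param channel_labels Character vector of electrode names, one per row.
#' @param sampling_rate_hz Positive sampling rate.
#' @param session_id Identifier carried through the pipeline.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, channel_labels, sampling_rate_hz,
                      session_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (length(channel_labels) != nrow(data))
    stop("one label per channel row required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (length(sampling_rate_hz) != 1L || !(sampling_rate_hz > 0))
    stop("sampling_rate_hz must be a positive number")
  rownames(data) <- channel_labels
  structure(list(channel_labels = as.character(channel_labels), data = data,
                 sampling_rate_hz = sampling_rate_hz,
                 session_id = session_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$session_id, nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Construct a single-channel analysis segment
#'
#' One channel's artifact-free sample vector with its sampling rate. The
#' canonical protocol uses 30 s eyes-closed segments (15,000 samples at
#' 500 Hz), two per session.
#'
#' @param samples Finite numeric vector (µV).
#' @param sampling_rate_hz Positive sampling rate.
#' @param channel Electrode name.
#' @param segment_index 1 or 2 within the session.
#' @return An object of class `eeg_segment` with field `n = length(samples)`.
#' @export
segment <- function(samples, sampling_rate_hz, channel = NA_character_,
                    segment_index = NA_integer_) {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("segment samples must be finite")
  if (!(sampling_rate_hz > 0)) stop("sampling_rate_hz must be positive")
  structure(list(samples = samples, n = length(samples),
                 sampling_rate_hz = sampling_rate_hz, channel = channel,
                 segment_index = as.integer(segment_index)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("eeg_segment: channel %s, %d samples @ %g Hz (%.3f s)\n",
              x$channel, x$n, x$sampling_rate_hz, x$n / x$sampling_rate_hz))
  invisible(x)
}

# ---- reading -----------------------------------------------------------

#' Read an EEG recording from EDF or matrix CSV
#'
#' Reads a multichannel recording and restricts it to the eight-electrode
#' montage (F3, F4, C3, C4, P3, P4, O1, O2) when those channels are present.
#' EDF labels are case-normalized (and stripped of "EEG "/reference suffixes)
#' before matching; physical units are converted to µV on read. Matrix CSV
#' files carry a header row of channel labels, one sample per row, and are
#' assumed to already be in µV; the sampling rate comes from an optional
#' `# sampling_rate_hz=...` comment line or the `sampling_rate_hz` argument.
#'
#' No filtering or other preprocessing is applied on read: the analysis
#' treats the acquisition bandpass as a property of the data, and software
#' filtering could distort the nonlinear structure the entropy analysis
#' measures.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"`, or `"matrix_csv"`.
#' @param require_montage If `TRUE` (default), error unless all eight montage
#'   channels are present.
#' @param sampling_rate_hz Fallback rate for matrix CSV files without a
#'   comment line (default 500).
#' @param session_id Session identifier (defaults to the file stem).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix_csv"),
                           require_montage = TRUE, sampling_rate_hz = 500,
                           session_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix_csv"
  }
  if (is.null(session_id))
    session_id <- sub("\\.[^.]*$", "", basename(path))
  rec <- switch(format,
    edf = read_edf(path, session_id = session_id),
    matrix_csv = read_matrix_csv(path, sampling_rate_hz = sampling_rate_hz,
                                 session_id = session_id))
  keep <- normalize_label(rec$channel_labels) %in% MONTAGE
  if (any(keep)) {
    labs <- normalize_label(rec$channel_labels)[keep]
    rec <- recording(rec$data[keep, , drop = FALSE], labs,
                     rec$sampling_rate_hz, rec$session_id)
  }
  if (require_montage) {
    missing <- setdiff(MONTAGE, rec$channel_labels)
    if (length(missing))
      stop("missing required channels: ", paste(missing, collapse = ", "))
  }
  rec
}

normalize_label <- function(lab) {
  lab <- toupper(trimws(lab))
  lab <- sub("^EEG\\s+", "", lab)
  sub("-(A1|A2|REF|LE|AVG)[0-9]*$", "", lab)
}

read_matrix_csv <- function(path, sampling_rate_hz = 500, session_id = NA) {
  first <- readLines(path, n = 2L)
  if (!length(first)) stop("empty matrix file: ", path)
  m <- regmatches(first, regexpr("#\\s*sampling_rate_hz\\s*=\\s*[0-9.]+", first))
  if (length(unlist(m)))
    sampling_rate_hz <- as.numeric(sub(".*=\\s*", "", unlist(m)[1]))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (!nrow(df)) stop("matrix file has a header but no samples: ", path)
  mat <- t(as.matrix(df))
  storage.mode(mat) <- "double"
  recording(mat, colnames(df), sampling_rate_hz, session_id)
}

#' Write a recording as matrix CSV
#'
#' Inverse of the matrix-CSV branch of [read_recording()]: header row of
#' channel labels, one sample per row, preceded by a
#' `# sampling_rate_hz=` comment line.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%g", rec$sampling_rate_hz), con)
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_labels
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# ---- EDF ---------------------------------------------------------------
# Minimal EDF/EDF+ continuous-recording support: 256-byte fixed header,
# 256 bytes per signal of field blocks, then data records of little-endian
# 16-bit integers scaled channel-wise between digital and physical ranges.

read_edf_field <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)),
         character(1))
}

read_edf <- function(path, session_id = NA) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8)
  if (!identical(version, "0")) stop("not an EDF file (version field): ", path)
  invisible(read_edf_field(con, 80))            # patient id
  invisible(read_edf_field(con, 80))            # recording id
  invisible(read_edf_field(con, 8))             # start date
  invisible(read_edf_field(con, 8))             # start time
  invisible(read_edf_field(con, 8))             # header bytes
  invisible(read_edf_field(con, 44))            # reserved / EDF+ flag
  n_rec <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF signal count")
  labels <- read_edf_field(con, 16, ns)
  invisible(read_edf_field(con, 80, ns))        # transducer
  phys_dim <- read_edf_field(con, 8, ns)
  phys_min <- as.numeric(read_edf_field(con, 8, ns))
  phys_max <- as.numeric(read_edf_field(con, 8, ns))
  dig_min <- as.numeric(read_edf_field(con, 8, ns))
  dig_max <- as.numeric(read_edf_field(con, 8, ns))
  invisible(read_edf_field(con, 80, ns))        # prefiltering
  spr <- as.integer(read_edf_field(con, 8, ns)) # samples per record
  invisible(read_edf_field(con, 32, ns))        # reserved
  is_annot <- grepl("ANNOTATION", toupper(labels))
  raw <- vector("list", ns)
  for (k in seq_len(ns)) raw[[k]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      raw[[k]][[r]] <- readBin(con, "integer", n = spr[k], size = 2,
                               signed = TRUE, endian = "little")
    }
  }
  keep <- which(!is_annot)
  rates <- spr[keep] / rec_dur
  if (length(unique(rates)) != 1L)
    stop("non-uniform sampling rate across channels")
  unit_scale <- function(dim) {
    switch(toupper(trimws(dim)), "UV" = 1, "µV" = 1, "MV" = 1e3,
           "V" = 1e6, 1)  # unknown units passed through
  }
  data <- do.call(rbind, lapply(keep, function(k) {
    dig <- unlist(raw[[k]])
    gain <- (phys_max[k] - phys_min[k]) / (dig_max[k] - dig_min[k])
    (dig - dig_min[k]) * gain + phys_min[k]
  }))
  scales <- vapply(phys_dim[keep], unit_scale, numeric(1))
  data <- data * scales
  recording(data, labels[keep], rates[1], session_id)
}

#' Write a recording as EDF
#'
#' Writes a continuous EDF file (1 s data records, 16-bit samples, physical
#' range spanning the data) readable by [read_recording()]. Quantization to
#' the 16-bit digital range makes the round trip accurate to the physical
#' range divided by 2^16, not bit-exact.
#'
#' @param rec An `eeg_recording` with an integral sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate_hz
  if (fs != round(fs)) stop("EDF writer requires an integral sampling rate")
  n <- ncol(rec$data)
  if (n %% fs != 0) stop("EDF writer requires a whole number of 1 s records")
  ns <- nrow(rec$data)
  n_rec <- n %/% fs
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  phys_min <- phys_min - 0.001 * span
  phys_max <- phys_max + 0.001 * span
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("X X X X", 80),
                pad(paste("Startdate 01-JAN-2000", rec$session_id), 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8),
                pad("1", 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste(vapply(vals, pad, "", w = w),
                                           collapse = ""), con, eos = NULL)
  num8 <- function(x) vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    strtrim(s, 8)
  }, character(1))
  phys_min <- as.numeric(num8(phys_min))  # header precision is authoritative
  phys_max <- as.numeric(num8(phys_max))
  fld(rec$channel_labels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(num8(phys_min), 8)
  fld(num8(phys_max), 8)
  fld(rep("-32768", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  gain <- 65535 / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (k in seq_len(ns)) {
      dig <- round((rec$data[k, idx] - phys_min[k]) * gain[k]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

# ---- segments and artifacts -------------------------------------------

#' Extract analysis segments from a recording
#'
#' Cuts the requested time windows from every channel, sample-exact. Windows
#' are half-open, `[start, start + duration)` in seconds, with 0-based sample
#' indexing, so a marker `(10, 30)` at 500 Hz yields samples 5000..19999
#' (15,000 points). No resampling or filtering is applied.
#'
#' @param rec An `eeg_recording`.
#' @param markers A list of `c(start_s, duration_s)` pairs, one per segment.
#' @return A named list (one element per channel) of lists of `eeg_segment`s,
#'   `segment_index` numbered in marker order.
#' @export
extract_segments <- function(rec, markers) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(markers)) stop("no segment markers supplied")
  fs <- rec$sampling_rate_hz
  n_total <- ncol(rec$data)
  win <- lapply(markers, function(mk) {
    start_s <- mk[[1]]; dur_s <- mk[[2]]
    ns <- dur_s * fs
    if (abs(ns - round(ns)) > 1e-9)
      stop("duration x sampling rate must be an integer number of samples")
    ns <- as.integer(round(ns))
    if (ns < 1) stop("segment duration must cover at least one sample")
    start <- round(start_s * fs)
    if (abs(start_s * fs - start) > 1e-9)
      stop("segment start must fall on a sample")
    if (start < 0 || start + ns > n_total)
      stop(sprintf("segment window [%g, %g) s out of bounds for %.3f s recording",
                   start_s, start_s + dur_s, n_total / fs))
    c(start = as.integer(start), n = ns)
  })
  starts <- vapply(win, `[`, integer(1), "start")
  ends <- starts + vapply(win, `[`, integer(1), "n")
  ord <- order(starts)
  if (length(win) > 1 && any(starts[ord][-1] < ends[ord][-length(ord)]))
    warning("segment windows overlap")
  out <- lapply(rec$channel_labels, function(ch) {
    lapply(seq_along(win), function(i) {
      w <- win[[i]]
      segment(rec$data[ch, (w["start"] + 1):(w["start"] + w["n"])], fs,
              channel = ch, segment_index = i)
    })
  })
  names(out) <- rec$channel_labels
  out
}

#' Amplitude/gradient artifact flag
#'
#' Automated stand-in for visual artifact rejection: a segment is clean iff
#' no sample exceeds `amp_limit_uv` in absolute value and no successive-sample
#' difference exceeds `grad_limit_uv`. Defaults (100 µV, 50 µV/sample) suit
#' eyes-closed resting EEG; both are configurable.
#'
#' @param seg An `eeg_segment` or numeric vector.
#' @param amp_limit_uv Positive amplitude limit in µV.
#' @param grad_limit_uv Positive successive-difference limit in µV.
#' @return `TRUE` if the segment is clean, else `FALSE`.
#' @export
flag_artifacts <- function(seg, amp_limit_uv = 100, grad_limit_uv = 50) {
  if (!(amp_limit_uv > 0) || !(grad_limit_uv > 0))
    stop("limits must be positive")
  x <- if (inherits(seg, "eeg_segment")) seg$samples else as.numeric(seg)
  if (any(abs(x) > amp_limit_uv)) return(FALSE)
  if (length(x) > 1 && any(abs(diff(x)) > grad_limit_uv)) return(FALSE)
  TRUE
}

# ---- tabular inputs ----------------------------------------------------

#' Read the per-session clinical table
#'
#' CSV with columns `session`, `condition`, `bfcrs`, `bdnf_ng_ml`. Conditions
#' must come from the four-level vocabulary `pre_ect`, `during_ect`,
#' `after_ect`, `lorazepam`. BFCRS is a non-negative integer score
#' (Bush-Francis Catatonia Rating Scale; may be missing), and serum BDNF in
#' ng/ml is typically sparse (missing cells allowed).
#'
#' @param path CSV path.
#' @return A data frame with one row per session.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty clinical table: ", path)
  need <- c("session", "condition", "bfcrs", "bdnf_ng_ml")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  if (any(df$bfcrs < 0, na.rm = TRUE)) stop("negative BFCRS score")
  if (any(df$bdnf_ng_ml <= 0, na.rm = TRUE)) stop("non-positive BDNF value")
  df[need]
}

#' Read the ECT course table
#'
#' CSV with columns exactly `session`, `stimulation`, `percent_energy`,
#' `charge_mC`, `seizure_duration_s`: one row per stimulation, charge in
#' millicoulombs, motor/EEG seizure duration in seconds (0 = failed seizure).
#'
#' @param path CSV path.
#' @return An object of class `ect_course_table` (a data frame).
#' @export
read_course_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_course_table(df)
}

as_course_table <- function(df) {
  need <- c("session", "stimulation", "percent_energy", "charge_mC",
            "seizure_duration_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("course table missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("empty course table")
  if (any(df$charge_mC <= 0)) stop("charge_mC must be positive")
  if (any(df$seizure_duration_s < 0)) stop("seizure_duration_s must be >= 0")
  s <- sort(unique(df$session))
  if (length(s) > 1 && any(diff(s) != 1))
    stop("session numbers must be contiguous")
  structure(df[need], class = c("ect_course_table", "data.frame"))
}

#' Read a session manifest
#'
#' YAML (or CSV) listing, per session: `id`, `condition`, the recording
#' `file`, and segment `markers` (list of `[start_s, duration_s]`). Paths are
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest path (`.yaml`/`.yml` or `.csv`).
#' @return A list of session entries.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  base <- dirname(path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    man <- yaml::read_yaml(path)
    sessions <- man$sessions
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    sessions <- lapply(seq_len(nrow(df)), function(i) {
      list(id = df$id[i], condition = df$condition[i], file = df$file[i],
           markers = list(c(df$start1_s[i], df$duration_s[i]),
                          c(df$start2_s[i], df$duration_s[i])))
    })
  }
  if (!length(sessions)) stop("empty manifest: ", path)
  lapply(sessions, function(s) {
    if (is.null(s$id) || is.null(s$condition) || is.null(s$file))
      stop("manifest entries need id, condition, file")
    if (!s$condition %in% CONDITIONS)
      stop("unknown condition label: ", s$condition)
    s$file <- file.path(base, s$file)
    if (is.null(s$markers)) s$markers <- list(c(0, 30), c(30, 30))
    s$markers <- lapply(s$markers, as.numeric)
    s
  })
}
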