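#' Multichannel EEG recording
#'
#' @param data electrodes x samples matrix (uV), rownames = labels.
#' @param fs sampling rate (Hz).
#' @param labels electrode labels (10-10 names); default taken from
#'   `rownames(data)`.
#' @param impedances per-electrode impedance (kOhm), recycled if scalar.
#' @param trial_onsets integer sample indices of stimulus onsets (eyes open)
#'   or `NULL` (eyes closed). Must be strictly increasing and at least
#'   `0.5 s * fs` from the start.
#' @param subject list with `id`, `age` (years), `gender` (`"M"`/`"F"`),
#'   `diagnosis` (`"healthy"`, `"mci"`, `"ad"`).
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param reference `"unipolar"` or `"bipolar"`.
#' @param eye_eccentricity optional list with `fs` and `traces`
#'   (repeats x samples, degrees) covering -0.5..0.75 s around each onset.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = rownames(data),
                          impedances = 5, trial_onsets = NULL,
                          subject = list(id = "s1", age = NA_real_,
                                         gender = NA_character_,
                                         diagnosis = "healthy"),
                          condition = c("eyes_open", "eyes_closed"),
                          reference = c("unipolar", "bipolar"),
                          eye_eccentricity = NULL) {
  condition <- match.arg(condition)
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (is.null(labels)) stop("electrode labels are required")
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  stopifnot(length(labels) == nrow(data), fs > 0)
  impedances <- rep_len(impedances, nrow(data))
  if (any(impedances < 0)) stop("impedances must be >= 0")
  names(impedances) <- labels
  rownames(data) <- labels
  if (!is.null(trial_onsets)) {
    trial_onsets <- as.integer(trial_onsets)
    if (any(diff(trial_onsets) <= 0))
      stop("trial onsets must be strictly increasing")
  }
  structure(list(data = data, fs = fs, labels = labels,
                 impedances = impedances, trial_onsets = trial_onsets,
                 subject = subject, condition = condition,
                 reference = reference,
                 eye_eccentricity = eye_eccentricity),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", nrow(x$data), "electrodes x", ncol(x$data),
      sprintf("samples @ %g Hz (%.1f s), %s, %s-referenced\n",
              x$fs, ncol(x$data) / x$fs, x$condition, x$reference))
  if (!is.null(x$trial_onsets))
    cat(" ", length(x$trial_onsets), "trial onsets\n")
  invisible(x)
}

#' Write a recording to disk
#'
#' Internal layout: `<stem>.f32` (electrodes x samples, little-endian 32-bit
#' float, uV, sample-major per electrode) plus JSON sidecar `<stem>.json`
#' (fs, labels, impedances, trial onsets, subject metadata). EDF: 16-bit
#' with physical range chosen so quantisation is `lsb_uv` per bit
#' (default 0.1 uV/bit, the acquisition resolution); metadata that EDF
#' cannot carry goes to the same JSON sidecar.
#'
#' @param rec an [eeg_recording].
#' @param path output stem or file name (extension added/replaced).
#' @param format `"internal"` or `"edf"`.
#' @param lsb_uv EDF quantisation step (uV per bit).
#' @return Invisibly, the path of the main data file.
#' @export
write_recording <- function(rec, path, format = c("internal", "edf"),
                            lsb_uv = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  stem <- sub("\\.(f32|edf|json)$", "", path)
  sidecar <- list(
    fs = rec$fs, n_electrodes = nrow(rec$data), n_samples = ncol(rec$data),
    labels = rec$labels, impedances_kohm = unname(rec$impedances),
    trial_onsets = rec$trial_onsets, subject = rec$subject,
    condition = rec$condition, reference = rec$reference
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  main <- if (format == "internal") {
    f <- paste0(stem, ".f32")
    con <- file(f, "wb")
    on.exit(close(con))
    # sample-major per electrode: electrode 1's samples, then electrode 2's
    writeBin(as.vector(t(rec$data)), con, size = 4, endian = "little")
    f
  } else {
    f <- paste0(stem, ".edf")
    write_edf(rec, f, lsb_uv = lsb_uv)
    f
  }
  invisible(main)
}

#' Read a recording written by [write_recording()]
#'
#' @param path stem or data file path.
#' @param format `"internal"` or `"edf"`.
#' @return An [eeg_recording]. Internal layout round-trips to within
#'   float32 precision; EDF to within half the quantisation step.
#' @export
read_recording <- function(path, format = c("internal", "edf")) {
  format <- match.arg(format)
  stem <- sub("\\.(f32|edf|json)$", "", path)
  side_path <- paste0(stem, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar file: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (is.null(side$fs) || is.null(side$labels))
    stop("malformed sidecar (need at least fs and labels): ", side_path)
  dat <- if (format == "internal") {
    f <- paste0(stem, ".f32")
    if (!file.exists(f)) stop("missing data file: ", f)
    n <- side$n_electrodes * side$n_samples
    con <- file(f, "rb")
    on.exit(close(con))
    v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    matrix(v, nrow = side$n_electrodes, byrow = TRUE)
  } else {
    read_edf(paste0(stem, ".edf"))$data
  }
  rownames(dat) <- side$labels
  known <- unique(unlist(.electrode_groups[1:5], use.names = FALSE))
  if (!any(side$labels %in% c(known, "FCz", "Fpz")))
    warning("unknown electrode label set; passing labels through unchanged")
  eeg_recording(
    data = dat, fs = side$fs, labels = side$labels,
    impedances = side$impedances_kohm,
    trial_onsets = if (length(side$trial_onsets)) side$trial_onsets,
    subject = side$subject, condition = side$condition,
    reference = side$reference
  )
}

# --- minimal EDF (European Data Format) writer/reader -----------------------
# Plain EDF: 256-byte fixed header, 256 bytes per signal header, then
# int16 little-endian data records. One-second records; the recording is
# truncated to whole records (with a warning) if needed.

edf_pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")

write_edf <- function(rec, path, lsb_uv = 0.1) {
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$fs))         # samples per 1-s record
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * spr < ncol(rec$data))
    warning("EDF export truncated to ", n_rec, " whole 1-s records")
  dig_min <- -32768; dig_max <- 32767
  phys_min <- dig_min * lsb_uv; phys_max <- dig_max * lsb_uv
  hdr <- paste0(
    edf_pad("0", 8),                                   # version
    edf_pad(substr(rec$subject$id, 1, 80), 80),        # patient id
    edf_pad("specslope", 80),                          # recording id
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),    # start date/time
    edf_pad(256 + 256 * ns, 8),                        # header bytes
    edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)   # records, dur, ns
  )
  sig <- paste0(
    paste(edf_pad(rec$labels, 16), collapse = ""),
    paste(rep(edf_pad("AgAgCl", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(phys_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(phys_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  dig <- pmin(pmax(round(rec$data / lsb_uv), dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(fld(hdr, 237, 8))
  dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  grab <- function(off0, len) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig, off0 + (i - 1) * len + 1, off0 + i * len)), "")
  }
  labels <- grab(0, 16)
  phys_min <- as.numeric(grab(ns * (16 + 80 + 8), 8))
  phys_max <- as.numeric(grab(ns * (16 + 80 + 8 + 8), 8))
  dig_min <- as.numeric(grab(ns * (16 + 80 + 8 + 8 + 8), 8))
  dig_max <- as.numeric(grab(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(grab(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dat <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    v <- readBin(con, "integer", n = sum(spr), size = 2, endian = "little",
                 signed = TRUE)
    m <- matrix(v, nrow = spr[1])                      # equal spr assumed
    dat[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(m) * gain + (phys_min - dig_min * gain)
  }
  rownames(dat) <- labels
  list(data = dat, fs = spr[1] / dur, labels = labels)
}
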