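#' Epoched EEG data
#'
#' @param epochs electrodes x repeats x samples array (uV).
#' @param fs sampling rate (Hz).
#' @param window `(start, end)` in seconds relative to the trial marker
#'   (eyes open) or segment start (eyes closed); half-open `[start, end)`.
#' @param labels electrode labels.
#' @param impedances per-electrode impedances (kOhm).
#' @return An object of class `epoch_set`. Per-(electrode, repeat) `flags`
#'   start as `"good"` and become `"outlier"` or `"bad_common"` during
#'   preprocessing; per-electrode `electrode_status` starts `"good"`.
#' @export
epoch_set <- function(epochs, fs, window, labels = dimnames(epochs)[[1]],
                      impedances = NULL) {
  stopifnot(length(dim(epochs)) == 3L)
  n_el <- dim(epochs)[1]; n_rep <- dim(epochs)[2]
  if (is.null(labels)) labels <- paste0("ch", seq_len(n_el))
  flags <- matrix("good", n_el, n_rep, dimnames = list(labels, NULL))
  structure(list(epochs = epochs, fs = fs, window = window, labels = labels,
                 impedances = impedances,
                 flags = flags,
                 electrode_status = setNames(rep("good", n_el), labels)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d electrodes x %d repeats x %d samples @ %g Hz, window [%g, %g) s\n",
              d[1], d[2], d[3], x$fs, x$window[1], x$window[2]))
  cat(sprintf("  %d repeats flagged, %d electrodes rejected\n",
              sum(apply(x$flags != "good", 2, any)),
              sum(x$electrode_status != "good")))
  invisible(x)
}

# good repeats for one electrode: neither its own outliers nor common-bad
good_repeats <- function(es, i) which(es$flags[i, ] == "good")

#' Segment a recording into analysis epochs
#'
#' Eyes open: one repeat per trial onset, the 500 ms pre-stimulus window
#' `[-0.5, 0)` s. Eyes closed: consecutive non-overlapping 2-s segments.
#' Sample index is `round(t * fs)`; the window is half-open so the onset
#' sample is not double counted.
#'
#' @param rec an [eeg_recording].
#' @param mode `"eyes_open"` or `"eyes_closed"`; defaults to the
#'   recording's condition.
#' @param window eyes-open analysis window (s, relative to onset).
#' @param epoch_s eyes-closed segment length (s).
#' @return An [epoch_set].
#' @export
segment_epochs <- function(rec, mode = rec$condition,
                           window = c(-0.5, 0), epoch_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  mode <- match.arg(mode, c("eyes_open", "eyes_closed"))
  fs <- rec$fs
  n_el <- nrow(rec$data)
  if (mode == "eyes_open") {
    if (is.null(rec$trial_onsets)) stop("eyes_open segmentation requires trial onsets")
    len <- round((window[2] - window[1]) * fs)
    starts <- rec$trial_onsets + round(window[1] * fs)
    ok <- starts >= 1 & (starts + len - 1) <= ncol(rec$data)
    if (any(!ok))
      warning(sum(!ok), " trial(s) too close to the recording edge skipped")
    starts <- starts[ok]
    if (length(starts) == 0L) stop("no usable repeats after segmentation")
    arr <- array(0, dim = c(n_el, length(starts), len),
                 dimnames = list(rec$labels, NULL, NULL))
    for (r in seq_along(starts))
      arr[, r, ] <- rec$data[, starts[r]:(starts[r] + len - 1)]
    epoch_set(arr, fs, window, rec$labels, rec$impedances)
  } else {
    len <- round(epoch_s * fs)
    n_rep <- floor(ncol(rec$data) / len)
    if (n_rep == 0L) stop("recording shorter than one ", epoch_s, " s epoch")
    arr <- array(0, dim = c(n_el, n_rep, len),
                 dimnames = list(rec$labels, NULL, NULL))
    for (r in seq_len(n_rep))
      arr[, r, ] <- rec$data[, ((r - 1) * len + 1):(r * len)]
    epoch_set(arr, fs, c(0, epoch_s), rec$labels, rec$impedances)
  }
}
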