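#' Line-noise "noise peak" bands
#'
#' Bands of `+/- half_width` Hz around the mains frequency and its
#' harmonics, up to `f_max`.
#'
#' @param f_line mains frequency (Hz, default 50).
#' @param half_width half-width of each band (Hz, default 4).
#' @param f_max ceiling (Hz).
#' @return Data frame with columns `lo`, `hi`, one row per harmonic.
#' @export
noise_peaks <- function(f_line = 50, half_width = 4, f_max = 1000) {
  k <- seq_len(floor(f_max / f_line))
  data.frame(lo = k * f_line - half_width, hi = k * f_line + half_width)
}

#' Sliding-window grid for slope profiling
#'
#' Windows of `width` Hz at centres `centre_range[1], +step, ...,
#' centre_range[2]`, clipped to `[f_min, f_max]`; the first and last
#' windows are slightly narrower because of the clipping.
#'
#' @param f_min,f_max frequency limits (Hz).
#' @param step centre spacing (Hz).
#' @param width window width (Hz).
#' @param centre_range first and last centre frequency (Hz).
#' @return Data frame with columns `centre`, `lo`, `hi` (47 rows with the
#'   defaults; first window `[4, 90]`, last `[910, 1000]`).
#' @export
make_windows <- function(f_min = 4, f_max = 1000, step = 20, width = 100,
                         centre_range = c(40, 960)) {
  stopifnot(step > 0, width > 0, step <= width)
  centres <- seq(centre_range[1], centre_range[2], by = step)
  data.frame(centre = centres,
             lo = pmax(centres - width / 2, f_min),
             hi = pmin(centres + width / 2, f_max))
}

# does x lie inside any closed band [lo, hi]?
in_band <- function(x, bands) {
  if (is.null(bands) || nrow(bands) == 0L) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(bands)))
    out <- out | (x >= bands$lo[i] & x <= bands$hi[i])
  out
}

fit_one_window <- function(fp, lo, hi, settings, noise, min_slope, method) {
  miss <- function(reason) list(exponent = NA_real_, offset = NA_real_,
                                r_squared = NA_real_, reason = reason)
  if (any(in_band(c(lo, hi), noise))) return(miss("noise_peak_at_edge"))
  eb <- if (is.null(noise)) NULL else cbind(noise$lo, noise$hi)
  fit <- tryCatch({
    if (method == "model") {
      f <- fit_spectral_model(fp, c(lo, hi), settings, exclude_bands = eb)
      if (f$status != "ok") stop("fit failed")
      f
    } else {
      fit_loglog_line(fp, c(lo, hi), exclude_bands = eb)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(miss("fit_failed"))
  if (fit$exponent < min_slope) return(miss("below_min_slope"))
  list(exponent = fit$exponent, offset = fit$offset,
       r_squared = fit$r_squared, reason = NA_character_)
}

#' Sliding-window aperiodic slope profile
#'
#' For each window: if either endpoint lies inside a noise band the window
#' is excluded (`noise_peak_at_edge`); otherwise bins inside noise bands are
#' removed and the window is fitted. Fitted exponents below `min_slope`
#' (default 0.01, indicating poor fits) are recorded as missing
#' (`below_min_slope`). Missingness is data, not an error.
#'
#' @param spectrum an [eeg_spectrum] (first row) or list `freqs`/`power`.
#' @param settings a [fit_settings()] object (used by the model fit).
#' @param noise noise bands from [noise_peaks()]; `NULL` disables exclusion.
#' @param min_slope minimum usable exponent.
#' @param windows window grid from [make_windows()].
#' @param method `"model"` (iterative aperiodic + peaks fit, the default)
#'   or `"loglog"` (direct line fit).
#' @return A `slope_profile` data frame: `centre`, `lo`, `hi`, `exponent`,
#'   `offset`, `r_squared`, `reason` (`NA` when fitted).
#' @export
sliding_slopes <- function(spectrum, settings = fit_settings(),
                           noise = noise_peaks(), min_slope = 0.01,
                           windows = make_windows(),
                           method = c("model", "loglog")) {
  method <- match.arg(method)
  fp <- spectrum_vectors(spectrum)
  rows <- lapply(seq_len(nrow(windows)), function(i)
    fit_one_window(fp, windows$lo[i], windows$hi[i], settings, noise,
                   min_slope, method))
  out <- data.frame(
    centre = windows$centre, lo = windows$lo, hi = windows$hi,
    exponent = vapply(rows, `[[`, 0, "exponent"),
    offset = vapply(rows, `[[`, 0, "offset"),
    r_squared = vapply(rows, `[[`, 0, "r_squared"),
    reason = vapply(rows, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("slope_profile", "data.frame")
  out
}

#' Fixed-band aperiodic slope
#'
#' Same fitting and exclusion contract as [sliding_slopes()] on a single
#' fixed band: the low-frequency range `LFR = (64, 140)` Hz, the
#' high-frequency range `HFR = (230, 430)` Hz, or a custom `(lo, hi)`.
#'
#' @param spectrum an [eeg_spectrum] or list `freqs`/`power`.
#' @param band `"LFR"`, `"HFR"`, or numeric `(lo, hi)` Hz.
#' @inheritParams sliding_slopes
#' @return One-row `slope_profile` data frame (exponent `NA` with a
#'   `reason` when excluded).
#' @export
band_slope <- function(spectrum, band = c("LFR", "HFR"),
                       settings = fit_settings(), noise = noise_peaks(),
                       min_slope = 0.01, method = c("model", "loglog")) {
  method <- match.arg(method)
  if (is.character(band)) {
    band <- match.arg(band)
    band <- if (band == "LFR") c(64, 140) else c(230, 430)
  }
  fp <- spectrum_vectors(spectrum)
  row <- fit_one_window(fp, band[1], band[2], settings, noise, min_slope,
                        method)
  out <- data.frame(centre = mean(band), lo = band[1], hi = band[2],
                    exponent = row$exponent, offset = row$offset,
                    r_squared = row$r_squared, reason = row$reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("slope_profile", "data.frame")
  out
}

#' Extract the alpha peak centre frequency from a fit
#'
#' @param fit an `aperiodic_fit`.
#' @param band alpha band (Hz, default 8--12).
#' @return Centre frequency (Hz) of the highest-amplitude peak inside the
#'   band, or `NA` if none.
#' @export
extract_alpha_peak <- function(fit, band = c(8, 12)) {
  stopifnot(inherits(fit, "aperiodic_fit"))
  pk <- fit$peaks
  pk <- pk[pk$centre >= band[1] & pk$centre <= band[2], , drop = FALSE]
  if (nrow(pk) == 0L) return(NA_real_)
  pk$centre[which.max(pk$height)]
}

#' Locate the spectral "knee" in a slope profile
#'
#' The knee is taken as the centre frequency at which the sliding-window
#' exponent is minimal within `search_range` (ties resolved to the lowest
#' frequency). If the minimum sits at the edge of the searched points the
#' result is flagged as a boundary solution.
#'
#' @param profile a `slope_profile` from [sliding_slopes()].
#' @param search_range `(lo, hi)` Hz for the search (default 100--300).
#' @return List with `f_knee` (Hz or `NA`) and `boundary` (logical).
#' @export
find_knee <- function(profile, search_range = c(100, 300)) {
  sel <- profile$centre >= search_range[1] & profile$centre <= search_range[2] &
    !is.na(profile$exponent)
  if (sum(sel) < 3) return(list(f_knee = NA_real_, boundary = NA))
  ctr <- profile$centre[sel]; ex <- profile$exponent[sel]
  i <- which(ex == min(ex))[1]
  list(f_knee = ctr[i], boundary = i == 1L || i == length(ctr))
}

#' Timescale associated with a knee frequency
#'
#' `tau = 1 / (2 pi f_knee)` seconds.
#'
#' @param f_knee knee frequency (Hz, > 0).
#' @return Timescale in seconds.
#' @export
knee_timescale <- function(f_knee) {
  stopifnot(f_knee > 0)
  1 / (2 * pi * f_knee)
}
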