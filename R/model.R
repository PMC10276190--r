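#' Parameters of the aperiodic + periodic spectral model
#'
#' The model PSD is, in log10-power space,
#' \deqn{\log_{10} P(f) = \log_{10} AP(f) + \sum_n G_n(f)}
#' where the aperiodic component is \eqn{AP(f) = 10^b f^{-\chi}} (or, with a
#' knee, \eqn{AP(f) = 10^b / (f_k^{\chi} + f^{\chi})}) and each periodic
#' component \eqn{G_n(f) = a_n \exp(-(f-\mu_n)^2 / 2\sigma_n^2)} is a
#' Gaussian in log10 power. Peaks therefore add in log-power space, the
#' space in which the model is fit; see the methods vignette.
#'
#' @param offset log10-power offset \eqn{b} (log10 uV^2/Hz).
#' @param exponent aperiodic exponent \eqn{\chi} (positive = power falls
#'   with frequency; typically 0--4).
#' @param knee_freq optional knee frequency in Hz; `NULL` (default) gives a
#'   single power law.
#' @param peaks `NULL` or a data frame with columns `height` (log10 power),
#'   `centre` (Hz) and `width` (Hz, Gaussian sigma).
#' @param line_noise `NULL` or a data frame with columns `freq` (Hz) and
#'   `amplitude` (uV, sinusoid amplitude).
#' @param emg_band `NULL` or a list with elements `f_lo`, `f_hi`,
#'   `peak_freq` (Hz) and `height` (log10 power): a log-Gaussian-in-frequency
#'   hump emulating band-limited EMG-like noise.
#' @return An object of class `spectral_model_params`.
#' @export
spectral_model_params <- function(offset = 2, exponent = 1.2,
                                  knee_freq = NULL, peaks = NULL,
                                  line_noise = NULL, emg_band = NULL) {
  stopifnot(is.numeric(offset), length(offset) == 1L, is.finite(offset))
  stopifnot(is.numeric(exponent), length(exponent) == 1L, is.finite(exponent))
  if (!is.null(knee_freq))
    stopifnot(is.finite(knee_freq), knee_freq > 0)
  if (!is.null(peaks)) {
    peaks <- as.data.frame(peaks)
    stopifnot(all(c("height", "centre", "width") %in% names(peaks)))
    if (any(peaks$width <= 0)) stop("peak widths must be > 0")
    if (any(peaks$centre <= 0)) stop("peak centres must be > 0 Hz")
  }
  if (!is.null(line_noise)) {
    line_noise <- as.data.frame(line_noise)
    stopifnot(all(c("freq", "amplitude") %in% names(line_noise)))
    stopifnot(all(line_noise$freq > 0))
  }
  if (!is.null(emg_band)) {
    stopifnot(is.list(emg_band),
              all(c("f_lo", "f_hi", "peak_freq", "height") %in% names(emg_band)))
    stopifnot(emg_band$f_lo > 0, emg_band$f_hi > emg_band$f_lo)
  }
  structure(list(offset = offset, exponent = exponent, knee_freq = knee_freq,
                 peaks = peaks, line_noise = line_noise, emg_band = emg_band),
            class = "spectral_model_params")
}

#' @export
print.spectral_model_params <- function(x, ...) {
  cat("<spectral_model_params> b =", format(x$offset),
      " chi =", format(x$exponent),
      if (!is.null(x$knee_freq)) paste(" knee =", x$knee_freq, "Hz"),
      "\n")
  if (!is.null(x$peaks)) {
    cat("  peaks (height, centre Hz, width Hz):\n")
    print(x$peaks, row.names = FALSE)
  }
  invisible(x)
}

# log10 of the aperiodic component; vectorised over f
aperiodic_log10 <- function(f, offset, exponent, knee_freq = NULL) {
  if (is.null(knee_freq)) {
    offset - exponent * log10(f)
  } else {
    offset - log10(knee_freq^exponent + f^exponent)
  }
}

# summed log10-power contribution of Gaussian peaks (in linear frequency)
peaks_log10 <- function(f, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(numeric(length(f)))
  out <- numeric(length(f))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$height[i] *
      exp(-((f - peaks$centre[i])^2) / (2 * peaks$width[i]^2))
  }
  out
}

# log10-power EMG-like hump: Gaussian in log10(f) centred at peak_freq,
# with width set from the band so the hump is confined to [f_lo, f_hi]
emg_log10 <- function(f, emg_band) {
  if (is.null(emg_band)) return(numeric(length(f)))
  s <- (log10(emg_band$f_hi) - log10(emg_band$f_lo)) / 4
  emg_band$height * exp(-((log10(f) - log10(emg_band$peak_freq))^2) / (2 * s^2))
}

#' Evaluate the model PSD on a frequency grid
#'
#' Returns the noiseless model power spectral density. With no peaks,
#' `log10 P(f) = b - chi * log10 f` exactly. Sinusoidal line-noise
#' components contribute their power (`amplitude^2 / 2`) to the single
#' nearest frequency bin, divided by the bin width.
#'
#' @param params a [spectral_model_params()] object.
#' @param freqs strictly positive, strictly increasing frequency grid (Hz).
#' @return An [eeg_spectrum] with one row named `"model"` (uV^2/Hz).
#' @export
evaluate_model_psd <- function(params, freqs) {
  stopifnot(inherits(params, "spectral_model_params"))
  if (any(freqs <= 0)) stop("frequencies must be strictly positive (power law undefined at 0)")
  if (any(diff(freqs) <= 0)) stop("frequencies must be strictly increasing")
  lp <- aperiodic_log10(freqs, params$offset, params$exponent, params$knee_freq) +
    peaks_log10(freqs, params$peaks) +
    emg_log10(freqs, params$emg_band)
  p <- 10^lp
  if (!is.null(params$line_noise) && length(freqs) > 1L) {
    df <- freqs[2] - freqs[1]
    for (i in seq_len(nrow(params$line_noise))) {
      f0 <- params$line_noise$freq[i]
      if (f0 > max(freqs) + df / 2) next
      k <- which.min(abs(freqs - f0))
      p[k] <- p[k] + params$line_noise$amplitude[i]^2 / 2 / df
    }
  }
  eeg_spectrum(freqs = freqs, power = matrix(p, nrow = 1,
                                             dimnames = list("model", NULL)),
               n_repeats = NA_integer_, taper_config = NULL)
}
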