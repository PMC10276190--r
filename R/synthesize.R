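#' Synthesize a single-channel time series with a prescribed PSD
#'
#' Spectral synthesis by inverse real FFT: Fourier amplitudes are set to
#' `sqrt(P(f) * fs * n / 2)` so the expected periodogram of the output
#' equals the target PSD, and phases are drawn independently and uniformly
#' on `[0, 2pi)`. Sinusoidal line-noise components are added in the time
#' domain with random phase. Deterministic given `seed`.
#'
#' @param params a [spectral_model_params()] object, or a function
#'   `f -> PSD` (uV^2/Hz) for a custom broadband target (line noise and
#'   peaks must then be part of the function).
#' @param duration length of the series in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; identical seeds give identical series.
#' @return Numeric vector of `round(duration * fs)` samples (uV).
#' @export
synthesize_timeseries <- function(params, duration, fs, seed = NULL) {
  n <- round(duration * fs)
  if (n < 2) stop("duration * fs must be at least 2 samples")
  psd_fun <- if (is.function(params)) {
    params
  } else {
    stopifnot(inherits(params, "spectral_model_params"))
    bad <- c(params$offset, params$exponent, unlist(params$peaks),
             unlist(params$line_noise))
    if (any(!is.finite(bad))) stop("non-finite model parameters")
    function(f) {
      10^(aperiodic_log10(f, params$offset, params$exponent, params$knee_freq) +
            peaks_log10(f, params$peaks) + emg_log10(f, params$emg_band))
    }
  }
  synth <- function() {
    df <- fs / n
    nh <- floor((n - 1) / 2)           # paired positive-frequency bins
    f <- df * seq_len(nh)
    amp <- sqrt(psd_fun(f) * fs * n / 2)
    xk <- complex(modulus = amp, argument = runif(nh, 0, 2 * pi))
    spec <- complex(length.out = n)    # DC stays 0 (zero-mean signal)
    spec[1L + seq_len(nh)] <- xk
    spec[n + 1L - seq_len(nh)] <- Conj(xk)
    if (n %% 2 == 0) {                 # unpaired Nyquist bin is real
      spec[n / 2 + 1] <- sample(c(-1, 1), 1) * sqrt(psd_fun(fs / 2) * fs * n)
    }
    x <- Re(fft(spec, inverse = TRUE)) / n
    if (!is.function(params) && !is.null(params$line_noise)) {
      tt <- seq_len(n) / fs
      for (i in seq_len(nrow(params$line_noise))) {
        f0 <- params$line_noise$freq[i]
        if (f0 >= fs / 2) next
        x <- x + params$line_noise$amplitude[i] *
          sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
      }
    }
    x
  }
  if (is.null(seed)) synth() else withr::with_seed(seed, synth())
}
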