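#' Trial-averaged power spectrum container
#'
#' @param freqs frequency grid (Hz), uniform spacing `df = 1/epoch length`.
#' @param power electrodes x frequencies matrix (uV^2/Hz); rows of `NA` mark
#'   electrodes with no good repeats.
#' @param n_repeats repeats averaged per electrode.
#' @param taper_config list `(nw, n_tapers, type)`.
#' @return An object of class `eeg_spectrum`.
#' @export
eeg_spectrum <- function(freqs, power, n_repeats = NA_integer_,
                         taper_config = NULL) {
  power <- as.matrix(power)
  stopifnot(ncol(power) == length(freqs))
  structure(list(freqs = freqs, power = power, n_repeats = n_repeats,
                 taper_config = taper_config),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d electrode(s), %d bins, df = %g Hz, %g-%g Hz\n",
              nrow(x$power), length(x$freqs),
              if (length(x$freqs) > 1) x$freqs[2] - x$freqs[1] else NA,
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

# single-taper PSD of one epoch (vector), one-sided, uV^2/Hz.
# taper has unit sum of squares so that sum(psd)*df ~= var(x).
single_taper_psd <- function(x, fs, taper) {
  n <- length(x)
  xf <- fft(x * taper)
  nh <- floor(n / 2)
  p <- (2 / fs) * Mod(xf[1:(nh + 1)])^2
  p[1] <- p[1] / 2
  if (n %% 2 == 0) p[nh + 1] <- p[nh + 1] / 2
  p   # frequencies 0, df, ..., nh*df
}

#' Trial-averaged single-taper (multitaper) PSD
#'
#' Computes a tapered periodogram per repeat and averages over the good
#' repeats of each electrode, which reduces the variance of the spectral
#' estimator roughly as 1/n. Frequency spacing is the reciprocal of the
#' epoch length (2 Hz for 500 ms epochs, 0.5 Hz for 2 s epochs).
#'
#' @param epochs an [epoch_set]; repeats flagged non-good and electrodes
#'   with non-good status are excluded.
#' @param nw time-bandwidth product of the Slepian taper (default 1).
#' @param n_tapers number of tapers; only 1 is supported (the analysis
#'   setting).
#' @param taper `"dpss"` or `"hann"`.
#' @return An [eeg_spectrum] (DC bin dropped). Electrodes with no good
#'   repeat get all-`NA` power.
#' @export
multitaper_psd <- function(epochs, nw = 1, n_tapers = 1,
                           taper = c("dpss", "hann")) {
  stopifnot(inherits(epochs, "epoch_set"))
  taper <- match.arg(taper)
  if (n_tapers != 1) stop("only the single-taper estimator is implemented")
  d <- dim(epochs$epochs)
  h <- if (taper == "dpss") dpss_taper(d[3], nw) else hann_taper(d[3])
  nh <- floor(d[3] / 2)
  freqs <- (epochs$fs / d[3]) * (1:nh)
  pw <- matrix(NA_real_, d[1], nh, dimnames = list(epochs$labels, NULL))
  n_used <- integer(d[1])
  for (i in seq_len(d[1])) {
    if (epochs$electrode_status[i] != "good") next
    reps <- good_repeats(epochs, i)
    if (length(reps) == 0L) next
    acc <- numeric(nh)
    for (r in reps)
      acc <- acc + single_taper_psd(epochs$epochs[i, r, ], epochs$fs, h)[-1]
    pw[i, ] <- acc / length(reps)
    n_used[i] <- length(reps)
  }
  eeg_spectrum(freqs, pw, n_repeats = n_used,
               taper_config = list(nw = nw, n_tapers = 1, type = taper))
}

check_same_grid <- function(a, b) {
  if (length(a$freqs) != length(b$freqs) ||
      any(abs(a$freqs - b$freqs) > 1e-9))
    stop("spectra are on different frequency grids")
}

#' Median power change between two groups, in decibels
#'
#' `10 * (log10 median_a(f) - log10 median_b(f))`: the log of the power
#' ratio, i.e. the multiplicative scaling that maps group b's spectrum onto
#' group a's.
#'
#' @param spec_a,spec_b [eeg_spectrum] objects on identical grids; rows are
#'   subjects (or electrodes) and the median is taken across rows.
#' @return Numeric vector (dB) per frequency; `NA` where a median is zero.
#' @export
power_change_db <- function(spec_a, spec_b) {
  check_same_grid(spec_a, spec_b)
  ma <- apply(spec_a$power, 2, median, na.rm = TRUE)
  mb <- apply(spec_b$power, 2, median, na.rm = TRUE)
  out <- 10 * (log10(ma) - log10(mb))
  out[ma <= 0 | mb <= 0] <- NA_real_
  out
}

#' Median power change between two groups, on a linear scale
#'
#' `median_a(f) - median_b(f)` in uV^2/Hz: under an additive-noise reading,
#' the PSD of the noise that must be added to b to obtain a. May be
#' negative (e.g. where oscillatory power declines).
#'
#' @inheritParams power_change_db
#' @return Numeric vector (uV^2/Hz) per frequency.
#' @export
power_change_linear <- function(spec_a, spec_b) {
  check_same_grid(spec_a, spec_b)
  apply(spec_a$power, 2, median, na.rm = TRUE) -
    apply(spec_b$power, 2, median, na.rm = TRUE)
}

#' Pool a subject's spectra over an electrode group
#'
#' Averages log10 power across the good electrodes of the group and
#' exponentiates back (log-domain pooling respects the power-law structure;
#' pooling two power laws with exponents 1 and 2 gives exponent 1.5).
#'
#' @param spectrum an [eeg_spectrum] with electrode rows.
#' @param group electrode labels to pool.
#' @return An [eeg_spectrum] with a single row named after the group, or
#'   all-`NA` power if no group electrode has a spectrum.
#' @export
pool_group <- function(spectrum, group) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  rows <- intersect(group, rownames(spectrum$power))
  sub <- spectrum$power[rows, , drop = FALSE]
  sub <- sub[!apply(is.na(sub), 1, all), , drop = FALSE]
  p <- if (nrow(sub) == 0L) {
    rep(NA_real_, length(spectrum$freqs))
  } else {
    10^colMeans(log10(sub))
  }
  eeg_spectrum(spectrum$freqs,
               matrix(p, nrow = 1, dimnames = list("pooled", NULL)),
               n_repeats = spectrum$n_repeats,
               taper_config = spectrum$taper_config)
}
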