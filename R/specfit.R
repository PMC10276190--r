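#' Spectral model fit settings
#'
#' The five fixed fitting settings, with peak width limits depending on the
#' frequency resolution of the condition: `[4, 8]` Hz for eyes open (2 Hz
#' bins), `[1, 8]` Hz for eyes closed (0.5 Hz bins).
#'
#' @param condition `"eyes_open"` or `"eyes_closed"` (sets default width
#'   limits).
#' @param peak_width_limits full-width limits (Hz) for fitted peaks;
#'   Gaussian sigma is clamped to half these values.
#' @param max_n_peaks maximum number of peaks.
#' @param min_peak_height minimum peak height (log10 power).
#' @param peak_threshold detection threshold in SD units of the flattened
#'   spectrum.
#' @param aperiodic_mode only `"fixed"` (single power law) is supported.
#' @param ap_percentile robust aperiodic refit percentile (see vignette).
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(condition = c("eyes_open", "eyes_closed"),
                         peak_width_limits = NULL,
                         max_n_peaks = 5, min_peak_height = 0.2,
                         peak_threshold = 2.0,
                         aperiodic_mode = "fixed",
                         ap_percentile = 0.025) {
  condition <- match.arg(condition)
  if (is.null(peak_width_limits))
    peak_width_limits <- if (condition == "eyes_open") c(4, 8) else c(1, 8)
  stopifnot(peak_width_limits[1] < peak_width_limits[2])
  if (aperiodic_mode != "fixed")
    stop("only aperiodic_mode = 'fixed' is supported")
  structure(list(condition = condition,
                 peak_width_limits = peak_width_limits,
                 max_n_peaks = max_n_peaks,
                 min_peak_height = min_peak_height,
                 peak_threshold = peak_threshold,
                 aperiodic_mode = aperiodic_mode,
                 ap_percentile = ap_percentile),
            class = "fit_settings")
}

# OLS line on (log10 f, log10 P); returns c(offset, exponent)
loglog_ols <- function(lf, lp) {
  mlf <- mean(lf); mlp <- mean(lp)
  slope <- sum((lf - mlf) * (lp - mlp)) / sum((lf - mlf)^2)
  c(offset = mlp - slope * mlf, exponent = -slope)
}

# robust aperiodic fit: initial OLS, then refit on the bins whose positive
# residual is below the ap_percentile quantile (drops peak regions)
robust_aperiodic <- function(lf, lp, ap_percentile) {
  init <- loglog_ols(lf, lp)
  res <- lp - (init["offset"] - init["exponent"] * lf)
  res[res < 0] <- 0
  thr <- quantile(res, ap_percentile, names = FALSE)
  keep <- res <= thr
  if (sum(keep) >= 3) loglog_ols(lf[keep], lp[keep]) else init
}

#' Direct log-log straight-line fit of the aperiodic exponent
#'
#' Least-squares line on `log10 P` versus `log10 f`, excluding bins inside
#' `exclude_bands` (e.g. line-noise bands). The negated slope is the
#' aperiodic exponent chi.
#'
#' @param spectrum an [eeg_spectrum] with one electrode row, or a list with
#'   `freqs` and `power` (vector).
#' @param fit_range `(lo, hi)` Hz.
#' @param exclude_bands optional 2-column matrix/data frame of `(lo, hi)`
#'   bands whose bins are removed before fitting.
#' @return List with `offset`, `exponent`, `n_bins`, `r_squared`.
#' @export
fit_loglog_line <- function(spectrum, fit_range, exclude_bands = NULL) {
  fp <- spectrum_vectors(spectrum)
  sel <- fp$freqs >= fit_range[1] & fp$freqs <= fit_range[2] &
    is.finite(fp$power) & fp$power > 0
  if (!is.null(exclude_bands)) {
    eb <- as.matrix(exclude_bands)
    for (i in seq_len(nrow(eb)))
      sel <- sel & !(fp$freqs >= eb[i, 1] & fp$freqs <= eb[i, 2])
  }
  if (sum(sel) < 3) stop("fewer than 3 usable bins in fit range")
  lf <- log10(fp$freqs[sel]); lp <- log10(fp$power[sel])
  co <- loglog_ols(lf, lp)
  fitted <- co["offset"] - co["exponent"] * lf
  r2 <- 1 - sum((lp - fitted)^2) / sum((lp - mean(lp))^2)
  list(offset = unname(co["offset"]), exponent = unname(co["exponent"]),
       n_bins = sum(sel), r_squared = r2)
}

spectrum_vectors <- function(spectrum, row = 1) {
  if (inherits(spectrum, "eeg_spectrum")) {
    list(freqs = spectrum$freqs, power = spectrum$power[row, ])
  } else {
    stopifnot(is.list(spectrum), !is.null(spectrum$freqs))
    list(freqs = spectrum$freqs, power = drop(spectrum$power))
  }
}

gaussian_sum <- function(f, pk) {
  out <- numeric(length(f))
  if (length(pk)) {
    pk <- matrix(pk, ncol = 3, byrow = TRUE)  # (height, centre, width)
    for (i in seq_len(nrow(pk)))
      out <- out + pk[i, 1] * exp(-((f - pk[i, 2])^2) / (2 * pk[i, 3]^2))
  }
  out
}

#' Fit the aperiodic + periodic spectral model
#'
#' Iterative fit in log10-power space: (1) robust straight-line aperiodic
#' fit, (2) flatten, (3) repeatedly detect the largest residual maximum
#' above `max(min_peak_height, peak_threshold * SD)` and subtract a Gaussian
#' guess (sigma clamped to half the width limits), up to `max_n_peaks`,
#' (4) bounded joint refit of all Gaussians, (5) aperiodic refit on the
#' peak-subtracted spectrum, (6) R^2 of the full model in log power.
#'
#' @param spectrum an [eeg_spectrum] (first row) or list with `freqs`,
#'   `power`.
#' @param fit_range `(lo, hi)` Hz; needs >= 5 bins.
#' @param settings a [fit_settings()] object.
#' @param exclude_bands optional bands removed before fitting (see
#'   [fit_loglog_line()]).
#' @return An object of class `aperiodic_fit`: `offset`, `exponent`
#'   (may be negative; downstream filters apply), `peaks` (data frame
#'   height/centre/width), `fit_range`, `r_squared`, `status`
#'   (`"ok"` or `"fit_failed"`).
#' @export
fit_spectral_model <- function(spectrum, fit_range,
                               settings = fit_settings(),
                               exclude_bands = NULL) {
  fp <- spectrum_vectors(spectrum)
  sel <- fp$freqs >= fit_range[1] & fp$freqs <= fit_range[2] &
    is.finite(fp$power) & fp$power > 0
  if (!is.null(exclude_bands)) {
    eb <- as.matrix(exclude_bands)
    for (i in seq_len(nrow(eb)))
      sel <- sel & !(fp$freqs >= eb[i, 1] & fp$freqs <= eb[i, 2])
  }
  f <- fp$freqs[sel]
  if (length(f) < 5) stop("fewer than 5 usable bins in fit range")
  lp <- log10(fp$power[sel])
  lf <- log10(f)
  sig_lim <- settings$peak_width_limits / 2

  ap <- robust_aperiodic(lf, lp, settings$ap_percentile)
  flat <- lp - (ap["offset"] - ap["exponent"] * lf)

  # iterative peak detection on the flattened spectrum
  guesses <- NULL
  resid <- flat
  for (k in seq_len(settings$max_n_peaks)) {
    i_max <- which.max(resid)
    h <- resid[i_max]
    if (h < settings$min_peak_height ||
        h < settings$peak_threshold * sd(resid)) break
    mu <- f[i_max]
    # sigma guess from half-height crossings, clamped to limits
    half <- h / 2
    lo_i <- i_max; while (lo_i > 1 && resid[lo_i] > half) lo_i <- lo_i - 1
    hi_i <- i_max; while (hi_i < length(f) && resid[hi_i] > half) hi_i <- hi_i + 1
    fwhm <- f[hi_i] - f[lo_i]
    sigma <- min(max(fwhm / 2.355, sig_lim[1]), sig_lim[2])
    guesses <- rbind(guesses, c(h, mu, sigma))
    resid <- resid - h * exp(-((f - mu)^2) / (2 * sigma^2))
  }

  peaks <- data.frame(height = numeric(0), centre = numeric(0),
                      width = numeric(0))
  status <- "ok"
  if (!is.null(guesses)) {
    par0 <- as.vector(t(guesses))
    npk <- nrow(guesses)
    lowb <- rep(c(0, fit_range[1], sig_lim[1]), npk)
    uppb <- rep(c(Inf, fit_range[2], sig_lim[2]), npk)
    obj <- function(p) sum((flat - gaussian_sum(f, p))^2)
    opt <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lowb, upper = uppb,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) {
      status <- "fit_failed"
      pk <- guesses
    } else {
      pk <- matrix(opt$par, ncol = 3, byrow = TRUE)
    }
    keep <- pk[, 1] >= settings$min_peak_height
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk))
      peaks <- data.frame(height = pk[, 1], centre = pk[, 2], width = pk[, 3])
  }

  # refit aperiodic on the peak-subtracted spectrum
  lp_sub <- lp - gaussian_sum(f, as.vector(t(as.matrix(peaks))))
  ap <- loglog_ols(lf, lp_sub)
  model <- (ap["offset"] - ap["exponent"] * lf) +
    gaussian_sum(f, as.vector(t(as.matrix(peaks))))
  r2 <- 1 - sum((lp - model)^2) / sum((lp - mean(lp))^2)

  structure(list(offset = unname(ap["offset"]),
                 exponent = unname(ap["exponent"]),
                 peaks = peaks, fit_range = fit_range,
                 r_squared = r2, status = status,
                 settings = settings),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> b = %.3f, chi = %.3f, %d peak(s), R2 = %.4f [%g-%g Hz]\n",
              x$offset, x$exponent, nrow(x$peaks), x$r_squared,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}
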