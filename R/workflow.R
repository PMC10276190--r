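#' Run the full single-subject analysis
#'
#' Chains artifact rejection, trial-averaged PSD estimation, log-domain
#' pooling over an electrode group, and slope profiling (sliding windows
#' plus the fixed LFR and HFR bands).
#'
#' @param rec an [eeg_recording].
#' @param montage an `eeg_montage`.
#' @param group electrode group pooled for the subject-level spectrum.
#' @param settings [fit_settings()]; defaults to the recording's condition.
#' @param method `"model"` or `"loglog"` (passed to the slope fitters).
#' @param windows sliding-window grid; the default grid is clipped to the
#'   frequencies the PSD covers.
#' @param f_ceiling analysis ceiling (Hz); defaults to 1000 (fits may use
#'   the full grid even though displays stop at 800 Hz).
#' @return List with `spectrum` (pooled [eeg_spectrum]), `profile`
#'   (`slope_profile`), `lfr`, `hfr` (one-row profiles), `alpha` (peak
#'   centre Hz or `NA`), `report` (rejection report). `NULL` with a message
#'   if the block is invalid or no group electrode survives.
#' @export
analyze_subject <- function(rec, montage = default_montage(),
                            group = "high_priority", settings = NULL,
                            method = c("model", "loglog"),
                            windows = NULL, f_ceiling = 1000) {
  method <- match.arg(method)
  if (is.null(settings)) settings <- fit_settings(rec$condition)
  pp <- run_pipeline(rec, montage = montage)
  if (!pp$report$block_valid) {
    message("subject ", rec$subject$id, " discarded: block invalid")
    return(NULL)
  }
  spec <- multitaper_psd(pp$epochs)
  pooled <- pool_group(spec, get_group(montage, group))
  if (all(is.na(pooled$power))) {
    message("subject ", rec$subject$id, " discarded: no good '", group,
            "' electrode")
    return(NULL)
  }
  f_max <- min(f_ceiling, max(pooled$freqs))
  if (is.null(windows)) {
    windows <- make_windows(f_max = f_max,
                            centre_range = c(40, 20 * floor((f_max - 40) / 20)))
  }
  noise <- noise_peaks(f_max = f_max)
  prof <- sliding_slopes(pooled, settings, noise, windows = windows,
                         method = method)
  lfr <- band_slope(pooled, "LFR", settings, noise, method = method)
  hfr <- band_slope(pooled, "HFR", settings, noise, method = method)
  alpha <- tryCatch({
    afit <- fit_spectral_model(pooled, c(max(2, min(pooled$freqs)), 40),
                               settings)
    extract_alpha_peak(afit)
  }, error = function(e) NA_real_)
  list(spectrum = pooled, profile = prof, lfr = lfr, hfr = hfr,
       alpha = alpha, report = pp$report)
}

#' Analyse a simulated (or loaded) cohort
#'
#' Runs [analyze_subject()] per recording and assembles tidy per-subject
#' results.
#'
#' @param recordings list of [eeg_recording] objects.
#' @param metadata data frame with a row per recording (`id`, `age`,
#'   `gender`, `diagnosis`).
#' @inheritParams analyze_subject
#' @return List with `slopes` (data frame: id, age, gender, diagnosis,
#'   lfr, hfr, alpha), `profiles` (subjects x windows exponent matrix),
#'   `centres` (window centre frequencies), `kept` (logical per input).
#' @export
analyze_cohort <- function(recordings, metadata,
                           montage = default_montage(),
                           group = "high_priority",
                           method = c("model", "loglog")) {
  method <- match.arg(method)
  res <- lapply(recordings, analyze_subject, montage = montage,
                group = group, method = method)
  kept <- !vapply(res, is.null, logical(1))
  res <- res[kept]
  if (!length(res)) stop("no analysable subject in the cohort")
  centres <- res[[1]]$profile$centre
  profiles <- t(vapply(res, function(r) r$profile$exponent,
                       numeric(length(centres))))
  slopes <- data.frame(
    metadata[kept, c("id", "age", "gender", "diagnosis")],
    lfr = vapply(res, function(r) r$lfr$exponent, 0),
    hfr = vapply(res, function(r) r$hfr$exponent, 0),
    alpha = vapply(res, function(r) r$alpha, 0),
    row.names = NULL
  )
  list(slopes = slopes, profiles = profiles, centres = centres, kept = kept)
}

#' Age-group labels
#'
#' @param ages years.
#' @param boundary Mid/Old boundary (years, default 64): `"mid"` for ages
#'   in `[50, boundary]`, `"old"` above.
#' @return Factor with levels `mid`, `old`.
#' @export
age_group <- function(ages, boundary = 64) {
  factor(ifelse(ages > boundary, "old", "mid"), levels = c("mid", "old"))
}
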