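# Artifact rejection: the ordered rule set for eyes-open recordings is
# (a) fixation breaks, (b) impedance > 25 kOhm, (c) 6-SD time/frequency
# outlier repeats then >30% electrode drop, (d) common-bad pooling over the
# visual electrodes / >10% of others, (e) 56-84 Hz negative-slope electrode
# rejection, (f) RMS bounds (1.25-35 uV) with a second electrode drop and
# common-bad append, (g) block validation. Eyes closed replaces the
# time-domain 6-SD screen with the RMS rule (lower cutoff 2.5 uV) applied
# first, and has no second RMS pass. All boundary comparisons are strict.

#' Flag repeats with fixation breaks
#'
#' A repeat is flagged iff eye eccentricity exceeds `window_deg` at any
#' sample inside `interval` (seconds relative to stimulus onset).
#'
#' @param eye list with `fs`, `t0` (time of first sample, s) and `traces`
#'   (repeats x samples, degrees), or `NULL`.
#' @param n_repeats number of repeats (used when `eye` is `NULL`).
#' @param window_deg fixation window radius (degrees).
#' @param interval `(lo, hi)` seconds to screen.
#' @return Logical vector, one entry per repeat; all `FALSE` with a warning
#'   when eye data are missing.
#' @export
reject_fixation_breaks <- function(eye, n_repeats = NULL, window_deg = 5,
                                   interval = c(-0.5, 0.75)) {
  if (is.null(eye)) {
    warning("no eye data: fixation-break screening skipped")
    return(rep(FALSE, n_repeats %||% 0L))
  }
  tt <- eye$t0 + (seq_len(ncol(eye$traces)) - 1) / eye$fs
  cols <- tt >= interval[1] & tt <= interval[2]
  if (!any(cols)) stop("eye traces do not cover the screening interval")
  apply(eye$traces[, cols, drop = FALSE], 1,
        function(x) any(abs(x) > window_deg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag high-impedance electrodes
#'
#' @param impedances per-electrode impedance (kOhm).
#' @param threshold rejection threshold (kOhm); rejection is strict
#'   (`> threshold`), so exactly 25 kOhm is kept.
#' @return Logical vector (`TRUE` = rejected).
#' @export
reject_high_impedance <- function(impedances, threshold = 25) {
  stopifnot(all(is.finite(impedances)), all(impedances >= 0))
  impedances > threshold
}

# per-repeat log10 single-taper spectra for one electrode (repeats x bins)
repeat_log_spectra <- function(epochs, i, reps) {
  d <- dim(epochs$epochs)
  h <- dpss_taper(d[3], 1)
  t(vapply(reps, function(r)
    log10(pmax(single_taper_psd(epochs$epochs[i, r, ], epochs$fs, h)[-1],
               1e-300)),
    numeric(floor(d[3] / 2))))
}

#' Flag 6-SD outlier repeats (time and/or frequency domain)
#'
#' For each electrode, the across-repeat mean and pointwise SD are computed
#' for the raw waveform (time domain) and the log10 single-taper spectrum
#' (frequency domain); a repeat is an outlier iff its maximum pointwise
#' `|deviation| / SD` exceeds `n_sd` in either domain. Points with zero SD
#' contribute no flag. Note that with the repeat included in the mean the
#' largest attainable pointwise z is `(n-1)/sqrt(n)`, so the rule only
#' bites for roughly 40+ repeats (the intended regime is hundreds).
#'
#' @param epochs an [epoch_set].
#' @param n_sd threshold in SD units (default 6).
#' @param domains subset of `c("time", "frequency")`.
#' @return Logical electrodes x repeats matrix (`TRUE` = outlier). Repeats
#'   already flagged non-good are skipped (kept `FALSE`).
#' @export
flag_outlier_repeats <- function(epochs, n_sd = 6,
                                 domains = c("time", "frequency")) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  out <- matrix(FALSE, d[1], d[2], dimnames = dimnames(epochs$flags))
  max_abs_z <- function(mat) {   # repeats x points
    mu <- colMeans(mat)
    s <- apply(mat, 2, sd)
    z <- abs(sweep(mat, 2, mu)) / rep(s, each = nrow(mat))
    z[, s == 0] <- 0             # zero-SD points are skipped
    apply(z, 1, max)
  }
  for (i in seq_len(d[1])) {
    if (epochs$electrode_status[i] != "good") next
    reps <- good_repeats(epochs, i)
    if (length(reps) < 3) next
    bad <- rep(FALSE, length(reps))
    if ("time" %in% domains) {
      tm <- t(vapply(reps, function(r) epochs$epochs[i, r, ], numeric(d[3])))
      bad <- bad | (max_abs_z(tm) > n_sd)
    }
    if ("frequency" %in% domains) {
      bad <- bad | (max_abs_z(repeat_log_spectra(epochs, i, reps)) > n_sd)
    }
    out[i, reps] <- bad
  }
  out
}

#' Flag repeats with out-of-range RMS
#'
#' @param epochs an [epoch_set].
#' @param lo_uv lower RMS cutoff (uV): 1.25 for eyes open, 2.5 for eyes
#'   closed.
#' @param hi_uv upper RMS cutoff (uV, default 35).
#' @return Logical electrodes x repeats matrix (`TRUE` = RMS `< lo_uv` or
#'   `> hi_uv`, strict). Non-good repeats/electrodes are skipped.
#' @export
flag_rms_outliers <- function(epochs, lo_uv = 1.25, hi_uv = 35) {
  stopifnot(lo_uv < hi_uv)
  d <- dim(epochs$epochs)
  out <- matrix(FALSE, d[1], d[2], dimnames = dimnames(epochs$flags))
  for (i in seq_len(d[1])) {
    if (epochs$electrode_status[i] != "good") next
    reps <- good_repeats(epochs, i)
    rms <- vapply(reps, function(r) sqrt(mean(epochs$epochs[i, r, ]^2)), 0)
    out[i, reps] <- rms < lo_uv | rms > hi_uv
  }
  out
}

#' Drop electrodes with too many outlier repeats
#'
#' @param flags logical electrodes x repeats outlier matrix.
#' @param considered logical matrix (or `NULL`) marking the repeats that
#'   were actually screened per electrode (denominator of the fraction).
#' @param max_fraction rejection threshold; strict (`> max_fraction`), so
#'   exactly 30% is kept.
#' @return Logical vector per electrode (`TRUE` = rejected).
#' @export
drop_bad_electrodes <- function(flags, considered = NULL,
                                max_fraction = 0.30) {
  if (is.null(considered)) considered <- matrix(TRUE, nrow(flags), ncol(flags))
  n_cons <- rowSums(considered)
  frac <- ifelse(n_cons > 0, rowSums(flags & considered) / n_cons, 0)
  setNames(frac > max_fraction, rownames(flags))
}

#' Pool common bad repeats across electrodes
#'
#' A repeat is common-bad iff it is flagged on at least one visual
#' electrode, or on strictly more than `other_fraction` of the remaining
#' good electrodes.
#'
#' @param flags logical electrodes x repeats outlier matrix (rownames =
#'   labels).
#' @param montage an `eeg_montage`; the visual set is its `high_priority`
#'   group.
#' @param good_electrodes labels still in play (default: all rows).
#' @param other_fraction threshold for non-visual electrodes (strict).
#' @return Logical vector per repeat (`TRUE` = common bad).
#' @export
common_bad_repeats <- function(flags, montage = default_montage(),
                               good_electrodes = rownames(flags),
                               other_fraction = 0.10) {
  visual <- intersect(get_group(montage, "high_priority"), good_electrodes)
  others <- setdiff(good_electrodes, visual)
  vis_bad <- if (length(visual))
    colSums(flags[visual, , drop = FALSE]) >= 1 else rep(FALSE, ncol(flags))
  oth_bad <- if (length(others))
    colSums(flags[others, , drop = FALSE]) / length(others) > other_fraction
  else rep(FALSE, ncol(flags))
  vis_bad | oth_bad
}

#' Reject electrodes with non-positive mid-band spectral slope
#'
#' Fits the aperiodic exponent on `band` (56--84 Hz, oscillation-free by
#' construction) with a direct log-log line fit and rejects electrodes with
#' exponent strictly below 0 (a rising spectrum indicates a bad contact).
#'
#' @param spectrum an [eeg_spectrum] with electrode rows.
#' @param band fit band (Hz).
#' @return Logical vector per electrode (`TRUE` = rejected); `NA`-power
#'   electrodes return `FALSE` (nothing to assess).
#' @export
reject_nonpositive_slope_electrodes <- function(spectrum, band = c(56, 84)) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  n_bins <- sum(spectrum$freqs >= band[1] & spectrum$freqs <= band[2])
  if (n_bins < 3) stop("fewer than 3 bins in the ", band[1], "-", band[2],
                       " Hz slope band")
  out <- logical(nrow(spectrum$power))
  for (i in seq_len(nrow(spectrum$power))) {
    if (all(is.na(spectrum$power[i, ]))) next
    # degenerate spectra (e.g. an all-zero channel) cannot be assessed
    # here; later stages catch them
    fit <- tryCatch(fit_loglog_line(list(freqs = spectrum$freqs,
                                         power = spectrum$power[i, ]), band),
                    error = function(e) NULL)
    if (!is.null(fit)) out[i] <- fit$exponent < 0
  }
  setNames(out, rownames(spectrum$power))
}

#' Validate a block after rejection
#'
#' A block is analysable iff each of the left visual anterolateral, right
#' visual anterolateral and posteromedial groups retains at least one good
#' electrode.
#'
#' @param electrode_status named status vector (`"good"` or a rejection
#'   reason).
#' @param montage an `eeg_montage`.
#' @return Logical scalar.
#' @export
validate_block <- function(electrode_status, montage = default_montage()) {
  good <- names(electrode_status)[electrode_status == "good"]
  all(vapply(c("left_anterolateral", "right_anterolateral", "posteromedial"),
             function(g) length(intersect(get_group(montage, g), good)) >= 1,
             logical(1)))
}

#' Run the full artifact-rejection pipeline
#'
#' Applies the ordered rejection rules for the requested mode (see the
#' comment block at the top of this file and the methods vignette) and
#' returns the cleaned epochs plus a stage-by-stage report.
#'
#' @param rec an [eeg_recording].
#' @param mode `"eyes_open"` or `"eyes_closed"` (default: the recording's
#'   condition).
#' @param montage an `eeg_montage`.
#' @param impedance_threshold kOhm (default 25).
#' @param n_sd deviation threshold (default 6).
#' @param max_outlier_fraction electrode-drop fraction (default 0.30).
#' @param other_fraction common-bad fraction (default 0.10).
#' @param rms_lo_uv lower RMS cutoff; default 1.25 (eyes open) or 2.5
#'   (eyes closed).
#' @param rms_hi_uv upper RMS cutoff (default 35).
#' @param slope_band electrode-rejection slope band (default 56--84 Hz).
#' @return List with `epochs` (flagged [epoch_set]) and `report` (class
#'   `rejection_report`): per-electrode status + reason, per-repeat flags,
#'   the fraction rejected at each stage in execution order, and
#'   `block_valid`.
#' @export
run_pipeline <- function(rec, mode = rec$condition,
                         montage = default_montage(),
                         impedance_threshold = 25, n_sd = 6,
                         max_outlier_fraction = 0.30, other_fraction = 0.10,
                         rms_lo_uv = NULL, rms_hi_uv = 35,
                         slope_band = c(56, 84)) {
  stopifnot(inherits(rec, "eeg_recording"))
  mode <- match.arg(mode, c("eyes_open", "eyes_closed"))
  if (mode != rec$condition)
    stop("mode '", mode, "' does not match recording condition '",
         rec$condition, "'")
  if (is.null(rms_lo_uv)) rms_lo_uv <- if (mode == "eyes_open") 1.25 else 2.5
  es <- segment_epochs(rec, mode)
  n_rep <- dim(es$epochs)[2]
  stages <- list()
  log_stage <- function(name, frac) stages[[length(stages) + 1L]] <<-
    list(stage = name, fraction_rejected = frac)
  mark_common <- function(which_reps) {
    if (any(which_reps)) es$flags[, which_reps] <<- "bad_common"
  }

  if (mode == "eyes_open") {
    # (a) fixation breaks
    fb <- withCallingHandlers(
      reject_fixation_breaks(rec$eye_eccentricity, n_repeats = n_rep),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(rec$eye_eccentricity))
      message("note: no eye data; fixation-break screening skipped")
    mark_common(fb)
    log_stage("fixation_breaks", mean(fb))
  }

  # (b) impedance
  imp_rej <- reject_high_impedance(es$impedances, impedance_threshold)
  es$electrode_status[imp_rej] <- "rejected_impedance"
  log_stage("impedance", mean(imp_rej))

  if (mode == "eyes_open") {
    # (c) 6-SD outliers, time + frequency
    fl <- flag_outlier_repeats(es, n_sd)
  } else {
    # RMS screen replaces the time-domain deviation rule, then 6-SD in
    # frequency only
    fl_rms <- flag_rms_outliers(es, rms_lo_uv, rms_hi_uv)
    es$flags[fl_rms] <- "outlier"
    fl <- fl_rms | flag_outlier_repeats(es, n_sd, domains = "frequency")
  }
  es$flags[fl & es$flags != "bad_common"] <- "outlier"
  log_stage(if (mode == "eyes_open") "sd_outliers_time_freq" else
    "rms_then_sd_outliers_freq", mean(fl))

  # electrode drop at >30% outliers (over repeats not already common-bad)
  considered <- es$flags != "bad_common"
  el_drop <- drop_bad_electrodes(fl, considered, max_outlier_fraction) &
    es$electrode_status == "good"
  es$electrode_status[el_drop] <- "rejected_outliers"
  log_stage("electrode_drop_outliers", mean(el_drop))

  # (d) common bad pooling
  good_el <- names(es$electrode_status)[es$electrode_status == "good"]
  cb <- common_bad_repeats(fl, montage, good_el, other_fraction)
  mark_common(cb)
  log_stage("common_bad", mean(cb))

  # (e) 56-84 Hz slope rejection
  spec <- multitaper_psd(es)
  sl_rej <- reject_nonpositive_slope_electrodes(spec, slope_band) &
    es$electrode_status == "good"
  es$electrode_status[sl_rej] <- "rejected_slope"
  log_stage("nonpositive_slope", mean(sl_rej))

  if (mode == "eyes_open") {
    # (f) RMS outliers + second electrode drop + common-bad append
    fl2 <- flag_rms_outliers(es, rms_lo_uv, rms_hi_uv)
    es$flags[fl2 & es$flags == "good"] <- "outlier"
    considered <- es$flags != "bad_common"
    el2 <- drop_bad_electrodes(fl2, considered, max_outlier_fraction) &
      es$electrode_status == "good"
    es$electrode_status[el2] <- "rejected_rms"
    good_el <- names(es$electrode_status)[es$electrode_status == "good"]
    cb2 <- common_bad_repeats(fl2, montage, good_el, other_fraction)
    mark_common(cb2)
    log_stage("rms_outliers", mean(fl2))
    log_stage("electrode_drop_rms", mean(el2))
    log_stage("common_bad_rms", mean(cb2))
  }

  # (g) block validation
  ok <- validate_block(es$electrode_status, montage)
  log_stage("block_valid", as.numeric(!ok))

  report <- structure(list(
    electrode_status = es$electrode_status,
    repeat_flags = es$flags,
    stages = do.call(rbind, lapply(stages, as.data.frame)),
    block_valid = ok,
    mode = mode
  ), class = "rejection_report")
  list(epochs = es, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("<rejection_report>", x$mode, "- block",
      if (x$block_valid) "VALID" else "INVALID", "\n")
  print(x$stages, row.names = FALSE)
  bad <- x$electrode_status[x$electrode_status != "good"]
  if (length(bad)) {
    cat("rejected electrodes:\n")
    print(bad)
  }
  invisible(x)
}

#' Write a rejection report to JSON
#'
#' @param report a `rejection_report`.
#' @param path output file.
#' @export
write_rejection_report <- function(report, path) {
  jsonlite::write_json(list(
    mode = report$mode,
    block_valid = report$block_valid,
    stages = report$stages,
    electrode_status = as.list(report$electrode_status),
    n_common_bad_repeats = sum(apply(report$repeat_flags == "bad_common", 2,
                                     any))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
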