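#' Cohort generator configuration
#'
#' Defaults state the emulated world: 2.5 kHz sampling, elderly ages
#' sampled uniformly on 50--88 years with the Mid/Old boundary at 64, an
#' LFR exponent falling by 0.010/yr and an HFR exponent rising by 0.017/yr
#' (the regression coefficients of the eyes-open cohort analysis), alpha
#' slowing by ~0.016 Hz/yr, and a two-regime aperiodic spectrum split near
#' the empirical knee at 175 Hz. See the methods vignette for the rationale
#' behind values the analysis itself does not pin down (reference
#' exponents, between-subject scatter, peak heights).
#'
#' @param n_subjects number of subjects.
#' @param age_range `(lo, hi)` years.
#' @param lfr_age_coeff LFR exponent change per year.
#' @param hfr_age_coeff HFR exponent change per year.
#' @param alpha_age_coeff alpha centre-frequency change (Hz per year).
#' @param group_boundary_age Mid/Old boundary (years); also the reference
#'   age at which the `*_ref` values apply.
#' @param diagnosis_mix named fractions (`healthy`, `mci`, `ad`), summing
#'   to 1.
#' @param seed integer seed for the cohort.
#' @param fs sampling rate (Hz).
#' @param n_trials eyes-open stimulus repeats per subject.
#' @param ec_duration eyes-closed duration (s).
#' @param lfr_exponent_ref,hfr_exponent_ref aperiodic exponents of the low-
#'   and high-frequency regimes at the reference age.
#' @param offset_ref log10 aperiodic power (uV^2/Hz) at the 50 Hz pivot;
#'   age-independent, so cohort spectra overlap below ~50 Hz and rotate
#'   apart beyond it.
#' @param subject_sd between-subject SD of each exponent.
#' @param electrode_sd between-electrode SD of each exponent.
#' @param split_freq regime split frequency (Hz).
#' @param alpha_centre_ref alpha centre at the reference age (Hz).
#' @param alpha_height alpha peak height, log10 power (eyes closed uses
#'   `alpha_height_ec`, the more prominent peak).
#' @param alpha_height_ec eyes-closed alpha height.
#' @param beta_height beta (15--35 Hz) peak height, log10 power.
#' @param beta_reduction multiplicative reduction of the beta peak height
#'   in MCI/AD subjects (default 0.48, i.e. roughly halved beta power).
#' @param line_amp 50 Hz line-noise amplitude (uV).
#' @param line_decay geometric amplitude decay per harmonic.
#' @param emg optional EMG hump passed to [spectral_model_params()]'s
#'   `emg_band`; `NULL` (default) for none.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40, age_range = c(50, 88),
                          lfr_age_coeff = -0.010, hfr_age_coeff = 0.017,
                          alpha_age_coeff = -0.016,
                          group_boundary_age = 64,
                          diagnosis_mix = c(healthy = 0.93, mci = 0.05,
                                            ad = 0.02),
                          seed = 1L, fs = 2500, n_trials = 300,
                          ec_duration = 90,
                          lfr_exponent_ref = 1.2, hfr_exponent_ref = 2.4,
                          offset_ref = -0.5, subject_sd = 0.15,
                          electrode_sd = 0.05, split_freq = 175,
                          alpha_centre_ref = 9.6, alpha_height = 0.4,
                          alpha_height_ec = 0.8, beta_height = 0.25,
                          beta_reduction = 0.48,
                          line_amp = 2, line_decay = 0.6, emg = NULL) {
  stopifnot(n_subjects >= 1, age_range[1] <= age_range[2])
  if (abs(sum(diagnosis_mix) - 1) > 1e-8)
    stop("diagnosis_mix fractions must sum to 1")
  structure(as.list(environment()), class = "cohort_config")
}

#' Artifact injection configuration
#'
#' Defaults emulate the rejection statistics of the real pipeline where
#' these are reported (14.6% fixation breaks) and plausible desk-scale
#' rates elsewhere. All-zero rates give a clean, artifact-free subject.
#'
#' @param blink_rate per-repeat blink probability on frontal electrodes.
#' @param blink_amplitude blink amplitude (uV).
#' @param bad_channel_fraction fraction of channels replaced by a
#'   high-amplitude rising-spectrum (bad contact) signal.
#' @param flat_channel_fraction fraction of channels with a flat (0 uV)
#'   signal.
#' @param impedance_distribution `(mean, sd)` kOhm of electrode impedances.
#' @param rms_outlier_fraction per-repeat probability of a large
#'   out-of-range amplitude excursion (all electrodes).
#' @param fixation_break_fraction per-repeat probability of an eye
#'   excursion beyond the 5 degree fixation window.
#' @return An object of class `artifact_config`.
#' @export
artifact_config <- function(blink_rate = 0.05, blink_amplitude = 300,
                            bad_channel_fraction = 0.03,
                            flat_channel_fraction = 0.02,
                            impedance_distribution = c(5.5, 1.8),
                            rms_outlier_fraction = 0.01,
                            fixation_break_fraction = 0.146) {
  probs <- c(blink_rate, bad_channel_fraction, flat_channel_fraction,
             rms_outlier_fraction, fixation_break_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(as.list(environment()), class = "artifact_config")
}

#' All-zero artifact configuration (clean subject)
#' @return An `artifact_config` with every rate and injection at zero.
#' @export
no_artifacts <- function() {
  artifact_config(blink_rate = 0, bad_channel_fraction = 0,
                  flat_channel_fraction = 0,
                  impedance_distribution = c(5.5, 1.8),
                  rms_outlier_fraction = 0, fixation_break_fraction = 0)
}

# broadband two-regime PSD function for one electrode (closure over
# subject/electrode parameters). The aperiodic component is anchored at a
# 50 Hz pivot (cohort PSDs overlap below ~50 Hz; age rotates the spectrum
# about that region, it does not shift it), is continuous at the split
# frequency, and plateaus below 1 Hz so the variance integral converges.
subject_psd_fun <- function(p50, chi_lo, chi_hi, split, peaks, emg,
                            pivot = 50) {
  lsplit <- log10(split / pivot)
  function(f) {
    fc <- pmax(f, 1)
    lfp <- log10(fc / pivot)
    lp <- ifelse(fc <= split,
                 p50 - chi_lo * lfp,
                 p50 - chi_lo * lsplit - chi_hi * (lfp - lsplit))
    lp <- lp + peaks_log10(fc, peaks) + emg_log10(fc, emg)
    10^lp
  }
}

#' Simulate one subject's recording
#'
#' Builds per-electrode time series from a two-regime aperiodic spectrum
#' whose low-regime exponent follows `lfr_age_coeff` and high-regime
#' exponent `hfr_age_coeff` (linear in age around the reference age), an
#' alpha peak that slows with age, a beta peak (reduced in MCI/AD), 50 Hz
#' line noise with decaying harmonics, and artifacts per the
#' [artifact_config()]. Eyes open yields `n_trials` onsets 1.5 s apart;
#' eyes closed a continuous segment.
#'
#' @param age years (must lie within the cohort's `age_range`).
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param cohort a [cohort_config()].
#' @param artifacts an [artifact_config()].
#' @param montage an `eeg_montage`; its `all` labels are simulated. Must
#'   contain at least one electrode of each block-validation group.
#' @param seed integer seed.
#' @param diagnosis `"healthy"`, `"mci"` or `"ad"`.
#' @param subject_id identifier.
#' @param gender `"M"` or `"F"`.
#' @return An [eeg_recording]. The generator's target exponents are
#'   attached as attribute `"targets"` (`chi_lfr`, `chi_hfr`,
#'   `alpha_centre`) for parameter-recovery testing.
#' @export
simulate_subject <- function(age, condition = c("eyes_open", "eyes_closed"),
                             cohort = cohort_config(),
                             artifacts = artifact_config(),
                             montage = default_montage(), seed = 1L,
                             diagnosis = "healthy", subject_id = "s1",
                             gender = "M") {
  condition <- match.arg(condition)
  if (age < cohort$age_range[1] || age > cohort$age_range[2])
    stop("age ", age, " outside cohort age range")
  needed <- c("left_anterolateral", "right_anterolateral", "posteromedial")
  missing_grp <- needed[vapply(needed, function(g)
    length(intersect(get_group(montage, g), montage$all)) == 0, logical(1))]
  if (length(missing_grp))
    stop("montage lacks electrodes for: ", paste(missing_grp, collapse = ", "),
         " (labels required: ",
         paste(unlist(montage$groups[missing_grp]), collapse = ", "), ")")
  labels <- montage$all
  fs <- cohort$fs
  withr::with_seed(seed, {
    ref <- cohort$group_boundary_age
    chi_lfr <- cohort$lfr_exponent_ref +
      cohort$lfr_age_coeff * (age - ref) + rnorm(1, 0, cohort$subject_sd)
    chi_hfr <- cohort$hfr_exponent_ref +
      cohort$hfr_age_coeff * (age - ref) + rnorm(1, 0, cohort$subject_sd)
    offset <- cohort$offset_ref + rnorm(1, 0, 0.15)
    alpha_centre <- cohort$alpha_centre_ref +
      cohort$alpha_age_coeff * (age - ref) + rnorm(1, 0, 0.15)
    alpha_h <- if (condition == "eyes_open") cohort$alpha_height
    else cohort$alpha_height_ec
    alpha_w <- if (condition == "eyes_open") 2.2 else 1.5
    beta_h <- cohort$beta_height *
      if (diagnosis %in% c("mci", "ad")) cohort$beta_reduction else 1
    peaks <- data.frame(height = c(alpha_h, beta_h),
                        centre = c(alpha_centre, 21),
                        width = c(alpha_w, 3))

    if (condition == "eyes_open") {
      onsets <- round((2 + 1.5 * (seq_len(cohort$n_trials) - 1)) * fs)
      duration <- (tail(onsets, 1) / fs) + 1.5
    } else {
      onsets <- NULL
      duration <- cohort$ec_duration
    }
    n <- round(duration * fs)
    n_el <- length(labels)
    dat <- matrix(0, n_el, n, dimnames = list(labels, NULL))

    n_flat <- round(artifacts$flat_channel_fraction * n_el)
    n_bad <- round(artifacts$bad_channel_fraction * n_el)
    special <- sample(n_el, min(n_el, n_flat + n_bad))
    flat_idx <- head(special, n_flat)
    bad_idx <- tail(special, n_bad)

    harm <- cohort$line_amp *
      cohort$line_decay^(seq_len(floor(fs / 2 / 50)) - 1)
    line <- data.frame(freq = 50 * seq_along(harm), amplitude = harm)
    # line noise enters through the synthesis PSD: a spike confined to the
    # FFT bin nearest each harmonic is exactly a random-phase sinusoid
    with_lines <- function(pf) {
      function(f) {
        p <- pf(f)
        if (length(f) > 1L) {
          df <- f[2] - f[1]
          for (k in seq_len(nrow(line))) {
            j <- which.min(abs(f - line$freq[k]))
            p[j] <- p[j] + line$amplitude[k]^2 / 2 / df
          }
        }
        p
      }
    }

    for (i in seq_len(n_el)) {
      if (i %in% flat_idx) next
      if (i %in% bad_idx) {
        # bad contact: high-amplitude, slightly rising spectrum
        pf <- subject_psd_fun(offset + 1.5, -0.3, -0.3, cohort$split_freq,
                              NULL, NULL)
      } else {
        pf <- subject_psd_fun(offset + rnorm(1, 0, 0.1),
                              chi_lfr + rnorm(1, 0, cohort$electrode_sd),
                              chi_hfr + rnorm(1, 0, cohort$electrode_sd),
                              cohort$split_freq, peaks, cohort$emg)
      }
      dat[i, ] <- synthesize_timeseries(with_lines(pf), duration, fs)
    }

    # blinks: frontal electrodes, random latency within the trial span
    frontal <- intersect(get_group(montage, "frontal"), labels)
    if (length(frontal) && artifacts$blink_rate > 0 && !is.null(onsets)) {
      pulse_w <- round(0.12 * fs)
      pulse <- artifacts$blink_amplitude *
        exp(-((seq_len(pulse_w) - pulse_w / 2)^2) / (2 * (pulse_w / 6)^2))
      for (r in seq_along(onsets)) {
        if (runif(1) > artifacts$blink_rate) next
        t0 <- onsets[r] + round(runif(1, -0.45, 0.6) * fs)
        idx <- t0:(t0 + pulse_w - 1)
        idx <- idx[idx >= 1 & idx <= n]
        dat[frontal, idx] <- sweep(dat[frontal, idx, drop = FALSE], 2,
                                   pulse[seq_along(idx)], `+`)
      }
    }

    # out-of-range repeats: scale the analysis window on all electrodes
    if (artifacts$rms_outlier_fraction > 0 && !is.null(onsets)) {
      for (r in seq_along(onsets)) {
        if (runif(1) > artifacts$rms_outlier_fraction) next
        idx <- (onsets[r] - round(0.5 * fs)):(onsets[r] - 1)
        idx <- idx[idx >= 1]
        dat[, idx] <- dat[, idx] * 6
      }
    }

    impedances <- pmax(rnorm(n_el, artifacts$impedance_distribution[1],
                             artifacts$impedance_distribution[2]), 0.5)

    eye <- NULL
    if (!is.null(onsets)) {
      eye_fs <- 500
      ns_eye <- round(1.25 * eye_fs)
      traces <- matrix(abs(rnorm(length(onsets) * ns_eye, 0, 0.5)),
                       length(onsets), ns_eye)
      if (artifacts$fixation_break_fraction > 0) {
        broken <- runif(length(onsets)) < artifacts$fixation_break_fraction
        for (r in which(broken)) {
          j0 <- sample(ns_eye - 25, 1)
          traces[r, j0:(j0 + 25)] <- runif(1, 6, 10)
        }
      }
      eye <- list(fs = eye_fs, t0 = -0.5, traces = traces)
    }

    rec <- eeg_recording(
      data = dat, fs = fs, labels = labels, impedances = impedances,
      trial_onsets = onsets,
      subject = list(id = subject_id, age = age, gender = gender,
                     diagnosis = diagnosis),
      condition = condition, reference = "unipolar",
      eye_eccentricity = eye
    )
    attr(rec, "targets") <- list(chi_lfr = chi_lfr, chi_hfr = chi_hfr,
                                 alpha_centre = alpha_centre,
                                 offset = offset)
    rec
  })
}

#' Simulate a cohort of subjects
#'
#' Ages are sampled uniformly on the cohort's `age_range`; gender
#' alternates M/F; diagnosis labels are sampled from `diagnosis_mix`.
#' Reproducible per the cohort seed (per-subject seeds are derived from
#' it).
#'
#' @param cohort a [cohort_config()].
#' @param artifacts an [artifact_config()].
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param montage an `eeg_montage`.
#' @return List with `recordings` (list of [eeg_recording]) and `metadata`
#'   (data frame: `id`, `age`, `gender`, `diagnosis`, `condition`).
#' @export
simulate_cohort <- function(cohort = cohort_config(),
                            artifacts = artifact_config(),
                            condition = c("eyes_open", "eyes_closed"),
                            montage = default_montage()) {
  condition <- match.arg(condition)
  n <- cohort$n_subjects
  meta <- withr::with_seed(cohort$seed, data.frame(
    id = sprintf("s%03d", seq_len(n)),
    age = runif(n, cohort$age_range[1], cohort$age_range[2]),
    gender = rep(c("M", "F"), length.out = n),
    diagnosis = sample(names(cohort$diagnosis_mix), n, replace = TRUE,
                       prob = cohort$diagnosis_mix),
    condition = condition,
    stringsAsFactors = FALSE
  ))
  recs <- lapply(seq_len(n), function(i) {
    simulate_subject(
      age = meta$age[i], condition = condition, cohort = cohort,
      artifacts = artifacts, montage = montage,
      seed = (cohort$seed * 10007L + i * 97L) %% 2147483647L,
      diagnosis = meta$diagnosis[i], subject_id = meta$id[i],
      gender = meta$gender[i]
    )
  })
  list(recordings = recs, metadata = meta)
}
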