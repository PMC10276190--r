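# Shared fixtures: small montages and desk-scale cohort settings so a
# simulated subject takes well under a second.

hp_montage <- function() {
  subset_montage(default_montage(),
                 get_group(default_montage(), "high_priority"))
}

quick_cohort <- function(...) {
  args <- list(n_trials = 24, ec_duration = 40, seed = 42)
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_config, args)
}

# a deterministic white-noise epoch_set (electrodes x repeats x samples)
white_epochs <- function(n_el = 1, n_rep = 20, n_samp = 500, fs = 1000,
                         sd = 1, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(rnorm(n_el * n_rep * n_samp, 0, sd),
                 dim = c(n_el, n_rep, n_samp),
                 dimnames = list(paste0("ch", seq_len(n_el)), NULL, NULL))
    epoch_set(arr, fs, c(0, n_samp / fs))
  })
}

# recording with prescribed per-electrode PSD functions (no artifacts)
psd_recording <- function(psd_funs, labels, fs = 2500, duration = 40,
                          onset_step = 1.5, seed = 1, impedances = 5,
                          condition = "eyes_open") {
  n <- round(duration * fs)
  dat <- matrix(0, length(labels), n, dimnames = list(labels, NULL))
  for (i in seq_along(labels))
    dat[i, ] <- synthesize_timeseries(psd_funs[[i]], duration, fs,
                                      seed = seed + i)
  onsets <- if (condition == "eyes_open") {
    round(seq(2, duration - 1.5, by = onset_step) * fs)
  }
  eeg_recording(dat, fs, labels, impedances = impedances,
                trial_onsets = onsets, condition = condition)
}

powerlaw_fun <- function(b, chi) function(f) 10^(b - chi * log10(pmax(f, 1)))
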