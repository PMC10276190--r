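# aperiodic module: model fitting, sliding windows, band slopes, knee.

test_that("in-family spectra are recovered exactly", {
  freqs <- seq(2, 500, 2)
  sp <- evaluate_model_psd(spectral_model_params(2, 1.5), freqs)
  for (rng in list(c(40, 400), c(64, 140), c(230, 430))) {
    fit <- fit_spectral_model(sp, rng)
    expect_equal(fit$offset, 2, tolerance = 1e-3)
    expect_equal(fit$exponent, 1.5, tolerance = 1e-3)
    expect_equal(nrow(fit$peaks), 0)
    expect_gt(fit$r_squared, 0.999)
  }
  flat <- evaluate_model_psd(spectral_model_params(1, 0), freqs)
  expect_equal(fit_spectral_model(flat, c(40, 400))$exponent, 0,
               tolerance = 1e-6)
})

test_that("a Gaussian peak is detected and parameterised", {
  freqs <- seq(2, 40, 0.5)
  pk <- data.frame(height = 0.6, centre = 10, width = 2)
  sp <- evaluate_model_psd(spectral_model_params(1, 1, peaks = pk), freqs)
  fit <- fit_spectral_model(sp, c(4, 40), fit_settings("eyes_closed"))
  expect_equal(nrow(fit$peaks), 1)
  expect_equal(fit$peaks$centre, 10, tolerance = 0.5)
  expect_equal(fit$exponent, 1, tolerance = 0.1)
  expect_equal(extract_alpha_peak(fit), fit$peaks$centre)
})

test_that("alpha extraction picks the tallest in-band peak or misses", {
  fit <- structure(list(peaks = data.frame(
    height = c(0.3, 0.8), centre = c(10, 21), width = c(2, 3))),
    class = "aperiodic_fit")
  expect_equal(extract_alpha_peak(fit), 10)
  fit$peaks <- fit$peaks[2, ]
  expect_true(is.na(extract_alpha_peak(fit)))
})

test_that("direct log-log fit is exact and honours exclusions", {
  freqs <- seq(2, 500, 2)
  ln <- data.frame(freq = 50, amplitude = 5)
  sp <- evaluate_model_psd(spectral_model_params(2, 1.5, line_noise = ln),
                           freqs)
  # contaminated: the 50 Hz spike biases the fit
  dirty <- fit_loglog_line(sp, c(20, 100))
  # removing (46, 54) restores exact recovery
  clean <- fit_loglog_line(sp, c(20, 100),
                           exclude_bands = cbind(46, 54))
  expect_equal(clean$exponent, 1.5, tolerance = 1e-9)
  expect_equal(clean$offset, 2, tolerance = 1e-9)
  expect_gt(abs(dirty$exponent - 1.5), 1e-3)
  expect_error(fit_loglog_line(sp, c(2, 5)), "3 usable bins")
})

test_that("model fit and line fit agree on peak-free spectra", {
  freqs <- seq(2, 800, 2)
  for (chi in c(0.5, 1.5, 3)) {
    sp <- evaluate_model_psd(spectral_model_params(1.5, chi), freqs)
    a <- fit_spectral_model(sp, c(64, 400))$exponent
    b <- fit_loglog_line(sp, c(64, 400))$exponent
    expect_lt(abs(a - b), 0.01)
  }
})

test_that("fits are scale-equivariant and grid-invariant", {
  freqs <- seq(2, 500, 2)
  sp <- evaluate_model_psd(spectral_model_params(2, 1.7), freqs)
  sp_scaled <- eeg_spectrum(freqs, sp$power * 100)
  f1 <- fit_spectral_model(sp, c(40, 400))
  f2 <- fit_spectral_model(sp_scaled, c(40, 400))
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-9)
  expect_equal(f2$offset, f1$offset + 2, tolerance = 1e-9)
  fine <- evaluate_model_psd(spectral_model_params(2, 1.7),
                             seq(0.5, 500, 0.5))
  expect_lt(abs(fit_spectral_model(fine, c(40, 400))$exponent -
                  f1$exponent), 1e-3)
})

test_that("window grid matches the published layout", {
  w <- make_windows()
  expect_equal(nrow(w), 47)
  expect_equal(w$centre, seq(40, 960, 20))
  expect_equal(c(w$lo[1], w$hi[1]), c(4, 90))
  expect_equal(c(w$lo[47], w$hi[47]), c(910, 1000))
  expect_equal(c(w$lo[2], w$hi[2]), c(10, 110))  # unclipped interior window
})

test_that("noise-peak bands cover the 50 Hz harmonics", {
  np <- noise_peaks()
  expect_equal(nrow(np), 20)
  expect_equal(np$lo[1], 46)
  expect_equal(np$hi[4], 204)
})

test_that("sliding profile applies exclusion and min-slope rules", {
  freqs <- seq(2, 1000, 2)
  sp <- evaluate_model_psd(spectral_model_params(2, 2), freqs)
  prof <- sliding_slopes(sp, method = "loglog")
  # window [50, 150]: endpoints in the 50 Hz and 150 Hz noise bands
  r100 <- prof[prof$centre == 100, ]
  expect_true(is.na(r100$exponent))
  expect_equal(r100$reason, "noise_peak_at_edge")
  # window [110, 210] is fitted; interior 146-154 and 196-204 bins removed
  r160 <- prof[prof$centre == 160, ]
  expect_equal(r160$exponent, 2, tolerance = 1e-6)
  # centres at multiples of 100 (odd-multiple-of-50 endpoints) are
  # edge-excluded, as is 960 whose upper endpoint 1000 sits in the
  # 996-1004 Hz harmonic band; everything else is fitted
  excl <- prof$centre[is.na(prof$exponent)]
  expect_equal(excl, c(seq(100, 900, 100), 960))
  # near-flat spectrum: slopes below 0.01 are recorded as missing
  flat <- evaluate_model_psd(spectral_model_params(1, 0.005), freqs)
  pf <- sliding_slopes(flat, method = "loglog")
  expect_true(all(is.na(pf$exponent)))
  expect_true(all(pf$reason[pf$centre == 160] == "below_min_slope"))
})

test_that("band slopes recover a two-regime spectrum", {
  freqs <- seq(2, 1000, 2)
  sp1 <- evaluate_model_psd(spectral_model_params(2, 1), freqs)
  b <- band_slope(sp1, "LFR", method = "loglog")
  expect_equal(b$exponent, 1, tolerance = 1e-6)
  expect_equal(c(b$lo, b$hi), c(64, 140))
  h <- band_slope(sp1, "HFR", method = "loglog")
  expect_equal(h$exponent, 1, tolerance = 1e-6)
  expect_equal(c(h$lo, h$hi), c(230, 430))
  # HFR endpoints are never inside a 50k +/- 4 band
  expect_false(any(c(230, 430) %in%
    unlist(Map(seq, noise_peaks()$lo, noise_peaks()$hi))))
  # two regimes: chi = 1 below 175 Hz, chi = 2 above
  pf <- function(f) {
    lp <- ifelse(f <= 175, 2 - log10(f), 2 + log10(175) - 2 * log10(f))
    10^lp
  }
  sp2 <- list(freqs = freqs, power = pf(freqs))
  expect_equal(band_slope(sp2, "LFR", method = "loglog")$exponent, 1,
               tolerance = 0.1)
  expect_equal(band_slope(sp2, "HFR", method = "loglog")$exponent, 2,
               tolerance = 0.1)
  # the model-fit route agrees on these peak-free inputs
  expect_equal(band_slope(sp2, "HFR", method = "model")$exponent, 2,
               tolerance = 0.1)
})

test_that("knee finding and its timescale behave as documented", {
  prof <- data.frame(centre = seq(40, 400, 20),
                     exponent = c(3, 2.5, 2, 1.8, 1.6, 1.4, 1.3, 1.25,
                                  1.3, 1.4, 1.6, 1.8, 2, 2.2, 2.4, 2.6,
                                  2.8, 3, 3.2))
  k <- find_knee(prof)
  expect_equal(k$f_knee, 180)   # unique minimum at 180 Hz
  expect_false(k$boundary)
  # monotone profile in range: endpoint returned, flagged boundary
  mono <- data.frame(centre = seq(40, 400, 20),
                     exponent = seq(3, 1.2, length.out = 19))
  km <- find_knee(mono)
  expect_equal(km$f_knee, 300)
  expect_true(km$boundary)
  # synthetic spectrum whose local exponent dips to a minimum at 175 Hz
  # (a V in log-frequency, as around an empirical knee): the profile
  # minimum localises the transition
  freqs <- seq(2, 1000, 2)
  lf <- log10(freqs)
  chi_local <- 1 + 2 * abs(lf - log10(175))
  lp <- 2 - cumsum(c(0, diff(lf)) * chi_local)
  prof2 <- sliding_slopes(list(freqs = freqs, power = 10^lp),
                          method = "loglog")
  k2 <- find_knee(prof2)
  expect_lte(abs(k2$f_knee - 175), 20)
  # timescale identities
  expect_equal(knee_timescale(175), 1 / (2 * pi * 175))
  expect_equal(knee_timescale(1 / (2 * pi)), 1)
  expect_equal(knee_timescale(350), knee_timescale(175) / 2)
  expect_error(knee_timescale(0))
})
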