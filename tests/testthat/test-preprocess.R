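# preprocess module: individual rejection rules and the ordered pipeline.

test_that("fixation-break rule flags excursions inside the interval only", {
  eye_fs <- 500
  tt <- seq(-0.5, 1.0, by = 1 / eye_fs)
  mk <- function(f) list(fs = eye_fs, t0 = -0.5,
                         traces = t(vapply(seq_len(1), function(i) f(tt),
                                           numeric(length(tt)))))
  expect_true(reject_fixation_breaks(mk(function(t) rep(6, length(t)))))
  expect_false(reject_fixation_breaks(mk(function(t) rep(0, length(t)))))
  # excursion strictly after 0.75 s does not count
  late <- mk(function(t) ifelse(t > 0.78, 5.1, 0))
  expect_false(reject_fixation_breaks(late))
  expect_warning(fl <- reject_fixation_breaks(NULL, n_repeats = 7),
                 "skipped")
  expect_equal(fl, rep(FALSE, 7))
})

test_that("impedance rejection is strict at 25 kOhm", {
  expect_equal(reject_high_impedance(c(25, 30, 24.9, 0)),
               c(FALSE, TRUE, FALSE, FALSE))
  expect_error(reject_high_impedance(c(5, -1)))
})

test_that("6-SD rule catches a spiked repeat and respects the SD=0 skip", {
  # 49 identical repeats + 1 with a 1000 uV spike: max attainable pointwise
  # z is (n-1)/sqrt(n) = 6.93 > 6, so the spike repeat is flagged
  n_rep <- 50; n_samp <- 200
  base <- sin(2 * pi * 10 * seq_len(n_samp) / 1000)
  arr <- array(rep(base, each = 1 * n_rep), dim = c(1, n_rep, n_samp),
               dimnames = list("Oz", NULL, NULL))
  arr[1, 7, 100] <- arr[1, 7, 100] + 1000
  es <- epoch_set(arr, 1000, c(0, 0.2))
  fl <- flag_outlier_repeats(es, domains = "time")
  expect_true(fl[1, 7])
  expect_equal(sum(fl), 1)
  # all repeats identical: every pointwise SD is 0, nothing is flagged
  arr0 <- array(rep(base, each = n_rep), dim = c(1, n_rep, n_samp),
                dimnames = list("Oz", NULL, NULL))
  expect_equal(sum(flag_outlier_repeats(epoch_set(arr0, 1000, c(0, 0.2)),
                                        domains = "time")), 0)
})

test_that("6-SD rule is conservative on i.i.d. Gaussian repeats", {
  es <- white_epochs(n_el = 2, n_rep = 100, n_samp = 250, seed = 8)
  fl <- flag_outlier_repeats(es)
  expect_lte(mean(fl), 0.05)
})

test_that("RMS bounds are applied strictly", {
  mk_es <- function(vals) {
    arr <- array(0, dim = c(1, length(vals), 100),
                 dimnames = list("Oz", NULL, NULL))
    for (r in seq_along(vals)) arr[1, r, ] <- vals[[r]]
    epoch_set(arr, 1000, c(0, 0.1))
  }
  es <- mk_es(list(rep(0.5, 100),                       # RMS 0.5 < 1.25
                   10 * sin(2 * pi * 50 * 1:100 / 1000), # RMS ~7.07
                   rep(40, 100)))                       # RMS 40 > 35
  expect_equal(unname(flag_rms_outliers(es)[1, ]), c(TRUE, FALSE, TRUE))
  # eyes-closed lower cutoff 2.5 catches the 2 uV repeat
  es2 <- mk_es(list(rep(2, 100), rep(3, 100)))
  expect_equal(unname(flag_rms_outliers(es2, lo_uv = 2.5)[1, ]),
               c(TRUE, FALSE))
})

test_that("electrode drop at >30% outliers is strict", {
  fl <- matrix(FALSE, 3, 100,
               dimnames = list(c("a", "b", "c"), NULL))
  fl[1, 1:31] <- TRUE   # 31% -> dropped
  fl[2, 1:30] <- TRUE   # exactly 30% -> kept
  expect_equal(unname(drop_bad_electrodes(fl)), c(TRUE, FALSE, FALSE))
})

test_that("common-bad pooling uses visual electrodes and the 10% rule", {
  m <- default_montage()
  labels <- c("Oz", paste0("x", 1:40))  # one visual + 40 non-visual
  fl <- matrix(FALSE, 41, 3, dimnames = list(labels, NULL))
  fl["Oz", 1] <- TRUE                  # repeat 1: visual electrode
  fl[paste0("x", 1:5), 2] <- TRUE      # repeat 2: 5/40 = 12.5% of others
  fl[paste0("x", 1:4), 3] <- TRUE      # repeat 3: 4/40 = 10%, strict -> no
  expect_equal(common_bad_repeats(fl, m), c(TRUE, TRUE, FALSE))
})

test_that("56-84 Hz slope rejection flags rising spectra only", {
  freqs <- seq(2, 200, 2)
  pw <- rbind(
    white = rep(1, length(freqs)),          # chi = 0 -> kept
    rising = 10^(0.5 * log10(freqs)),       # chi = -0.5 -> rejected
    steep = 10^(2 - 2 * log10(freqs))       # chi = 2 -> kept
  )
  sp <- eeg_spectrum(freqs, pw)
  expect_equal(unname(reject_nonpositive_slope_electrodes(sp)),
               c(FALSE, TRUE, FALSE))
  sp_small <- eeg_spectrum(c(60, 70), pw[, 1:2])
  expect_error(reject_nonpositive_slope_electrodes(sp_small), "3 bins")
})

test_that("block validation needs all three posterior groups", {
  m <- default_montage()
  status <- setNames(rep("good", 64), m$all)
  expect_true(validate_block(status, m))
  status2 <- status
  status2[c("POz", "Oz")] <- "rejected_impedance"
  expect_false(validate_block(status2, m))
  status3 <- status
  status3[c("P3", "P1", "PO3")] <- "rejected_outliers"  # O1 remains
  expect_true(validate_block(status3, m))
})

test_that("pipeline on a clean subject rejects nothing", {
  rec <- simulate_subject(60, "eyes_open", quick_cohort(), no_artifacts(),
                          hp_montage(), seed = 17)
  pp <- run_pipeline(rec, montage = hp_montage())
  expect_true(pp$report$block_valid)
  expect_true(all(pp$report$electrode_status == "good"))
  expect_equal(sum(pp$report$repeat_flags != "good"), 0)
})

test_that("a flat channel is rejected at the RMS stage", {
  mon <- hp_montage()
  rec <- simulate_subject(60, "eyes_open", quick_cohort(), no_artifacts(),
                          mon, seed = 18)
  rec$data["P3", ] <- 0
  pp <- run_pipeline(rec, montage = mon)
  expect_equal(unname(pp$report$electrode_status["P3"]), "rejected_rms")
  expect_true(pp$report$block_valid)  # left group still has P1, PO3, O1
})

test_that("pipeline stages are ordered, reported, and reproducible", {
  mon <- hp_montage()
  art <- artifact_config(rms_outlier_fraction = 0.1,
                         fixation_break_fraction = 0.2)
  rec <- simulate_subject(66, "eyes_open", quick_cohort(), art, mon,
                          seed = 23)
  pp1 <- run_pipeline(rec, montage = mon)
  pp2 <- run_pipeline(rec, montage = mon)
  expect_identical(pp1$report$stages, pp2$report$stages)
  expect_equal(pp1$report$stages$stage,
               c("fixation_breaks", "impedance", "sd_outliers_time_freq",
                 "electrode_drop_outliers", "common_bad",
                 "nonpositive_slope", "rms_outliers", "electrode_drop_rms",
                 "common_bad_rms", "block_valid"))
  expect_gt(pp1$report$stages$fraction_rejected[1], 0)  # fixation breaks
  expect_true(all(pp1$report$stages$fraction_rejected >= 0 &
                    pp1$report$stages$fraction_rejected <= 1))
  # injected out-of-range repeats are flagged somewhere in the pipeline
  expect_gt(sum(pp1$report$repeat_flags != "good"), 0)
})

test_that("adding artifacts never decreases the flag count", {
  mon <- hp_montage()
  rec <- simulate_subject(60, "eyes_open", quick_cohort(), no_artifacts(),
                          mon, seed = 37)
  base_flags <- sum(run_pipeline(rec, montage = mon)$report$repeat_flags !=
                      "good")
  worse <- rec
  spans <- lapply(rec$trial_onsets[c(3, 9)],
                  function(o) (o - 1250):(o - 1))
  for (s in spans) worse$data[, s] <- worse$data[, s] * 10
  worse_flags <- sum(run_pipeline(worse, montage = mon)$report$repeat_flags !=
                       "good")
  expect_gte(worse_flags, base_flags + 2)  # both spoiled repeats caught
})

test_that("running the pipeline on its own clean output flags nothing new", {
  mon <- hp_montage()
  rec <- simulate_subject(60, "eyes_open", quick_cohort(), no_artifacts(),
                          mon, seed = 29)
  pp <- run_pipeline(rec, montage = mon)
  # rebuild a recording from the surviving repeats and re-run
  keep <- which(apply(pp$epochs$flags == "good", 2, all))
  fs <- rec$fs
  segs <- lapply(keep, function(r) pp$epochs$epochs[, r, ])
  dat2 <- do.call(cbind, segs)
  rec2 <- eeg_recording(dat2, fs, labels = rec$labels,
                        impedances = rec$impedances,
                        trial_onsets = (seq_along(keep) - 1) * 1250 + 1251,
                        condition = "eyes_open")
  pp2 <- run_pipeline(rec2, montage = mon)
  expect_equal(sum(pp2$report$repeat_flags != "good"), 0)
  expect_true(all(pp2$report$electrode_status == "good"))
})

test_that("eyes-closed pipeline uses the RMS-first variant", {
  mon <- hp_montage()
  rec <- simulate_subject(70, "eyes_closed", quick_cohort(), no_artifacts(),
                          mon, seed = 31)
  pp <- run_pipeline(rec, montage = mon)
  expect_true(pp$report$block_valid)
  expect_equal(pp$report$stages$stage[1:2],
               c("impedance", "rms_then_sd_outliers_freq"))
  expect_false("rms_outliers" %in% pp$report$stages$stage)
  expect_error(run_pipeline(rec, mode = "eyes_open", montage = mon),
               "does not match")
})
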