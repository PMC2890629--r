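test_that("cohort generation is deterministic and correctly labelled", {
  sp <- calib_spec(seed = 71)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_length(c1, 40)
  expect_equal(sum(vapply(c1, `[[`, "", "group") == "control"), 20)
  expect_identical(lapply(c1, `[[`, "data"), lapply(c2, `[[`, "data"))
  # different seed changes the data
  sp2 <- calib_spec(seed = 72)
  c3 <- generate_cohort(sp2)
  expect_false(identical(c1[[1]]$data, c3[[1]]$data))
  # default spec matches the 20 + 20 study structure at full scale
  dflt <- cohort_spec()
  expect_equal(dflt$n_control, 20)
  expect_equal(dflt$n_epileptic, 20)
  expect_equal(dflt$sampling_rate, 400)
  expect_equal(dflt$epoch_duration, 10.24)
  expect_length(dflt$channels, 30)
})

test_that("spec validation rejects impossible configurations", {
  expect_error(calib_spec(coupling = c(theta = 1.2, alpha = 0.5)),
               "\\[0, 1\\]")
  expect_error(calib_spec(band_amplitude = c(theta = -1, alpha = 1)),
               "nonnegative")
  expect_error(cohort_spec(n_control = 0), "at least 1")
  expect_error(cohort_spec(sampling_rate = 100), "Nyquist")
  expect_error(calib_spec(effect_lobes = "XX"), "unknown")
})

test_that("raising coupling raises within-lobe coherence monotonically", {
  m <- montage_scheme("bivariate", list(CL = list(c("C3", "CP3"))))
  mean_coh <- vapply(c(0.1, 0.5, 0.9), function(cp) {
    sp <- calib_spec(seed = 73, coupling = c(theta = cp, alpha = cp),
                     coupling_sd = 0)
    vals <- vapply(1:8, function(i) {
      ep <- generate_subject(sp, "control", 5000 + i, "S")
      bm <- coherence_biomarkers(ep, m, calib_bands(), methods = "MS-COH",
                                 window_len = 64)
      mean(bm)
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_coh) > 0))
})

test_that("raising band amplitude raises the band power biomarker", {
  mean_bm <- vapply(c(1, 3, 9), function(a) {
    sp <- calib_spec(seed = 74,
                     band_amplitude = c(theta = a, alpha = 3),
                     subject_sd = 0)
    vals <- vapply(1:6, function(i) {
      ep <- generate_subject(sp, "control", 6000 + i, "S")
      bm <- wt_biomarkers(ep, calib_montage(), calib_bands(),
                          calib_wavelet())
      mean(bm[grep("^theta", names(bm))])
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_bm) > 0))
})

test_that("uncoupled white-noise subjects hit the Welch no-coupling floor", {
  sp <- calib_spec(seed = 75, coupling = c(theta = 0, alpha = 0),
                   coupling_sd = 0, noise_exponent = 0,
                   epoch_duration = 2)
  m <- montage_scheme("bivariate", list(CL = list(c("C3", "CP3"))))
  # window 64 on 256 samples -> K = 4 segments -> floor 1/4
  vals <- vapply(1:200, function(i) {
    ep <- generate_subject(sp, "control", 7000 + i, "S")
    bm <- coherence_biomarkers(ep, m, calib_bands(), methods = "MS-COH",
                               window_len = 64)
    mean(bm)
  }, 0)
  # band-filtering correlates adjacent segments slightly, so the realized
  # floor sits just above 1/K; the +-0.05 band covers it
  expect_lt(abs(mean(vals) - 0.25), 0.05)
})

test_that("amplitude calibration hits the requested group separation", {
  sp <- calib_spec(seed = 76)
  cal <- calibrate_band_effect(sp, "theta", "CL", target_d = 2,
                               montage = calib_montage(),
                               config = calib_wavelet(), n_pilot = 8)
  expect_gt(cal$multiplier, 1)
  expect_gt(cal$slope, 0)
  # apply the multiplier and verify the realized effect is near 2 pooled SD
  sp$group_effect["theta"] <- cal$multiplier
  bt <- compute_biomarkers(generate_cohort(sp), measures = "WT",
                           montage_uni = calib_montage(),
                           bands = calib_bands(),
                           wavelet = calib_wavelet())
  j <- which(colnames(bt$values) == "WT.theta.CL")
  e <- bt$values[bt$groups == "epileptic", j]
  c0 <- bt$values[bt$groups == "control", j]
  d_real <- (mean(e) - mean(c0)) /
    sqrt((var(e) + var(c0)) / 2)
  expect_gt(d_real, 1)
  expect_lt(d_real, 3.5)
})

test_that("a null-calibrated effect reproduces non-significant group gaps", {
  # mild theta elevation (amplitude ratio ~ 1.07, the default) at n = 20
  # per group stays non-significant in most cohorts, matching the reported
  # pattern for resting theta power
  ps <- vapply(1:10, function(k) {
    sp <- calib_spec(seed = 800 + k,
                     group_effect = c(theta = 1.07, alpha = 1))
    bt <- compute_biomarkers(generate_cohort(sp), measures = "WT",
                             montage_uni = calib_montage(),
                             bands = calib_bands(),
                             wavelet = calib_wavelet())
    j <- which(colnames(bt$values) == "WT.theta.CL")
    welch_t_test(bt$values[bt$groups == "epileptic", j],
                 bt$values[bt$groups == "control", j])$p
  }, 0)
  expect_gt(median(ps), 0.1)
})
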