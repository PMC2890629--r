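test_that("scale-frequency conversion uses f = 1/(k s) and inverts", {
  wc <- wavelet_config()
  expect_equal(scale_to_frequency(1, wc), 1 / 1.03, tolerance = 1e-12)
  s <- c(0.01, 0.1, 1, 2)
  expect_equal(frequency_to_scale(scale_to_frequency(s, wc), wc), s,
               tolerance = 1e-12)
  expect_error(scale_to_frequency(-1, wc), "positive")
  expect_error(frequency_to_scale(0, wc), "positive")
})

test_that("the analytic Fourier factor for omega0 = 6 rounds to 1.03", {
  k <- morlet_fourier_factor(6)
  expect_equal(k, 4 * pi / (6 + sqrt(38)), tolerance = 1e-15)
  expect_equal(round(k, 2), wavelet_config()$k)
})

test_that("FFT-based CWT equals the direct-convolution oracle", {
  set.seed(42)
  x <- rnorm(300)
  dt <- 1 / 400
  wc <- wavelet_config(f_range = c(2, 90), n_voices = 3)
  res <- morlet_cwt(x, dt, wc)
  for (i in c(1, 4, 8, length(wc$scales))) {
    Wd <- cwt_direct(x, wc$scales[i], dt)
    expect_lt(max(Mod(res$W[i, ] - Wd)) / max(Mod(Wd)), 1e-8)
  }
})

test_that("CWT of zero signal is zero; constant signal has near-zero power", {
  wc <- wavelet_config(f_range = c(1, 40), n_voices = 6)
  dt <- 1 / 128
  z <- morlet_cwt(rep(0, 256), dt, wc)
  expect_true(all(Mod(z$W) == 0))
  # the omega0 = 6 Morlet has negligible mean, so away from the epoch edges
  # a constant input leaves only the numerically computed DC leakage of the
  # sampled wavelet (edge samples see a truncated wavelet and are larger)
  r1 <- morlet_cwt(rep(1, 256), dt, wc)
  for (i in which(wc$freqs >= 8)) {   # scales whose 6s support fits inside
    s <- wc$scales[i]
    dc_leak <- abs(sum(eegmarkers:::morlet_kernel(s, dt, 1024, 6)))
    interior <- Mod(r1$W[i, 120:136])
    expect_lt(max(interior), dc_leak + 1e-7)
    expect_lt(max(interior), 1e-6)
  }
  # even with edges included, a constant is far below a unit sinusoid
  t <- (0:255) * dt
  sine_pk <- max(morlet_cwt(sqrt(2) * sin(2 * pi * 10 * t), dt, wc)$power)
  expect_lt(max(r1$power), 0.01 * sine_pk)
})

test_that("power localizes at the sinusoid frequency across the grid", {
  dt <- 1 / 400
  t <- (0:4095) * dt
  wc <- wavelet_config()
  step <- 2^(1 / wc$n_voices)
  for (f0 in c(5, 10, 20, 40)) {
    r <- morlet_cwt(sqrt(2) * sin(2 * pi * f0 * t), dt, wc)
    fpk <- r$freqs[which.max(r$power)]
    expect_lt(abs(log2(fpk / f0)), log2(step) + 1e-9)
  }
})

test_that("unit-energy normalization equalizes sinusoid peak power", {
  dt <- 1 / 400
  t <- (0:4095) * dt
  pks <- vapply(c(5, 10, 20, 40), function(f0)
    max(morlet_cwt(sqrt(2) * sin(2 * pi * f0 * t), dt)$power), 0)
  expect_lt(max(pks) / min(pks), 1.10)
})

test_that("band biomarkers average power then convert to the log scale", {
  # hand-built case: 2 channels x 2 scales with powers {1, 100; 10, 1000}
  # averaged jointly -> 277.75 -> 10*log10
  pw <- matrix(c(1, 10, 100, 1000), 2)   # scales x channels
  expect_equal(10 * log10(mean(pw)), 10 * log10(277.75))

  # through the real pipeline: equal powers give 10*log10(P)
  e <- toy_epoch(3, 512, 128, seed = 9, labels = c("C3", "CP3", "C4"))
  m <- montage_scheme("univariate", list(CL = c("C3", "CP3")))
  bs <- band_scheme(list(alpha = c(8, 13)))
  wc <- wavelet_config(f_range = c(8, 13))
  bm <- wt_biomarkers(e, m, bs, wc)
  # oracle: recompute from raw per-scale powers
  es <- standardize_epoch(e)
  p1 <- morlet_cwt(es$data["C3", ], 1 / 128, wc)$power
  p2 <- morlet_cwt(es$data["CP3", ], 1 / 128, wc)$power
  idx <- eegmarkers:::band_scale_index(wc$freqs, c(8, 13))
  expect_equal(unname(bm["alpha.CL"]),
               10 * log10(mean(c(p1[idx], p2[idx]))), tolerance = 1e-12)
})

test_that("scaling a signal by c shifts every band biomarker by 20 log10(c)", {
  e <- toy_epoch(2, 512, 128, seed = 10, labels = c("C3", "C4"))
  m <- montage_scheme("univariate", list(CL = "C3", CR = "C4"))
  bs <- calib_bands()
  wc <- calib_wavelet()
  b1 <- wt_biomarkers(e, m, bs, wc, standardize = FALSE)
  e2 <- e; e2$data <- e2$data * 3.5
  b2 <- wt_biomarkers(e2, m, bs, wc, standardize = FALSE)
  expect_equal(as.numeric(b2 - b1), rep(20 * log10(3.5), length(b1)),
               tolerance = 1e-9)
})

test_that("configuration errors are caught", {
  expect_error(wavelet_config(f_range = c(10, 5)))
  # grid above Nyquist
  expect_error(morlet_cwt(rnorm(128), 1 / 100, wavelet_config()),
               "Nyquist")
  # band with no scales
  e <- toy_epoch(1, 256, 128, labels = "C3")
  m <- montage_scheme("univariate", list(X = "C3"))
  bs <- band_scheme(list(theta = c(4, 8), hi = c(40, 60)))
  expect_error(wt_biomarkers(e, m, bs, wavelet_config(f_range = c(4, 8))),
               "hi")
})
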