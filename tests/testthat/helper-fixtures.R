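# Shared fixtures: small epochs, reduced-scale cohort specs, and independent
# oracles used across the test files.

toy_epoch <- function(n_channels = 3, n = 256, fs = 128, seed = 1,
                      labels = NULL, group = "unknown") {
  set.seed(seed)
  if (is.null(labels)) labels <- paste0("CH", seq_len(n_channels))
  eeg_epoch(matrix(rnorm(n_channels * n), n_channels), labels, fs,
            subject_id = paste0("T", seed), group = group)
}

# Reduced-scale two-band, two-lobe cohort spec used for Monte-Carlo checks;
# 4 channels, 128 Hz, 2 s epochs keep each cohort cheap while preserving the
# group structure (20 + 20 subjects).
calib_bands <- function() band_scheme(list(theta = c(4, 8),
                                           alpha = c(8, 13)))

calib_spec <- function(seed = 1, ...) {
  defaults <- list(
    n_control = 20, n_epileptic = 20, sampling_rate = 128,
    epoch_duration = 2, bands = calib_bands(),
    channels = c("C3", "CP3", "C4", "CP4"),
    lobes = list(CL = c("C3", "CP3"), CR = c("C4", "CP4")),
    band_amplitude = c(theta = 3, alpha = 3),
    group_effect = c(theta = 1, alpha = 1),
    seed = seed)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

calib_wavelet <- function() wavelet_config(f_range = c(4, 13))

calib_montage <- function() montage_scheme("univariate",
  list(CL = c("C3", "CP3"), CR = c("C4", "CP4")))

# Direct time-domain CWT: the independent oracle for the FFT implementation.
cwt_direct <- function(x, s, dt, omega0 = 6) {
  N <- length(x)
  W <- complex(length.out = N)
  for (n in seq_len(N)) {
    eta <- ((1:N) - n) * dt / s
    psi <- sqrt(dt / s) * pi^(-0.25) * exp(1i * omega0 * eta - eta^2 / 2)
    W[n] <- sum(x * Conj(psi))
  }
  W
}

# Fixed stable bivariate AR(2) generators used by the recovery tests. The
# coupled variant has symmetric cross-dynamics and strongly correlated
# innovations, giving in-band coherence near 0.9-1 (where the Welch
# estimator's variance is small enough for tight parametric comparison).
bvar2_generator <- function(coupled = FALSE) {
  if (coupled) {
    phi1 <- matrix(c(0.6, 0.25, 0.25, 0.5), 2, byrow = TRUE)
    phi2 <- matrix(c(-0.2, 0.1, 0.1, -0.2), 2, byrow = TRUE)
    Q <- matrix(c(1, 0.99, 0.99, 1), 2)
  } else {
    phi1 <- matrix(c(0.5, 0.3, 0.2, 0.4), 2, byrow = TRUE)
    phi2 <- matrix(c(-0.3, 0.1, 0.05, -0.25), 2, byrow = TRUE)
    Q <- diag(2)
  }
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- -phi1
  A[, , 2] <- -phi2
  structure(list(A = A, Q = Q, order = 2, N = 0,
                 criterion_curve = numeric(0), stable = TRUE),
            class = "bvar")
}

# From-scratch Welch t oracle applying the two formulas symbolically.
welch_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
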