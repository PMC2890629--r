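test_that("WWR solution equals the block-Toeplitz normal-equations oracle", {
  gen <- bvar2_generator()
  z <- simulate(gen, nsim = 2048, seed = 99)
  fit <- fit_bivariate_ar(z[, 1], z[, 2], max_order = 5,
                          standardize = FALSE)
  m <- fit$order
  # oracle: direct linear solve of the Yule-Walker block system built from
  # the same biased autocovariances
  zc <- z
  n <- nrow(zc)
  Rh <- function(h) {
    if (h >= 0) crossprod(zc[(h + 1):n, , drop = FALSE],
                          zc[1:(n - h), , drop = FALSE]) / n
    else t(Rh(-h))
  }
  G <- matrix(0, 2 * m, 2 * m)
  for (j in 1:m) for (i in 1:m)
    G[(2 * j - 1):(2 * j), (2 * i - 1):(2 * i)] <- Rh(i - j)
  RHS <- do.call(cbind, lapply(1:m, Rh))
  PHI <- RHS %*% solve(G)
  A_oracle <- array(0, c(2, 2, m))
  for (j in 1:m) A_oracle[, , j] <- -PHI[, (2 * j - 1):(2 * j)]
  expect_lt(max(abs(fit$A - A_oracle)), 1e-6)
  Q_oracle <- Rh(0)
  for (j in 1:m) Q_oracle <- Q_oracle - PHI[, (2 * j - 1):(2 * j)] %*%
      t(Rh(j))
  expect_lt(max(abs(fit$Q - (Q_oracle + t(Q_oracle)) / 2)), 1e-6)
})

test_that("MDL recovers the true order and coefficients of an AR(2)", {
  gen <- bvar2_generator()
  n_seeds <- 20
  orders <- integer(n_seeds)
  errs <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    z <- simulate(gen, nsim = 4096, seed = 300 + s)
    fit <- fit_bivariate_ar(z[, 1], z[, 2], max_order = 50,
                            standardize = FALSE)
    orders[s] <- fit$order
    errs[s] <- if (fit$order == 2) max(abs(fit$A - gen$A)) else NA
  }
  expect_gte(mean(orders == 2), 0.9)
  expect_gte(mean(errs <= 0.05, na.rm = TRUE), 0.9)
})

test_that("independent white noise yields small order and tiny couplings", {
  set.seed(44)
  hits <- replicate(10, {
    x <- rnorm(2048); y <- rnorm(2048)
    fit <- fit_bivariate_ar(x, y, max_order = 20)
    offdiag <- if (fit$order > 0)
      max(abs(c(fit$A[1, 2, ], fit$A[2, 1, ]))) else 0
    c(order = fit$order, off = offdiag)
  })
  expect_gte(mean(hits["order", ] <= 2), 0.7)
  expect_lt(max(hits["off", ]), 0.1)
})

test_that("AR spectral matrix has the analytic limits and mass", {
  dt <- 1 / 400
  # m = 0 white noise with identity covariance: S(f) = dt * I
  white <- structure(list(A = array(0, c(2, 2, 0)), Q = diag(2)),
                     class = "bvar")
  S <- ar_spectral_matrix(white, c(0, 10, 100), dt)
  expect_equal(Re(S[1, 1, ]), rep(dt, 3), tolerance = 1e-12)
  expect_equal(Mod(S[1, 2, ]), rep(0, 3), tolerance = 1e-12)

  # diagonal dynamics + diagonal Q: zero cross-spectrum everywhere
  Ad <- array(0, c(2, 2, 1)); Ad[, , 1] <- diag(c(-0.5, 0.3))
  diagm <- structure(list(A = Ad, Q = diag(c(1, 2))), class = "bvar")
  Sd <- ar_spectral_matrix(diagm, seq(0, 200, by = 10), dt)
  expect_true(all(Mod(Sd[1, 2, ]) < 1e-12))
  expect_true(all(abs(ar_coherence(diagm, seq(0, 200, 10), dt)$coherence)
                  < 1e-12))

  # spectral mass integrates to the process covariance (2% tolerance)
  gen <- bvar2_generator()
  fr <- seq(0, 200, length.out = 2049)
  Sg <- ar_spectral_matrix(gen, fr, dt)
  df <- fr[2] - fr[1]
  intS <- 2 * (apply(Re(Sg), c(1, 2), sum) -
                 0.5 * Re(Sg[, , 1]) - 0.5 * Re(Sg[, , 2049])) * df
  zz <- simulate(gen, nsim = 2e5, seed = 7)
  expect_equal(intS, cov(zz), tolerance = 0.02)
})

test_that("AR coherence is bounded, symmetric, and matches Welch on long
           coupled simulations", {
  gen <- bvar2_generator(coupled = TRUE)
  fs <- 400
  z <- simulate(gen, nsim = 8192, seed = 11)
  cs <- welch_cross_spectrum(z[, 1], z[, 2], fs, window_len = 1024)
  msc <- ms_coherence(cs)
  fit <- fit_bivariate_ar(z[, 1], z[, 2], max_order = 50)
  arc <- ar_coherence(fit, cs$freq, 1 / fs)
  expect_true(all(arc$coherence >= 0 & arc$coherence <= 1))
  inb <- cs$freq >= 2 & cs$freq <= 45
  expect_lt(max(abs(arc$coherence[inb] - msc$coherence[inb])), 0.1)
  # swap invariance
  fit_rev <- fit_bivariate_ar(z[, 2], z[, 1], max_order = 50)
  arc_rev <- ar_coherence(fit_rev, cs$freq, 1 / fs)
  expect_equal(arc$coherence, arc_rev$coherence, tolerance = 1e-8)
})

test_that("fit preconditions and accessors behave", {
  expect_error(fit_bivariate_ar(rnorm(100), rnorm(100), max_order = 50),
               "10 x max_order")
  gen <- bvar2_generator()
  z <- simulate(gen, nsim = 1024, seed = 1)
  fit <- fit_bivariate_ar(z[, 1], z[, 2], max_order = 10)
  expect_true(fit$stable)
  expect_equal(dim(coef(fit)), c(2, 2, fit$order))
  expect_true(isSymmetric(fit$Q))
  expect_true(all(eigen(fit$Q, only.values = TRUE)$values > 0))
})
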