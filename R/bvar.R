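#' Fit a bivariate autoregressive model with MDL order selection
#'
#' Models the joint dynamics of two channels as
#' \eqn{z_n = -A_1 z_{n-1} - \dots - A_m z_{n-m} + e_n} with real 2x2
#' coefficient matrices, \eqn{A_0 = I}, and residual covariance \eqn{Q_m};
#' pre-sample values are treated as zero. Autocovariances are estimated with
#' the biased (1/N) estimator and the model is fitted for every candidate
#' order by the Whittle-Wiggins-Robinson multichannel Levinson recursion.
#' The returned order minimizes the minimum description length criterion
#' \deqn{MDL(m) = N \log\det\hat Q_m + 4 m \log N,}
#' where 4 is the number of real parameters per lag of a bivariate model.
#'
#' @param x,y numeric signals of equal length (typically standardized); the
#'   length must be at least `10 * max_order`.
#' @param max_order largest candidate order (default 50; candidates are
#'   `1:max_order`).
#' @param criterion order-selection criterion: a function
#'   `(N, logdetQ, m) -> value` to minimize; default is the MDL above.
#' @param standardize standardize the two signals first (default TRUE).
#' @return an object of class `bvar`: list with `order`, coefficient array
#'   `A` (2 x 2 x order), residual covariance `Q`, sample size `N`,
#'   `criterion_curve` over candidate orders, `stable` flag and the
#'   channel sampling metadata needed for spectra.
#' @seealso [ar_spectral_matrix()], [ar_coherence()]
#' @export
fit_bivariate_ar <- function(x, y, max_order = 50, criterion = NULL,
                             standardize = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("signals must have equal length")
  if (n < 10 * max_order)
    stop("need at least 10 x max_order (", 10 * max_order, ") samples, got ",
         n)
  if (standardize) {
    x <- (x - mean(x)) / stats::sd(x)
    y <- (y - mean(y)) / stats::sd(y)
  }
  if (is.null(criterion))
    criterion <- function(N, logdetQ, m) N * logdetQ + 4 * m * log(N)
  z <- cbind(x, y)
  R <- autocov_blocks(z, max_order)
  ww <- wwr_recursion(R, max_order)
  crit <- vapply(seq_len(max_order), function(m) {
    ld <- determinant(ww$Pf[[m]], logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    criterion(n, as.numeric(ld$modulus), m)
  }, 0)
  if (all(!is.finite(crit)))
    stop("numerically singular autocovariance: no admissible order in 1:",
         max_order)
  m <- which.min(crit)
  phi <- ww$phi[[m]]                       # list of 2x2 forward coefficients
  A <- array(0, c(2, 2, m))
  for (j in seq_len(m)) A[, , j] <- -phi[[j]]
  Q <- ww$Pf[[m]]
  Q <- (Q + t(Q)) / 2
  structure(list(
    order = m, A = A, Q = Q, N = n,
    criterion_curve = crit,
    stable = bvar_stable(A),
    channel_names = c(deparse(substitute(x))[1], deparse(substitute(y))[1])
  ), class = "bvar")
}

# Biased sample autocovariance blocks R(h) = (1/N) sum z_n z_{n-h}^T,
# h = 0..m, consistent with the zero pre-sample convention.
autocov_blocks <- function(z, m) {
  n <- nrow(z)
  R <- vector("list", m + 1)
  for (h in 0:m)
    R[[h + 1]] <- crossprod(z[(h + 1):n, , drop = FALSE],
                            z[1:(n - h), , drop = FALSE]) / n
  R
}

# Whittle-Wiggins-Robinson recursion over orders 1..m for the forward
# predictor z_n ~ sum_j phi_j z_{n-j}. Returns per-order forward
# coefficients and prediction-error covariances.
wwr_recursion <- function(R, m) {
  Rh <- function(h) if (h >= 0) R[[h + 1]] else t(R[[-h + 1]])
  phi <- list(); psi <- list()
  Pf <- vector("list", m); phis <- vector("list", m)
  R0i <- solve(R[[1]])
  phi[[1]] <- Rh(1) %*% R0i
  psi[[1]] <- Rh(-1) %*% R0i
  pf <- R[[1]] - phi[[1]] %*% Rh(-1)
  pb <- R[[1]] - psi[[1]] %*% Rh(1)
  Pf[[1]] <- pf; phis[[1]] <- phi
  if (m >= 2) {
    for (k in 2:m) {
      D <- Rh(k)
      for (j in 1:(k - 1)) D <- D - phi[[j]] %*% Rh(k - j)
      fk <- D %*% solve(pb)
      bk <- t(D) %*% solve(pf)
      nphi <- vector("list", k); npsi <- vector("list", k)
      for (j in 1:(k - 1)) {
        nphi[[j]] <- phi[[j]] - fk %*% psi[[k - j]]
        npsi[[j]] <- psi[[j]] - bk %*% phi[[k - j]]
      }
      nphi[[k]] <- fk; npsi[[k]] <- bk
      pf <- pf - fk %*% t(D)
      pb <- pb - bk %*% D
      phi <- nphi; psi <- npsi
      Pf[[k]] <- pf; phis[[k]] <- phi
    }
  }
  list(phi = phis, Pf = Pf)
}

# Companion-matrix stability check: all eigenvalues strictly inside the unit
# circle.
bvar_stable <- function(A) {
  m <- dim(A)[3]
  C <- matrix(0, 2 * m, 2 * m)
  for (j in seq_len(m)) C[1:2, (2 * j - 1):(2 * j)] <- -A[, , j]
  if (m > 1) C[3:(2 * m), 1:(2 * (m - 1))] <- diag(2 * (m - 1))
  max(Mod(eigen(C, only.values = TRUE)$values)) < 1
}

#' @export
print.bvar <- function(x, ...) {
  cat(sprintf("Bivariate AR model: order %d (of %d candidates), N = %d, %s\n",
              x$order, length(x$criterion_curve), x$N,
              if (x$stable) "stable" else "UNSTABLE"))
  cat("Residual covariance Q:\n")
  print(signif(x$Q, 4))
  invisible(x)
}

#' @export
coef.bvar <- function(object, ...) object$A

#' @export
summary.bvar <- function(object, ...) {
  cat(sprintf("Bivariate AR(%d), N = %d\n", object$order, object$N))
  cat(sprintf("MDL at selected order: %.2f (min over 1:%d)\n",
              object$criterion_curve[object$order],
              length(object$criterion_curve)))
  cat(if (object$stable) "Model is stable.\n" else
    "WARNING: companion matrix has spectral radius >= 1.\n")
  for (j in seq_len(object$order)) {
    cat("A_", j, ":\n", sep = "")
    print(signif(object$A[, , j], 4))
  }
  invisible(object)
}

#' Simulate from a bivariate AR model
#'
#' Draws a realization of \eqn{z_n = -A_1 z_{n-1} - \dots - A_m z_{n-m} +
#' e_n} with Gaussian innovations of covariance `Q`, discarding a burn-in.
#'
#' @param object a `bvar` fit, or a list with elements `A` (2 x 2 x m array)
#'   and `Q` (2 x 2 covariance).
#' @param nsim number of samples to return.
#' @param seed optional integer seed.
#' @param burn_in samples to discard (default 500).
#' @param ... unused.
#' @return an `nsim` x 2 numeric matrix.
#' @export
simulate.bvar <- function(object, nsim = 1000, seed = NULL, burn_in = 500,
                          ...) {
  if (!is.null(seed)) set.seed(seed)
  A <- object$A
  Q <- object$Q
  m <- dim(A)[3]
  L <- t(chol(Q))
  ntot <- nsim + burn_in
  z <- matrix(0, ntot, 2)
  e <- matrix(stats::rnorm(2 * ntot), 2, ntot)
  for (nn in seq_len(ntot)) {
    acc <- L %*% e[, nn]
    for (j in seq_len(min(m, nn - 1)))
      acc <- acc - A[, , j] %*% z[nn - j, ]
    z[nn, ] <- acc
  }
  z[(burn_in + 1):ntot, , drop = FALSE]
}

#' Parametric spectral matrix of a bivariate AR model
#'
#' Evaluates the factorization \eqn{S(f) = H(f) Q H(f)^*} with
#' \eqn{H(f) = [\sum_{j=0}^m A_j e^{-i 2\pi f j \Delta t}]^{-1}} and
#' \eqn{A_0 = I}. Every returned matrix is Hermitian positive semi-definite.
#'
#' @param model a `bvar` fit (or compatible list with `A`, `Q`, `order`).
#' @param freqs frequencies in Hz at which to evaluate.
#' @param dt sample spacing in seconds.
#' @return a 2 x 2 x length(freqs) complex array.
#' @export
ar_spectral_matrix <- function(model, freqs, dt) {
  A <- model$A
  Q <- model$Q
  m <- if (is.null(dim(A))) 0 else dim(A)[3]
  S <- array(0i, c(2, 2, length(freqs)))
  for (i in seq_along(freqs)) {
    Af <- diag(2) + 0i
    for (j in seq_len(m))
      Af <- Af + A[, , j] * exp(-1i * 2 * pi * freqs[i] * j * dt)
    H <- tryCatch(solve(Af), error = function(e)
      stop("transfer matrix singular at ", freqs[i], " Hz"))
    Sf <- dt * (H %*% Q %*% Conj(t(H)))
    S[, , i] <- (Sf + Conj(t(Sf))) / 2
  }
  S
}

#' Coherence spectrum of a bivariate AR model
#'
#' The magnitude-squared coherence evaluated from the parametric spectral
#' matrix ("AR-COH"): \eqn{\gamma^2(f) = |S_{12}|^2/(S_{11} S_{22})},
#' clamped to `[0, 1]`.
#'
#' @param model a `bvar` fit.
#' @param freqs frequencies in Hz.
#' @param dt sample spacing in seconds.
#' @return an object of class `coherence_spectrum` with `method = "AR-COH"`.
#' @export
ar_coherence <- function(model, freqs, dt) {
  S <- ar_spectral_matrix(model, freqs, dt)
  s11 <- Re(S[1, 1, ]); s22 <- Re(S[2, 2, ])
  den <- s11 * s22
  coh <- rep(NA_real_, length(freqs))
  ok <- den > 0
  coh[ok] <- Mod(S[1, 2, ok])^2 / den[ok]
  coh[ok] <- pmin(pmax(coh[ok], 0), 1)
  structure(list(freq = freqs, coherence = coh, method = "AR-COH",
                 n_flagged = sum(!ok)),
            class = "coherence_spectrum")
}
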