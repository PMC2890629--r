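#' Morlet continuous wavelet transform configuration
#'
#' The analyzing wavelet is the unit-energy complex Morlet
#' \eqn{\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}} with
#' dimensionless centre frequency `omega0 = 6`, a standard trade-off between
#' time and frequency localization. Each scale `s` maps to an equivalent
#' Fourier frequency through `f = 1/(k s)`; for `omega0 = 6` the analytic
#' Fourier-period factor \eqn{4\pi/(\omega_0 + \sqrt{2+\omega_0^2})} rounds
#' to the conventional `k = 1.03`.
#'
#' The scale grid is logarithmic with `n_voices` scales per octave spanning
#' `f_range` (default 0.5--90 Hz; 0 Hz is not representable by a finite
#' scale, so the delta band is gridded from 0.5 Hz).
#'
#' @param omega0 dimensionless centre frequency (default 6).
#' @param k scale-to-frequency constant in `f = 1/(k s)` (default 1.03).
#' @param n_voices scales per octave of the grid (default 12).
#' @param f_range length-2 numeric, equivalent-frequency span of the grid in
#'   Hz.
#' @param db_multiplier multiplier applied to `log10(power)` for the band
#'   biomarker: 10 gives dB, 1 gives plain log10 power. Downstream statistics
#'   are invariant to this monotone rescaling.
#' @return an object of class `wavelet_config` with the scale grid and its
#'   frequency axis.
#' @examples
#' wc <- wavelet_config()
#' range(wc$freqs)
#' @export
wavelet_config <- function(omega0 = 6, k = 1.03, n_voices = 12,
                           f_range = c(0.5, 90), db_multiplier = 10) {
  stopifnot(omega0 > 0, k > 0, n_voices >= 1,
            length(f_range) == 2, f_range[1] > 0, f_range[1] < f_range[2])
  lf <- seq(log2(f_range[1]), log2(f_range[2]), by = 1 / n_voices)
  if (lf[length(lf)] < log2(f_range[2]) - 1e-9) lf <- c(lf, log2(f_range[2]))
  freqs <- 2^lf
  scales <- 1 / (k * freqs)              # decreasing in f -> increasing in s
  structure(list(
    omega0 = omega0, k = k, n_voices = n_voices, f_range = f_range,
    db_multiplier = db_multiplier,
    freqs = freqs, scales = scales
  ), class = "wavelet_config")
}

#' Analytic Fourier-period factor of the Morlet wavelet
#'
#' The constant `k` relating scale and equivalent Fourier frequency,
#' `f = 1/(k s)`, computed analytically as
#' \eqn{4\pi/(\omega_0 + \sqrt{2 + \omega_0^2})}.
#'
#' @param omega0 dimensionless centre frequency.
#' @return the factor (about 1.033 for `omega0 = 6`).
#' @export
morlet_fourier_factor <- function(omega0 = 6) {
  stopifnot(omega0 > 0)
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Convert Morlet scale to equivalent frequency (and back)
#'
#' @param s scale (seconds); must be positive.
#' @param f frequency in Hz; must be positive.
#' @param config a [wavelet_config()].
#' @return frequency in Hz (resp. scale in seconds).
#' @export
scale_to_frequency <- function(s, config = wavelet_config()) {
  if (any(s <= 0)) stop("scale must be positive")
  1 / (config$k * s)
}

#' @rdname scale_to_frequency
#' @export
frequency_to_scale <- function(f, config = wavelet_config()) {
  if (any(f <= 0)) stop("frequency must be positive")
  1 / (config$k * f)
}

# Sampled unit-energy Morlet wavelet at scale s on a circular offset grid of
# length P: offsets j = 0..P-1 map to signed lags jj in [-P/2, P/2).
morlet_kernel <- function(s, dt, P, omega0) {
  j <- 0:(P - 1)
  jj <- ifelse(j <= P / 2, j, j - P)
  eta <- jj * dt / s
  sqrt(dt / s) * pi^(-0.25) * exp(1i * omega0 * eta - eta^2 / 2)
}

# Cache of conjugated kernel FFTs keyed by (P, dt, omega0, scale grid hash):
# the kernels depend only on the grid geometry, so they are shared across
# channels, subjects and cohorts of identical shape.
.wavelet_cache <- new.env(parent = emptyenv())

kernel_ffts <- function(scales, dt, P, omega0) {
  key <- paste0(P, "_", format(dt, digits = 17), "_", omega0, "_",
                paste(format(range(scales), digits = 10), collapse = "_"),
                "_", length(scales))
  hit <- .wavelet_cache[[key]]
  if (!is.null(hit)) return(hit)
  K <- matrix(0i, length(scales), P)
  for (i in seq_along(scales))
    K[i, ] <- Conj(stats::fft(morlet_kernel(scales[i], dt, P, omega0)))
  .wavelet_cache[[key]] <- K
  K
}

#' Continuous Morlet wavelet transform of one channel
#'
#' Computes, for every scale on the configured grid, the convolution of the
#' signal with the conjugated, time-reversed, scaled unit-energy Morlet
#' wavelet. The convolution is evaluated by FFT against the explicitly
#' sampled wavelet on a zero-padded grid (signal taken as zero outside the
#' epoch), which is numerically identical to direct time-domain convolution.
#'
#' @param x numeric signal (one channel), typically standardized; at least 64
#'   samples.
#' @param dt sample spacing in seconds (`1 / sampling_rate`).
#' @param config a [wavelet_config()].
#' @return an object of class `morlet_cwt`: list with complex coefficient
#'   matrix `W` (scales x samples), per-scale time-averaged `power`, `scales`,
#'   `freqs` and the config. The reported power is the scale-rectified
#'   spectrum `mean(|W|^2) / s`, which makes the peak power of a
#'   fixed-amplitude sinusoid comparable across frequencies.
#' @export
morlet_cwt <- function(x, dt, config = wavelet_config()) {
  stopifnot(is.numeric(x), length(x) >= 64, dt > 0)
  nyq <- 1 / (2 * dt)
  if (any(config$freqs > nyq + 1e-9))
    stop("scale grid maps above the Nyquist frequency (", nyq, " Hz)")
  N <- length(x)
  P <- 2^ceiling(log2(2 * N))
  K <- kernel_ffts(config$scales, dt, P, config$omega0)
  xhat <- stats::fft(c(x, rep(0, P - N)))
  W <- matrix(0i, length(config$scales), N)
  for (i in seq_len(nrow(K))) {
    w <- stats::fft(xhat * K[i, ], inverse = TRUE) / P
    W[i, ] <- w[seq_len(N)]
  }
  structure(list(
    W = W,
    power = rowMeans(Mod(W)^2) / config$scales,
    scales = config$scales,
    freqs = config$freqs,
    config = config
  ), class = "morlet_cwt")
}

#' @export
print.morlet_cwt <- function(x, ...) {
  cat(sprintf("Morlet CWT: %d scales (%.3g-%.3g Hz) x %d samples\n",
              length(x$scales), min(x$freqs), max(x$freqs), ncol(x$W)))
  invisible(x)
}

# Scale-grid indices belonging to band (f_low, f_high]; a 0 Hz lower edge is
# open at the 0.5 Hz grid floor (inclusive).
band_scale_index <- function(freqs, band, floor_hz = 0.5) {
  lo <- if (band[1] <= 0) floor_hz - 1e-9 else band[1]
  which(freqs > lo & freqs <= band[2] + 1e-9)
}

#' Wavelet band x lobe power biomarkers for one epoch
#'
#' For each (band, lobe) cell the per-scale time-averaged wavelet power is
#' averaged jointly over the scales falling in the band and the channels of
#' the lobe, then transformed to the log scale
#' (`db_multiplier * log10(mean power)`). The epoch is standardized per
#' channel first unless `standardize = FALSE`.
#'
#' @param epoch an [eeg_epoch()].
#' @param montage a univariate [montage_scheme()].
#' @param bands a [band_scheme()].
#' @param config a [wavelet_config()].
#' @param standardize standardize channels before the transform (default
#'   TRUE).
#' @return named numeric vector of biomarkers, names `"<band>.<lobe>"`, with
#'   attribute `features`: a data.frame (measure, band, lobe).
#' @export
wt_biomarkers <- function(epoch, montage = default_montage("univariate"),
                          bands = default_bands(),
                          config = wavelet_config(), standardize = TRUE) {
  stopifnot(inherits(epoch, "eeg_epoch"), montage$kind == "univariate")
  validate_montage(montage, epoch$channel_labels)
  if (standardize) epoch <- standardize_epoch(epoch)
  dt <- 1 / epoch$sampling_rate
  need <- montage_channels(montage)
  pw <- matrix(NA_real_, length(config$scales), length(need),
               dimnames = list(NULL, toupper(need)))
  for (ch in need) {
    i <- match_channel(ch, epoch$channel_labels)
    pw[, toupper(ch)] <- morlet_cwt(epoch$data[i, ], dt, config)$power
  }
  idx <- lapply(bands$bands, band_scale_index, freqs = config$freqs)
  empty <- names(idx)[vapply(idx, length, 0L) == 0]
  if (length(empty) > 0)
    stop("no grid scales fall inside band(s): ", paste(empty, collapse = ", "))
  out <- numeric(0)
  feat <- NULL
  for (b in names(bands$bands)) {
    for (l in names(montage$lobes)) {
      cols <- toupper(montage$lobes[[l]])
      m <- mean(pw[idx[[b]], cols, drop = FALSE])
      out <- c(out, config$db_multiplier * log10(m))
      feat <- rbind(feat, data.frame(measure = "WT", band = b, lobe = l,
                                     stringsAsFactors = FALSE))
    }
  }
  names(out) <- paste(feat$band, feat$lobe, sep = ".")
  attr(out, "features") <- feat
  out
}
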