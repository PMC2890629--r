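#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero phase distortion) 4th-order Butterworth band-pass.
#' A lower edge of 0 Hz degrades to a low-pass; the delta band is filtered as
#' 0.5--4 Hz by the pipeline since a DC-reaching band-pass is not realizable.
#'
#' @param x numeric signal.
#' @param band length-2 numeric `c(f_low, f_high)` in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @return the filtered signal.
#' @export
eeg_bandpass <- function(x, band, fs, order = 4) {
  stopifnot(length(band) == 2, band[1] >= 0, band[1] < band[2])
  nyq <- fs / 2
  if (band[2] >= nyq)
    stop("band upper edge (", band[2], " Hz) must be below Nyquist (",
         nyq, " Hz)")
  bf <- if (band[1] <= 0) {
    signal::butter(order, band[2] / nyq, type = "low")
  } else {
    signal::butter(order, band / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Welch cross-spectrum of two signals
#'
#' Periodograms of tapered, non-overlapping, consecutive segments are
#' averaged; a trailing partial segment is discarded. The default
#' configuration (1024-sample Hamming window) yields exactly 4 segments on a
#' 4096-sample epoch. One-sided spectral densities are returned; the scaling
#' constants cancel in the coherence ratio.
#'
#' @param x,y numeric signals of equal length, at least `window_len` samples.
#' @param fs sampling rate in Hz.
#' @param window_len segment length in samples (default 1024).
#' @param window taper: `"hamming"`, `"hanning"` or `"boxcar"`.
#' @return an object of class `cross_spectrum`: list with `freq`, `S_xx`,
#'   `S_yy` (real), `S_xy` (complex) and `n_segments`.
#' @export
welch_cross_spectrum <- function(x, y, fs, window_len = 1024,
                                 window = c("hamming", "hanning", "boxcar")) {
  window <- match.arg(window)
  n <- length(x)
  if (length(y) != n) stop("signals must have equal length")
  if (n < window_len)
    stop("need at least one full segment (", window_len, " samples), got ", n)
  L <- window_len
  K <- floor(n / L)
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)),
    hanning = 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1)),
    boxcar = rep(1, L))
  nb <- L %/% 2 + 1
  Sxx <- Syy <- numeric(nb)
  Sxy <- complex(nb)
  for (k in seq_len(K)) {
    i <- ((k - 1) * L + 1):(k * L)
    X <- stats::fft(w * x[i])[seq_len(nb)]
    Y <- stats::fft(w * y[i])[seq_len(nb)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  scale <- 2 / (K * fs * sum(w^2))     # one-sided density
  Sxx <- Sxx * scale; Syy <- Syy * scale; Sxy <- Sxy * scale
  half <- c(1, nb)                     # DC and Nyquist are not doubled
  Sxx[half] <- Sxx[half] / 2; Syy[half] <- Syy[half] / 2
  Sxy[half] <- Sxy[half] / 2
  structure(list(
    freq = (0:(nb - 1)) * fs / L,
    S_xx = Sxx, S_yy = Syy, S_xy = Sxy,
    n_segments = K, window_len = L, window = window
  ), class = "cross_spectrum")
}

#' Magnitude-squared coherence from a cross-spectrum
#'
#' \eqn{\gamma^2(f) = |S_{xy}(f)|^2 / (S_{xx}(f) S_{yy}(f))}, in `[0, 1]`:
#' 0 means no linear coupling, 1 maximum linear interdependence. With a
#' single segment the estimator degenerates to 1 at every bin. Bins where
#' the auto-spectral product is zero are flagged `NA` rather than divided;
#' their count is reported in attribute `n_flagged`.
#'
#' @param cross a [welch_cross_spectrum()] result.
#' @return an object of class `coherence_spectrum`: list with `freq`,
#'   `coherence` and `method = "MS-COH"`.
#' @export
ms_coherence <- function(cross) {
  stopifnot(inherits(cross, "cross_spectrum"))
  den <- cross$S_xx * cross$S_yy
  coh <- rep(NA_real_, length(den))
  ok <- den > 0
  coh[ok] <- Mod(cross$S_xy[ok])^2 / den[ok]
  coh[ok] <- pmin(pmax(coh[ok], 0), 1)
  structure(list(freq = cross$freq, coherence = coh, method = "MS-COH",
                 n_flagged = sum(!ok)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d bins (%.3g-%.3g Hz), mean %.3f\n",
              x$method, length(x$freq), min(x$freq), max(x$freq),
              mean(x$coherence, na.rm = TRUE)))
  invisible(x)
}

# Mean coherence over the frequency bins inside the (effective) band.
band_coherence <- function(coh, band, floor_hz = 0.5) {
  eb <- effective_band(band, floor_hz)
  sel <- coh$freq > eb[1] - 1e-9 & coh$freq <= eb[2] + 1e-9
  if (!any(sel)) stop("no frequency bins inside band ", eb[1], "-", eb[2],
                      " Hz")
  mean(coh$coherence[sel], na.rm = TRUE)
}

#' Coherence band x pair-group biomarkers for one epoch
#'
#' For each frequency band the two channels of every pair are band-pass
#' filtered (zero-phase 4th-order Butterworth), the coherence spectrum is
#' estimated, and bins inside the band are averaged; the biomarker for a
#' (band, pair-group) cell is the mean over the group's pairs. Methods:
#' `"MS-COH"` (Welch estimate, [ms_coherence()]) and/or `"AR-COH"`
#' (parametric estimate from a bivariate autoregressive fit,
#' [ar_coherence()], evaluated on the same frequency grid).
#'
#' @param epoch an [eeg_epoch()].
#' @param montage a bivariate [montage_scheme()].
#' @param bands a [band_scheme()].
#' @param methods subset of `c("MS-COH", "AR-COH")`.
#' @param window_len Welch segment length in samples (default 1024).
#' @param max_order maximum candidate order for the AR fit (default 50).
#' @param standardize standardize channels first (default TRUE).
#' @param broadband if TRUE, estimate coherence on the unfiltered broadband
#'   signals instead of band-filtered ones (band averaging unchanged).
#' @return named numeric vector, names `"<method>.<band>.<lobe>"`, with
#'   attribute `features` (measure, band, lobe).
#' @export
coherence_biomarkers <- function(epoch,
                                 montage = default_montage("bivariate"),
                                 bands = default_bands(),
                                 methods = c("MS-COH", "AR-COH"),
                                 window_len = 1024, max_order = 50,
                                 standardize = TRUE, broadband = FALSE) {
  stopifnot(inherits(epoch, "eeg_epoch"), montage$kind == "bivariate")
  methods <- match.arg(methods, c("MS-COH", "AR-COH"), several.ok = TRUE)
  validate_montage(montage, epoch$channel_labels)
  if (standardize) epoch <- standardize_epoch(epoch)
  fs <- epoch$sampling_rate
  pairs <- unique(unlist(lapply(montage$lobes, function(prs)
    vapply(prs, function(p) paste(sort(toupper(p)), collapse = "|"), "")),
    use.names = FALSE))
  # per (pair, band, method) band-mean coherence
  cell <- list()
  for (pk in pairs) {
    chs <- strsplit(pk, "|", fixed = TRUE)[[1]]
    xi <- epoch$data[match_channel(chs[1], epoch$channel_labels), ]
    yi <- epoch$data[match_channel(chs[2], epoch$channel_labels), ]
    for (b in names(bands$bands)) {
      eb <- effective_band(bands$bands[[b]])
      if (broadband) {
        xf <- xi; yf <- yi
      } else {
        xf <- eeg_bandpass(xi, eb, fs)
        yf <- eeg_bandpass(yi, eb, fs)
      }
      cs <- welch_cross_spectrum(xf, yf, fs, window_len = window_len)
      if ("MS-COH" %in% methods) {
        coh <- ms_coherence(cs)
        cell[[paste("MS-COH", b, pk)]] <- band_coherence(coh,
                                                         bands$bands[[b]])
      }
      if ("AR-COH" %in% methods) {
        fit <- fit_bivariate_ar(xf, yf, max_order = max_order,
                                standardize = FALSE)
        coh <- ar_coherence(fit, freqs = cs$freq, dt = 1 / fs)
        cell[[paste("AR-COH", b, pk)]] <- band_coherence(coh,
                                                         bands$bands[[b]])
      }
    }
  }
  out <- numeric(0)
  feat <- NULL
  for (m in methods) {
    for (b in names(bands$bands)) {
      for (l in names(montage$lobes)) {
        pks <- vapply(montage$lobes[[l]], function(p)
          paste(sort(toupper(p)), collapse = "|"), "")
        vals <- vapply(pks, function(pk) cell[[paste(m, b, pk)]], 0)
        out <- c(out, mean(vals))
        feat <- rbind(feat, data.frame(measure = m, band = b, lobe = l,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  names(out) <- paste(feat$measure, feat$band, feat$lobe, sep = ".")
  attr(out, "features") <- feat
  out
}
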