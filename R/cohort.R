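#' Specification of a synthetic two-group EEG cohort
#'
#' Describes a cohort of `n_control + n_epileptic` subjects whose epochs are
#' built, per frequency band, from linear mixtures of band-limited Gaussian
#' noise: each synthesis lobe has one shared band-limited source mixed into
#' its channels with weight equal to the coupling strength, each channel adds
#' independent band-limited noise with weight `1 - coupling`, and every
#' channel receives broadband \eqn{1/f^a} noise. Band limiting uses the same
#' zero-phase 4th-order Butterworth band-pass as the coherence pipeline, so
#' synthetic spectra and coherences are directly controllable.
#'
#' Group effects are specified as multiplicative amplitude factors applied to
#' the epileptic group (`group_effect`, per band, optionally restricted to
#' `effect_lobes`). Between-subject variability is injected as a regional
#' log-normal amplitude gain drawn per subject, band and lobe, whose
#' standard deviation (`subject_sd`) is expressed on the log10-power
#' biomarker scale, and as a per-subject jitter of the coupling strengths
#' (`coupling_sd`). The default
#' spec emulates the structure reported for resting-state cohorts of
#' controlled-epileptic versus control children: 20 subjects per group,
#' 400 Hz, 10.24 s epochs, slightly elevated theta/alpha power in the
#' epileptic group (an effect small enough to be non-significant at n = 20),
#' and within-lobe band coherences in the 0.6--0.8 range.
#'
#' @param n_control,n_epileptic subjects per group (default 20 each).
#' @param sampling_rate Hz (default 400).
#' @param epoch_duration seconds (default 10.24).
#' @param bands a [band_scheme()].
#' @param channels channel label set (default the 30-electrode 10/20 layout).
#' @param lobes synthesis lobes: named list of channel vectors (default: the
#'   default univariate montage lobes).
#' @param band_amplitude named numeric, per-band oscillation amplitude in
#'   linear units (defaults decay with frequency like resting EEG).
#' @param coupling named numeric in `[0, 1]`, per-band within-lobe coupling
#'   strength (default 0.75 in every band).
#' @param group_effect named numeric, per-band amplitude multiplier for the
#'   epileptic group (default: mild theta/alpha elevation).
#' @param effect_lobes lobes receiving the group effect (`NULL` = all).
#' @param subject_sd SD of the per-subject band gain, on the log10-power
#'   scale (default 0.25).
#' @param coupling_sd SD of the per-subject coupling jitter (default 0.05).
#' @param noise_amplitude broadband noise amplitude (default 1).
#' @param noise_exponent spectral exponent `a` of the broadband `1/f^a`
#'   noise: 0 = white, 1 = pink (default 1).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 20, n_epileptic = 20,
                        sampling_rate = 400, epoch_duration = 10.24,
                        bands = default_bands(),
                        channels = default_channels(),
                        lobes = default_montage("univariate")$lobes,
                        band_amplitude = NULL,
                        coupling = NULL,
                        group_effect = NULL,
                        effect_lobes = NULL,
                        subject_sd = 0.25,
                        coupling_sd = 0.05,
                        noise_amplitude = 1,
                        noise_exponent = 1,
                        seed = 1L) {
  bn <- names(bands$bands)
  fill <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, length(bn)), bn)
    if (!all(bn %in% names(x)))
      stop("per-band parameter must name every band")
    x[bn]
  }
  default_amp <- stats::setNames(
    c(4, 3, 3, 1.5, 0.6, 0.5)[seq_along(bn)] , bn)
  if (length(bn) > 6) default_amp[is.na(default_amp)] <- 1
  default_eff <- stats::setNames(rep(1, length(bn)), bn)
  if ("theta" %in% bn) default_eff["theta"] <- 1.07
  if ("alpha" %in% bn) default_eff["alpha"] <- 1.13
  band_amplitude <- fill(band_amplitude, default_amp)
  coupling <- fill(coupling, 0.75)
  group_effect <- fill(group_effect, default_eff)
  if (any(coupling < 0 | coupling > 1)) stop("coupling must lie in [0, 1]")
  if (any(band_amplitude < 0)) stop("amplitudes must be nonnegative")
  if (n_control < 1 || n_epileptic < 1) stop("need at least 1 subject per group")
  nyq <- sampling_rate / 2
  for (b in bn)
    if (bands$bands[[b]][2] >= nyq)
      stop("band '", b, "' upper edge reaches Nyquist (", nyq, " Hz)")
  miss <- setdiff(unique(unlist(lobes)), channels)
  if (length(miss) > 0)
    stop("synthesis lobes reference absent channel(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(effect_lobes) && !all(effect_lobes %in% names(lobes)))
    stop("unknown effect lobe(s)")
  structure(list(
    n_control = n_control, n_epileptic = n_epileptic,
    sampling_rate = sampling_rate, epoch_duration = epoch_duration,
    bands = bands, channels = channels, lobes = lobes,
    band_amplitude = band_amplitude, coupling = coupling,
    group_effect = group_effect, effect_lobes = effect_lobes,
    subject_sd = subject_sd, coupling_sd = coupling_sd,
    noise_amplitude = noise_amplitude, noise_exponent = noise_exponent,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d control + %d epileptic, %d ch x %.2f s @ %g Hz\n",
    x$n_control, x$n_epileptic, length(x$channels), x$epoch_duration,
    x$sampling_rate))
  cat("  bands:", paste(names(x$bands$bands), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Deterministic per-subject seed derived from the cohort seed and subject
# index (kept below 2^31).
subject_seed <- function(spec_seed, index) {
  as.integer((as.numeric(spec_seed) + 104729 * as.numeric(index)) %%
               2147483647)
}

# Unit-variance band-limited Gaussian noise.
bandlimited_noise <- function(n, band, fs) {
  x <- eeg_bandpass(stats::rnorm(n), band, fs)
  s <- stats::sd(x)
  if (s <= 0) stop("degenerate band-limited noise")
  x / s
}

# 1/f^a broadband noise with unit variance, shaped in the Fourier domain.
broadband_noise <- function(n, exponent, fs) {
  if (exponent <= 0) {
    x <- stats::rnorm(n)
  } else {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(1, seq_len(n - 1))             # avoid a DC singularity
    f <- pmin(f, n - f + 1) * fs / n
    W <- W * f^(-exponent / 2)
    W[1] <- 0
    x <- Re(stats::fft(W, inverse = TRUE) / n)
  }
  x / stats::sd(x)
}

#' Generate one synthetic subject epoch
#'
#' See [cohort_spec()] for the generative model. The subject's random state
#' is fully determined by `subject_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param group `"control"` or `"epileptic"`.
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @return an [eeg_epoch()].
#' @export
generate_subject <- function(spec, group = c("control", "epileptic"),
                             subject_seed, subject_id = "S1") {
  group <- match.arg(group)
  set.seed(as.integer(subject_seed))
  fs <- spec$sampling_rate
  n <- round(spec$epoch_duration * fs)
  chans <- spec$channels
  d <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
  bn <- names(spec$bands$bands)
  in_lobe <- chans %in% unique(unlist(spec$lobes))
  # per-subject regional gain, one draw per (band, lobe): subject_sd is on
  # the log10-power scale and power scales with amplitude^2, so the
  # amplitude gain is 10^(g/2) with g ~ N(0, subject_sd)
  draw_gain <- function() 10^(stats::rnorm(1, 0, spec$subject_sd) / 2)
  for (b in bn) {
    eb <- effective_band(spec$bands$bands[[b]])
    cpl <- spec$coupling[b] +
      if (spec$coupling_sd > 0) stats::rnorm(1, 0, spec$coupling_sd) else 0
    cpl <- min(max(cpl, 0), 1)
    for (l in names(spec$lobes)) {
      eff <- if (group == "epileptic" &&
                 (is.null(spec$effect_lobes) ||
                  l %in% spec$effect_lobes)) spec$group_effect[b] else 1
      amp <- spec$band_amplitude[b] * draw_gain() * eff
      shared <- bandlimited_noise(n, eb, fs)
      for (ch in spec$lobes[[l]]) {
        own <- bandlimited_noise(n, eb, fs)
        d[ch, ] <- d[ch, ] + amp * (cpl * shared + (1 - cpl) * own)
      }
    }
    # channels outside every synthesis lobe still carry band activity
    for (ch in chans[!in_lobe])
      d[ch, ] <- d[ch, ] + spec$band_amplitude[b] * draw_gain() *
        bandlimited_noise(n, eb, fs)
  }
  if (spec$noise_amplitude > 0)
    for (i in seq_along(chans))
      d[i, ] <- d[i, ] + spec$noise_amplitude *
        broadband_noise(n, spec$noise_exponent, fs)
  eeg_epoch(d, chans, fs, subject_id = subject_id, group = group,
            epoch_duration = spec$epoch_duration)
}

#' Generate a full synthetic cohort
#'
#' Subject seeds are derived deterministically from `spec$seed`, so the same
#' spec always yields a bit-identical cohort and subjects are mutually
#' independent.
#'
#' @param spec a [cohort_spec()].
#' @return list of [eeg_epoch()] objects (controls first), with group labels
#'   attached.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("control", spec$n_control),
              rep("epileptic", spec$n_epileptic))
  ids <- sprintf("%s%02d",
                 ifelse(groups == "control", "C", "E"),
                 c(seq_len(spec$n_control), seq_len(spec$n_epileptic)))
  lapply(seq_along(groups), function(i)
    generate_subject(spec, groups[i], subject_seed(spec$seed, i), ids[i]))
}

#' Calibrate a band amplitude effect to a target group separation
#'
#' The generator specifies group effects on linear amplitude while study
#' effect sizes live on the log-power biomarker scale, so the mapping is
#' measured empirically: pilot cohorts are generated at unit effect, the
#' pooled between-subject SD of the target (band, lobe) wavelet biomarker is
#' estimated, and the amplitude multiplier achieving a mean difference of
#' `target_d` pooled SDs is returned using the analytic slope of the
#' biomarker in log-amplitude (`2 * db_multiplier * log10(gain)` dB per
#' gain, attenuated by the broadband noise share measured in the pilots).
#'
#' @param spec a [cohort_spec()] (its `group_effect` is ignored).
#' @param band,lobe the target biomarker cell.
#' @param target_d desired group separation in pooled-SD units.
#' @param montage univariate montage used for the biomarker (default: the
#'   spec's synthesis lobes).
#' @param config a [wavelet_config()] whose grid covers the spec's bands.
#' @param n_pilot pilot subjects per amplitude level (default 6).
#' @return list with `multiplier` (amplitude factor for the epileptic group),
#'   `sd_pooled` and `slope` (biomarker units per log10 amplitude gain).
#' @export
calibrate_band_effect <- function(spec, band, lobe, target_d = 2,
                                  montage = NULL, config = NULL,
                                  n_pilot = 6) {
  if (is.null(montage))
    montage <- montage_scheme("univariate", spec$lobes)
  if (is.null(config)) {
    fmax <- max(vapply(spec$bands$bands, `[`, 0, 2))
    config <- wavelet_config(f_range = c(0.5, min(fmax,
                                                  spec$sampling_rate / 2 * 0.98)))
  }
  null_spec <- spec
  null_spec$group_effect[] <- 1
  probe <- function(mult, seed_off) {
    s2 <- null_spec
    s2$band_amplitude[band] <- s2$band_amplitude[band] * mult
    vapply(seq_len(n_pilot), function(i) {
      ep <- generate_subject(s2, "control",
                            subject_seed(spec$seed + seed_off, i),
                            sprintf("P%02d", i))
      bm <- wt_biomarkers(ep, montage, spec$bands, config)
      bm[paste(band, lobe, sep = ".")]
    }, 0)
  }
  base <- probe(1, 7919)
  high <- probe(10^0.25, 15731)          # +0.5 log10-power probe level
  sd_pooled <- stats::sd(c(base - mean(base), high - mean(high)))
  slope <- (mean(high) - mean(base)) / 0.25   # units per log10 amplitude gain
  if (!is.finite(slope) || slope <= 0)
    stop("calibration failed: nonpositive amplitude-to-biomarker slope")
  dg <- target_d * sd_pooled / slope          # log10 amplitude gain needed
  list(multiplier = 10^dg, sd_pooled = sd_pooled, slope = slope)
}
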