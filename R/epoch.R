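#' A single-subject EEG epoch
#'
#' Container for one subject's multichannel EEG epoch: a channels x samples
#' amplitude matrix plus sampling metadata and a group label. The default
#' recording configuration is 30 channels of the 10/20 layout sampled at
#' 400 Hz for 10.24 s (4096 samples).
#'
#' @param data numeric matrix, channels x samples.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param subject_id subject identifier string.
#' @param group `"control"`, `"epileptic"` or `"unknown"`.
#' @param epoch_duration epoch length in seconds; defaults to
#'   `ncol(data) / sampling_rate`.
#' @return an object of class `eeg_epoch`.
#' @examples
#' e <- eeg_epoch(matrix(rnorm(2 * 100), 2), c("C3", "C4"), 100)
#' e
#' @export
eeg_epoch <- function(data, channel_labels, sampling_rate,
                      subject_id = "S1", group = "unknown",
                      epoch_duration = ncol(data) / sampling_rate) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric channels x samples matrix")
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row required")
  if (anyDuplicated(toupper(channel_labels)))
    stop("duplicate channel labels")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number")
  group <- match.arg(group, c("control", "epileptic", "unknown"))
  n_expect <- round(epoch_duration * sampling_rate)
  if (ncol(data) != n_expect)
    stop("sample count (", ncol(data), ") does not match epoch_duration x ",
         "sampling_rate (", n_expect, ")")
  rownames(data) <- channel_labels
  structure(list(
    subject_id = as.character(subject_id),
    group = group,
    data = data,
    channel_labels = as.character(channel_labels),
    sampling_rate = sampling_rate,
    epoch_duration = epoch_duration
  ), class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf(
    "EEG epoch '%s' [%s]: %d channels x %d samples (%.2f s @ %g Hz)\n",
    x$subject_id, x$group, nrow(x$data), ncol(x$data),
    x$epoch_duration, x$sampling_rate))
  invisible(x)
}

#' Standardize an epoch to zero mean, unit variance per channel
#'
#' Each channel is centred and scaled to unit sample variance, as done before
#' spectral feature extraction. The operation is idempotent and preserves all
#' pairwise channel correlations.
#'
#' @param epoch an [eeg_epoch()].
#' @return the standardized `eeg_epoch`.
#' @export
standardize_epoch <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  d <- epoch$data
  v <- apply(d, 1, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- epoch$channel_labels[which(v <= 0 | !is.finite(v))]
    stop("constant or degenerate channel(s): ", paste(bad, collapse = ", "))
  }
  d <- (d - rowMeans(d)) / sqrt(v)
  epoch$data <- d
  rownames(epoch$data) <- epoch$channel_labels
  epoch
}

#' Crop an epoch to a target duration
#'
#' Keeps the first `duration` seconds. Epochs shorter than the target are
#' rejected rather than padded, since zero-padding would bias spectral
#' estimates.
#'
#' @param epoch an [eeg_epoch()].
#' @param duration target duration in seconds.
#' @return the cropped `eeg_epoch`.
#' @export
crop_epoch <- function(epoch, duration) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  n <- round(duration * epoch$sampling_rate)
  if (ncol(epoch$data) < n)
    stop("epoch shorter (", ncol(epoch$data), " samples) than requested ",
         "duration (", n, " samples); refusing to pad")
  epoch$data <- epoch$data[, seq_len(n), drop = FALSE]
  epoch$epoch_duration <- n / epoch$sampling_rate
  epoch
}
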