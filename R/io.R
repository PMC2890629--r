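#' Read an EEG epoch from disk
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`matrix`}{a plain-text format with a small commented header
#'     (subject id, group, sampling rate, channel labels) followed by one row
#'     of whitespace-separated amplitudes per sample. Values are written with
#'     17 significant digits, so a write/read round trip is bit-faithful.}
#'   \item{`edf`}{European Data Format (EDF), the standard EEG interchange
#'     format. EDF stores samples as 16-bit integers against a declared
#'     physical range, so a round trip is faithful only to one quantization
#'     step of that range.}
#' }
#'
#' @param path file to read.
#' @param format `"matrix"` or `"edf"`.
#' @param duration optional target duration in seconds; longer epochs are
#'   cropped from the start (see [crop_epoch()]), shorter ones rejected.
#' @return an [eeg_epoch()].
#' @export
read_epoch <- function(path, format = c("matrix", "edf"), duration = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ep <- switch(format,
    matrix = read_epoch_matrix(path),
    edf = read_epoch_edf(path))
  if (!is.null(duration)) ep <- crop_epoch(ep, duration)
  ep
}

#' Write an EEG epoch to disk
#'
#' @param epoch an [eeg_epoch()]; epochs containing non-finite samples are
#'   refused.
#' @param path output file.
#' @param format `"matrix"` or `"edf"` (see [read_epoch()]).
#' @return invisibly, `path`.
#' @export
write_epoch <- function(epoch, path, format = c("matrix", "edf")) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  format <- match.arg(format)
  if (any(!is.finite(epoch$data)))
    stop("epoch contains non-finite samples; refusing to write")
  switch(format,
    matrix = write_epoch_matrix(epoch, path),
    edf = write_epoch_edf(epoch, path))
  invisible(path)
}

## ---- matrix dialect ------------------------------------------------------

write_epoch_matrix <- function(epoch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# eeg_epoch v1",
    paste0("# subject_id: ", epoch$subject_id),
    paste0("# group: ", epoch$group),
    paste0("# sampling_rate: ", format(epoch$sampling_rate, digits = 17)),
    paste0("# epoch_duration: ", format(epoch$epoch_duration, digits = 17)),
    paste0("# channels: ", paste(epoch$channel_labels, collapse = " "))
  ), con)
  # samples as rows, channels as columns; %.17g round-trips doubles exactly
  txt <- apply(t(epoch$data), 1, function(row)
    paste(sprintf("%.17g", row), collapse = " "))
  writeLines(txt, con)
}

read_epoch_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    pat <- paste0("^# ", key, ": ")
    hit <- grep(pat, hdr, value = TRUE)
    if (length(hit) != 1) stop("matrix dialect header missing field '", key,
                               "' in ", path)
    sub(pat, "", hit)
  }
  channels <- strsplit(field("channels"), "[[:space:]]+")[[1]]
  if (anyDuplicated(toupper(channels)))
    stop("duplicate channel labels in ", path)
  fs <- as.numeric(field("sampling_rate"))
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling_rate in ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) %% length(channels) != 0)
    stop("data block not a multiple of channel count in ", path)
  n <- length(vals) / length(channels)
  d <- t(matrix(vals, nrow = length(channels)))  # samples x channels
  eeg_epoch(t(d), channels, fs,
            subject_id = field("subject_id"), group = field("group"),
            epoch_duration = n / fs)
}

## ---- EDF -----------------------------------------------------------------

# Minimal EDF reader/writer: one data record holding the whole epoch,
# 16-bit little-endian samples scaled between declared physical min/max.
# Subject id and group are carried in the local patient identification field.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

write_epoch_edf <- function(epoch, path) {
  d <- epoch$data
  ns <- nrow(d)
  nsamp <- ncol(d)
  pmin <- apply(d, 1, min)
  pmax <- apply(d, 1, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # 8-char ASCII fields for physical range limit the precision we can declare
  pmin_s <- sprintf("%-8.6g", pmin); pmin <- as.numeric(pmin_s)
  pmax_s <- sprintf("%-8.6g", pmax); pmax <- as.numeric(pmax_s)
  bad <- pmax <= pmin | pmin > apply(d, 1, min) | pmax < apply(d, 1, max)
  if (any(bad)) { # widen if rounding clipped the range
    pmin[bad] <- pmin[bad] - abs(pmin[bad]) * 1e-3 - 1e-6
    pmax[bad] <- pmax[bad] + abs(pmax[bad]) * 1e-3 + 1e-6
    pmin_s[bad] <- sprintf("%-8.6g", pmin[bad]); pmin[bad] <- as.numeric(pmin_s[bad])
    pmax_s[bad] <- sprintf("%-8.6g", pmax[bad]); pmax[bad] <- as.numeric(pmax_s[bad])
  }
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)                                           # version
  wr(paste(epoch$subject_id, epoch$group), 80)         # patient id
  wr("eegmarkers epoch", 80)                           # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)                 # start date/time
  wr(256 + ns * 256, 8)                                # header bytes
  wr("", 44)                                           # reserved
  wr(1, 8)                                             # number of records
  wr(format(epoch$epoch_duration, digits = 8), 8)      # record duration (s)
  wr(ns, 4)                                            # number of signals
  for (i in seq_len(ns)) wr(epoch$channel_labels[i], 16)
  for (i in seq_len(ns)) wr("", 80)                    # transducer
  for (i in seq_len(ns)) wr("uV", 8)                   # physical dimension
  for (i in seq_len(ns)) wr(pmin_s[i], 8)
  for (i in seq_len(ns)) wr(pmax_s[i], 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                    # prefiltering
  for (i in seq_len(ns)) wr(nsamp, 8)                  # samples per record
  for (i in seq_len(ns)) wr("", 32)                    # reserved
  for (i in seq_len(ns)) {
    dig <- round((d[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                   (dmax - dmin) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
}

read_epoch_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                              # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                              # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("invalid EDF: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  if (anyDuplicated(toupper(labels))) stop("invalid EDF: duplicate labels")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("EDF files with mixed per-signal sampling rates are not supported")
  nsamp <- spr[1] * nrec
  d <- matrix(NA_real_, ns, nsamp)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) +
        pmin[i]
      d[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  fs <- spr[1] / recdur
  if (!is.finite(fs) || fs <= 0) stop("invalid EDF: bad sampling rate")
  toks <- strsplit(patient, "[[:space:]]+")[[1]]
  grp <- if (length(toks) >= 2 &&
             toks[2] %in% c("control", "epileptic")) toks[2] else "unknown"
  sid <- if (length(toks) >= 1 && nzchar(toks[1])) toks[1] else "S1"
  eeg_epoch(d, labels, fs, subject_id = sid, group = grp,
            epoch_duration = nsamp / fs)
}

# One quantization step of the EDF encoding per channel, for tolerance checks.
edf_quant_step <- function(epoch) {
  pmin <- apply(epoch$data, 1, min)
  pmax <- apply(epoch$data, 1, max)
  rng <- pmax - pmin
  rng[rng <= 0] <- 2
  rng / 65535
}

## ---- cohorts on disk -----------------------------------------------------

#' Write a cohort of epochs to a directory
#'
#' @param cohort list of [eeg_epoch()] objects.
#' @param dir output directory (created if needed).
#' @param format `"matrix"` or `"edf"`.
#' @return invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") ".edf" else ".txt"
  paths <- vapply(cohort, function(ep) {
    p <- file.path(dir, paste0(ep$subject_id, ext))
    write_epoch(ep, p, format)
    p
  }, "")
  invisible(paths)
}

#' Read a cohort of epochs from a directory
#'
#' @param dir directory holding epoch files written by [write_cohort()].
#' @param format `"matrix"` or `"edf"`.
#' @return list of [eeg_epoch()] objects, sorted by file name.
#' @export
read_cohort <- function(dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  ext <- if (format == "edf") "\\.edf$" else "\\.txt$"
  files <- sort(list.files(dir, pattern = ext, full.names = TRUE))
  if (length(files) == 0) stop("no epoch files found in ", dir)
  lapply(files, read_epoch, format = format)
}
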