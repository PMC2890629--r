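#' Frequency band scheme
#'
#' A named, ordered set of frequency bands given as `(f_low, f_high)` edges in
#' Hz. The default is the six-band clinical scheme: delta (0--4), theta
#' (4--8), alpha (8--13), beta (13--30), gamma1 (30--45) and gamma2 (45--90).
#' Bands may share edges but must not overlap; a shared edge belongs to the
#' lower band (intervals are treated as `(f_low, f_high]`).
#'
#' @param bands named list of length-2 numeric vectors `c(f_low, f_high)` in
#'   Hz, ordered by frequency.
#' @return an object of class `band_scheme`.
#' @examples
#' bs <- default_bands()
#' names(bs$bands)
#' @export
band_scheme <- function(bands) {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop("'bands' must be a named list of c(f_low, f_high) pairs")
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || !is.numeric(b) || b[1] < 0 || b[1] >= b[2])
      stop("band '", nm, "' must satisfy 0 <= f_low < f_high")
  }
  edges <- do.call(rbind, bands)
  o <- order(edges[, 1])
  if (any(o != seq_along(bands))) stop("bands must be ordered by frequency")
  if (any(edges[-1, 1] < edges[-nrow(edges), 2] - 1e-12))
    stop("bands overlap beyond shared edges")
  structure(list(bands = bands), class = "band_scheme")
}

#' @rdname band_scheme
#' @export
default_bands <- function() {
  band_scheme(list(
    delta  = c(0, 4),
    theta  = c(4, 8),
    alpha  = c(8, 13),
    beta   = c(13, 30),
    gamma1 = c(30, 45),
    gamma2 = c(45, 90)
  ))
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("Band scheme (", length(x$bands), " bands)\n", sep = "")
  for (nm in names(x$bands))
    cat(sprintf("  %-8s %g-%g Hz\n", nm, x$bands[[nm]][1], x$bands[[nm]][2]))
  invisible(x)
}

# Effective band edges for filtering / scale gridding: a 0 Hz lower edge is
# replaced by 0.5 Hz (a DC-reaching band-pass is not realizable on finite
# epochs).
effective_band <- function(band, floor_hz = 0.5) {
  c(max(band[1], floor_hz), band[2])
}

#' The default 30-channel 10/20 electrode label set
#'
#' @return character vector of 30 channel labels.
#' @export
default_channels <- function() {
  c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "FT7", "FC3", "FCZ", "FC4", "FT8",
    "T3", "C3", "CZ", "C4", "T4",
    "TP7", "CP3", "CPZ", "CP4", "TP8",
    "P7", "P3", "PZ", "P4", "P8",
    "O1", "OZ", "O2")
}

#' Montage scheme: named lobes of channels or channel pairs
#'
#' A montage scheme groups channels (univariate kind) or channel pairs
#' (bivariate kind) into named scalp regions ("lobes") over which biomarkers
#' are averaged. Channel reuse across lobes is permitted (e.g. P7 belongs to
#' both the left parietal and left occipital groups in the default univariate
#' scheme).
#'
#' @param kind `"univariate"` or `"bivariate"`.
#' @param lobes named list. For univariate schemes each element is a character
#'   vector of channel labels; for bivariate schemes each element is a list of
#'   length-2 character vectors (channel pairs).
#' @return an object of class `montage_scheme`.
#' @examples
#' m <- default_montage("univariate")
#' m$lobes$FL
#' @export
montage_scheme <- function(kind = c("univariate", "bivariate"), lobes) {
  kind <- match.arg(kind)
  if (!is.list(lobes) || is.null(names(lobes)))
    stop("'lobes' must be a named list")
  if (kind == "univariate") {
    ok <- vapply(lobes, function(l) is.character(l) && length(l) >= 1, TRUE)
    if (!all(ok)) stop("univariate lobes must be character vectors of channels")
  } else {
    for (nm in names(lobes)) {
      prs <- lobes[[nm]]
      if (!is.list(prs) ||
          !all(vapply(prs, function(p) is.character(p) && length(p) == 2, TRUE)))
        stop("bivariate lobe '", nm, "' must be a list of channel pairs")
    }
  }
  structure(list(kind = kind, lobes = lobes), class = "montage_scheme")
}

#' @rdname montage_scheme
#' @export
default_montage <- function(kind = c("univariate", "bivariate")) {
  kind <- match.arg(kind)
  if (kind == "univariate") {
    montage_scheme("univariate", list(
      FL = c("FP1", "F3", "F7"),
      FR = c("FP2", "F4", "F8"),
      CL = c("C3", "CP3"),
      CR = c("C4", "CP4"),
      PL = c("P3", "P7"),
      PR = c("P4", "P8"),
      TL = c("FT7", "T3", "TP7"),
      TR = c("FT8", "T4", "TP8"),
      OL = c("O1", "P7"),
      OR = c("O2", "P8")
    ))
  } else {
    pr <- function(...) {
      xs <- list(...)
      lapply(xs, function(s) strsplit(s, "-", fixed = TRUE)[[1]])
    }
    montage_scheme("bivariate", list(
      OPL = pr("O1-P3", "O1-P7", "P7-P3"),
      OPR = pr("O2-P4", "O2-P8", "P8-P4"),
      CPL = pr("CP3-P3", "C3-CP3", "P3-P7"),
      CPR = pr("CP4-P4", "C4-CP4", "P4-P8"),
      FTL = pr("FP1-F7", "FP1-F3", "FT7-T3", "FT7-TP7", "T3-TP7"),
      FTR = pr("FP2-F8", "FP2-F4", "FT8-T4", "FT8-TP8", "T4-TP8"),
      TL  = pr("FT7-T3", "T3-TP7", "FT7-TP7"),
      TR  = pr("FT8-T4", "T4-TP8", "FT8-TP8")
    ))
  }
}

# All channel labels referenced by a montage scheme (unique, in order of
# first appearance).
montage_channels <- function(montage) {
  if (montage$kind == "univariate") {
    unique(unlist(montage$lobes))
  } else {
    unique(unlist(lapply(montage$lobes, function(prs) unlist(prs))))
  }
}

#' Validate a montage against an epoch's channel labels
#'
#' Matching is case-insensitive; no T3/T7 (T4/T8) aliasing is applied, so a
#' montage naming "T3" will not silently bind to a channel labelled "T7".
#'
#' @param montage a [montage_scheme()].
#' @param channel_labels character vector of available channel labels.
#' @return invisibly `TRUE`; errors if any referenced channel is absent.
#' @export
validate_montage <- function(montage, channel_labels) {
  stopifnot(inherits(montage, "montage_scheme"))
  need <- montage_channels(montage)
  missing <- need[!toupper(need) %in% toupper(channel_labels)]
  if (length(missing) > 0)
    stop("montage references absent channel(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.montage_scheme <- function(x, ...) {
  cat("Montage scheme (", x$kind, ", ", length(x$lobes), " lobes)\n", sep = "")
  for (nm in names(x$lobes)) {
    l <- x$lobes[[nm]]
    if (x$kind == "univariate") {
      cat(sprintf("  %-4s %s\n", nm, paste(l, collapse = ", ")))
    } else {
      cat(sprintf("  %-4s %s\n", nm,
                  paste(vapply(l, paste, "", collapse = "-"), collapse = ", ")))
    }
  }
  invisible(x)
}

# Resolve a montage channel name to a row index of the epoch data
# (case-insensitive, exact otherwise).
match_channel <- function(name, channel_labels) {
  i <- match(toupper(name), toupper(channel_labels))
  if (is.na(i)) stop("channel '", name, "' not found in epoch")
  i
}
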