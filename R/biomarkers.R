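#' Subjects x features biomarker table
#'
#' Holds one row per subject of band x lobe biomarkers, together with the
#' feature index (measure, band, lobe) and group labels. Wavelet power
#' ("WT") features are finite reals on a log/dB scale; coherence features
#' ("MS-COH", "AR-COH") lie in `[0, 1]`.
#'
#' @param values numeric subjects x features matrix.
#' @param features data.frame with columns `measure`, `band`, `lobe` (one row
#'   per column of `values`).
#' @param subject_ids character vector, one per row.
#' @param groups character vector of `"control"` / `"epileptic"` labels.
#' @return an object of class `biomarker_table`.
#' @export
biomarker_table <- function(values, features, subject_ids, groups) {
  values <- as.matrix(values)
  if (nrow(features) != ncol(values))
    stop("feature index must describe every column")
  if (length(subject_ids) != nrow(values) ||
      length(groups) != nrow(values))
    stop("one subject id and group per row required")
  if (!all(groups %in% c("control", "epileptic", "unknown")))
    stop("invalid group label(s)")
  if (any(!is.finite(values)))
    stop("biomarker table contains non-finite cells")
  coh <- features$measure %in% c("MS-COH", "AR-COH")
  if (any(coh)) {
    v <- values[, coh, drop = FALSE]
    if (any(v < -1e-9 | v > 1 + 1e-9))
      stop("coherence biomarkers must lie in [0, 1]")
  }
  colnames(values) <- paste(features$measure, features$band, features$lobe,
                            sep = ".")
  rownames(values) <- subject_ids
  structure(list(values = values, features = features,
                 subject_ids = as.character(subject_ids),
                 groups = as.character(groups)),
            class = "biomarker_table")
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat(sprintf("Biomarker table: %d subjects (%d control, %d epileptic) x %d features\n",
              nrow(x$values), sum(x$groups == "control"),
              sum(x$groups == "epileptic"), ncol(x$values)))
  cat("  measures:", paste(unique(x$features$measure), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.biomarker_table <- function(x, ...) {
  long <- expand.grid(subject = x$subject_ids,
                      feature = seq_len(ncol(x$values)),
                      stringsAsFactors = FALSE)
  data.frame(
    subject_id = long$subject,
    group = x$groups[match(long$subject, x$subject_ids)],
    measure = x$features$measure[long$feature],
    band = x$features$band[long$feature],
    lobe = x$features$lobe[long$feature],
    value = x$values[cbind(match(long$subject, x$subject_ids),
                           long$feature)],
    stringsAsFactors = FALSE
  )
}

#' Write / read a biomarker table as CSV
#'
#' Long format, one row per (subject, measure, band, lobe).
#'
#' @param table a [biomarker_table()].
#' @param path CSV file path.
#' @return `write_biomarkers`: invisibly, `path`; `read_biomarkers`: a
#'   [biomarker_table()].
#' @export
write_biomarkers <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biomarkers
#' @export
read_biomarkers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "measure", "band", "lobe", "value")
  if (!all(need %in% names(df)))
    stop("biomarker CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$measure, df$band, df$lobe, sep = ".")
  feats <- unique(data.frame(measure = df$measure, band = df$band,
                             lobe = df$lobe, key = key,
                             stringsAsFactors = FALSE))
  subs <- unique(df$subject_id)
  vals <- matrix(NA_real_, length(subs), nrow(feats),
                 dimnames = list(subs, feats$key))
  vals[cbind(match(df$subject_id, subs), match(key, feats$key))] <- df$value
  if (any(is.na(vals))) stop("missing cells in biomarker CSV")
  groups <- df$group[match(subs, df$subject_id)]
  biomarker_table(vals, feats[, 1:3], subs, groups)
}

#' Compute the biomarker table of a cohort
#'
#' Runs the univariate wavelet and/or bivariate coherence feature extraction
#' on every epoch and assembles the subjects x features matrix.
#'
#' @param cohort list of [eeg_epoch()] objects with group labels.
#' @param measures subset of `c("WT", "MS-COH", "AR-COH")`.
#' @param montage_uni univariate [montage_scheme()] for the WT features.
#' @param montage_biv bivariate [montage_scheme()] for the coherence
#'   features.
#' @param bands a [band_scheme()].
#' @param wavelet a [wavelet_config()].
#' @param window_len Welch segment length (default 1024).
#' @param max_order AR candidate order cap (default 50).
#' @return a [biomarker_table()].
#' @export
compute_biomarkers <- function(cohort,
                               measures = c("WT", "MS-COH", "AR-COH"),
                               montage_uni = default_montage("univariate"),
                               montage_biv = default_montage("bivariate"),
                               bands = default_bands(),
                               wavelet = wavelet_config(),
                               window_len = 1024, max_order = 50) {
  measures <- match.arg(measures, c("WT", "MS-COH", "AR-COH"),
                        several.ok = TRUE)
  rows <- lapply(cohort, function(ep) {
    out <- numeric(0); feat <- NULL
    if ("WT" %in% measures) {
      v <- wt_biomarkers(ep, montage_uni, bands, wavelet)
      out <- c(out, v); feat <- rbind(feat, attr(v, "features"))
    }
    coh_methods <- intersect(measures, c("MS-COH", "AR-COH"))
    if (length(coh_methods) > 0) {
      v <- coherence_biomarkers(ep, montage_biv, bands,
                                methods = coh_methods,
                                window_len = window_len,
                                max_order = max_order)
      out <- c(out, v); feat <- rbind(feat, attr(v, "features"))
    }
    list(values = out, features = feat)
  })
  vals <- do.call(rbind, lapply(rows, `[[`, "values"))
  biomarker_table(vals, rows[[1]]$features,
                  vapply(cohort, `[[`, "", "subject_id"),
                  vapply(cohort, `[[`, "", "group"))
}
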