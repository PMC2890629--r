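#' Pipeline configuration
#'
#' One structured object holding every parameter of an end-to-end run:
#' cohort source, band scheme, both montage schemes, wavelet and Welch
#' settings, AR order cap, significance thresholds, fusion settings and the
#' global seed. A run is reproducible from config + seed alone. The config
#' serializes to YAML via [write_pipeline_config()].
#'
#' @param cohort either a [cohort_spec()] (synthetic source) or a list
#'   `list(dir = <path>, format = "matrix"|"edf")` naming a directory of
#'   epoch files.
#' @param measures biomarkers to compute, subset of
#'   `c("WT", "MS-COH", "AR-COH")`.
#' @param bands a [band_scheme()].
#' @param montage_uni,montage_biv montage schemes.
#' @param wavelet a [wavelet_config()].
#' @param window_len Welch segment length in samples.
#' @param max_order AR candidate order cap.
#' @param thresholds significance-map thresholds `c(blank, strong)`
#'   (informational; the map always uses 0.1 / 0.01).
#' @param fusion fusion operator: one of `"majority_vote"`, `"ldc_average"`,
#'   `"weighted_sum"`, `"mindist"`.
#' @param n_features number of top features fused.
#' @param preset optional preset name (see [biomarker_presets()]) overriding
#'   score-based selection.
#' @param seed global seed (fanned out deterministically per stage).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            measures = c("WT", "MS-COH"),
                            bands = default_bands(),
                            montage_uni = default_montage("univariate"),
                            montage_biv = default_montage("bivariate"),
                            wavelet = wavelet_config(),
                            window_len = 1024,
                            max_order = 50,
                            thresholds = c(0.1, 0.01),
                            fusion = "majority_vote",
                            n_features = 5,
                            preset = NULL,
                            seed = 1L) {
  fusion <- match.arg(fusion, c("majority_vote", "ldc_average",
                                "weighted_sum", "mindist"))
  measures <- match.arg(measures, c("WT", "MS-COH", "AR-COH"),
                        several.ok = TRUE)
  for (l in names(montage_uni$lobes)) NULL # structure check via class below
  stopifnot(inherits(bands, "band_scheme"),
            inherits(montage_uni, "montage_scheme"),
            inherits(montage_biv, "montage_scheme"),
            inherits(wavelet, "wavelet_config"))
  if (inherits(cohort, "cohort_spec")) cohort$seed <- as.integer(seed)
  structure(list(
    cohort = cohort, measures = measures, bands = bands,
    montage_uni = montage_uni, montage_biv = montage_biv,
    wavelet = wavelet, window_len = window_len, max_order = max_order,
    thresholds = thresholds, fusion = fusion, n_features = n_features,
    preset = preset, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Serialize / restore a pipeline config as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config`: invisibly `path`;
#'   `read_pipeline_config`: a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- config
  class(x) <- NULL
  x$bands <- lapply(config$bands$bands, as.numeric)
  x$montage_uni <- config$montage_uni$lobes
  x$montage_biv <- lapply(config$montage_biv$lobes, function(prs)
    vapply(prs, paste, "", collapse = "-"))
  x$wavelet <- unclass(config$wavelet)[c("omega0", "k", "n_voices",
                                         "f_range", "db_multiplier")]
  if (inherits(config$cohort, "cohort_spec")) {
    cs <- unclass(config$cohort)
    cs$bands <- lapply(cs$bands$bands, as.numeric)
    cs$band_amplitude <- as.list(cs$band_amplitude)
    cs$coupling <- as.list(cs$coupling)
    cs$group_effect <- as.list(cs$group_effect)
    x$cohort <- cs
    x$cohort_kind <- "synthetic"
  } else {
    x$cohort_kind <- "directory"
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  bands <- band_scheme(lapply(x$bands, as.numeric))
  montage_uni <- montage_scheme("univariate",
                                lapply(x$montage_uni, as.character))
  montage_biv <- montage_scheme("bivariate", lapply(x$montage_biv,
    function(prs) lapply(prs, function(s)
      strsplit(s, "-", fixed = TRUE)[[1]])))
  wc <- wavelet_config(omega0 = x$wavelet$omega0, k = x$wavelet$k,
                       n_voices = x$wavelet$n_voices,
                       f_range = as.numeric(x$wavelet$f_range),
                       db_multiplier = x$wavelet$db_multiplier)
  cohort <- if (identical(x$cohort_kind, "synthetic")) {
    cs <- x$cohort
    cohort_spec(
      n_control = cs$n_control, n_epileptic = cs$n_epileptic,
      sampling_rate = cs$sampling_rate, epoch_duration = cs$epoch_duration,
      bands = band_scheme(lapply(cs$bands, as.numeric)),
      channels = as.character(cs$channels),
      lobes = lapply(cs$lobes, as.character),
      band_amplitude = unlist(cs$band_amplitude),
      coupling = unlist(cs$coupling),
      group_effect = unlist(cs$group_effect),
      effect_lobes = if (length(cs$effect_lobes)) as.character(cs$effect_lobes) else NULL,
      subject_sd = cs$subject_sd, coupling_sd = cs$coupling_sd,
      noise_amplitude = cs$noise_amplitude,
      noise_exponent = cs$noise_exponent, seed = cs$seed)
  } else {
    list(dir = x$cohort$dir, format = x$cohort$format)
  }
  pipeline_config(cohort = cohort, measures = x$measures, bands = bands,
                  montage_uni = montage_uni, montage_biv = montage_biv,
                  wavelet = wc, window_len = x$window_len,
                  max_order = x$max_order,
                  thresholds = as.numeric(x$thresholds),
                  fusion = x$fusion, n_features = x$n_features,
                  preset = if (length(x$preset)) x$preset else NULL,
                  seed = x$seed)
}

#' Run the full biomarker pipeline
#'
#' Generate-or-read cohort, extract biomarkers, map group significance, run
#' single-feature leave-one-out classification, fuse the selected subset,
#' and write all tabular outputs to `out_dir`:
#' `biomarkers.csv`, `stats_map.csv`, `single_feature_reports.csv`,
#' `fusion_report.csv` and `run_log.txt`. Outputs are fully determined by
#' config + seed. On a stage failure, partial outputs are retained alongside
#' a `FAILED` marker naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`cohort` omitted):
#'   `biomarkers`, `stats_map`, `single_reports`, `fusion_report`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("eegmarkers pipeline run")
  logf("package version: %s",
       as.character(utils::packageVersion("eegmarkers")))
  logf("seed: %d", config$seed)
  logf("measures: %s", paste(config$measures, collapse = ", "))
  stage <- "init"
  fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "cohort"
    cohort <- if (inherits(config$cohort, "cohort_spec")) {
      generate_cohort(config$cohort)
    } else {
      read_cohort(config$cohort$dir, config$cohort$format)
    }
    logf("cohort: %d subjects", length(cohort))

    stage <- "biomarkers"
    bt <- compute_biomarkers(cohort, measures = config$measures,
                             montage_uni = config$montage_uni,
                             montage_biv = config$montage_biv,
                             bands = config$bands,
                             wavelet = config$wavelet,
                             window_len = config$window_len,
                             max_order = config$max_order)
    write_biomarkers(bt, file.path(out_dir, "biomarkers.csv"))
    logf("biomarkers: %d features", ncol(bt$values))

    stage <- "stats"
    sm <- significance_map(bt)
    utils::write.csv(as.data.frame(sm), file.path(out_dir, "stats_map.csv"),
                     row.names = FALSE)
    logf("stats map: %d cells, %d with p <= 0.1", nrow(sm),
         sum(sm$p <= 0.1))

    stage <- "classify"
    sr <- single_feature_reports(bt)
    utils::write.csv(sr, file.path(out_dir, "single_feature_reports.csv"),
                     row.names = FALSE)

    stage <- "fusion"
    sel <- if (!is.null(config$preset)) {
      match_features(bt, biomarker_presets(config$preset))
    } else {
      select_features(sr, n_features = config$n_features)
    }
    votes <- attr(sr, "votes")[, sel, drop = FALSE]
    fr <- switch(config$fusion,
      majority_vote = fuse_majority_vote(votes, bt$groups),
      weighted_sum = fuse_weighted_sum(votes, sr$score[sel], bt$groups),
      ldc_average = fuse_ldc_average(bt$values[, sel, drop = FALSE],
                                     bt$groups),
      mindist = fuse_mindist(bt$values[, sel, drop = FALSE], bt$groups))
    fdf <- data.frame(
      operator = fr$operator,
      n_features = length(sel),
      features = paste(colnames(bt$values)[sel], collapse = ";"),
      score = fr$score, sensitivity = fr$sensitivity,
      specificity = fr$specificity,
      best_single_score = max(sr$score[sel]),
      stringsAsFactors = FALSE)
    utils::write.csv(fdf, file.path(out_dir, "fusion_report.csv"),
                     row.names = FALSE)
    logf("fusion [%s]: score %.1f%% (best single %.1f%%)", fr$operator,
         fr$score, fdf$best_single_score)

    invisible(list(biomarkers = bt, stats_map = sm, single_reports = sr,
                   fusion_report = fr, selected = sel))
  }, error = fail)
}
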