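#' Classification report
#'
#' Per-subject leave-one-out predictions with the aggregate metrics used
#' throughout: classification score (percent of all subjects correctly
#' labelled), sensitivity (percent of epileptics correctly labelled) and
#' specificity (percent of controls correctly labelled). With balanced 20/20
#' groups the score equals the mean of sensitivity and specificity.
#'
#' @param predictions character vector of predicted labels.
#' @param labels character vector of true labels (`"control"` /
#'   `"epileptic"`).
#' @param feature_set description of the feature subset used.
#' @param operator fusion operator used, or `"single"`.
#' @return an object of class `eeg_classification`.
#' @export
classification_report <- function(predictions, labels,
                                  feature_set = "", operator = "single") {
  m <- confusion_metrics(predictions, labels)
  structure(list(
    predictions = predictions, labels = labels,
    score = m$score, sensitivity = m$sensitivity,
    specificity = m$specificity,
    feature_set = feature_set, operator = operator
  ), class = "eeg_classification")
}

#' @export
print.eeg_classification <- function(x, ...) {
  cat(sprintf(
    "Classification [%s%s]: score %.1f%%, sensitivity %.1f%%, specificity %.1f%% (n = %d)\n",
    x$operator,
    if (nzchar(x$feature_set)) paste0(", ", x$feature_set) else "",
    x$score, x$sensitivity, x$specificity, length(x$labels)))
  invisible(x)
}

#' Classification score, sensitivity and specificity
#'
#' The epileptic group is the positive class: score = (TP + TN) / n,
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), all in
#' percent.
#'
#' @param predictions,labels equal-length character vectors over
#'   `c("control", "epileptic")`.
#' @return list with `score`, `sensitivity`, `specificity` (percent).
#' @export
confusion_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  ok <- c("control", "epileptic")
  if (!all(predictions %in% ok) || !all(labels %in% ok))
    stop("labels must be 'control' or 'epileptic'")
  tp <- sum(predictions == "epileptic" & labels == "epileptic")
  tn <- sum(predictions == "control" & labels == "control")
  fn <- sum(predictions == "control" & labels == "epileptic")
  fp <- sum(predictions == "epileptic" & labels == "control")
  list(score = 100 * (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# Two-class LDA with shared covariance and equal priors. Returns a predict
# function. The pooled covariance is ridge-regularized
# (eps = 1e-6 * trace/dim) when numerically singular.
lda_fit <- function(X, labels, tie_break = "control") {
  X <- as.matrix(X)
  i1 <- labels == "epileptic"
  mu0 <- colMeans(X[!i1, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  n0 <- sum(!i1); n1 <- sum(i1)
  S <- ((n0 - 1) * stats::cov(X[!i1, , drop = FALSE]) +
          (n1 - 1) * stats::cov(X[i1, , drop = FALSE])) / (n0 + n1 - 2)
  S <- as.matrix(S)
  if (rcond_safe(S) < 1e-10) {
    S <- S + diag(1e-6 * sum(diag(S)) / ncol(S) + 1e-12, ncol(S))
    warning("singular pooled covariance: ridge regularization applied",
            call. = FALSE)
  }
  w <- solve(S, mu1 - mu0)
  thr <- sum(w * (mu0 + mu1)) / 2
  function(xnew) {
    sc <- as.numeric(as.matrix(xnew) %*% w) - thr
    ifelse(sc > 0, "epileptic", ifelse(sc < 0, "control", tie_break))
  }
}

rcond_safe <- function(S) {
  if (any(!is.finite(S))) return(0)
  tryCatch(rcond(S), error = function(e) 0)
}

#' LDA classification with leave-one-out validation
#'
#' For each subject a two-class linear discriminant (shared covariance,
#' equal priors) is fitted on the remaining n - 1 subjects and the held-out
#' subject is predicted; under the default 20 + 20 cohort each fold trains
#' on 39 of the 40 children.
#'
#' @param features numeric subjects x features matrix (a single feature may
#'   be passed as a vector).
#' @param labels character vector of true group labels.
#' @param tie_break label assigned on a decision tie (default `"control"`,
#'   favouring specificity).
#' @param feature_set,operator annotations for the report.
#' @return an `eeg_classification` report.
#' @export
lda_loo <- function(features, labels, tie_break = "control",
                    feature_set = "", operator = "single") {
  X <- as.matrix(features)
  n <- nrow(X)
  if (length(labels) != n) stop("one label per subject required")
  if (any(!is.finite(X))) stop("features must be finite")
  if (sum(labels == "control") < 2 || sum(labels == "epileptic") < 2)
    stop("need at least 2 subjects per class")
  preds <- character(n)
  for (i in seq_len(n)) {
    fit <- lda_fit(X[-i, , drop = FALSE], labels[-i], tie_break)
    preds[i] <- fit(X[i, , drop = FALSE])
  }
  classification_report(preds, labels, feature_set, operator)
}

# Column standardization by training-fold statistics (avoids leakage).
scale_by_train <- function(Xtrain, Xtest) {
  mu <- colMeans(Xtrain)
  sdv <- apply(Xtrain, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(Xtrain, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xtest, 2, mu), 2, sdv, "/"))
}

#' Fusion operator: LDC on the average of selected features
#'
#' Selected features are column-standardized (using training-fold statistics
#' inside the leave-one-out loop) and averaged into one scalar per subject;
#' a linear discriminant is then applied to that scalar.
#'
#' @param features numeric subjects x features matrix (>= 2 columns).
#' @param labels true group labels.
#' @param tie_break tie-break label.
#' @return an `eeg_classification` report with `operator = "ldc_average"`.
#' @export
fuse_ldc_average <- function(features, labels, tie_break = "control") {
  X <- as.matrix(features)
  if (ncol(X) < 2) stop("need at least 2 features to average")
  n <- nrow(X)
  preds <- character(n)
  for (i in seq_len(n)) {
    sc <- scale_by_train(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    avg_train <- rowMeans(sc$train)
    avg_test <- rowMeans(sc$test)
    fit <- lda_fit(matrix(avg_train, ncol = 1), labels[-i], tie_break)
    preds[i] <- fit(matrix(avg_test, ncol = 1))
  }
  classification_report(preds, labels,
                        feature_set = paste0(ncol(X), " features"),
                        operator = "ldc_average")
}

#' Fusion operator: majority vote over per-feature predictions
#'
#' Each feature votes with its own leave-one-out prediction; the class with
#' more than half the votes wins. Even-split ties are resolved to
#' `tie_break`.
#'
#' @param votes subjects x features character matrix of per-feature
#'   predictions (e.g. column-bound from single-feature [lda_loo()] runs).
#' @param labels true group labels.
#' @param tie_break tie-break label (default `"control"`).
#' @return an `eeg_classification` report with `operator = "majority_vote"`.
#' @export
fuse_majority_vote <- function(votes, labels, tie_break = "control") {
  votes <- as.matrix(votes)
  n_e <- rowSums(votes == "epileptic")
  n_tot <- ncol(votes)
  preds <- ifelse(n_e > n_tot / 2, "epileptic",
                  ifelse(n_e < n_tot / 2, "control", tie_break))
  classification_report(preds, labels,
                        feature_set = paste0(n_tot, " voters"),
                        operator = "majority_vote")
}

#' Fusion operator: score-weighted sum of per-feature votes
#'
#' Votes are encoded +1 (epileptic) / -1 (control), weighted by each
#' feature's individual classification score and summed; the fused label is
#' the sign of the normalized sum (zero resolves to `tie_break`). With equal
#' weights this reduces exactly to the majority vote.
#'
#' @param votes subjects x features character matrix of per-feature
#'   predictions.
#' @param weights per-feature nonnegative weights (individual classification
#'   scores); must not be all zero.
#' @param labels true group labels.
#' @param tie_break tie-break label.
#' @return an `eeg_classification` report with `operator = "weighted_sum"`.
#' @export
fuse_weighted_sum <- function(votes, weights, labels,
                              tie_break = "control") {
  votes <- as.matrix(votes)
  if (length(weights) != ncol(votes))
    stop("one weight per voting feature required")
  if (all(weights == 0)) stop("weights must not be all zero")
  enc <- ifelse(votes == "epileptic", 1, -1)
  s <- as.numeric(enc %*% weights) / sum(weights)
  preds <- ifelse(s > 0, "epileptic", ifelse(s < 0, "control", tie_break))
  classification_report(preds, labels,
                        feature_set = paste0(ncol(votes), " voters"),
                        operator = "weighted_sum")
}

#' Fusion operator: minimum-distance-to-class-mean (MINDIST)
#'
#' Nearest-class-centroid classification in Euclidean (least-squares)
#' distance on the selected, column-standardized features. Class centroids
#' are computed on the training subjects only, inside the leave-one-out
#' loop; equidistant cases resolve to `tie_break`.
#'
#' @param features numeric subjects x features matrix.
#' @param labels true group labels.
#' @param tie_break tie-break label.
#' @return an `eeg_classification` report with `operator = "mindist"`.
#' @export
fuse_mindist <- function(features, labels, tie_break = "control") {
  X <- as.matrix(features)
  n <- nrow(X)
  preds <- character(n)
  for (i in seq_len(n)) {
    sc <- scale_by_train(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    lab <- labels[-i]
    mu0 <- colMeans(sc$train[lab == "control", , drop = FALSE])
    mu1 <- colMeans(sc$train[lab == "epileptic", , drop = FALSE])
    d0 <- sum((sc$test - mu0)^2)
    d1 <- sum((sc$test - mu1)^2)
    preds[i] <- if (d1 < d0) "epileptic" else if (d0 < d1) "control" else
      tie_break
  }
  classification_report(preds, labels,
                        feature_set = paste0(ncol(X), " features"),
                        operator = "mindist")
}

#' Single-feature leave-one-out reports for every biomarker
#'
#' @param table a [biomarker_table()].
#' @param tie_break tie-break label.
#' @return data.frame with one row per feature: measure, band, lobe, score,
#'   sensitivity, specificity; attribute `votes` holds the subjects x
#'   features matrix of per-feature LOO predictions.
#' @export
single_feature_reports <- function(table, tie_break = "control") {
  stopifnot(inherits(table, "biomarker_table"))
  nfeat <- ncol(table$values)
  votes <- matrix("", nrow(table$values), nfeat,
                  dimnames = dimnames(table$values))
  rows <- lapply(seq_len(nfeat), function(j) {
    rep_j <- lda_loo(table$values[, j], table$groups,
                     tie_break = tie_break,
                     feature_set = colnames(table$values)[j])
    votes[, j] <<- rep_j$predictions
    data.frame(measure = table$features$measure[j],
               band = table$features$band[j],
               lobe = table$features$lobe[j],
               score = rep_j$score, sensitivity = rep_j$sensitivity,
               specificity = rep_j$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "votes") <- votes
  out
}

#' Select a biomarker feature subset for fusion
#'
#' Filters features to those whose individual sensitivity and specificity
#' both exceed 50%, ranks by individual classification score, and truncates
#' to the requested count. Named presets reproduce published feature
#' subsets; see [biomarker_presets()].
#'
#' @param reports data.frame from [single_feature_reports()].
#' @param n_features number of features to keep (default all passing).
#' @param min_sensitivity,min_specificity filter thresholds in percent
#'   (default 50).
#' @return integer vector of selected feature (row) indices, ranked by
#'   score.
#' @export
select_features <- function(reports, n_features = Inf,
                            min_sensitivity = 50, min_specificity = 50) {
  pass <- which(reports$sensitivity > min_sensitivity &
                  reports$specificity > min_specificity)
  if (length(pass) == 0)
    stop("no features pass the sensitivity/specificity filters; ",
         "consider relaxing the criteria")
  pass[order(reports$score[pass], decreasing = TRUE)][
    seq_len(min(n_features, length(pass)))]
}

#' Published biomarker feature subsets
#'
#' Named presets of (measure, band, lobe) feature subsets used in fusion
#' experiments on the resting (task 1) and arithmetic (task 2) conditions:
#' \describe{
#'   \item{`task1_best5`}{2 WT features (alpha FL, PL) + 3 MS-COH features
#'     (theta FTR, theta OPL, alpha OPR) -- the five-feature resting-state
#'     subset.}
#'   \item{`task1_10`}{7 WT features (theta FL, FR, CR, OL; alpha FL, PL,
#'     OL) + 3 MS-COH features (theta FTR, OPL; alpha OPR).}
#'   \item{`task2_20`}{16 WT features (alpha PL, OL, OR; beta CL, PL, OL;
#'     gamma1 CL, CR, PL, PR, OL, OR; gamma2 PL, PR, OL, OR) + 4 MS-COH
#'     features (beta CPL, CPR, OPL, OPR).}
#' }
#'
#' @param name preset name, or `NULL` to list available presets.
#' @return data.frame with columns `measure`, `band`, `lobe`; or a character
#'   vector of preset names when `name` is `NULL`.
#' @export
biomarker_presets <- function(name = NULL) {
  presets <- list(
    task1_best5 = data.frame(
      measure = c("WT", "WT", "MS-COH", "MS-COH", "MS-COH"),
      band = c("alpha", "alpha", "theta", "theta", "alpha"),
      lobe = c("FL", "PL", "FTR", "OPL", "OPR"),
      stringsAsFactors = FALSE),
    task1_10 = data.frame(
      measure = c(rep("WT", 7), rep("MS-COH", 3)),
      band = c("theta", "theta", "theta", "theta", "alpha", "alpha",
               "alpha", "theta", "theta", "alpha"),
      lobe = c("FL", "FR", "CR", "OL", "FL", "PL", "OL",
               "FTR", "OPL", "OPR"),
      stringsAsFactors = FALSE),
    task2_20 = data.frame(
      measure = c(rep("WT", 16), rep("MS-COH", 4)),
      band = c(rep("alpha", 3), rep("beta", 3), rep("gamma1", 6),
               rep("gamma2", 4), rep("beta", 4)),
      lobe = c("PL", "OL", "OR", "CL", "PL", "OL",
               "CL", "CR", "PL", "PR", "OL", "OR",
               "PL", "PR", "OL", "OR",
               "CPL", "CPR", "OPL", "OPR"),
      stringsAsFactors = FALSE)
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

# Columns of a biomarker table matching a (measure, band, lobe) data.frame.
match_features <- function(table, subset) {
  idx <- mapply(function(m, b, l) {
    j <- which(table$features$measure == m & table$features$band == b &
                 table$features$lobe == l)
    if (length(j) != 1)
      stop("feature ", m, ".", b, ".", l, " not present in table")
    j
  }, subset$measure, subset$band, subset$lobe)
  as.integer(idx)
}
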