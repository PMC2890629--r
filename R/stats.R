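#' Welch two-sample t-test (unequal variances)
#'
#' The Behrens-Fisher setting: group variances are not assumed equal, so the
#' statistic is \eqn{t = (\bar a - \bar b)/\sqrt{s_a^2/n_1 + s_b^2/n_2}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' Student's t distribution.
#'
#' @param a,b numeric vectors (n >= 2 each, finite).
#' @return list with `t`, `df`, `p` and `degenerate` flag.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: constant groups
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = TRUE))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Normality diagnostics: D'Agostino-Pearson and Kolmogorov-Smirnov
#'
#' The D'Agostino-Pearson omnibus test combines transformed skewness and
#' kurtosis into a statistic that is approximately chi-squared with 2 df; it
#' needs n >= 8 for its approximations. The KS test is run against a normal
#' distribution with mean and SD estimated from the sample (a Lilliefors-
#' style usage whose nominal p-values are conservative; flagged in the
#' result).
#'
#' @param x numeric sample.
#' @return list with `dagostino_p`, `ks_p` (either may be `NA` when the
#'   method's minimum n is not met or the sample is degenerate) and `notes`.
#' @export
normality_tests <- function(x) {
  notes <- character(0)
  dp <- NA_real_; ks <- NA_real_
  if (stats::sd(x) == 0) {
    notes <- c(notes, "constant sample: normality tests skipped")
    return(list(dagostino_p = dp, ks_p = ks, notes = notes))
  }
  if (length(x) >= 8) {
    dp <- dagostino_pearson(x)$p
  } else {
    notes <- c(notes, "n < 8: D'Agostino-Pearson skipped")
  }
  if (length(x) >= 3) {
    ks <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    notes <- c(notes,
               "KS run with estimated parameters (Lilliefors caveat)")
  } else {
    notes <- c(notes, "n < 3: KS skipped")
  }
  list(dagostino_p = dp, ks_p = ks, notes = notes)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines D'Agostino's transformed skewness Z1 and the Anscombe-Glynn
#' transformed kurtosis Z2 into \eqn{K^2 = Z_1^2 + Z_2^2 \sim \chi^2_2}.
#'
#' @param x numeric sample, n >= 8.
#' @return list with `statistic` (K^2) and `p`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(Y / alpha)
  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p = stats::pchisq(K2, 2, lower.tail = FALSE))
}

#' Levene's test for homogeneity of variances (two samples)
#'
#' Levene's F statistic on absolute deviations from the group means.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return list with `F`, `p` and `degenerate` flag.
#' @export
levene_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  y <- c(a, b)
  g <- factor(c(rep("a", length(a)), rep("b", length(b))))
  dev <- c(abs(a - mean(a)), abs(b - mean(b)))
  if (stats::sd(dev) == 0) {
    return(list(F = 0, p = 1, degenerate = TRUE))
  }
  lt <- car::leveneTest(y, g, center = mean)
  list(F = lt[1, "F value"], p = lt[1, "Pr(>F)"], degenerate = FALSE)
}

min_or_na <- function(...) {
  v <- c(...)
  if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
}

#' Group significance map over all biomarkers
#'
#' Runs one Welch two-sample test per (measure, band, lobe) biomarker,
#' attaches assumption diagnostics (per-group normality, Levene), and
#' assigns the topographic significance class used for p-value maps:
#' `blank` (p > 0.1), `shaded` (0.01 <= p <= 0.1), `strong` (p < 0.01).
#' No multiple-testing correction is applied; the number of cells tested is
#' recorded in attribute `n_cells` so users can apply their own.
#'
#' @param table a [biomarker_table()] containing both groups (n >= 2 each).
#' @return a data.frame of class `group_stats_map`, one row per cell, with
#'   group means/SDs, `t`, `df`, `p`, diagnostics and `class`.
#' @export
significance_map <- function(table) {
  stopifnot(inherits(table, "biomarker_table"))
  ic <- table$groups == "control"
  ie <- table$groups == "epileptic"
  if (sum(ic) < 2 || sum(ie) < 2)
    stop("both groups must be present with n >= 2")
  rows <- lapply(seq_len(ncol(table$values)), function(j) {
    e <- table$values[ie, j]
    c0 <- table$values[ic, j]
    wt <- welch_t_test(e, c0)
    ne <- normality_tests(e); nc <- normality_tests(c0)
    lv <- levene_test(e, c0)
    cls <- if (wt$p > 0.1) "blank" else if (wt$p < 0.01) "strong" else
      "shaded"
    data.frame(
      measure = table$features$measure[j],
      band = table$features$band[j],
      lobe = table$features$lobe[j],
      mean_epileptic = mean(e), sd_epileptic = stats::sd(e),
      mean_control = mean(c0), sd_control = stats::sd(c0),
      t = wt$t, df = wt$df, p = wt$p,
      normality_p_epileptic = min_or_na(ne$dagostino_p, ne$ks_p),
      normality_p_control = min_or_na(nc$dagostino_p, nc$ks_p),
      levene_p = lv$p,
      class = cls,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_cells") <- nrow(out)
  class(out) <- c("group_stats_map", "data.frame")
  out
}

#' @export
print.group_stats_map <- function(x, ...) {
  cat(sprintf("Group significance map: %d cells (%d shaded, %d strong)\n",
              nrow(x), sum(x$class == "shaded"), sum(x$class == "strong")))
  NextMethod()
  invisible(x)
}
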