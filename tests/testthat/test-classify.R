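make_labels <- function(n = 20) rep(c("control", "epileptic"), each = n)

test_that("confusion metrics compute the standard identities", {
  lab <- make_labels(20)
  # 16/20 epileptics and 12/20 controls correct -> 80 / 60 / 70
  pred <- lab
  pred[21:24] <- "control"          # 4 epileptics missed
  pred[1:8] <- "epileptic"          # 8 controls missed
  m <- confusion_metrics(pred, lab)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 60)
  expect_equal(m$score, 70)
  expect_equal(m$score, (m$sensitivity + m$specificity) / 2)
  # all correct / all positive
  expect_equal(confusion_metrics(lab, lab)$score, 100)
  allp <- confusion_metrics(rep("epileptic", 40), lab)
  expect_equal(allp$sensitivity, 100)
  expect_equal(allp$specificity, 0)
  expect_equal(allp$score, 50)
  expect_error(confusion_metrics(c("x", "y"), c("control", "control")),
               "labels")
})

test_that("LOO-LDA separates well-separated clouds and is deterministic", {
  set.seed(61)
  lab <- make_labels(20)
  X <- cbind(rnorm(40) + ifelse(lab == "epileptic", 6, 0), rnorm(40))
  r <- lda_loo(X, lab)
  expect_equal(r$score, 100)
  r2 <- lda_loo(X, lab)
  expect_identical(r$predictions, r2$predictions)
  # single near-perfect feature
  x1 <- ifelse(lab == "epileptic", 1, 0) + rnorm(40, sd = 1e-3)
  r3 <- lda_loo(x1, lab)
  expect_equal(r3$sensitivity, 100)
  expect_equal(r3$specificity, 100)
})

test_that("in-house LDA decisions agree with the reference implementation", {
  # independent route: MASS::lda with equal priors on well-conditioned data
  set.seed(68)
  lab <- make_labels(20)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 3), 40) +
      outer(ifelse(lab == "epileptic", 1, 0), c(1, 0.5, -0.8))
    fit <- eegmarkers:::lda_fit(X, lab)
    mine <- fit(X)
    ref <- MASS::lda(X, grouping = factor(lab), prior = c(0.5, 0.5))
    theirs <- as.character(predict(ref, X)$class)
    expect_equal(mine, theirs)
  }
})

test_that("permuted labels give chance-level mean LOO score", {
  set.seed(62)
  lab <- make_labels(20)
  X <- matrix(rnorm(40 * 2), 40)
  scores <- replicate(200, lda_loo(X, sample(lab))$score)
  expect_lt(abs(mean(scores) - 50), 3)
})

test_that("singular covariance triggers ridge regularization, not failure", {
  lab <- make_labels(5)
  X <- cbind(c(rnorm(5), rnorm(5) + 2), 0)   # constant second column
  X <- rbind(X, X)[1:10, ]
  r <- withCallingHandlers(
    lda_loo(X, lab),
    warning = function(w) {
      expect_match(conditionMessage(w), "ridge")
      invokeRestart("muffleWarning")
    })
  expect_s3_class(r, "eeg_classification")
})

test_that("ldc-average fusion reduces to single-feature LDA on duplicates", {
  set.seed(63)
  lab <- make_labels(15)
  f <- rnorm(30) + ifelse(lab == "epileptic", 1.2, 0)
  X <- cbind(f, f, f)
  ra <- fuse_ldc_average(X, lab)
  rs <- lda_loo(f, lab)
  expect_identical(ra$predictions, rs$predictions)
  # anti-correlated informative columns cancel under averaging (the
  # degenerate averaged feature triggers the ridge fallback)
  X2 <- cbind(f, -f)
  r2 <- suppressWarnings(fuse_ldc_average(X2, lab))
  best <- max(lda_loo(f, lab)$score, lda_loo(-f, lab)$score)
  expect_lte(r2$score, best)
})

test_that("majority vote follows more-than-half rule with documented ties", {
  lab <- c("control", "epileptic")
  v <- rbind(c("epileptic", "epileptic", "control"),
             c("epileptic", "epileptic", "epileptic"))
  r <- fuse_majority_vote(v, lab)
  expect_equal(r$predictions, c("epileptic", "epileptic"))
  # even split resolves to the tie-break label
  v2 <- rbind(c("epileptic", "control"), c("epileptic", "control"))
  expect_equal(fuse_majority_vote(v2, lab)$predictions,
               c("control", "control"))
  expect_equal(fuse_majority_vote(v2, lab,
                                  tie_break = "epileptic")$predictions,
               c("epileptic", "epileptic"))
})

test_that("independent voters approach the binomial fusion accuracy", {
  # 5 independent voters at 70%: P(>=3 correct) = 0.83692
  set.seed(64)
  n <- 4000
  lab <- rep(c("control", "epileptic"), each = n / 2)
  votes <- sapply(1:5, function(j) {
    flip <- runif(n) > 0.7
    ifelse(flip, ifelse(lab == "control", "epileptic", "control"), lab)
  })
  r <- fuse_majority_vote(votes, lab)
  p_expect <- 100 * sum(dbinom(3:5, 5, 0.7))
  expect_equal(r$score, p_expect, tolerance = 0.03)
})

test_that("weighted sum reduces to majority vote at equal weights", {
  set.seed(65)
  lab <- make_labels(10)
  votes <- matrix(sample(c("control", "epileptic"), 20 * 5, replace = TRUE),
                  20)
  rmv <- fuse_majority_vote(votes, lab)
  rws <- fuse_weighted_sum(votes, rep(1, 5), lab)
  expect_identical(rmv$predictions, rws$predictions)
  # one dominant weight follows its feature
  rd <- fuse_weighted_sum(votes, c(1, 0, 0, 0, 0), lab)
  expect_identical(rd$predictions, unname(votes[, 1]))
  # worked example: weights (0.9, 0.4, 0.4), votes (E, C, C) -> E
  r1 <- fuse_weighted_sum(matrix(c("epileptic", "control", "control"), 1),
                          c(0.9, 0.4, 0.4), "epileptic")
  expect_equal(r1$predictions, "epileptic")
  expect_error(fuse_weighted_sum(votes, rep(0, 5), lab), "all zero")
})

test_that("mindist assigns nearest centroid and matches LDA when isotropic", {
  set.seed(66)
  lab <- make_labels(20)
  # isotropic shared covariance: decisions agree with LDA >= 95%
  X <- matrix(rnorm(40 * 3), 40) + ifelse(lab == "epileptic", 1, 0)
  agree <- mean(fuse_mindist(X, lab)$predictions ==
                  lda_loo(X, lab)$predictions)
  expect_gte(agree, 0.95)
  # 1-D: centroids at 0 and 2, test points classified by proximity
  xs <- c(rep(0, 5), rep(2, 5), 0.9)
  lb <- c(rep("control", 5), rep("epileptic", 5), "control")
  r <- fuse_mindist(matrix(xs, ncol = 1), lb)
  expect_equal(r$predictions[11], "control")
})

test_that("feature selection filters by 50% sens/spec and ranks by score", {
  rep_df <- data.frame(
    measure = "WT", band = "alpha", lobe = paste0("L", 1:6),
    score = c(70, 65, 80, 55, 60, 75),
    sensitivity = c(60, 70, 55, 40, 65, 80),
    specificity = c(70, 55, 60, 80, 45, 70))
  sel <- select_features(rep_df, n_features = 3)
  # rows 4 and 5 fail the filters; ranked by score: 3 (80), 6 (75), 1 (70)
  expect_equal(sel, c(3, 6, 1))
  all_fail <- transform(rep_df, sensitivity = 10)
  expect_error(select_features(all_fail), "relaxing")
})

test_that("published presets name the expected feature subsets", {
  expect_setequal(biomarker_presets(),
                  c("task1_best5", "task1_10", "task2_20"))
  p5 <- biomarker_presets("task1_best5")
  expect_equal(nrow(p5), 5)
  expect_equal(p5$measure, c("WT", "WT", "MS-COH", "MS-COH", "MS-COH"))
  expect_equal(p5$lobe, c("FL", "PL", "FTR", "OPL", "OPR"))
  expect_equal(nrow(biomarker_presets("task1_10")), 10)
  expect_equal(nrow(biomarker_presets("task2_20")), 20)
  expect_equal(sum(biomarker_presets("task2_20")$measure == "WT"), 16)
  expect_error(biomarker_presets("nope"), "unknown preset")
})
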