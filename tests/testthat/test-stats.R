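# Statistical layer: exact Mann-Whitney, ROC oracle equality, LDA
# calibration, ICC against frozen pingouin values, report schemas.

test_that("mann_whitney exact mode matches enumeration and wilcox.test", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$method, "exact")

  # all 2-group splits of 1..8 with |a| = 3: agree with stats::wilcox.test
  pool <- c(0.3, 1.1, 2.7, 3.1, 4.9, 5.2, 6.8, 7.5)
  combs <- utils::combn(8, 3)
  for (j in seq_len(ncol(combs))) {
    a <- pool[combs[, j]]; b <- pool[-combs[, j]]
    expect_equal(mann_whitney(a, b)$p_value,
                 suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("mann_whitney normal approximation matches wilcox.test with ties", {
  set.seed(5)
  a <- round(rnorm(30), 1); b <- round(rnorm(35, 0.4), 1)  # forced ties
  expect_equal(mann_whitney(a, b)$p_value,
               suppressWarnings(
                 stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-10)
  # symmetric case
  x <- rep(c(1, 2, 3, 4), 10)
  expect_gt(mann_whitney(x, x)$p_value, 0.95)
  # strongly separated
  expect_lt(mann_whitney(1:20, 21:40)$p_value, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "finite")
})

test_that("roc_analysis: perfect separation, orientation, tie handling", {
  r <- roc_analysis(1:4, c("non", "non", "metastatic", "metastatic"),
                    positive = "metastatic")
  expect_equal(r$auroc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$misclassification_error, 0)
  expect_equal(r$orientation, "high")

  rf <- roc_analysis(1:4, c("metastatic", "metastatic", "non", "non"))
  expect_equal(rf$auroc, 1)
  expect_equal(rf$orientation, "low")

  rt <- roc_analysis(c(1, 2, 2, 3), c("n", "metastatic", "n", "metastatic"))
  expect_equal(rt$auroc, 0.875)  # brute-force pair count with tie half-credit

  expect_error(roc_analysis(1:4, rep("metastatic", 4)), "both classes")
})

test_that("roc auroc equals brute-force pair counting on random sets", {
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    labels <- sample(c("metastatic", "nonmetastatic"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(round(rnorm(n), 1))  # ties likely
    r <- roc_analysis(scores, labels)
    bf <- brute_auroc(scores, labels)
    expect_equal(r$auroc, max(bf, 1 - bf), tolerance = 1e-12)
    expect_equal(r$accuracy + r$misclassification_error, 100)
  }
})

test_that("operating point maximizes the requested criterion", {
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c("n", "n", "metastatic", "n", "metastatic", "metastatic")
  ry <- roc_analysis(scores, labels, operating_point = "youden")
  ra <- roc_analysis(scores, labels, operating_point = "accuracy")
  # brute check over all midpoints
  best_j <- -Inf; best_acc <- -Inf
  for (th in (1:5) + 0.5) {
    sens <- mean(scores[labels == "metastatic"] > th)
    spec <- mean(scores[labels != "metastatic"] <= th)
    best_j <- max(best_j, sens + spec - 1)
    best_acc <- max(best_acc, (3 * sens + 3 * spec) / 6)
  }
  expect_equal((ry$sensitivity + ry$specificity) / 100 - 1, best_j)
  expect_equal(ra$accuracy / 100, best_acc)
})

test_that("LDA cross-validation: separable, null and leave-one-out", {
  set.seed(1)
  df <- data.frame(
    label = rep(c("metastatic", "nonmetastatic"), each = 50),
    f1 = c(rnorm(50, 5), rnorm(50, -5)))
  ld <- lda_crossval(df, "f1", k = 10, seed = 1)
  expect_gt(ld$pooled$auroc, 0.99)
  loo <- lda_crossval(df, "f1", k = 100, seed = 1)
  expect_lt(abs(loo$pooled$auroc - ld$pooled$auroc), 0.01)

  # null: identical class distributions (unflipped pooled auroc)
  aurocs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    d0 <- data.frame(label = rep(c("metastatic", "nonmetastatic"), each = 50),
                     f1 = rnorm(100), f2 = rnorm(100))
    lda_crossval(d0, c("f1", "f2"), k = 10, seed = s)$auroc_raw
  }, numeric(1))
  expect_true(all(aurocs > 0.3 & aurocs < 0.7))
  expect_gt(mean(aurocs), 0.4)
  expect_lt(mean(aurocs), 0.6)

  df$flat <- 1
  expect_error(lda_crossval(df, c("f1", "flat")), "zero-variance")
})

test_that("ICC(2,1) matches frozen pingouin ICC(A,1) values", {
  r <- interobserver_icc(1:20, 1:20)
  expect_equal(r$icc, 1)
  expect_equal(r$band, "excellent")

  # variance components 0.7/0.3: frozen oracle from pingouin.intraclass_corr
  # (ICC(A,1) = 0.745938, CI [0.68, 0.80]) on this exact draw
  set.seed(2)
  s <- rnorm(200, sd = sqrt(0.7))
  e1 <- rnorm(200, sd = sqrt(0.3)); e2 <- rnorm(200, sd = sqrt(0.3))
  r2 <- interobserver_icc(s + e1, s + e2)
  expect_equal(r2$icc, 0.745938, tolerance = 1e-5)
  expect_equal(r2$ci_lower, 0.68, tolerance = 0.005)
  expect_equal(r2$ci_upper, 0.80, tolerance = 0.005)
  expect_equal(r2$band, "good")
  expect_true(r2$ci_lower <= r2$icc && r2$icc <= r2$ci_upper)

  # reader noise far above subject variance -> poor agreement
  set.seed(3)
  subj <- rnorm(100, sd = 1)
  r3 <- interobserver_icc(subj + rnorm(100, sd = 5), subj + rnorm(100, sd = 5))
  expect_lt(r3$icc, 0.2)
  expect_equal(r3$band, "poor")

  expect_error(interobserver_icc(1:4, 1:4), "at least 5")
  expect_error(interobserver_icc(rep(1, 10), rep(1, 10)), "between-subject")
})

test_that("report_tables produces the four report schemas", {
  set.seed(7)
  n <- 40
  lab <- rep(c("metastatic", "nonmetastatic"), each = n / 2)
  tab <- data.frame(node_id = sprintf("n%02d", 1:n), label = lab)
  for (f in morph_feature_names()) tab[[f]] <- rnorm(n, ifelse(lab == "metastatic", 1, 0))
  for (f in dyn_feature_names()) tab[[f]] <- rnorm(n, ifelse(lab == "metastatic", 0.8, 0))
  tab$circularity <- rnorm(n)          # uninformative
  tab$constant_extra <- NULL
  rep <- report_tables(tab, k = 5, seed = 1)

  expect_equal(rep$group_morph$feature, morph_feature_names())
  expect_equal(rep$group_dyn$feature, dyn_feature_names())
  expect_named(rep$group_morph,
               c("feature", "metastatic_median", "metastatic_sd",
                 "nonmetastatic_median", "nonmetastatic_sd", "p_value"))
  expect_equal(nrow(rep$roc), 26)
  expect_equal(rep$roc$misclassification_error, 100 - rep$roc$accuracy)
  expect_equal(rep$lda$feature_set,
               c("all_dynamic", "all_morphological", "all_features",
                 "significant_dynamic", "significant_morphological",
                 "significant_features"))
  expect_true(all(rep$significant_features %in% rep$roc$feature))

  # a feature constant across classes: p ~ 1, never "significant"
  tab$volume <- rep(c(5, 6), n / 2)
  rep2 <- report_tables(tab, k = 5, seed = 1)
  expect_gt(rep2$group_morph$p_value[rep2$group_morph$feature == "volume"], 0.5)
  expect_false("volume" %in% rep2$significant_features)
})
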