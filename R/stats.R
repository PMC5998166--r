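# Statistical layer: group comparison, per-feature ROC operating points,
# Fisher LDA with stratified k-fold cross-validation, and two-reader
# agreement. The positive class is "metastatic" throughout.

#' Two-sided Mann-Whitney test
#'
#' Exact by full enumeration of group assignments when
#' `length(a) + length(b) <= 12` and there are no ties (two-sided p = the
#' probability of a U at least as extreme on either side); otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (non-finite values dropped).
#' @return List with `p_value`, `U` (statistic of group `a`), `method`
#'   ("exact" or "normal") and `significant` (p < 0.05).
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("each group needs at least one finite value")
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_a <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(pooled))

  if (N <= 12L && !ties) {
    # enumerate all C(N, m) assignments of the pooled ranks to group a
    combs <- utils::combn(N, m)
    ranks <- rank(pooled)  # == a permutation of 1..N (no ties)
    us <- colSums(matrix(sort(ranks)[combs], nrow = m)) - m * (m + 1) / 2
    mn <- m * n
    extreme <- min(u_a, mn - u_a)
    p <- sum(us <= extreme | us >= mn - extreme) / ncol(combs)
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u_a - mu - sign(u_a - mu) * 0.5) / sigma
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  p <- min(p, 1)
  list(p_value = p, U = u_a, method = method, significant = p < 0.05)
}

#' ROC analysis of one feature
#'
#' AUROC by the rank statistic (ties get half credit). The orientation is
#' chosen so that AUROC >= 0.5 and recorded (`"high"`: high scores indicate
#' the positive class). The operating point is the threshold maximizing
#' Youden's J (or accuracy) over all midpoints between consecutive sorted
#' unique scores, ties broken toward the lower threshold; a sample is called
#' positive when its oriented score exceeds the threshold.
#'
#' @param scores Numeric feature values.
#' @param labels Class labels; `positive` names the positive class.
#' @param positive Positive class label (default "metastatic").
#' @param operating_point `"youden"` (default) or `"accuracy"`.
#' @return List of class `roc_result`: `auroc`, `orientation`, `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`, `misclassification_error`
#'   (percent scales), `n_pos`, `n_neg`, `n_missing`.
#' @export
roc_analysis <- function(scores, labels, positive = "metastatic",
                         operating_point = c("youden", "accuracy")) {
  operating_point <- match.arg(operating_point)
  keep <- is.finite(scores)
  n_missing <- sum(!keep)
  scores <- scores[keep]; labels <- labels[keep]
  is_pos <- labels == positive
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) stop("both classes must be present")

  rk <- rank(scores)
  auroc <- (sum(rk[is_pos]) - np * (np + 1) / 2) / (np * nn)
  orientation <- "high"
  if (auroc < 0.5) {
    orientation <- "low"
    scores <- -scores
    auroc <- 1 - auroc
  }

  su <- sort(unique(scores))
  thr <- if (length(su) > 1) (utils::head(su, -1) + utils::tail(su, -1)) / 2 else su - 0.5
  sens <- vapply(thr, function(th) sum(is_pos & scores > th) / np, numeric(1))
  spec <- vapply(thr, function(th) sum(!is_pos & scores <= th) / nn, numeric(1))
  crit <- switch(operating_point,
                 youden = sens + spec - 1,
                 accuracy = (sens * np + spec * nn) / (np + nn))
  best <- which.max(crit)  # ties: first = lowest threshold
  acc <- (sens[best] * np + spec[best] * nn) / (np + nn) * 100
  structure(list(
    auroc = auroc, orientation = orientation, threshold = thr[best],
    sensitivity = sens[best] * 100, specificity = spec[best] * 100,
    accuracy = acc, misclassification_error = 100 - acc,
    n_pos = np, n_neg = nn, n_missing = n_missing,
    operating_point = operating_point
  ), class = "roc_result")
}

# Stratified fold assignment: within each class, shuffled then dealt
# round-robin into k folds.
.stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fisher LDA with stratified k-fold cross-validation
#'
#' Per fold: features are standardized with the training fold's mean/SD, a
#' Fisher discriminant direction w = S^-1 (mu_pos - mu_neg) is computed from
#' the pooled within-class covariance S (ridge-regularized by
#' 1e-6 tr(S) I), and out-of-fold discriminant scores are pooled. The pooled
#' scores are then assessed with [roc_analysis()].
#'
#' @param table Data.frame with a `label` column and feature columns.
#' @param features Character vector of feature columns to use.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param positive Positive class label.
#' @param operating_point Passed to [roc_analysis()].
#' @return List of class `lda_result`: `weights` (full-data direction on
#'   standardized features), `pooled` ([roc_analysis()] of pooled scores),
#'   `auroc_raw` (pooled auroc without orientation flipping, the null-centred
#'   statistic), `fold_auroc`, `features`, `k`, `seed`, `n`, `n_dropped`
#'   (rows lost to missing values).
#' @export
lda_crossval <- function(table, features, k = 10L, seed = 17L,
                         positive = "metastatic",
                         operating_point = c("youden", "accuracy")) {
  operating_point <- match.arg(operating_point)
  stopifnot("label" %in% names(table), all(features %in% names(table)))
  x <- as.matrix(table[, features, drop = FALSE])
  storage.mode(x) <- "double"
  complete <- rowSums(!is.finite(x)) == 0
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  labels <- table$label[complete]
  n <- nrow(x)
  if (n < k) stop("need at least k samples")
  pooled_sd <- apply(x, 2, stats::sd)
  if (any(pooled_sd == 0)) {
    stop("zero-variance features: ",
         paste(features[pooled_sd == 0], collapse = ", "))
  }

  fisher_direction <- function(xt, yt) {
    mu1 <- colMeans(xt[yt, , drop = FALSE])
    mu0 <- colMeans(xt[!yt, , drop = FALSE])
    n1 <- sum(yt); n0 <- sum(!yt)
    c1 <- stats::cov(xt[yt, , drop = FALSE]) * (n1 - 1)
    c0 <- stats::cov(xt[!yt, , drop = FALSE]) * (n0 - 1)
    S <- (c1 + c0) / (n1 + n0 - 2)
    S <- S + diag(1e-6 * sum(diag(S)), ncol(xt))
    w <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
      stop("singular pooled covariance for features: ",
           paste(colnames(xt), collapse = ", "))
    })
    w
  }

  fold <- .stratified_folds(labels, k, seed)
  scores <- rep(NA_real_, n)
  fold_auroc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (!any(te)) next
    ctr <- colMeans(x[tr, , drop = FALSE])
    str <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    str[str == 0] <- 1
    xt <- sweep(sweep(x[tr, , drop = FALSE], 2, ctr), 2, str, `/`)
    xe <- sweep(sweep(x[te, , drop = FALSE], 2, ctr), 2, str, `/`)
    w <- fisher_direction(xt, labels[tr] == positive)
    scores[te] <- as.numeric(xe %*% w)
    yf <- labels[te] == positive
    if (any(yf) && any(!yf)) {
      rkf <- rank(scores[te])
      fold_auroc[f] <- (sum(rkf[yf]) - sum(yf) * (sum(yf) + 1) / 2) /
        (sum(yf) * sum(!yf))
    }
  }

  xs <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, stats::sd), `/`)
  w_full <- fisher_direction(xs, labels == positive)
  pooled <- roc_analysis(scores, labels, positive = positive,
                         operating_point = operating_point)
  # unflipped auroc of the pooled scores (w points toward the positive class
  # by construction, so no data-driven orientation is applied); this is the
  # statistic whose null distribution is centred at 0.5
  yy <- labels == positive
  rk <- rank(scores)
  auroc_raw <- (sum(rk[yy]) - sum(yy) * (sum(yy) + 1) / 2) /
    (sum(yy) * sum(!yy))
  structure(list(
    weights = stats::setNames(w_full, features),
    pooled = pooled, auroc_raw = auroc_raw, fold_auroc = fold_auroc,
    features = features, k = k, seed = seed, n = n, n_dropped = n_dropped
  ), class = "lda_result")
}

#' Two-reader agreement: ICC(2,1)
#'
#' Single-measure, absolute-agreement intraclass correlation from the
#' two-way random-effects model, with the F-distribution 95% confidence
#' interval (McGraw & Wong), and the qualitative band
#' (poor < 0.21 <= fair < 0.41 <= moderate < 0.61 <= good < 0.81 <= excellent).
#'
#' @param reader1_values,reader2_values Paired measurements, length >= 5.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `agreement_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `band`, `n`.
#' @export
interobserver_icc <- function(reader1_values, reader2_values,
                              conf_level = 0.95) {
  x <- cbind(as.numeric(reader1_values), as.numeric(reader2_values))
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x); k <- 2L
  if (n < 5L) stop("need at least 5 paired observations")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= mse && msr == 0) stop("zero between-subject variance")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (!is.finite(icc)) stop("zero between-subject variance")

  if (mse == 0 && msc == 0) {
    # exact agreement: degenerate CI at the estimate
    return(structure(list(icc = icc, ci_lower = icc, ci_upper = icc,
                          band = "excellent", n = n),
                     class = "agreement_result"))
  }
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / (n - 1))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  bands <- c("poor", "fair", "moderate", "good", "excellent")
  band <- bands[findInterval(icc, c(-Inf, 0.205, 0.405, 0.605, 0.805)) ]
  structure(list(icc = icc, ci_lower = lower, ci_upper = upper,
                 band = band, n = n), class = "agreement_result")
}

#' Group-comparison, ROC, and LDA report tables
#'
#' Produces the four report tables of the analysis layer from a cohort
#' feature table: per-feature median/SD by class with Mann-Whitney p
#' (morphological and dynamic tables), per-feature ROC operating points, and
#' LDA results for all-dynamic / all-morphological / all features plus the
#' "significant" subsets (features with ROC accuracy > 70%).
#'
#' @param table Cohort data.frame: `node_id`, `label`, feature columns
#'   (one row per node; if a `reader_id` column is present, only the first
#'   reader is used for group statistics).
#' @param morph_features,dyn_features Feature name vectors; defaults are the
#'   canonical 17 + 9 names intersected with the table's columns.
#' @param k,seed,operating_point Cross-validation settings for the LDA table.
#' @return List of data.frames `group_morph`, `group_dyn`, `roc`, `lda`, plus
#'   `significant_features`.
#' @export
report_tables <- function(table,
                          morph_features = intersect(morph_feature_names(), names(table)),
                          dyn_features = intersect(dyn_feature_names(), names(table)),
                          k = 10L, seed = 17L,
                          operating_point = c("youden", "accuracy")) {
  operating_point <- match.arg(operating_point)
  stopifnot(all(c("label") %in% names(table)))
  if ("reader_id" %in% names(table)) {
    first_reader <- sort(unique(table$reader_id))[1]
    table <- table[table$reader_id == first_reader, , drop = FALSE]
  }
  pos <- table$label == "metastatic"

  group_table <- function(feats) {
    if (!length(feats)) return(NULL)
    rows <- lapply(feats, function(f) {
      v <- table[[f]]
      vm <- v[pos & is.finite(v)]; vn <- v[!pos & is.finite(v)]
      p <- tryCatch(mann_whitney(vm, vn)$p_value, error = function(e) NA_real_)
      data.frame(feature = f,
                 metastatic_median = stats::median(vm),
                 metastatic_sd = stats::sd(vm),
                 nonmetastatic_median = stats::median(vn),
                 nonmetastatic_sd = stats::sd(vn),
                 p_value = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  all_feats <- c(dyn_features, morph_features)
  roc_rows <- lapply(all_feats, function(f) {
    v <- table[[f]]
    r <- tryCatch(roc_analysis(v, table$label,
                               operating_point = operating_point),
                  error = function(e) NULL)
    if (is.null(r)) {
      return(data.frame(feature = f, sensitivity = NA_real_,
                        specificity = NA_real_,
                        misclassification_error = NA_real_,
                        accuracy = NA_real_, auroc = NA_real_,
                        orientation = NA_character_, n_missing = sum(!is.finite(v)),
                        stringsAsFactors = FALSE))
    }
    data.frame(feature = f, sensitivity = r$sensitivity,
               specificity = r$specificity,
               misclassification_error = r$misclassification_error,
               accuracy = r$accuracy, auroc = r$auroc,
               orientation = r$orientation, n_missing = r$n_missing,
               stringsAsFactors = FALSE)
  })
  roc_tab <- do.call(rbind, roc_rows)

  sig <- roc_tab$feature[!is.na(roc_tab$accuracy) & roc_tab$accuracy > 70]
  lda_sets <- list(
    all_dynamic = dyn_features,
    all_morphological = morph_features,
    all_features = all_feats,
    significant_dynamic = intersect(sig, dyn_features),
    significant_morphological = intersect(sig, morph_features),
    significant_features = sig)
  lda_rows <- lapply(names(lda_sets), function(nm) {
    feats <- lda_sets[[nm]]
    if (length(feats) < 1L) {
      return(data.frame(feature_set = nm, n_features = 0L,
                        sensitivity = NA_real_, specificity = NA_real_,
                        auroc = NA_real_, stringsAsFactors = FALSE))
    }
    res <- tryCatch(
      lda_crossval(table, feats, k = k, seed = seed,
                   operating_point = operating_point),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(feature_set = nm, n_features = length(feats),
                        sensitivity = NA_real_, specificity = NA_real_,
                        auroc = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(feature_set = nm, n_features = length(feats),
               sensitivity = res$pooled$sensitivity,
               specificity = res$pooled$specificity,
               auroc = res$pooled$auroc, stringsAsFactors = FALSE)
  })

  list(group_morph = group_table(morph_features),
       group_dyn = group_table(dyn_features),
       roc = roc_tab,
       lda = do.call(rbind, lda_rows),
       significant_features = sig)
}
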