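# Cross-validation machinery shared by the outcome and predictability
# models, plus drop-predictor importance and confidence-sorted curves.

# Stratified fold assignment. Rows are put in canonical sample_id order
# before drawing so the folds depend on the seed, not on input row order.
stratified_folds <- function(y, sample_ids, folds, seed) {
  n <- length(y)
  fold <- integer(n)
  canonical <- order(sample_ids)
  withr::with_seed(seed, {
    for (cl in unique(as.character(y[canonical]))) {
      idx <- canonical[as.character(y[canonical]) == cl]
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

fit_rf_binary <- function(df, outcome, predictors, n_trees, balance, seed) {
  y <- droplevels(df[[outcome]])
  if (nlevels(y) != 2L) {
    stop("outcome must have two observed classes", call. = FALSE)
  }
  train <- df
  if (balance) {
    keep <- downsample_majority(stats::setNames(y, seq_along(y)), seed)
    train <- df[as.integer(keep), , drop = FALSE]
  }
  withr::with_seed(seed,
    randomForest::randomForest(x = train[predictors],
                               y = droplevels(train[[outcome]]),
                               ntree = n_trees))
}

# Pooled out-of-fold probabilities of the positive class for one fold split.
oof_probabilities <- function(df, outcome, predictors, positive, folds,
                              n_trees, balance, seed) {
  y <- df[[outcome]]
  fold <- stratified_folds(y, df$sample_id, folds, seed)
  p <- rep(NA_real_, nrow(df))
  for (k in seq_len(folds)) {
    tr <- fold != k
    te <- fold == k
    if (!any(te)) next
    model <- fit_rf_binary(df[tr, , drop = FALSE], outcome, predictors,
                           n_trees, balance, seed + k)
    p[te] <- predict(model, newdata = df[te, predictors, drop = FALSE],
                     type = "prob")[, positive]
  }
  p
}

auc_binary <- function(truth, prob, positive) {
  lv <- c(setdiff(unique(as.character(truth)), positive), positive)
  as.numeric(pROC::auc(pROC::roc(
    response = factor(as.character(truth), levels = lv),
    predictor = prob, levels = lv, direction = "<", quiet = TRUE)))
}

#' Repeated stratified cross-validated AUC
#'
#' Samples are split into `folds` outcome-stratified folds; each fold is
#' predicted by a random forest trained on the remaining folds (with
#' majority down-sampling applied inside the training folds when
#' `balance = TRUE`), and one ROC AUC is computed from the pooled
#' out-of-fold probabilities. The split-and-evaluate procedure is repeated
#' `repeats` times and the mean AUC over repeats is reported.
#'
#' @param data A data.frame with a `sample_id` column, the outcome and the
#'   predictors (see [build_model_frame()] for assembling one from a
#'   cohort).
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor columns.
#' @param positive The outcome level whose probability is ranked (default:
#'   the minority class).
#' @param folds,repeats Cross-validation geometry (defaults 10 and 10).
#' @param n_trees Trees per forest.
#' @param balance Down-sample the majority class inside each training fold.
#' @param seed Integer seed; repeat r uses `seed + r - 1` for its fold
#'   draw, so the whole procedure is reproducible.
#' @return Object of class `cv_result`: list with `auc_per_repeat`,
#'   `mean_auc`, `folds`, `repeats`, `seed`.
#' @export
cross_validated_auc <- function(data, outcome, predictors, positive = NULL,
                                folds = 10, repeats = 10, n_trees = 10000,
                                balance = TRUE, seed) {
  seed <- check_seed(seed)
  df <- factorize(data, c(outcome, predictors))
  if (!"sample_id" %in% names(df)) {
    df$sample_id <- as.character(seq_len(nrow(df)))
  }
  df <- drop_incomplete(df, c(outcome, predictors), "cross-validation")
  y <- droplevels(as.factor(df[[outcome]]))
  df[[outcome]] <- y
  if (nlevels(y) != 2L) {
    stop("outcome must have two observed classes", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("need at least 2 samples in each outcome class", call. = FALSE)
  }
  positive <- positive %||% names(which.min(table(y)))
  aucs <- vapply(seq_len(repeats), function(r) {
    p <- oof_probabilities(df, outcome, predictors, positive, folds,
                           n_trees, balance, seed + r - 1L)
    auc_binary(df[[outcome]], p, positive)
  }, numeric(1))
  structure(list(auc_per_repeat = aucs, mean_auc = mean(aucs),
                 folds = folds, repeats = repeats, seed = seed,
                 positive = positive),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> mean AUC ", format(x$mean_auc, digits = 4), " over ",
      x$repeats, " x ", x$folds, "-fold CV\n", sep = "")
  invisible(x)
}

#' Assemble a modelling data.frame from a cohort
#'
#' Convenience wrapper used before [cross_validated_auc()] and
#' [drop_column_importance()]: returns `sample_id`, the optional signature
#' `score`, the requested clinical columns, and any outcome columns.
#'
#' @inheritParams fit_classification_cpm
#' @param outcome Outcome column name(s) to carry along (e.g. `"response"`).
#' @export
build_model_frame <- function(cohort, scores = NULL,
                              predictors = character(), outcome = NULL) {
  build_frame(cohort, scores, predictors, outcome)
}

#' Drop-predictor relative importance
#'
#' The importance of a predictor is the decrease in cross-validated AUC
#' when it is removed from the full model: each reduced model is refit and
#' evaluated with exactly the same seed (hence the same fold draws) as the
#' full model. Note that redundant predictors shade each other: two copies
#' of the same informative variable both receive near-zero drop importance.
#'
#' @inheritParams cross_validated_auc
#' @return A data.frame `predictor`, `importance` (AUC of the full model
#'   minus AUC without the predictor), with the full-model AUC attached as
#'   attribute `full_auc`.
#' @export
drop_column_importance <- function(data, outcome, predictors,
                                   positive = NULL, folds = 10, repeats = 10,
                                   n_trees = 10000, balance = TRUE, seed) {
  if (length(predictors) < 2L) {
    stop("need at least 2 predictors to compare drop models", call. = FALSE)
  }
  full <- cross_validated_auc(data, outcome, predictors, positive, folds,
                              repeats, n_trees, balance, seed)
  drop_auc <- vapply(predictors, function(p) {
    cross_validated_auc(data, outcome, setdiff(predictors, p), positive,
                        folds, repeats, n_trees, balance, seed)$mean_auc
  }, numeric(1))
  structure(data.frame(predictor = predictors,
                       importance = full$mean_auc - unname(drop_auc),
                       stringsAsFactors = FALSE),
            full_auc = full$mean_auc)
}

#' Confidence-sorted cumulative accuracy curve
#'
#' Samples are sorted by decreasing C-score (ties broken by sample id) and
#' the running mean of a per-sample outcome metric — a 0/1 correctness
#' indicator, or a sample-specific concordance — is computed over the top N
#' samples for N = 1 to all. If the confidence scores carry information,
#' the curve declines as low-confidence samples accumulate. The curve is
#' additionally smoothed with a centered moving average (window truncated
#' at the series edges).
#'
#' @param cscores A data.frame `sample_id`, `c_score`.
#' @param metric Per-sample metric: numeric vector aligned with `cscores`,
#'   or a data.frame `sample_id`, `metric`. Samples with `NA` metric (e.g.
#'   no effective comparison) are excluded and reported.
#' @param window Smoothing window size (1 = no smoothing). The classifier
#'   analyses in this framework use 20; survival analyses, with their much
#'   smoother concordance metric, use 200.
#' @return Object of class `sorted_accuracy_curve`: data.frame `rank`,
#'   `sample_id`, `c_score`, `cumulative`, `smoothed` with attribute
#'   `window`.
#' @export
sorted_accuracy_curve <- function(cscores, metric, window = 20) {
  if (is.data.frame(metric)) {
    metric <- metric$metric[match(cscores$sample_id, metric$sample_id)]
  }
  stopifnot(length(metric) == nrow(cscores))
  if (window < 1 || window != round(window)) {
    stop("window must be a positive integer", call. = FALSE)
  }
  keep <- !is.na(metric) & !is.na(cscores$c_score)
  if (!any(keep)) stop("no samples with a defined metric", call. = FALSE)
  if (any(!keep)) {
    as_log_msg(sum(!keep), " sample(s) without a defined metric excluded ",
               "from the sorted curve")
  }
  df <- data.frame(sample_id = cscores$sample_id[keep],
                   c_score = cscores$c_score[keep],
                   metric = metric[keep], stringsAsFactors = FALSE)
  df <- df[order(-df$c_score, df$sample_id), , drop = FALSE]
  n <- nrow(df)
  cumulative <- cumsum(df$metric) / seq_len(n)
  h_lo <- floor((window - 1) / 2)
  h_hi <- window - 1L - h_lo
  csum <- cumsum(c(0, cumulative))
  lo <- pmax(1L, seq_len(n) - h_lo)
  hi <- pmin(n, seq_len(n) + h_hi)
  smoothed <- (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
  structure(data.frame(rank = seq_len(n), sample_id = df$sample_id,
                       c_score = df$c_score, cumulative = cumulative,
                       smoothed = smoothed, stringsAsFactors = FALSE),
            window = window, class = c("sorted_accuracy_curve",
                                       "data.frame"))
}
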