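#' Label samples as correctly or incorrectly predicted (classification)
#'
#' A sample is predicted pCR when its P-score exceeds the threshold (strict
#' inequality; exactly 0.5 is an RD call) and RD otherwise; the label is
#' positive when the call matches the observed response. These labels are
#' the training outcome of the predictability model.
#'
#' @param pscores A data.frame `sample_id`, `p_score` (see
#'   [predict_pscore()] or [out_of_fold_pscores()]).
#' @param truth Observed responses: a data.frame `sample_id`, `response` or
#'   a vector aligned with `pscores` (values `"pCR"`/`"RD"`).
#' @param threshold P-score cut-off for a pCR call.
#' @param provenance How the P-scores were obtained (`"out_of_fold"` or
#'   `"in_sample"`); recorded on the result.
#' @return A data.frame `sample_id`, `label` (factor negative/positive)
#'   with attributes `source` and `provenance`. Samples with a missing
#'   P-score or response are excluded and reported.
#' @export
label_classification_predictability <- function(pscores, truth,
                                                threshold = 0.5,
                                                provenance = c("out_of_fold",
                                                               "in_sample")) {
  provenance <- match.arg(provenance)
  if (is.data.frame(truth)) {
    truth <- truth$response[match(pscores$sample_id, truth$sample_id)]
  }
  stopifnot(length(truth) == nrow(pscores))
  truth <- as.character(truth)
  bad <- !truth %in% c("pCR", "RD") & !is.na(truth)
  if (any(bad)) stop("response must be 'pCR' or 'RD'", call. = FALSE)
  keep <- !is.na(pscores$p_score) & !is.na(truth)
  if (any(!keep)) {
    as_log_msg(sum(!keep), " sample(s) without P-score or response ",
               "excluded from predictability labels")
  }
  predicted_pcr <- pscores$p_score[keep] > threshold
  correct <- predicted_pcr == (truth[keep] == "pCR")
  structure(data.frame(sample_id = pscores$sample_id[keep],
                       label = factor(ifelse(correct, "positive",
                                             "negative"),
                                      levels = c("negative", "positive")),
                       stringsAsFactors = FALSE),
            source = "classification", provenance = provenance)
}

#' Label samples as well or poorly predicted (survival)
#'
#' Samples whose number of effective comparisons falls below the
#' [effective_fraction_filter()] threshold are excluded; among the
#' remainder, a sample is well predicted (positive) when its
#' sample-specific concordance strictly exceeds the overall concordance of
#' the model, and poorly predicted otherwise.
#'
#' @param decomp A `concordance_decomposition` for the cohort.
#' @param cohort_size,fraction Passed to [effective_fraction_filter()].
#' @return A data.frame `sample_id`, `label` restricted to retained
#'   samples, with attributes `source = "survival"`, `overall` and
#'   `n_excluded`.
#' @export
label_survival_predictability <- function(decomp, cohort_size = NULL,
                                          fraction = 0.2) {
  mask <- effective_fraction_filter(decomp, cohort_size, fraction)
  if (!any(mask)) {
    stop("all samples fall below the effective-comparison threshold",
         call. = FALSE)
  }
  if (any(!mask)) {
    as_log_msg(sum(!mask), " sample(s) below the effective-comparison ",
               "threshold excluded from predictability labels")
  }
  ps <- decomp$per_sample[mask, , drop = FALSE]
  well <- ps$c_sample > decomp$overall
  structure(data.frame(sample_id = ps$sample_id,
                       label = factor(ifelse(well, "positive", "negative"),
                                      levels = c("negative", "positive")),
                       stringsAsFactors = FALSE),
            source = "survival", overall = decomp$overall,
            n_excluded = sum(!mask))
}

#' Train the predictability prediction model (PPM)
#'
#' Random forest classifying correctly/well versus incorrectly/poorly
#' predicted samples from clinical features alone. The larger group is
#' randomly down-sampled to the smaller one before fitting (group sizes
#' before and after balancing are recorded in `train_log`). The fitted
#' model's probability of the positive group is the confidence C-score.
#'
#' @param cohort The cohort the labels refer to.
#' @param labels Predictability labels from
#'   [label_classification_predictability()] or
#'   [label_survival_predictability()].
#' @param predictors Clinical predictor columns (e.g.
#'   `c("age", "er_status", "stage", "subtype")`).
#' @param n_trees Trees in the forest (default 10000).
#' @param balance Down-sample the larger label group.
#' @param seed Integer seed.
#' @return Object of class `ppm_fit`.
#' @export
train_ppm <- function(cohort, labels, predictors, n_trees = 10000,
                      balance = TRUE, seed) {
  seed <- check_seed(seed)
  check_flag(balance, "balance")
  df <- build_frame(cohort, predictors = predictors)
  df$label <- labels$label[match(df$sample_id, labels$sample_id)]
  df <- df[!is.na(df$label), , drop = FALSE]
  df <- drop_incomplete(df, predictors, "PPM training")
  counts <- table(df$label)
  if (any(counts == 0L)) {
    stop("both predictability groups must be present; got ",
         paste(names(counts), unname(counts), collapse = ", ",
               sep = " = "), call. = FALSE)
  }
  train <- df
  if (balance) {
    keep <- downsample_majority(stats::setNames(df$label, df$sample_id),
                                seed)
    train <- df[df$sample_id %in% keep, , drop = FALSE]
  }
  balanced <- table(train$label)
  as_log_msg("PPM trained with ", paste(unname(balanced), collapse = "/"),
             " (negative/positive) samples",
             if (balance) paste0(" after balancing from ",
                                 paste(unname(counts), collapse = "/")))
  model <- withr::with_seed(seed,
    randomForest::randomForest(x = train[predictors], y = train$label,
                               ntree = n_trees))
  structure(list(model = model, predictors = predictors,
                 xlevels = rf_xlevels(train, predictors),
                 source = attr(labels, "source", exact = TRUE),
                 provenance = attr(labels, "provenance", exact = TRUE),
                 train_log = list(group_counts = as.list(counts),
                                  balanced_counts = as.list(balanced),
                                  balance = balance, seed = seed,
                                  n_trees = n_trees)),
            class = "ppm_fit")
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat("<ppm_fit> random forest, ", x$train_log$n_trees, " trees, ",
      "predictors: ", paste(x$predictors, collapse = ", "),
      "\n  trained on ", paste(unlist(x$train_log$balanced_counts),
                               collapse = "/"),
      " (negative/positive) samples\n", sep = "")
  invisible(x)
}

#' Confidence C-scores from a fitted PPM
#'
#' One C-score in [0, 1] per cohort sample: the predicted probability that
#' the outcome model's prediction for this sample is correct, interpreted
#' as the biomarker's applicability to the patient. Samples with missing
#' predictors get `NA` and are reported.
#'
#' @param fit A `ppm_fit`.
#' @param cohort The cohort to score.
#' @return A data.frame `sample_id`, `c_score`.
#' @export
predict_cscore <- function(fit, cohort) {
  df <- build_frame(cohort, predictors = fit$predictors)
  df <- apply_xlevels(df, fit$xlevels)
  ok <- stats::complete.cases(df[fit$predictors])
  if (any(!ok)) {
    as_log_msg(sum(!ok), " sample(s) got NA C-score for missing predictors")
  }
  p <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    p[ok] <- predict(fit$model, newdata = df[ok, fit$predictors,
                                             drop = FALSE],
                     type = "prob")[, "positive"]
  }
  data.frame(sample_id = df$sample_id, c_score = p,
             stringsAsFactors = FALSE)
}
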