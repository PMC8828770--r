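#' Down-sample the majority class to balance a binary outcome
#'
#' Randomly removes majority-class samples until both classes have the same
#' size; every minority-class sample is kept. Used before training both the
#' outcome model and the predictability model so that imbalanced cohorts
#' (residual disease typically far outnumbers pathologic complete response)
#' do not collapse the classifier onto the dominant class.
#'
#' @param labels Binary labels (factor or vector with exactly two observed
#'   classes), optionally named by sample id.
#' @param seed Integer seed; the same seed always selects the same subset.
#' @return The retained sample ids (names of `labels`) or integer indices
#'   when `labels` is unnamed.
#' @export
downsample_majority <- function(labels, seed) {
  seed <- check_seed(seed)
  ids <- names(labels) %||% seq_along(labels)
  keep <- !is.na(labels)
  labels <- labels[keep]
  ids <- ids[keep]
  tab <- table(as.character(labels))
  if (length(tab) != 2L) {
    stop("need exactly two observed classes, got ", length(tab),
         call. = FALSE)
  }
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  maj_ids <- ids[labels == majority]
  sampled <- withr::with_seed(seed, sample(maj_ids, tab[[minority]]))
  out <- c(ids[labels == minority], sampled)
  out[order(match(out, ids))]
}

# Assemble the modelling frame: sample_id, optional signature score, the
# requested clinical covariates and (optionally) an outcome column.
# Character covariates become factors; missing values stay NA and are
# excluded listwise by the fitting functions.
build_frame <- function(cohort, scores = NULL, predictors = character(),
                        outcome = NULL) {
  cl <- cohort$clinical
  need <- c(predictors, outcome)
  miss <- setdiff(need, names(cl))
  if (length(miss)) {
    stop("column(s) not found in clinical table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(predictors)) {
    stop("duplicated predictor names", call. = FALSE)
  }
  df <- cl[c("sample_id", need)]
  if (!is.null(scores)) {
    df$score <- scores$score[match(cl$sample_id, scores$sample_id)]
  }
  factorize(df, setdiff(names(df), "sample_id"))
}

drop_incomplete <- function(df, cols, what) {
  ok <- stats::complete.cases(df[cols])
  if (any(!ok)) {
    as_log_msg(sum(!ok), " sample(s) excluded from ", what,
               " for missing values")
  }
  df[ok, , drop = FALSE]
}

rf_xlevels <- function(df, cols) {
  lv <- lapply(df[cols], function(v) if (is.factor(v)) levels(v))
  lv[!vapply(lv, is.null, logical(1))]
}

#' Fit a classification outcome prediction model (CPM)
#'
#' Trains a random forest to predict binary treatment response (pathologic
#' complete response, pCR, versus residual disease, RD) from a signature
#' score and clinical covariates. With `balance = TRUE` (default) the RD
#' majority is randomly down-sampled to the pCR count before fitting; the
#' discarded samples are still scored at prediction time.
#'
#' @param cohort A `cohort` whose clinical table has a `response` column
#'   with values `"pCR"`/`"RD"`.
#' @param scores Signature scores from [score_signature()] (or `NULL` to fit
#'   on clinical covariates only).
#' @param predictors Character vector of clinical covariate columns (e.g.
#'   `c("age", "er_status", "stage")`).
#' @param n_trees Number of trees; large forests (default 10000) change
#'   little beyond a few thousand trees but stabilise the probabilities.
#' @param balance Down-sample the majority class before fitting.
#' @param seed Integer seed for down-sampling and forest growth.
#' @return Object of class `classification_cpm`.
#' @export
fit_classification_cpm <- function(cohort, scores = NULL, predictors,
                                   n_trees = 10000, balance = TRUE, seed) {
  seed <- check_seed(seed)
  check_flag(balance, "balance")
  df <- build_frame(cohort, scores, predictors, outcome = "response")
  xcols <- c(if (!is.null(scores)) "score", predictors)
  df <- drop_incomplete(df, c(xcols, "response"), "CPM training")
  df$response <- factor(as.character(df$response), levels = c("pCR", "RD"))
  if (anyNA(df$response)) {
    stop("response must be 'pCR' or 'RD'", call. = FALSE)
  }
  counts <- table(df$response)
  if (any(counts < 2L)) {
    stop("need at least 2 samples per response class after exclusions",
         call. = FALSE)
  }
  train <- df
  if (balance) {
    keep <- downsample_majority(stats::setNames(df$response, df$sample_id),
                                seed)
    train <- df[df$sample_id %in% keep, , drop = FALSE]
  }
  balanced <- table(train$response)
  if (balance) stopifnot(balanced[1] == balanced[2])
  model <- withr::with_seed(seed,
    randomForest::randomForest(x = train[xcols], y = train$response,
                               ntree = n_trees))
  structure(list(model = model,
                 predictors = xcols,
                 clinical_predictors = predictors,
                 uses_score = !is.null(scores),
                 classes = c("pCR", "RD"),
                 xlevels = rf_xlevels(train, xcols),
                 train_ids = train$sample_id,
                 train_log = list(n_input = nrow(df),
                                  class_counts = as.list(counts),
                                  balanced_counts = as.list(balanced),
                                  balance = balance, seed = seed,
                                  n_trees = n_trees)),
            class = "classification_cpm")
}

#' @export
print.classification_cpm <- function(x, ...) {
  cat("<classification_cpm> random forest, ", x$train_log$n_trees,
      " trees, predictors: ", paste(x$predictors, collapse = ", "),
      "\n  trained on ", paste(unlist(x$train_log$balanced_counts),
                               collapse = "/"),
      " (pCR/RD) samples\n", sep = "")
  invisible(x)
}

#' Fit a univariate Cox outcome prediction model
#'
#' Proportional-hazards regression of recurrence-free survival on the
#' signature score alone, with the Efron approximation for tied event
#' times. The P-score of a sample is its linear predictor (higher = higher
#' risk, i.e. shorter predicted survival).
#'
#' @param cohort A `cohort` whose clinical table has `time` and `event`
#'   columns.
#' @param scores Signature scores from [score_signature()].
#' @return Object of class `cox_cpm` with the fitted `survival::coxph`
#'   model and its `coefficient`.
#' @export
fit_cox_cpm <- function(cohort, scores) {
  df <- build_frame(cohort, scores, outcome = c("time", "event"))
  df <- drop_incomplete(df, c("score", "time", "event"), "Cox CPM training")
  if (sum(df$event) == 0) {
    stop("no events in the training data", call. = FALSE)
  }
  model <- survival::coxph(survival::Surv(time, event) ~ score, data = df,
                           ties = "efron")
  if (!is.finite(stats::coef(model))) {
    stop("Cox fit did not converge to a finite coefficient", call. = FALSE)
  }
  structure(list(model = model,
                 coefficient = unname(stats::coef(model)),
                 kind = "cox_univariate",
                 train_log = list(n = nrow(df), n_events = sum(df$event))),
            class = "cox_cpm")
}

#' @export
print.cox_cpm <- function(x, ...) {
  cat("<cox_cpm> univariate Cox (Efron ties), coefficient ",
      format(x$coefficient, digits = 4), ", ", x$train_log$n, " samples, ",
      x$train_log$n_events, " events\n", sep = "")
  invisible(x)
}

#' Fit a random survival forest outcome prediction model
#'
#' Nonlinear alternative to [fit_cox_cpm()]: a survival forest (default 500
#' trees) on the signature score. The P-score is the ensemble mortality
#' (the sample's cumulative hazard summed over the event-time grid); higher
#' values mean higher risk.
#'
#' @inheritParams fit_cox_cpm
#' @param n_trees Number of survival trees.
#' @param seed Integer seed for forest growth.
#' @export
fit_survival_forest_cpm <- function(cohort, scores, n_trees = 500, seed) {
  seed <- check_seed(seed)
  df <- build_frame(cohort, scores, outcome = c("time", "event"))
  df <- drop_incomplete(df, c("score", "time", "event"),
                        "survival forest training")
  if (sum(df$event) == 0) {
    stop("no events in the training data", call. = FALSE)
  }
  model <- ranger::ranger(
    formula = survival::Surv(time, event) ~ score, data = df,
    num.trees = n_trees, seed = seed, num.threads = 1)
  structure(list(model = model, kind = "survival_forest",
                 train_log = list(n = nrow(df), n_events = sum(df$event),
                                  n_trees = n_trees, seed = seed)),
            class = "survival_forest_cpm")
}

#' Prognostic P-scores from a fitted outcome model
#'
#' One P-score per cohort sample: the probability of pathologic complete
#' response for a classification CPM, the Cox linear predictor, or the
#' survival-forest ensemble mortality. Samples with a missing predictor get
#' `NA` and are reported.
#'
#' @param fit A fitted CPM (`classification_cpm`, `cox_cpm` or
#'   `survival_forest_cpm`).
#' @param cohort The cohort to score.
#' @param scores Signature scores for the cohort (required when the model
#'   uses one).
#' @param ... Method-specific arguments.
#' @return A data.frame `sample_id`, `p_score`.
#' @export
predict_pscore <- function(fit, cohort, scores = NULL, ...) {
  UseMethod("predict_pscore")
}

#' @rdname predict_pscore
#' @param out_of_bag For training samples of a classification CPM, return
#'   the forest's out-of-bag class probabilities instead of the (optimistic)
#'   refitted ones. Non-training samples are always predicted normally.
#' @export
predict_pscore.classification_cpm <- function(fit, cohort, scores = NULL,
                                              out_of_bag = FALSE, ...) {
  if (fit$uses_score && is.null(scores)) {
    stop("this CPM uses a signature score; supply `scores`", call. = FALSE)
  }
  df <- build_frame(cohort, scores, fit$clinical_predictors)
  df <- apply_xlevels(df, fit$xlevels)
  ok <- stats::complete.cases(df[fit$predictors])
  if (any(!ok)) {
    as_log_msg(sum(!ok), " sample(s) got NA P-score for missing predictors")
  }
  p <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    p[ok] <- predict(fit$model, newdata = df[ok, fit$predictors,
                                             drop = FALSE],
                     type = "prob")[, "pCR"]
  }
  if (out_of_bag) {
    votes <- fit$model$votes[, "pCR"]
    in_train <- ok & df$sample_id %in% fit$train_ids
    p[in_train] <- votes[match(df$sample_id[in_train], fit$train_ids)]
  }
  data.frame(sample_id = df$sample_id, p_score = p,
             stringsAsFactors = FALSE)
}

#' @rdname predict_pscore
#' @export
predict_pscore.cox_cpm <- function(fit, cohort, scores, ...) {
  df <- build_frame(cohort, scores)
  p <- fit$coefficient * df$score
  if (anyNA(p)) {
    as_log_msg(sum(is.na(p)), " sample(s) got NA P-score (missing score)")
  }
  data.frame(sample_id = df$sample_id, p_score = p,
             stringsAsFactors = FALSE)
}

#' @rdname predict_pscore
#' @export
predict_pscore.survival_forest_cpm <- function(fit, cohort, scores, ...) {
  df <- build_frame(cohort, scores)
  ok <- !is.na(df$score)
  if (any(!ok)) {
    as_log_msg(sum(!ok), " sample(s) got NA P-score (missing score)")
  }
  p <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    pr <- predict(fit$model, data = df[ok, , drop = FALSE],
                  num.threads = 1)
    p[ok] <- rowSums(pr$chf)
  }
  data.frame(sample_id = df$sample_id, p_score = p,
             stringsAsFactors = FALSE)
}

#' Out-of-fold P-scores via stratified cross-validation
#'
#' Every sample is predicted by a classification CPM trained on the other
#' folds (down-sampling applied inside each training fold), so the
#' resulting P-scores — and any correctness labels derived from them — are
#' free of training optimism.
#'
#' @inheritParams fit_classification_cpm
#' @param folds Number of stratified folds.
#' @return A data.frame `sample_id`, `p_score` covering every sample with
#'   complete predictors and outcome.
#' @export
out_of_fold_pscores <- function(cohort, scores = NULL, predictors,
                                folds = 10, n_trees = 10000, balance = TRUE,
                                seed) {
  seed <- check_seed(seed)
  df <- build_frame(cohort, scores, predictors, outcome = "response")
  xcols <- c(if (!is.null(scores)) "score", predictors)
  df <- drop_incomplete(df, c(xcols, "response"), "out-of-fold P-scores")
  df$response <- factor(as.character(df$response), levels = c("pCR", "RD"))
  p <- oof_probabilities(df, outcome = "response", predictors = xcols,
                         positive = "pCR", folds = folds, n_trees = n_trees,
                         balance = balance, seed = seed)
  data.frame(sample_id = df$sample_id, p_score = p,
             stringsAsFactors = FALSE)
}
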