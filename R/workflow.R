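# End-to-end workflows wiring the modules together, plus model
# serialization with JSON manifests. Both workflows follow the same shape:
# fit the outcome model, derive per-sample correctness (or concordance)
# labels from its own predictions, train the predictability model on
# clinical features, and emit P-scores, C-scores and a confidence-sorted
# accuracy curve.

#' Save a fitted model with a JSON manifest
#'
#' The model object is serialized to `path` (RDS) and a human-readable
#' manifest — class, predictors, training log, package version — is
#' written next to it as `<path>.json`.
#'
#' @param fit A fitted CPM or PPM.
#' @param path Output path for the model file.
#' @export
save_model <- function(fit, path) {
  saveRDS(fit, path)
  manifest <- list(
    class = class(fit)[1],
    predictors = fit$predictors %||% "score",
    train_log = fit$train_log,
    package = "appliscore",
    version = as.character(utils::packageVersion("appliscore")))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Default workflow configuration
#'
#' Returns the full configuration list for [run_workflow()] with the
#' framework's standard settings: 10,000-tree forests, 10x10-fold CV, a
#' P-score threshold of 0.5, an effective-comparison fraction of 0.2, and
#' smoothing windows of 20 (classification) / 200 (survival). Any element
#' can be overridden by the `...` arguments.
#'
#' @param task `"classify"` or `"survival"`.
#' @param seed Integer seed for the whole run.
#' @param out_dir Directory for the artifact files.
#' @param ... Named overrides merged over the defaults (one level deep,
#'   e.g. `simulate = list(n = 500)` replaces only the fields it names).
#' @export
default_config <- function(task = c("classify", "survival"), seed,
                           out_dir = ".", ...) {
  task <- match.arg(task)
  base <- list(
    task = task, seed = check_seed(seed), out_dir = out_dir,
    simulate = list(n = 1000, applicable_fraction = 0.5,
                    effect_beta = if (task == "classify") 2 else 1),
    input = NULL,  # list(clinical =, scores =) to use files instead
    cpm = list(n_trees = 10000,
               predictors = c("age", "er_status", "stage"),
               kind = if (task == "classify") "classify" else "cox"),
    ppm = list(n_trees = 10000,
               predictors = c("age", "er_status", "stage", "subtype")),
    label = list(provenance = "out_of_fold", threshold = 0.5,
                 fraction = 0.2),
    evaluate = list(window = if (task == "classify") 20 else 200,
                    folds = 10, repeats = 10, cv = TRUE))
  for (nm in names(list(...))) {
    ov <- list(...)[[nm]]
    if (is.list(ov) && is.list(base[[nm]])) {
      base[[nm]][names(ov)] <- ov
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

load_workflow_inputs <- function(config) {
  if (!is.null(config$input)) {
    clinical <- read_clinical(config$input$clinical)
    scores <- read_scores(config$input$scores)
    list(cohort = join_cohort(clinical, name = "input cohort"),
         scores = scores, truth = NULL)
  } else if (config$task == "classify") {
    do.call(simulate_classification_cohort,
            c(config$simulate, list(seed = config$seed)))
  } else {
    do.call(simulate_survival_cohort,
            c(config$simulate, list(seed = config$seed)))
  }
}

#' Run an end-to-end biomarker applicability workflow
#'
#' Executes the full pipeline on simulated or file-based inputs:
#' outcome-model fitting, predictability labelling from the model's own
#' predictions, PPM training, P-/C-score prediction, and the
#' confidence-sorted accuracy curve. Writes `scored.tsv`, `curve.tsv`,
#' `summary.json` and a `config.json` echo (carrying the config hash and
#' seed) into `config$out_dir`. Reruns with an identical configuration
#' reproduce identical outputs.
#'
#' @param config Configuration list from [default_config()].
#' @return Invisibly, a list with the in-memory results (`cpm`, `ppm`,
#'   `scored`, `curve`, `summary`) and the written file paths.
#' @export
run_workflow <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- check_seed(config$seed)
  sim <- load_workflow_inputs(config)
  cohort <- sim$cohort
  scores <- sim$scores

  if (config$task == "classify") {
    cpm <- fit_classification_cpm(cohort, scores,
                                  predictors = config$cpm$predictors,
                                  n_trees = config$cpm$n_trees,
                                  seed = seed)
    pscores <- predict_pscore(cpm, cohort, scores)
    label_ps <- if (config$label$provenance == "out_of_fold") {
      out_of_fold_pscores(cohort, scores, config$cpm$predictors,
                          folds = config$evaluate$folds,
                          n_trees = config$cpm$n_trees, seed = seed + 1L)
    } else {
      predict_pscore(cpm, cohort, scores, out_of_bag = TRUE)
    }
    labels <- label_classification_predictability(
      label_ps, cohort$clinical, threshold = config$label$threshold,
      provenance = config$label$provenance)
    metric_df <- data.frame(sample_id = labels$sample_id,
                            metric = as.numeric(labels$label == "positive"))
    extra <- data.frame(sample_id = cohort$clinical$sample_id,
                        stringsAsFactors = FALSE)
  } else {
    cpm <- if (identical(config$cpm$kind, "rsf")) {
      fit_survival_forest_cpm(cohort, scores,
                              n_trees = config$cpm$n_trees %||% 500,
                              seed = seed)
    } else {
      fit_cox_cpm(cohort, scores)
    }
    pscores <- predict_pscore(cpm, cohort, scores)
    cc <- stats::complete.cases(cohort$clinical[c("time", "event")]) &
      !is.na(pscores$p_score)
    decomp <- concordance_decomposition(
      cohort$clinical$time[cc], cohort$clinical$event[cc],
      pscores$p_score[cc], sample_ids = cohort$clinical$sample_id[cc])
    labels <- label_survival_predictability(
      decomp, fraction = config$label$fraction)
    metric_df <- data.frame(sample_id = decomp$per_sample$sample_id,
                            metric = decomp$per_sample$c_sample)
    extra <- decomp$per_sample
    names(extra)[names(extra) == "c_sample"] <- "c_sample"
  }

  ppm <- train_ppm(cohort, labels, predictors = config$ppm$predictors,
                   n_trees = config$ppm$n_trees, seed = seed + 2L)
  cscores <- predict_cscore(ppm, cohort)

  curve <- sorted_accuracy_curve(cscores, metric_df,
                                 window = config$evaluate$window)

  scored <- data.frame(sample_id = cohort$clinical$sample_id,
                       stringsAsFactors = FALSE)
  scored$p_score <- pscores$p_score[match(scored$sample_id,
                                          pscores$sample_id)]
  scored$c_score <- cscores$c_score[match(scored$sample_id,
                                          cscores$sample_id)]
  scored$label <- as.character(labels$label)[match(scored$sample_id,
                                                   labels$sample_id)]
  if (config$task == "survival") {
    scored$n_effective <- extra$n_effective[match(scored$sample_id,
                                                  extra$sample_id)]
    scored$c_sample <- extra$c_sample[match(scored$sample_id,
                                            extra$sample_id)]
  }

  summary <- list(task = config$task, seed = seed,
                  n_samples = cohort_size(cohort),
                  # hash of the analysis configuration (output location
                  # excluded, so reruns elsewhere are comparable)
                  config_hash = config_hash(
                    config[setdiff(names(config), "out_dir")]),
                  ppm_groups = ppm$train_log$group_counts,
                  ppm_balanced = ppm$train_log$balanced_counts)
  if (config$task == "survival") {
    summary$overall_concordance <- decomp$overall
    summary$n_effective_pairs <- decomp$n_effective_pairs
    if (inherits(cpm, "cox_cpm")) summary$cox_coefficient <- cpm$coefficient
  }
  if (isTRUE(config$evaluate$cv) && config$task == "classify") {
    frame <- build_frame(cohort, scores, config$cpm$predictors,
                         outcome = "response")
    cpm_cv <- cross_validated_auc(
      frame, "response", c("score", config$cpm$predictors),
      positive = "pCR", folds = config$evaluate$folds,
      repeats = config$evaluate$repeats, n_trees = config$cpm$n_trees,
      seed = seed + 3L)
    summary$cpm_cv_auc <- cpm_cv$mean_auc
  }
  if (isTRUE(config$evaluate$cv)) {
    pframe <- build_frame(cohort, predictors = config$ppm$predictors)
    pframe$label <- labels$label[match(pframe$sample_id, labels$sample_id)]
    pframe <- pframe[!is.na(pframe$label), , drop = FALSE]
    ppm_cv <- cross_validated_auc(
      pframe, "label", config$ppm$predictors, positive = "positive",
      folds = config$evaluate$folds, repeats = config$evaluate$repeats,
      n_trees = config$ppm$n_trees, seed = seed + 4L)
    summary$ppm_cv_auc <- ppm_cv$mean_auc
  }

  paths <- list(
    scored = write_tsv(scored, file.path(config$out_dir, "scored.tsv")),
    curve = write_tsv(as.data.frame(curve),
                      file.path(config$out_dir, "curve.tsv")),
    summary = file.path(config$out_dir, "summary.json"),
    config = file.path(config$out_dir, "config.json"))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  jsonlite::write_json(c(config, list(hash = summary$config_hash)),
                       paths$config, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(cpm = cpm, ppm = ppm, scored = scored, curve = curve,
                 summary = summary, paths = paths))
}
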