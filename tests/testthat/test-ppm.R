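test_that("classification correctness labels apply the strict 0.5 rule", {
  ps <- data.frame(sample_id = c("a", "b", "c", "d"),
                   p_score = c(0.7, 0.5, 0.9, 0.2))
  truth <- c("pCR", "RD", "RD", "RD")
  lab <- label_classification_predictability(ps, truth)
  expect_equal(as.character(lab$label),
               c("positive",   # P > 0.5 and pCR: correct
                 "positive",   # exactly 0.5 is an RD call, truth RD
                 "negative",   # P > 0.5 but truth RD
                 "positive"))
  expect_equal(attr(lab, "source"), "classification")

  # missing truth drops the sample with a message
  expect_message(
    lab2 <- label_classification_predictability(
      ps, c("pCR", NA, "RD", "RD")),
    "excluded")
  expect_equal(nrow(lab2), 3)
  expect_error(label_classification_predictability(ps, rep("yes", 4)),
               "pCR")
})

test_that("survival labels split at the overall concordance after filtering", {
  fake <- structure(
    list(overall = 0.679,
         per_sample = data.frame(
           sample_id = c("a", "b", "c", "d"),
           n_effective = c(250, 250, 250, 10),
           c_sample = c(0.80, 0.50, 0.679, 0.99))),
    class = "concordance_decomposition")
  lab <- quietly(label_survival_predictability(fake, cohort_size = 997))
  expect_equal(nrow(lab), 3)  # d fails the >= 199 filter despite c = 0.99
  expect_equal(as.character(lab$label[lab$sample_id == "a"]), "positive")
  expect_equal(as.character(lab$label[lab$sample_id == "b"]), "negative")
  # exact equality with the overall concordance is not "well predicted"
  expect_equal(as.character(lab$label[lab$sample_id == "c"]), "negative")

  none <- fake
  none$per_sample$n_effective <- rep(1, 4)
  expect_error(label_survival_predictability(none, cohort_size = 997),
               "below the effective-comparison threshold")
})

test_that("PPM balancing reproduces equal group sizes (64 vs 241 -> 64/64)", {
  n <- 305
  withr::with_seed(90, {
    clin <- data.frame(
      sample_id = sprintf("p%03d", 1:n),
      age = rnorm(n, 55, 10),
      er_status = sample(c("positive", "negative"), n, replace = TRUE),
      stage = sample(c("I", "II", "III"), n, replace = TRUE),
      subtype = sample(SUBTYPE_ORDER, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  labels <- structure(data.frame(
    sample_id = clin$sample_id,
    label = factor(rep(c("negative", "positive"), c(64, 241)),
                   levels = c("negative", "positive"))),
    source = "classification")
  fit <- quietly(train_ppm(quietly(join_cohort(clin)), labels,
                           c("age", "er_status", "stage", "subtype"),
                           n_trees = 50, seed = 91))
  expect_equal(fit$train_log$group_counts,
               list(negative = 64L, positive = 241L))
  expect_equal(fit$train_log$balanced_counts,
               list(negative = 64L, positive = 64L))
})

test_that("the PPM recovers planted applicability from clinical features", {
  sim <- simulate_classification_cohort(n = 1000, applicable_fraction = 0.5,
                                        effect_beta = 2, seed = 201)
  lab <- plant_applicability_labels(sim$truth, p_in = 1, p_out = 0.5,
                                    seed = 202)
  pframe <- quietly(build_model_frame(
    sim$cohort, predictors = c("age", "er_status", "stage", "subtype")))
  pframe$label <- lab$label[match(pframe$sample_id, lab$sample_id)]
  cv <- quietly(cross_validated_auc(
    pframe, "label", c("age", "er_status", "stage", "subtype"),
    positive = "positive", repeats = 2, n_trees = 500, seed = 203))
  expect_gte(cv$mean_auc, 0.8)

  # C-scores separate the strata in the right direction
  ppm <- quietly(train_ppm(sim$cohort, lab,
                           c("age", "er_status", "stage", "subtype"),
                           n_trees = 500, seed = 204))
  cs <- quietly(predict_cscore(ppm, sim$cohort))
  ap <- sim$truth$applicable[match(cs$sample_id, sim$truth$sample_id)]
  expect_gt(mean(cs$c_score[ap]), mean(cs$c_score[!ap]))
  expect_true(all(cs$c_score >= 0 & cs$c_score <= 1))
})

test_that("random labels give chance-level PPM cross-validation", {
  sim <- simulate_classification_cohort(n = 400, seed = 211)
  withr::with_seed(212, {
    lab <- structure(data.frame(
      sample_id = sim$truth$sample_id,
      label = factor(sample(c("negative", "positive"), 400, replace = TRUE),
                     levels = c("negative", "positive"))),
      source = "classification")
  })
  pframe <- quietly(build_model_frame(
    sim$cohort, predictors = c("age", "er_status", "stage", "subtype")))
  pframe$label <- lab$label[match(pframe$sample_id, lab$sample_id)]
  cv <- quietly(cross_validated_auc(
    pframe, "label", c("age", "er_status", "stage", "subtype"),
    positive = "positive", repeats = 2, n_trees = 200, seed = 213))
  expect_gte(cv$mean_auc, 0.42)
  expect_lte(cv$mean_auc, 0.58)
})

test_that("labeling is deterministic and C-scores are per-row", {
  sim <- simulate_classification_cohort(n = 150, seed = 221)
  oof <- quietly(out_of_fold_pscores(sim$cohort, sim$scores,
                                     c("age", "er_status"),
                                     n_trees = 100, seed = 222))
  l1 <- quietly(label_classification_predictability(oof,
                                                    sim$cohort$clinical))
  l2 <- quietly(label_classification_predictability(oof,
                                                    sim$cohort$clinical))
  expect_identical(l1, l2)

  ppm <- quietly(train_ppm(sim$cohort, l1, c("age", "er_status"),
                           n_trees = 100, seed = 223))
  dup <- sim$cohort$clinical[c(2, 2), ]
  dup$sample_id <- c("d1", "d2")
  cs <- quietly(predict_cscore(ppm, quietly(join_cohort(dup))))
  expect_equal(cs$c_score[1], cs$c_score[2])

  missing <- sim$cohort$clinical[1:4, ]
  missing$age[1] <- NA
  expect_message(
    csm <- predict_cscore(ppm, quietly(join_cohort(missing))),
    "NA C-score")
  expect_true(is.na(csm$c_score[1]))
})

test_that("training fails cleanly when a label class is empty", {
  sim <- simulate_classification_cohort(n = 100, seed = 231)
  lab <- structure(data.frame(
    sample_id = sim$truth$sample_id,
    label = factor(rep("positive", 100),
                   levels = c("negative", "positive"))),
    source = "classification")
  expect_error(
    quietly(train_ppm(sim$cohort, lab, c("age", "er_status"),
                      n_trees = 50, seed = 232)),
    "both predictability groups")
})
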