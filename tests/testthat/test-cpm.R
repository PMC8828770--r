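test_that("down-sampling balances classes and keeps every minority sample", {
  labs <- setNames(factor(rep(c("RD", "pCR"), c(10, 4))),
                   sprintf("s%02d", 1:14))
  keep <- downsample_majority(labs, seed = 4)
  expect_length(keep, 8)
  expect_true(all(names(labs)[labs == "pCR"] %in% keep))
  expect_equal(sum(labs[keep] == "RD"), 4)

  balanced <- setNames(factor(rep(c("a", "b"), 5)), letters[1:10])
  expect_setequal(downsample_majority(balanced, seed = 1), letters[1:10])

  expect_identical(downsample_majority(labs, seed = 4), keep)
  seeds <- vapply(1:20, function(s)
    paste(sort(downsample_majority(labs, seed = s)), collapse = ","), "")
  expect_gt(length(unique(seeds)), 1)

  expect_error(downsample_majority(factor(rep("RD", 5)), seed = 1),
               "two observed classes")
})

test_that("a separable cohort is fit perfectly and logged as balanced", {
  sep <- separable_cohort(n = 60, seed = 2)
  fit <- quietly(fit_classification_cpm(sep$cohort, sep$scores,
                                        c("age", "er_status", "stage"),
                                        n_trees = 200, seed = 3))
  expect_equal(fit$train_log$balanced_counts$pCR,
               fit$train_log$balanced_counts$RD)
  ps <- quietly(predict_pscore(fit, sep$cohort, sep$scores))
  predicted <- ifelse(ps$p_score > 0.5, "pCR", "RD")
  expect_equal(predicted, sep$cohort$clinical$response)
  expect_true(all(ps$p_score >= 0 & ps$p_score <= 1))
})

test_that("P-score prediction is per-row and deterministic", {
  sep <- separable_cohort(n = 40, seed = 6)
  fit <- quietly(fit_classification_cpm(sep$cohort, sep$scores,
                                        c("age", "er_status"),
                                        n_trees = 100, seed = 7))
  one <- quietly(join_cohort(sep$cohort$clinical[5, , drop = FALSE]))
  p1 <- quietly(predict_pscore(fit, one, sep$scores[5, , drop = FALSE]))
  expect_length(p1$p_score, 1)

  dup_clin <- sep$cohort$clinical[c(5, 5, 9), ]
  dup_clin$sample_id <- c("d1", "d2", "x")
  dup_scores <- sep$scores[c(5, 5, 9), ]
  dup_scores$sample_id <- c("d1", "d2", "x")
  dp <- quietly(predict_pscore(fit, quietly(join_cohort(dup_clin)),
                               dup_scores))
  expect_equal(dp$p_score[1], dp$p_score[2])

  # P-scores do not depend on sample order
  perm <- c(3, 1, 2)
  dp2 <- quietly(predict_pscore(fit,
                                quietly(join_cohort(dup_clin[perm, ])),
                                dup_scores[perm, ]))
  expect_equal(dp2$p_score[match(dp$sample_id, dp2$sample_id)],
               dp$p_score)

  expect_error(
    quietly(predict_pscore(fit, quietly(join_cohort(
      data.frame(sample_id = "q", age = 5))), dup_scores)),
    "er_status")
})

test_that("samples with missing predictors are excluded or scored NA", {
  sep <- separable_cohort(n = 40, seed = 10)
  clin <- sep$cohort$clinical
  clin$er_status[1:3] <- NA
  co <- quietly(join_cohort(clin))
  expect_message(
    fit <- fit_classification_cpm(co, sep$scores,
                                  c("age", "er_status"),
                                  n_trees = 100, seed = 1),
    "excluded")
  expect_message(ps <- predict_pscore(fit, co, sep$scores), "NA P-score")
  expect_true(all(is.na(ps$p_score[1:3])))
})

test_that("permuted outcomes give chance-level cross-validated AUC", {
  sim <- simulate_classification_cohort(n = 400, effect_beta = 2,
                                        applicable_fraction = 1, seed = 31)
  clin <- sim$cohort$clinical
  clin$response <- withr::with_seed(32, sample(clin$response))
  frame <- quietly(build_model_frame(quietly(join_cohort(clin)),
                                     sim$scores,
                                     c("age", "er_status", "stage"),
                                     outcome = "response"))
  cv <- quietly(cross_validated_auc(
    frame, "response", c("score", "age", "er_status", "stage"),
    positive = "pCR", repeats = 2, n_trees = 200, seed = 33))
  expect_gte(cv$mean_auc, 0.4)
  expect_lte(cv$mean_auc, 0.6)
})

test_that("a planted score effect is detected by cross-validated AUC", {
  sim <- simulate_classification_cohort(n = 600, effect_beta = 2,
                                        applicable_fraction = 1, seed = 41)
  frame <- quietly(build_model_frame(sim$cohort, sim$scores,
                                     c("age", "er_status", "stage"),
                                     outcome = "response"))
  cv <- quietly(cross_validated_auc(
    frame, "response", c("score", "age", "er_status", "stage"),
    positive = "pCR", repeats = 2, n_trees = 200, seed = 42))
  expect_gte(cv$mean_auc, 0.75)
})

test_that("the Cox CPM recovers a planted log-hazard ratio", {
  sim <- simulate_survival_cohort(n = 2000, applicable_fraction = 1,
                                  effect_beta = 1, seed = 51)
  fit <- quietly(fit_cox_cpm(sim$cohort, sim$scores))
  expect_gt(fit$coefficient, 0.85)
  expect_lt(fit$coefficient, 1.15)

  # under the null the coefficient is near zero
  null <- simulate_survival_cohort(n = 2000, applicable_fraction = 1,
                                   effect_beta = 0, seed = 52)
  fit0 <- quietly(fit_cox_cpm(null$cohort, null$scores))
  expect_lt(abs(fit0$coefficient), 0.1)
})

test_that("Cox P-score ranking is invariant to affine score rescaling", {
  sim <- simulate_survival_cohort(n = 300, applicable_fraction = 1,
                                  seed = 61)
  fit <- quietly(fit_cox_cpm(sim$cohort, sim$scores))
  doubled <- sim$scores
  doubled$score <- 2 * doubled$score
  fit2 <- quietly(fit_cox_cpm(sim$cohort, doubled))
  expect_equal(fit2$coefficient, fit$coefficient / 2, tolerance = 1e-6)
  r1 <- quietly(predict_pscore(fit, sim$cohort, sim$scores))
  r2 <- quietly(predict_pscore(fit2, sim$cohort, doubled))
  expect_equal(order(r1$p_score), order(r2$p_score))

  censored_only <- sim$cohort$clinical
  censored_only$event <- 0L
  expect_error(
    quietly(fit_cox_cpm(quietly(join_cohort(censored_only)), sim$scores)),
    "no events")
})

test_that("the survival forest ranks risk better than chance on planted data", {
  sim <- simulate_survival_cohort(n = 400, applicable_fraction = 1,
                                  effect_beta = 1, seed = 71)
  half <- seq_len(200)
  train_co <- quietly(join_cohort(sim$cohort$clinical[half, ]))
  test_cl <- sim$cohort$clinical[-half, ]
  test_co <- quietly(join_cohort(test_cl))
  fit <- quietly(fit_survival_forest_cpm(train_co, sim$scores[half, ],
                                         n_trees = 500, seed = 72))
  risks <- quietly(predict_pscore(fit, test_co, sim$scores[-half, ]))
  c500 <- concordance_decomposition(test_cl$time, test_cl$event,
                                    risks$p_score)$overall
  expect_gt(c500, 0.55)

  # a single tree does no better than the full forest out of sample
  fit1 <- quietly(fit_survival_forest_cpm(train_co, sim$scores[half, ],
                                          n_trees = 1, seed = 72))
  risks1 <- quietly(predict_pscore(fit1, test_co, sim$scores[-half, ]))
  c1 <- concordance_decomposition(test_cl$time, test_cl$event,
                                  risks1$p_score)$overall
  expect_gte(c500, c1)

  # permuted follow-up destroys the association
  perm <- test_cl
  withr::with_seed(73, {
    idx <- sample(nrow(perm))
    perm$time <- perm$time[idx]
    perm$event <- perm$event[idx]
  })
  cp <- concordance_decomposition(perm$time, perm$event,
                                  risks$p_score)$overall
  expect_gte(cp, 0.45)
  expect_lte(cp, 0.55)
})

test_that("out-of-fold P-scores cover all complete samples", {
  sim <- simulate_classification_cohort(n = 200, seed = 81)
  oof <- quietly(out_of_fold_pscores(sim$cohort, sim$scores,
                                     c("age", "er_status"),
                                     n_trees = 100, seed = 82))
  expect_equal(nrow(oof), 200)
  expect_true(all(oof$p_score >= 0 & oof$p_score <= 1))
  oof2 <- quietly(out_of_fold_pscores(sim$cohort, sim$scores,
                                      c("age", "er_status"),
                                      n_trees = 100, seed = 82))
  expect_identical(oof, oof2)
})
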