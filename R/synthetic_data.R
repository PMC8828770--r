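# Seeded synthetic cohorts with the statistical structure the framework
# assumes: a biomarker whose association with outcome holds only inside a
# covariate-defined stratum (here keyed to ER status, mirroring the common
# situation of assays validated in ER+ disease), imbalanced binary
# response, and right-censored survival.

sim_covariates <- function(n) {
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = stats::rnorm(n, 55, 10),
    stage = factor(sample(c("I", "II", "III"), n, replace = TRUE,
                          prob = c(0.3, 0.5, 0.2)),
                   levels = c("I", "II", "III")),
    subtype = factor(sample(SUBTYPE_ORDER, n, replace = TRUE),
                     levels = SUBTYPE_ORDER),
    stringsAsFactors = FALSE
  )
}

check_config <- function(n, applicable_fraction, noise) {
  stopifnot(n >= 1, n == round(n))
  if (applicable_fraction <= 0 || applicable_fraction > 1) {
    stop("applicable_fraction must be in (0, 1]", call. = FALSE)
  }
}

#' Simulate a binary-response cohort with partial biomarker applicability
#'
#' Draws age ~ Normal(55, 10), a three-level stage, a five-level molecular
#' subtype, a standard-normal biomarker score, and an ER stratum
#' (`er_status = "positive"` with probability `applicable_fraction`) inside
#' which — and only inside which — the score shifts the response log-odds
#' by `effect_beta` per unit. The intercept is calibrated so the marginal
#' pCR prevalence is close to `prevalence` (responders are the minority, as
#' in neoadjuvant chemotherapy cohorts).
#'
#' @param n Cohort size.
#' @param applicable_fraction Probability of the applicable (ER+) stratum.
#' @param effect_beta Log-odds of pCR per unit score inside the stratum.
#' @param prevalence Target marginal pCR fraction (default 0.25).
#' @param seed Integer seed; output is fully reproducible.
#' @return A list with elements `cohort` (a `cohort` whose clinical table
#'   has `age`, `er_status`, `stage`, `subtype`, `response`), `scores` (a
#'   P-score-ready signature-score data.frame) and `truth` (data.frame
#'   `sample_id`, `applicable`).
#' @export
simulate_classification_cohort <- function(n = 1000,
                                           applicable_fraction = 0.5,
                                           effect_beta = 2,
                                           prevalence = 0.25, seed) {
  seed <- check_seed(seed)
  check_config(n, applicable_fraction)
  stopifnot(prevalence > 0, prevalence < 1)
  withr::with_seed(seed, {
    cl <- sim_covariates(n)
    applicable <- stats::rbinom(n, 1, applicable_fraction) == 1
    cl$er_status <- factor(ifelse(applicable, "positive", "negative"),
                           levels = c("negative", "positive"))
    score <- stats::rnorm(n)
    latent <- ifelse(applicable, effect_beta * score, 0)
    intercept <- stats::uniroot(
      function(a) mean(stats::plogis(a + latent)) - prevalence,
      c(-30, 30))$root
    pcr <- stats::rbinom(n, 1, stats::plogis(intercept + latent)) == 1
    cl$response <- factor(ifelse(pcr, "pCR", "RD"), levels = c("pCR", "RD"))
  })
  list(
    cohort = join_cohort(cl, name = "simulated classification cohort"),
    scores = structure(data.frame(sample_id = cl$sample_id, score = score,
                                  stringsAsFactors = FALSE),
                       signature_name = "simulated"),
    truth = data.frame(sample_id = cl$sample_id, applicable = applicable,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a right-censored survival cohort with partial applicability
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(effect_beta * score)` inside the applicable (ER+)
#' stratum and `baseline_hazard` outside; censoring times are exponential
#' with rate `censoring_rate`, the observed time is the minimum and the
#' event indicator marks which came first. The realized censoring fraction
#' is reported.
#'
#' @inheritParams simulate_classification_cohort
#' @param effect_beta Log-hazard ratio per unit score inside the stratum.
#' @param baseline_hazard Exponential event rate at score 0 (per time
#'   unit).
#' @param censoring_rate Exponential censoring rate; the defaults give
#'   roughly 30% censoring.
#' @return As [simulate_classification_cohort()], with clinical columns
#'   `time` and `event` instead of `response`.
#' @export
simulate_survival_cohort <- function(n = 1000, applicable_fraction = 0.5,
                                     effect_beta = 1,
                                     baseline_hazard = 0.1,
                                     censoring_rate = 0.05, seed) {
  seed <- check_seed(seed)
  check_config(n, applicable_fraction)
  stopifnot(baseline_hazard > 0, censoring_rate >= 0)
  withr::with_seed(seed, {
    cl <- sim_covariates(n)
    applicable <- stats::rbinom(n, 1, applicable_fraction) == 1
    cl$er_status <- factor(ifelse(applicable, "positive", "negative"),
                           levels = c("negative", "positive"))
    score <- stats::rnorm(n)
    hazard <- ifelse(applicable, baseline_hazard * exp(effect_beta * score),
                     baseline_hazard)
    t_event <- stats::rexp(n, hazard)
    t_cens <- if (censoring_rate > 0) stats::rexp(n, censoring_rate)
              else rep(Inf, n)
    cl$time <- pmin(t_event, t_cens)
    cl$event <- as.integer(t_event <= t_cens)
  })
  as_log_msg("simulated survival cohort: ",
             format(100 * mean(cl$event == 0), digits = 3), "% censored")
  list(
    cohort = join_cohort(cl, name = "simulated survival cohort"),
    scores = structure(data.frame(sample_id = cl$sample_id, score = score,
                                  stringsAsFactors = FALSE),
                       signature_name = "simulated"),
    truth = data.frame(sample_id = cl$sample_id, applicable = applicable,
                       stringsAsFactors = FALSE)
  )
}

#' Generate synthetic centroid profiles
#'
#' A stand-in for published 50-gene subtype centroids: independent
#' standard-normal profiles per subtype, row-median-centred across
#' subtypes (as published centroids are centred on their reference
#' population).
#'
#' @param n_genes Number of genes (default 50).
#' @param subtypes Subtype names.
#' @param seed Integer seed.
#' @return Numeric matrix, genes in rows, subtypes in columns.
#' @export
make_centroids <- function(n_genes = 50, subtypes = SUBTYPE_ORDER, seed) {
  seed <- check_seed(seed)
  m <- withr::with_seed(seed,
    matrix(stats::rnorm(n_genes * length(subtypes)), n_genes,
           dimnames = list(sprintf("G%03d", seq_len(n_genes)), subtypes)))
  m - apply(m, 1, stats::median)
}

#' Simulate expression samples around centroid profiles
#'
#' Each sample is one centroid column plus a shared per-gene baseline
#' intensity (Normal(8, 1), the typical log2 microarray scale) plus iid
#' Normal(0, `noise_sd`) noise — a fixture with known subtype truth for
#' exercising [assign_pam50()].
#'
#' @param centroids Centroid matrix (genes x subtypes).
#' @param per_subtype Samples generated per subtype.
#' @param noise_sd Standard deviation of the added noise.
#' @param seed Integer seed.
#' @return A list with `expression` (genes x samples matrix) and `truth`
#'   (data.frame `sample_id`, `subtype`).
#' @export
make_subtype_samples <- function(centroids, per_subtype = 100,
                                 noise_sd = 0.5, seed) {
  seed <- check_seed(seed)
  stopifnot(per_subtype >= 1, noise_sd >= 0)
  k <- ncol(centroids)
  g <- nrow(centroids)
  n <- per_subtype * k
  withr::with_seed(seed, {
    baseline <- stats::rnorm(g, 8, 1)
    truth_subtype <- rep(colnames(centroids), each = per_subtype)
    expr <- centroids[, truth_subtype, drop = FALSE] + baseline +
      matrix(stats::rnorm(g * n, 0, noise_sd), g, n)
  })
  colnames(expr) <- sprintf("S%04d", seq_len(n))
  list(expression = expr,
       truth = data.frame(sample_id = colnames(expr),
                          subtype = truth_subtype,
                          stringsAsFactors = FALSE))
}
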