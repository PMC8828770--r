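# Shared fixtures and independent oracles.

quietly <- function(expr) suppressMessages(expr)

# Independent brute-force concordance oracle: a plain double loop over all
# pairs applying the effective-comparison scenarios and tie rules directly.
# Deliberately naive (O(n^2) with scalar ifs) so it shares no code path
# with the vectorized implementation it checks.
brute_force_concordance <- function(time, event, risk) {
  n <- length(time)
  n_eff <- integer(n)
  score <- numeric(n)
  total_eff <- 0
  total_score <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      eff <- (event[i] == 1 && event[j] == 1) ||
        (event[i] == 0 && event[j] == 1 && time[i] > time[j]) ||
        (event[i] == 1 && event[j] == 0 && time[i] < time[j])
      if (!eff) next
      if (risk[i] == risk[j] ||
          (time[i] == time[j] && event[i] == 1 && event[j] == 1)) {
        s <- 0.5
      } else if (time[i] > time[j]) {
        s <- if (risk[i] < risk[j]) 1 else 0
      } else {
        s <- if (risk[j] < risk[i]) 1 else 0
      }
      n_eff[i] <- n_eff[i] + 1L
      n_eff[j] <- n_eff[j] + 1L
      score[i] <- score[i] + s
      score[j] <- score[j] + s
      total_eff <- total_eff + 1
      total_score <- total_score + s
    }
  }
  list(overall = total_score / total_eff,
       n_effective = n_eff,
       c_sample = ifelse(n_eff > 0, score / n_eff, NA_real_))
}

# Planted-applicability correctness labels: the outcome model is correct
# with probability `p_in` inside the applicable stratum and `p_out`
# outside. With p_in = 1 this is the idealized scenario where the
# biomarker works perfectly in its stratum and is a coin flip elsewhere.
plant_applicability_labels <- function(truth, p_in = 1, p_out = 0.5,
                                       seed) {
  withr::with_seed(seed, {
    p <- ifelse(truth$applicable, p_in, p_out)
    correct <- stats::runif(nrow(truth)) < p
  })
  structure(data.frame(
    sample_id = truth$sample_id,
    label = factor(ifelse(correct, "positive", "negative"),
                   levels = c("negative", "positive")),
    stringsAsFactors = FALSE), source = "classification")
}

# A tiny cohort where the signature score separates responders perfectly.
separable_cohort <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    score <- c(stats::runif(n / 2, 1, 2), stats::runif(n / 2, -2, -1))
    cl <- data.frame(
      sample_id = sprintf("P%03d", seq_len(n)),
      age = stats::rnorm(n, 55, 10),
      er_status = sample(c("positive", "negative"), n, replace = TRUE),
      stage = sample(c("I", "II", "III"), n, replace = TRUE),
      response = rep(c("pCR", "RD"), each = n / 2),
      stringsAsFactors = FALSE)
  })
  list(cohort = quietly(join_cohort(cl, name = "separable")),
       scores = data.frame(sample_id = cl$sample_id, score = score,
                           stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
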