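#' Effective pairwise comparisons under right censoring
#'
#' A pair of survival observations (t1, e1), (t2, e2) can be ordered with
#' certainty — is "effective" — exactly when both have the event, or the
#' censored member was followed beyond the other member's event time:
#' e1 = e2 = 1; or t1 > t2 with e1 = 0, e2 = 1; or t1 < t2 with e1 = 1,
#' e2 = 0. All arguments are vectorized.
#'
#' @param t1,e1 Time and event indicator (1 event, 0 censored) of the first
#'   member.
#' @param t2,e2 Time and event indicator of the second member.
#' @return Logical vector.
#' @export
is_effective_pair <- function(t1, e1, t2, e2) {
  (e1 == 1 & e2 == 1) |
    (e1 == 0 & e2 == 1 & t1 > t2) |
    (e1 == 1 & e2 == 0 & t1 < t2)
}

#' Classify one effective pair as concordant, discordant or tied
#'
#' The pair is concordant when the longer-surviving member carries the lower
#' predicted risk, discordant when it carries the higher risk, and tied when
#' the two risks are equal or both members have the event at the same time.
#'
#' @param t1,e1,t2,e2 Survival observations of the two members (must form an
#'   effective pair).
#' @param risk1,risk2 Predicted risks (higher = shorter predicted survival).
#' @return One of `"concordant"`, `"discordant"`, `"tied"`.
#' @export
pair_concordant <- function(t1, e1, t2, e2, risk1, risk2) {
  if (!is_effective_pair(t1, e1, t2, e2)) {
    stop("pair is not effective; cannot be ordered under censoring",
         call. = FALSE)
  }
  if (risk1 == risk2 || (t1 == t2 && e1 == 1 && e2 == 1)) return("tied")
  longer_is_1 <- t1 > t2
  if (longer_is_1 == (risk1 < risk2)) "concordant" else "discordant"
}

#' Decompose the concordance index into sample-specific contributions
#'
#' Computes Harrell-type overall concordance over all effective pairs —
#' (concordant + 0.5 tied) / effective — and, for every sample, the number
#' of effective comparisons it enters and its sample-specific concordance:
#' the fraction of those comparisons the risk score orders correctly (ties
#' again counting one half). The n_effective-weighted mean of the
#' sample-specific concordances reproduces the overall concordance exactly,
#' because every pair contributes its outcome to both members.
#'
#' @param time,event Survival times and event indicators (1 event, 0
#'   censored).
#' @param risk Predicted risks, higher = higher risk of an early event.
#' @param sample_ids Optional identifiers carried into the per-sample table.
#' @return An object of class `concordance_decomposition`: list with
#'   `overall`, `n_effective_pairs`, `n_total_pairs` and a `per_sample`
#'   data.frame (`sample_id`, `n_effective`, `c_sample`; `c_sample` is `NA`
#'   for samples with no effective comparison).
#' @export
concordance_decomposition <- function(time, event, risk,
                                      sample_ids = NULL) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  if (anyNA(time) || anyNA(event) || anyNA(risk)) {
    stop("time, event and risk must be complete", call. = FALSE)
  }
  if (!all(is.finite(time)) || any(time < 0)) {
    stop("times must be finite and nonnegative", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event must be 0 or 1", call. = FALSE)
  }
  sample_ids <- sample_ids %||% as.character(seq_len(n))

  T1 <- matrix(time, n, n)
  E1 <- matrix(event, n, n)
  R1 <- matrix(risk, n, n)
  T2 <- t(T1); E2 <- t(E1); R2 <- t(R1)
  eff <- is_effective_pair(T1, E1, T2, E2)
  diag(eff) <- FALSE

  # Pair score as seen from the row sample: 1 concordant, 0.5 tied, 0
  # discordant. The matrix is symmetric, so row sums give each sample's
  # concordant-equivalent count over its own effective comparisons. For an
  # effective pair with a strict time ordering the longer survivor is the
  # one with the larger time (censored-vs-event pairs are effective only in
  # that orientation).
  tied <- (R1 == R2) | (T1 == T2 & E1 == 1 & E2 == 1)
  conc <- ifelse(tied, 0.5, as.numeric((T1 > T2) == (R1 < R2)))
  conc[!eff] <- 0

  n_eff_i <- rowSums(eff)
  score_i <- rowSums(conc)
  n_eff_pairs <- sum(eff) / 2
  if (n_eff_pairs == 0) {
    stop("no effective pairs in the data", call. = FALSE)
  }
  overall <- sum(conc) / 2 / n_eff_pairs

  per_sample <- data.frame(
    sample_id = sample_ids,
    n_effective = n_eff_i,
    c_sample = ifelse(n_eff_i > 0, score_i / n_eff_i, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(overall = overall,
                 n_effective_pairs = n_eff_pairs,
                 n_total_pairs = n * (n - 1) / 2,
                 per_sample = per_sample),
            class = "concordance_decomposition")
}

#' @export
print.concordance_decomposition <- function(x, ...) {
  cat("<concordance_decomposition> overall ", format(x$overall, digits = 4),
      " over ", x$n_effective_pairs, "/", x$n_total_pairs,
      " effective pairs, ", nrow(x$per_sample), " samples\n", sep = "")
  invisible(x)
}

#' Retain samples with enough effective comparisons
#'
#' A sample is kept when it enters at least `floor(fraction * cohort_size)`
#' effective pairwise comparisons, so that its sample-specific concordance
#' rests on enough pairs to be meaningful (e.g. a 997-patient cohort at the
#' default 20% requires at least 199 effective comparisons).
#'
#' @param decomp A `concordance_decomposition`.
#' @param cohort_size Number of samples the fraction refers to; defaults to
#'   the number of samples in `decomp`.
#' @param fraction Required fraction of comparisons, in (0, 1].
#' @return Logical mask over the samples of `decomp`.
#' @export
effective_fraction_filter <- function(decomp, cohort_size = NULL,
                                      fraction = 0.2) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  cohort_size <- cohort_size %||% nrow(decomp$per_sample)
  threshold <- floor(fraction * cohort_size)
  decomp$per_sample$n_effective >= threshold
}
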