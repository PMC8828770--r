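#' Score a gene signature on every sample of a cohort
#'
#' Computes a weighted mean of (optionally z-scored) expression over the
#' signature genes present in the cohort:
#' \deqn{score(s) = \sum_g w_g \tilde x_g(s) / \sum_g |w_g|}
#' where \eqn{\tilde x} is the per-gene z-score across the cohort when
#' `standardize = "zscore"` and the raw log2 intensity otherwise. This is a
#' generic scorer: it preserves the ranking behaviour of published
#' signature scores without reproducing any assay's proprietary rescaling.
#' Externally computed scores can be supplied instead via [read_scores()].
#'
#' @param cohort A `cohort` with expression data.
#' @param signature A `gene_signature`.
#' @param standardize `"zscore"` (default) or `"none"`.
#' @return A data.frame with columns `sample_id` and `score`; the signature
#'   name is attached as attribute `signature_name`.
#' @export
score_signature <- function(cohort, signature,
                            standardize = c("zscore", "none")) {
  standardize <- match.arg(standardize)
  if (is.null(cohort$expression)) {
    stop("cohort has no expression data", call. = FALSE)
  }
  expr <- cohort$expression
  present <- signature$genes %in% rownames(expr)
  if (!any(present)) {
    stop("none of the ", length(signature$genes),
         " signature genes are present in the expression matrix",
         call. = FALSE)
  }
  as_log_msg("signature '", signature$name, "': ", sum(present), "/",
             length(signature$genes), " genes present")
  genes <- signature$genes[present]
  w <- signature$weights[present]
  x <- expr[genes, , drop = FALSE]
  if (standardize == "zscore") {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    flat <- sdv == 0
    if (any(flat)) {
      as_log_msg(sum(flat), " signature gene(s) with zero variance ",
                 "contribute 0 to the score")
      sdv[flat] <- 1
    }
    x <- (x - mu) / sdv
    x[flat, ] <- 0
  }
  score <- as.numeric(crossprod(w, x)) / sum(abs(w))
  structure(data.frame(sample_id = colnames(expr), score = score,
                       stringsAsFactors = FALSE),
            signature_name = signature$name)
}

#' Import externally computed signature scores
#'
#' Cross-check hook for users who compute scores with a dedicated package
#' (e.g. assay-specific recurrence scores): a two-column `sample_id`,
#' `score` TSV/CSV is accepted anywhere a [score_signature()] result is.
#'
#' @param path Path to the score table.
#' @param signature_name Label recorded on the result.
#' @export
read_scores <- function(path, signature_name = "imported") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "score") %in% names(df))) {
    stop("score table needs 'sample_id' and 'score' columns", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$score <- as.numeric(df$score)
  structure(df[c("sample_id", "score")], signature_name = signature_name)
}

#' Canonical order used to break correlation ties between subtypes
#' @export
SUBTYPE_ORDER <- c("Basal", "Her2", "LumA", "LumB", "Normal")

#' Assign molecular subtypes by Spearman nearest-centroid
#'
#' Expression is restricted to the genes shared with the centroid profiles,
#' median-normalized per gene across all cohort samples, and each sample's
#' normalized vector is Spearman-correlated with every centroid column. The
#' called subtype is the one with the maximal correlation; exact correlation
#' ties are broken by the fixed subtype order (Basal, Her2, LumA, LumB,
#' Normal, then any other names in column order) and reported.
#'
#' @param cohort A `cohort` with expression data.
#' @param centroids Numeric matrix of centroid profiles, genes in rows and
#'   subtypes in columns (see [read_centroids()]).
#' @return A data.frame `sample_id`, `subtype` with the full sample-by-
#'   subtype Spearman correlation matrix attached as attribute
#'   `correlations`.
#' @export
assign_pam50 <- function(cohort, centroids) {
  if (is.null(cohort$expression)) {
    stop("cohort has no expression data", call. = FALSE)
  }
  expr <- cohort$expression
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < 2L) {
    stop("need at least 2 genes shared with the centroid profiles, got ",
         length(shared), call. = FALSE)
  }
  as_log_msg("subtyping on ", length(shared), "/", nrow(centroids),
             " centroid genes")
  ord <- c(intersect(SUBTYPE_ORDER, colnames(centroids)),
           setdiff(colnames(centroids), SUBTYPE_ORDER))
  cen <- centroids[shared, ord, drop = FALSE]
  x <- expr[shared, , drop = FALSE]
  x <- x - apply(x, 1, stats::median)
  cors <- stats::cor(x, cen, method = "spearman")
  ties <- apply(cors, 1, function(r) sum(r == max(r)) > 1L)
  if (any(ties)) {
    as_log_msg(sum(ties), " sample(s) with tied subtype correlations; ",
               "first subtype in canonical order kept")
  }
  calls <- ord[apply(cors, 1, which.max)]
  structure(data.frame(sample_id = colnames(x), subtype = calls,
                       stringsAsFactors = FALSE),
            correlations = cors)
}
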