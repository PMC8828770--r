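#' Read a gene expression matrix from TSV/CSV
#'
#' Expression tables are expected with one row per probeset or gene and one
#' column per sample (log2 intensity scale); a flag transposes. The first
#' column (or the column named by `id_column`) holds the feature identifiers.
#'
#' @param path Path to a tab- or comma-separated text file with a header row.
#' @param id_column Name of the identifier column; defaults to the first
#'   column.
#' @param genes_in_rows If `FALSE` the file is transposed on read (samples in
#'   rows).
#' @param sep Field separator; guessed from the file extension by default
#'   (`.csv` gives a comma, anything else a tab).
#' @return A numeric matrix with feature identifiers as rownames and sample
#'   identifiers as colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, id_column = NULL, genes_in_rows = TRUE,
                            sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  id_column <- id_column %||% header[1]
  if (!id_column %in% names(df)) {
    stop("id column '", id_column, "' not found", call. = FALSE)
  }
  if (anyDuplicated(header)) {
    stop("duplicated sample columns: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(df[[id_column]])
  vals <- df[names(df) != id_column]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stop("non-numeric value '", v[bad[1]], "' at row ", bad[1],
             ", column '", names(vals)[j], "'", call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing cell at row '", rownames(m)[idx[1]], "', column '",
         colnames(m)[idx[2]], "'", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("non-finite expression values", call. = FALSE)
  if (!genes_in_rows) m <- t(m)
  m
}

#' Write an expression matrix as tab-delimited text
#'
#' @param m Numeric matrix, genes in rows.
#' @param path Output path.
#' @param id_column Header for the identifier column.
#' @export
write_expression <- function(m, path, id_column = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Collapse probeset-level rows to gene level
#'
#' When a gene is measured by several probesets, the probeset with the
#' highest mean intensity across all samples represents the gene. Probesets
#' without a mapping are dropped. Ties on the mean are broken in favour of
#' the probeset that appears first in the input, and reported.
#'
#' @param m Numeric matrix, probesets in rows, samples in columns.
#' @param probe_to_gene Mapping from probeset to gene symbol: either a named
#'   character vector (names = probesets) or a two-column data.frame
#'   (probeset, gene).
#' @return A matrix with one row per gene.
#' @export
collapse_probesets <- function(m, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2]]),
                           as.character(probe_to_gene[[1]]))
  } else {
    map <- probe_to_gene
  }
  if (length(map) == 0L) stop("empty probeset-to-gene mapping", call. = FALSE)
  keep <- rownames(m) %in% names(map)
  if (!any(keep)) stop("no probesets map to a gene", call. = FALSE)
  dropped <- sum(!keep)
  if (dropped) as_log_msg(dropped, " unmapped probeset(s) dropped")
  m <- m[keep, , drop = FALSE]
  gene <- unname(map[rownames(m)])
  means <- rowMeans(m)
  # which.max returns the first maximum, giving the documented first-in-file
  # tie rule for free; ties are still detected so they can be reported.
  pick <- vapply(split(seq_len(nrow(m)), factor(gene, levels = unique(gene))),
                 function(idx) {
                   mx <- means[idx]
                   if (sum(mx == max(mx)) > 1L) {
                     as_log_msg("mean-intensity tie for gene '",
                                gene[idx[1]], "'; keeping first probeset")
                   }
                   idx[which.max(mx)]
                 }, integer(1))
  out <- m[pick, , drop = FALSE]
  rownames(out) <- unique(gene)
  out
}

#' Read a per-sample clinical table
#'
#' The table must contain a `sample_id` column; recognised covariates
#' (`age`, `tumor_size`, `time` as numerics, `event` as 0/1) are coerced and
#' validated, all other columns are kept as-is. Missing values are `NA`.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @param sep Field separator; guessed from the extension by default.
#' @return A data.frame with one row per sample.
#' @export
read_clinical <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("NA", ""))
  validate_clinical(df)
}

validate_clinical <- function(df) {
  if (!"sample_id" %in% names(df)) {
    stop("clinical table must contain a 'sample_id' column", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in clinical table", call. = FALSE)
  }
  for (nm in intersect(c("age", "tumor_size", "time"), names(df))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  if ("time" %in% names(df) && any(df$time < 0, na.rm = TRUE)) {
    stop("negative survival time", call. = FALSE)
  }
  if ("event" %in% names(df)) {
    ev <- df$event
    if (!all(ev %in% c(0, 1, NA))) {
      stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
    }
    df$event <- as.integer(ev)
  }
  df
}

#' Assemble a cohort from expression and clinical data
#'
#' Restricts both inputs to their shared samples (order taken from the
#' clinical table) and reports any samples dropped on either side. Sample
#' identifiers are matched case-sensitively.
#'
#' @param clinical A clinical data.frame with a `sample_id` column (see
#'   [read_clinical()]).
#' @param expression Optional numeric matrix, genes in rows, samples in
#'   columns.
#' @param name Cohort label used in printouts and logs.
#' @return An object of class `cohort`: a list with elements `clinical`,
#'   `expression` (possibly `NULL`) and `name`.
#' @export
join_cohort <- function(clinical, expression = NULL, name = "cohort") {
  clinical <- validate_clinical(clinical)
  if (!is.null(expression)) {
    shared <- intersect(clinical$sample_id, colnames(expression))
    if (length(shared) == 0L) {
      stop("no samples shared between expression and clinical data",
           call. = FALSE)
    }
    drop_c <- setdiff(clinical$sample_id, shared)
    drop_e <- setdiff(colnames(expression), shared)
    if (length(drop_c)) {
      as_log_msg(length(drop_c), " clinical sample(s) without expression ",
                 "dropped")
    }
    if (length(drop_e)) {
      as_log_msg(length(drop_e), " expression sample(s) without clinical ",
                 "data dropped")
    }
    clinical <- clinical[clinical$sample_id %in% shared, , drop = FALSE]
    rownames(clinical) <- NULL
    expression <- expression[, clinical$sample_id, drop = FALSE]
  }
  structure(list(clinical = clinical, expression = expression, name = name),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort '", x$name, "'> ", nrow(x$clinical), " samples",
      if (!is.null(x$expression)) {
        paste0(", expression ", nrow(x$expression), " genes")
      } else {
        ", clinical only"
      }, "\n", sep = "")
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A `cohort` object.
#' @export
cohort_size <- function(cohort) nrow(cohort$clinical)

#' Read a gene signature (GMT or two-column TSV)
#'
#' GMT files carry one signature per line (`name`, description, genes);
#' weights default to 1. TSV files need `gene` and `weight` columns and keep
#' signed weights.
#'
#' @param path Path to the signature file.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @param name For GMT files with several lines, the signature to extract
#'   (default: first line).
#' @return A `gene_signature`: list with `name`, `genes`, `weights`.
#' @export
read_signature <- function(path, format = c("auto", "gmt", "tsv"),
                           name = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty GMT file", call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    sig_names <- vapply(fields, `[[`, "", 1L)
    i <- if (is.null(name)) 1L else match(name, sig_names)
    if (is.na(i)) stop("signature '", name, "' not in GMT", call. = FALSE)
    genes <- fields[[i]][-(1:2)]
    weights <- rep(1, length(genes))
    sig_name <- sig_names[i]
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("gene", "weight") %in% names(df))) {
      stop("TSV signature needs 'gene' and 'weight' columns", call. = FALSE)
    }
    genes <- as.character(df$gene)
    weights <- as.numeric(df$weight)
    sig_name <- name %||% sub("\\.[^.]*$", "", basename(path))
  }
  gene_signature(sig_name, genes, weights)
}

#' Construct a gene signature
#' @param name Signature label.
#' @param genes Character vector of gene symbols (unique).
#' @param weights Numeric weights, recycled from 1 if omitted.
#' @export
gene_signature <- function(name, genes, weights = rep(1, length(genes))) {
  if (anyDuplicated(genes)) {
    stop("duplicated gene(s) in signature: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(weights) != length(genes) || !all(is.finite(weights))) {
    stop("weights must be finite, one per gene", call. = FALSE)
  }
  structure(list(name = name, genes = as.character(genes),
                 weights = as.numeric(weights)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature '", x$name, "'> ", length(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Read centroid profiles for molecular subtyping
#'
#' Expects a tab-delimited table with genes in rows and one column per
#' subtype (the 50-gene by 5-subtype layout of PAM50-style centroids, though
#' neither count is enforced).
#'
#' @param path Path to the centroid TSV.
#' @return A numeric matrix, genes in rows, subtypes in columns.
#' @export
read_centroids <- function(path) {
  m <- read_expression(path)
  if (anyDuplicated(colnames(m))) {
    stop("duplicated subtype columns", call. = FALSE)
  }
  m
}
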