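# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
as_log_msg <- function(...) message("appliscore: ", ...)

# Validate an integer seed; all stochastic entry points require one so that
# no function depends on the global RNG state.
check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

check_flag <- function(x, name) {
  if (length(x) != 1L || !is.logical(x) || is.na(x)) {
    stop("`", name, "` must be TRUE or FALSE", call. = FALSE)
  }
  x
}

# Coerce character columns to factors, applying stored levels when predicting
# so that train/apply factor codings always agree.
apply_xlevels <- function(df, xlevels) {
  for (nm in names(xlevels)) {
    if (!nm %in% names(df)) next
    v <- df[[nm]]
    if (!is.factor(v)) v <- factor(v)
    bad <- !is.na(v) & !(as.character(v) %in% xlevels[[nm]])
    if (any(bad)) {
      stop("unseen level(s) in predictor '", nm, "': ",
           paste(unique(as.character(v)[bad]), collapse = ", "),
           call. = FALSE)
    }
    df[[nm]] <- factor(as.character(v), levels = xlevels[[nm]])
  }
  df
}

factorize <- function(df, cols) {
  for (nm in cols) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
    }
  }
  df
}
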