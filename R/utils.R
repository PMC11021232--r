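# Internal helpers shared across modules.

# Coerce a wide time-series table (one row per frame, one numeric column per
# region) to a plain numeric matrix with region labels as colnames.
ts_matrix <- function(ts) {
  if (is.matrix(ts)) {
    m <- ts
  } else if (is.data.frame(ts)) {
    bad <- names(ts)[!vapply(ts, is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(paste0("non-numeric region column(s): ", paste(bad, collapse = ", ")),
            class = "vgfc_error_validation")
    }
    m <- as.matrix(ts)
  } else {
    abort("time series must be a data frame or matrix (frames x regions)",
          class = "vgfc_error_validation")
  }
  if (is.null(colnames(m))) colnames(m) <- sprintf("R%03d", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m))) {
    abort("duplicate region labels", class = "vgfc_error_validation")
  }
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite value at frame %d, region '%s'",
                  idx[1], colnames(m)[idx[2]]),
          class = "vgfc_error_validation")
  }
  if (nrow(m) < 3) {
    abort("need at least 3 frames", class = "vgfc_error_validation")
  }
  m
}

check_series <- function(x, min_len = 2) {
  if (!is.numeric(x)) {
    abort("series must be numeric", class = "vgfc_error_validation")
  }
  if (length(x) < min_len) {
    abort(sprintf("series must have at least %d points", min_len),
          class = "vgfc_error_validation")
  }
  if (any(!is.finite(x))) {
    abort(sprintf("non-finite value at position %d", which(!is.finite(x))[1]),
          class = "vgfc_error_validation")
  }
  invisible(as.numeric(x))
}

# Positive scalar check with the field name in the message.
check_scalar <- function(value, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  ok <- is.numeric(value) && length(value) == 1 && is.finite(value) &&
    (if (strict_lower) value > lower else value >= lower) && value <= upper &&
    (!integer || value == round(value))
  if (!ok) {
    abort(sprintf("invalid field '%s': must be %s in %s%s, %s]", name,
                  if (integer) "an integer" else "a real",
                  if (strict_lower) "(" else "[", lower, upper),
          class = "vgfc_error_validation")
  }
  invisible(value)
}
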