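## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort with a classed condition
#'
#' All user-facing errors in the package carry a subclass so callers (and
#' tests) can distinguish parse, validation, schema and config failures.
#' @noRd
hif_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "hifbind_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

hif_log <- function(...) {
  message("[hifbind] ", sprintf(...))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

## reverse cumulative sum over rows of a matrix (or a vector);
## the matrix branch runs one cumsum over the flattened matrix and
## subtracts per-column offsets, avoiding apply() in hot loops
revcumsum <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    v <- as.vector(x[n:1, , drop = FALSE])
    cv <- cumsum(v)
    off <- rep(c(0, cv[seq_len(ncol(x) - 1) * n]), each = n)
    matrix(cv - off, n)[n:1, , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

## columnwise standard deviations without apply()
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(NA_real_, ncol(x)))
  m <- colMeans(x)
  sqrt(pmax(colMeans(x^2) - m^2, 0) * n / (n - 1))
}
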