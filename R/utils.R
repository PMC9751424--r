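# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raise a classed error
#'
#' Errors carry one of three condition classes so callers (and the command
#' line wrapper) can distinguish I/O problems, input-validation failures and
#' statistical degeneracy.
#' @noRd
mgm_stop <- function(msg, class = "mgm_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mgm_error")))
}

mgm_io_stop <- function(msg) mgm_stop(msg, class = "mgm_io_error")
mgm_degenerate_stop <- function(msg) mgm_stop(msg, class = "mgm_degenerate_error")

#' Evaluate code under a temporary RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible substream seed from a root seed and stream indices
#'
#' Keeps all derived seeds inside the 32-bit signed integer range.
#' @noRd
derive_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 69069 + as.double(idx[k]) * 12553 + 97) %% 2147483647
  }
  as.integer(s)
}

# Coordinate convention used throughout: matrices are rows x columns, row 1
# is the top of the image, "vertical" runs along rows; coordinates are
# reported as (row, col).
stopifnot_matrix <- function(x, what = "input") {
  if (!is.matrix(x) || nrow(x) < 1L || ncol(x) < 1L)
    mgm_stop(sprintf("%s must be a matrix with at least 1 row and 1 column", what))
}

check_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b)))
    mgm_stop(sprintf("%s must have identical dimensions (%s vs %s)",
                     what, paste(dim(a), collapse = "x"),
                     paste(dim(b), collapse = "x")))
}
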