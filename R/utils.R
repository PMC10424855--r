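# Classed conditions so callers (and the CLI) can distinguish bad arguments
# from bad data.  All abort helpers are internal.

stop_param <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("wgmcat_parameter_error", "wgmcat_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("wgmcat_domain_error", "wgmcat_error")))
}

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("wgmcat_schema_error", "wgmcat_error")))
}

# Coerce a length-3 vector or n x 3 matrix/data.frame to a double matrix,
# remembering whether the input was a bare triple.
as_triple_matrix <- function(x, what = "triple") {
  if (is.data.frame(x)) x <- as.matrix(x)
  vec <- is.null(dim(x))
  if (vec) {
    if (length(x) != 3L)
      stop_param("%s must be a length-3 vector or an n x 3 matrix", what)
    x <- matrix(as.double(x), nrow = 1L)
  } else {
    if (ncol(x) != 3L) stop_param("%s must have exactly 3 columns", what)
    storage.mode(x) <- "double"
  }
  if (anyNA(x) || any(!is.finite(x)))
    stop_domain("%s contains non-finite values", what)
  dimnames(x) <- NULL
  attr(x, "was_vector") <- vec
  x
}

restore_shape <- function(m, template, names3) {
  if (isTRUE(attr(template, "was_vector"))) {
    out <- as.vector(m)
    names(out) <- names3
    return(out)
  }
  attr(m, "was_vector") <- NULL
  dimnames(m) <- list(NULL, names3)
  m
}

# Broadcast a length-3 anchor across the rows of an n x 3 matrix.
rep_rows <- function(v, n) matrix(v, nrow = n, ncol = 3L, byrow = TRUE)

check_positive <- function(m, what) {
  if (any(m <= 0))
    stop_domain("%s must be strictly positive in every channel", what)
  invisible(m)
}

clamp01 <- function(x) pmin(1, pmax(0, x))
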