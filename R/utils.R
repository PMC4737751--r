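#' @useDynLib denfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif setNames sd
#' @importFrom utils head write.table
NULL

# Signal a classed error so callers (and the pipeline driver) can map
# failures to machine-readable outcomes without parsing messages.
stop_denfit <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "denfit_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Pairwise Euclidean distance matrix between two coordinate matrices.
cdist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Deterministic child seeds: spread a user seed into k distinct streams
# while staying inside the 32-bit integer range set.seed() accepts.
derive_seeds <- function(seed, k) {
  (as.integer(seed) + 1000003L * seq_len(k)) %% 2147483647L
}
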