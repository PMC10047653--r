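# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a vector / matrix / data.frame to a numeric matrix block and
# validate finiteness. Used for the x, y and z blocks of a sample.
.as_block <- function(v, name) {
  if (is.data.frame(v)) v <- data.matrix(v)
  if (is.null(dim(v))) v <- matrix(as.numeric(v), ncol = 1L)
  if (!is.matrix(v)) stop(sprintf("'%s' must be a vector, matrix or data frame", name), call. = FALSE)
  storage.mode(v) <- "double"
  if (!all(is.finite(v)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  v
}

# Squared Euclidean distance matrix. The identity
# ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b keeps this at O(n^2 d) with
# vectorised primitives; tiny negative round-off is clamped.
.sqdist <- function(p) {
  s <- rowSums(p * p)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

.stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
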