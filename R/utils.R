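# Internal helpers shared across the pipeline stages.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded generators never disturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a named substream seed from a top-level seed
#'
#' Every random stage of the pipeline draws its seed from the single
#' top-level seed through this map, so stages are reproducible in isolation
#' and insensitive to the order in which other stages consume random numbers.
#'
#' @param seed integer top-level seed.
#' @param name character substream name (e.g. "simulate", "nulls").
#' @return an integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 + h * 97) %% 2147483563)
}

# is x a symmetric square numeric matrix (within tol)?
check_square_symmetric <- function(x, tol = 1e-12, what = "matrix") {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(what, " must be a square matrix", call. = FALSE)
  d <- x; d[!is.finite(d)] <- 0
  if (max(abs(d - t(d))) > tol * max(1, max(abs(d))))
    stop(what, " must be symmetric", call. = FALSE)
  invisible(TRUE)
}

# node names of a matrix, requiring dimnames
node_names <- function(x) {
  nm <- rownames(x)
  if (is.null(nm)) nm <- colnames(x)
  if (is.null(nm)) stop("matrix must carry node names in its dimnames", call. = FALSE)
  nm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
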