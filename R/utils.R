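# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_snn <- function(...) stop(..., call. = FALSE)

check_binary_matrix <- function(S, what = "spike train") {
  if (!is.matrix(S)) stop_snn(what, " must be a matrix (time x neurons)")
  if (nrow(S) < 1L || ncol(S) < 1L) stop_snn(what, " must have T >= 1 and N >= 1")
  if (anyNA(S) || !all(S == 0 | S == 1)) {
    stop_snn(what, " entries must all be 0 or 1")
  }
  invisible(S)
}

check_finite_matrix <- function(M, what = "drive") {
  if (!is.matrix(M)) stop_snn(what, " must be a matrix")
  if (!all(is.finite(M))) stop_snn(what, " contains non-finite entries")
  invisible(M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
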