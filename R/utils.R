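## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(ok, msg, call. = FALSE) {
  if (!isTRUE(ok)) stop(msg, call. = call.)
}

## set the RNG locally when a seed is supplied, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## column standardization that tolerates monomorphic columns (returns 0s)
.standardize_dosages <- function(x, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(x) / 2
  sds <- sqrt(2 * freq * (1 - freq))
  z <- sweep(x, 2L, 2 * freq, "-")
  keep <- sds > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, sds[keep], "/")
  z[, !keep] <- 0
  z
}
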