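#' @include AllClasses.R
NULL

## Evaluate expr under a given RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Flatten a T x H x W stack into a T x (H*W) matrix (pixel j -> (row, col)
## in column-major order, i.e. row = ((j-1) %% H) + 1).
.stackMatrix <- function(stack) {
  f <- frames(stack)
  d <- dim(f)
  dim(f) <- c(d[1], d[2] * d[3])
  f
}

## Inverse of .stackMatrix for per-pixel scalars.
.pixelMatrix <- function(v, h, w) matrix(v, nrow = h, ncol = w)

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
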