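# internal helpers

# round half away from zero (MATLAB-style), not banker's rounding
roundHalfUp <- function(x) floor(x + 0.5)

# evaluate expr with a local, reproducible RNG stream; the caller's
# global RNG state is left untouched
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# disk structuring element of the given radius as a 0/1 matrix
diskKernel <- function(radiusPx) {
  EBImage::makeBrush(2L * as.integer(radiusPx) + 1L, shape = "disc")
}
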