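# run code under a local RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# slice a 3D array perpendicular to `axis` at index i (drops the axis)
ap_slice <- function(arr, axis, i) {
  switch(axis, `1` = arr[i, , ], `2` = arr[, i, ], `3` = arr[, , i])
}
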