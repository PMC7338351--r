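# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed below 2^31 from a base seed and a stream index.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435761 + stream * 97) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:x; this never does.
shuffle <- function(x) x[sample.int(length(x))]
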