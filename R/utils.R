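# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-item 31-bit seed from a master seed, reproducibly.
deriveSeed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 1299721) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Stable hash of an R object (base tools only).
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# Shared geometry check for paired grids.
checkSameGrid <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stopf("%s have different shapes: %s vs %s", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
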