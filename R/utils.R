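# internal helpers shared across modules

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
# so that library calls do not perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# atomic file write: render to a sibling temp file, then rename into place
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("cannot write output file '%s'", path)
  invisible(path)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
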