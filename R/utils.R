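# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one master seed into per-run (or per-replicate) seeds by polynomial
#' hashing of an index path, so any simulated run can be regenerated in
#' isolation. All values stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param ... Integer indices identifying the sub-stream (e.g. subject, run).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  h <- 0
  for (v in idx) h <- (h * 69069 + as.numeric(v) + 1) %% 2147483563
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Shift a 3-D logical/numeric array by integer offsets, padding with `fill`.
shift_array <- function(x, off, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) { dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o) }
    else        { dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Deterministic 31-bit polynomial hash of a character string; used for config
# provenance stamps (not cryptographic).
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
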