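# Classed conditions so callers can distinguish failure modes programmatically.

rp_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rpclim_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG stream derived from `seed`, restoring the
# caller's stream afterwards so generators never perturb each other.
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

# Stable per-generator substream: keeps derived seeds in 32-bit range.
derive_seed <- function(seed, stream) {
  offset <- c(climate = 101L, studies = 211L, diaries = 307L, sites = 401L)[[stream]]
  (as.integer(seed) %% 1000000L) * 1009L + offset
}
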