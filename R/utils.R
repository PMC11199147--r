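# Seed the RNG for the duration of the calling function, restoring the
# caller's RNG state when that function exits.
local_rng <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  expr <- if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}

# Deterministic per-stage seed derived from a master seed by a counter
# scheme, kept within 32-bit integer range.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 1009 + stage * 9973) %% 2147483647)
}
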