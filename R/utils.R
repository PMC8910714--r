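# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# seed = NULL evaluates the code under the current RNG stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Leveled logging to stderr. verbose = 0 silences info, 1 shows info,
# 2 adds debug.
podgp_log <- function(msg, level = "info", verbose = 1L) {
  threshold <- c(error = 0L, warn = 0L, info = 1L, debug = 2L)[[level]]
  if (verbose >= threshold) {
    message(sprintf("[%s] %s", level, msg))
  }
  invisible(NULL)
}
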