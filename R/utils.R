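# internal helpers

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All stochastic stages fork from one master seed by fixed integer offsets
# (documented in the methods vignette), so whole-study runs are reproducible
# from a single integer.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic seed forking: stage offsets keep the stages' streams apart
# while everything derives from one master seed. Kept below 2^31 - 1.
fork_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(mesh = 0L, lge = 1000L, cleft = 2000L, fixture = 3000L,
               protocol = 4000L, study = 5000L, stats = 6000L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) + off + index) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_fs <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fibrosim_error"))
}
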