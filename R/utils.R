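# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Named per-stream offsets so that every source of randomness in the package
# flows from one master seed but draws from distinct, documented streams.
.stream_offsets <- c(
  duration    = 1L,
  struggle    = 2L,
  levels      = 3L,
  waveform    = 4L,
  orientation = 5L,
  covariates  = 6L,
  physio      = 7L,
  cluster     = 8L,
  posterior   = 9L,
  study       = 10L,
  pipeline    = 11L
)

#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each
#' stochastic component (bout chain, waveform draws, logger orientation,
#' covariates, blood-panel noise, k-means restarts, posterior draws, ...)
#' draws from its own stream derived deterministically from the master seed,
#' so that e.g. changing the number of posterior simulations never perturbs
#' the simulated traces.
#'
#' @param master integer master seed.
#' @param stream one of `"duration"`, `"struggle"`, `"levels"`, `"waveform"`,
#'   `"orientation"`, `"covariates"`, `"physio"`, `"cluster"`, `"posterior"`,
#'   `"study"`, `"pipeline"`.
#' @param index optional non-negative integer (e.g. shark index within a
#'   study) giving a sub-stream.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  if (!stream %in% names(.stream_offsets)) {
    stopf("unknown random stream '%s'", stream)
  }
  off <- .stream_offsets[[stream]]
  # modular mix kept in exact double arithmetic (< 2^53), result < 2^31
  v <- (as.numeric(master) %% 2147483629) * 33013 +
    off * 2473 + as.numeric(index) * 97
  as.integer(v %% 2147483629)
}

# Evaluate `code` under a given seed without disturbing the caller's RNG.
with_stream_seed <- function(master, stream, index = 0L, code) {
  withr::with_seed(derive_seed(master, stream, index), code)
}

# %||% as in rlang, without the dependency
`%||%` <- function(a, b) if (is.null(a)) b else a
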