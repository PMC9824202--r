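# Seed management: every stochastic operation takes an integer seed and runs
# in a locally-seeded RNG scope, leaving the caller's RNG state untouched.
# Named sub-streams let one cohort seed drive independent kinematics, noise
# and fold randomness.

#' Evaluate an expression with a local RNG seed
#'
#' Seeds the RNG, evaluates `code`, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a named sub-stream seed
#'
#' Deterministic 31-bit hash of a parent seed and a stream name, so the
#' kinematics, noise and fold streams of one cohort are independent but all
#' reproducible from the single cohort seed.
#'
#' @param seed Parent integer seed.
#' @param name Stream name.
#' @return Integer in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# smoothstep: C^1 ramp 0 -> 1 on u in [0, 1]
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# trapezoidal cumulative integral on a uniform grid
cumtrapz_uniform <- function(x, dt) {
  c(0, cumsum((x[-1] + x[-length(x)]) / 2 * dt))
}

# data.frame constructor without validation overhead (hot paths: one frame
# per trial and per angle series); columns must be equal-length vectors
fast_df <- function(cols, n) {
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}
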