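#' Derive a reproducible sub-seed from a base seed and a stream key
#'
#' Fans a single user-facing seed out into independent per-stage or per-eye
#' substreams by hashing a character key, so that adding a stream never
#' perturbs the draws of existing ones.
#'
#' @param seed Integer base seed.
#' @param key Character scalar naming the stream (e.g. `"cohort/G1-01/OD"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "phantom")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(key), length(key) == 1L)
  m <- 2147483563
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(((abs(as.numeric(seed)) %% m) * 48271 + h) %% m)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Quintic smootherstep: 0 at t <= 0, 1 at t >= 1, with zero first and second
# derivatives at both ends (keeps phantom surfaces flat at the rim so chord
# error of the grid triangulation stays negligible near the BMO ring).
smootherstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t^3 * (t * (t * 6 - 15) + 10)
}
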