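#' Derive a per-assay random seed from a global seed
#'
#' Each simulated assay draws from its own random stream, derived
#' deterministically from one global integer seed and a short assay tag.
#' Adding or reordering assays in a simulation therefore never perturbs the
#' draws of another assay.
#'
#' @param seed Integer global seed.
#' @param tag Character scalar naming the stream (e.g. `"swimming"`).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "swimming")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(tag), length(tag) == 1L, nzchar(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  # mix: multiplicative hash of the seed, then fold in the tag hash
  s <- (abs(seed) %% m) * 48271 %% m
  out <- (s + h * 69621) %% m
  as.integer(out %% (m - 1L) + 1L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards (or removing it if absent before).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
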