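#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows through named streams derived from a
#' single master seed, so that data generation, weight initialisation,
#' window sampling and augmentation can be replayed independently.
#'
#' @param master Integer master seed.
#' @param key Character stream label (e.g. `"init"`, `"augment"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(key))
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
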