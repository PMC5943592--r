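# Run code with a local, fully specified RNG state.
# Mersenne-Twister + inversion are pinned so seeded output is identical
# across platforms and R sessions; the caller's RNG state is restored.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Deterministic per-stage seed derived from a single top-level seed.
# Multiplicative mixing keeps stages and extra keys (e.g. individual-id
# hashes) in distinct seed blocks; the result stays below 2^31.
stage_seed <- function(seed, stage, extra = 0) {
  offsets <- c(lightfield = 101, individuals = 211, measurements = 307,
               dark = 401, draws = 503, scenarios = 601)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  x <- (as.double(seed) * 48271 + offsets[[stage]] * 99991 +
          as.double(extra)) %% 2147483647
  as.integer(x)
}
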