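# Seed-stream plumbing. All randomness in the package flows from one root seed
# through named substreams so that individual stages (placement, arbors,
# appositions, the three pruning steps, patch sampling) can be re-run in
# isolation and still reproduce bit-identically.

.stream_ids <- c(
  placement   = 1L,
  arbors      = 2L,
  appositions = 3L,
  prune1      = 4L,
  prune2      = 5L,
  prune3      = 6L,
  patch       = 7L,
  misc        = 8L
)

# Derive a substream seed; keeps the result a valid 32-bit integer.
substream_seed <- function(seed, stream) {
  if (!stream %in% names(.stream_ids)) {
    stop("unknown RNG stream: ", stream)
  }
  seed <- as.integer(seed)
  ((abs(seed) %% 1000003L) * 131L + .stream_ids[[stream]] * 7919L) %% 2147483123L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
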