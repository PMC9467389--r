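# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# session RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stage seed from a root seed; keeps results < 2^31 and decorrelates
# stages that consume different amounts of randomness.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, diversity = 23L, nmds = 37L, network = 53L,
               risk = 71L, cv = 89L, boot = 101L, rarefaction = 113L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
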