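# Internal helpers shared across modules.

DNA_STATES <- c("A", "C", "G", "T")

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

is_transition_pair <- function(b1, b2) {
  (b1 == "A" & b2 == "G") | (b1 == "G" & b2 == "A") |
    (b1 == "C" & b2 == "T") | (b1 == "T" & b2 == "C")
}
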