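# Internal helpers: seeded evaluation and seed derivation.

# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-unit seed below 2^31, so one master seed fans out into
# independent streams for subjects, views, augmentation, and the annotator.
.derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483647
  s <- (as.double(master) %% m)
  s <- (s * 48271 + as.double(index) * 7919 + as.double(stream) * 104729) %% m
  as.integer(s)
}

# Truncated-normal draw by rejection; bounds in SD units.
.rnorm_trunc <- function(n, mean = 0, sd = 1, bound = 3) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- rnorm(1L)
      if (abs(z) <= bound) break
    }
    out[i] <- mean + sd * z
  }
  out
}

.stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
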