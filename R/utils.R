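# Small internal helpers.

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# second central difference of a sampled signal; endpoints zero
second_derivative <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) {
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
  }
  d
}

# first central difference; one-sided at the ends
first_derivative <- function(x, fs) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}
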