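## internal helpers

# Run code with a local, seeded RNG state; caller's RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact integer allocation of n among classes by largest remainder
# (Hamilton method): composition is deterministic, not multinomial.
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 1, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  exact <- n * proportions
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    rem <- exact - base
    # stable tie-break: larger remainder first, then original order
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

# Truncated-normal draws by rejection; truncation bounds are far in the tail
# for all defaults so this stays cheap.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) {
      out[bad] <- pmin(pmax(mean, lower), upper)
      break
    }
  }
  out
}
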