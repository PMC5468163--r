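# Internal helpers shared across modules.

# Run `expr` under a locally-seeded RNG, restoring the caller's RNG state on
# exit. All user-facing generators route randomness through this so that the
# same seed gives byte-identical output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Effective sample size from the initial positive sequence of autocorrelation
# pair sums (Geyer 1992). Small, dependency-free stand-in for coda::effectiveSize.
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2L, 500L), plot = FALSE)$acf[, 1, 1]
  # pair sums Gamma_k = rho_{2k} + rho_{2k+1}; truncate at first non-positive
  m <- floor((length(ac) - 1) / 2)
  denom <- 1
  for (k in seq_len(m)) {
    g <- ac[2 * k] + ac[2 * k + 1]
    if (g <= 0) break
    denom <- denom + 2 * g
  }
  max(1, n / denom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
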