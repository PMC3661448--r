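# Internal helpers shared across modules.

# centred moving average with window w samples (w >= 1); edges use a
# shrinking window so the output has the same length and no phase shift
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# indices of strict-ish local maxima: x[i] >= x[i-1] & x[i] > x[i+1]
# (the asymmetric tie-break picks one index per flat-topped peak)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] >= x[i - 1L] & x[i] > x[i + 1L]]
}

local_minima <- function(x) local_maxima(-x)

# lognormal multiplier with mean exactly 1 and coefficient of variation cv
rlnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

# deterministic stream of sub-seeds (kept below 2^31 for R's 32-bit ints)
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so simulation calls do not perturb user code
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
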