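#' @importFrom data.table data.table as.data.table := setorder setorderv
#'   rbindlist copy setnames setkeyv .N .SD
#' @importFrom stats rbinom rnorm runif rnbinom cor sd var median
#'   complete.cases quantile pnorm setNames
NULL

## Deterministic round-half-up (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so that stochastic operations are
#' reproducible without side effects on the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## Centred rolling statistic with window truncation at the edges: the
## window at index i spans [max(1, i-h), min(n, i+h)] with h = floor(w/2),
## so edge positions keep a full one-sided neighbourhood rather than
## shrinking to a single point.
rolling_stat <- function(x, window, fun) {
  n <- length(x)
  h <- max(1L, floor(window / 2))
  vapply(seq_len(n), function(i) {
    fun(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

rolling_median <- function(x, window) rolling_stat(x, window, median)
rolling_mean   <- function(x, window) rolling_stat(x, window, mean)

## Sliding-window Z-score: each value is standardised against the mean and
## s.d. of the centred (edge-truncated) window around it; a zero-variance
## window yields z = 0 by convention.
sliding_window_z <- function(x, window) {
  n <- length(x)
  h <- max(1L, floor(window / 2))
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    s <- sd(w)
    if (!is.finite(s) || s == 0) return(0)
    (x[i] - mean(w)) / s
  }, numeric(1))
}
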