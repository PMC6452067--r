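# Small shared helpers.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state so seeded package functions never
#' disturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Wrap angles into (-pi, pi]
#' @param x Angles in radians.
#' @return Wrapped angles.
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Centred running mean with full-support edges: positions whose window is
# not fully contained in the series are NA. `k` is the window length in
# samples (odd lengths are symmetric; even lengths cover k/2 before and
# k/2 - 1 after, consistent throughout the package).
run_mean <- function(x, k) {
  n <- length(x)
  if (k > n) return(rep(NA_real_, n))
  if (k <= 1L) return(x)
  cs <- cumsum(c(0, x))
  lead <- ceiling((k - 1) / 2)   # samples before the centre
  out <- rep(NA_real_, n)
  starts <- seq_len(n - k + 1L)
  out[starts + lead] <- (cs[starts + k] - cs[starts]) / k
  out
}

# Running sum over centred windows of k samples, NA at unsupported edges.
run_sum <- function(x, k) run_mean(x, k) * k

db <- function(x) 10 * log10(x)
undb <- function(x) 10^(x / 10)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
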