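## Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed so that a
#' pipeline run is reproducible end to end while stages remain decoupled
#' (re-running one stage does not perturb another's stream).
#'
#' @param seed master seed (integer).
#' @param stage stage label (character) hashed into the offset.
#' @return an integer seed in `[0, 2^31)`.
#' @keywords internal
spawn_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483629)
}

#' Run code under a local RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Shortest interval containing a given probability mass
#'
#' Highest-density interval by the shortest-interval estimator on a sample:
#' the narrowest window of the order statistics holding `prob` of the draws.
#'
#' @param x numeric sample (NAs dropped).
#' @param prob probability mass, e.g. 0.95.
#' @return c(lower, upper); `c(NA, NA)` when fewer than 2 finite values.
#' @export
hdi_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(NA_real_, NA_real_))
  k <- max(2L, ceiling(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  lo <- 1L:(n - k + 1L)
  w <- x[lo + k - 1L] - x[lo]
  i <- which.min(w)
  c(x[i], x[i + k - 1L])
}

## Stop with a classed condition so callers can discriminate error families.
abort <- function(msg, class) {
  stop(structure(class = c(class, "limnoflux_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## Piecewise-linear interpolation that refuses to extrapolate.
interp_strict <- function(x, y, xout, what = "depth") {
  if (any(xout < min(x) - 1e-9 | xout > max(x) + 1e-9)) {
    abort(sprintf("%s out of modelled range [%g, %g]", what, min(x), max(x)),
          "limnoflux_range_error")
  }
  stats::approx(x, y, xout = pmin(pmax(xout, min(x)), max(x)), ties = "ordered")$y
}

## Mean per time bin; NA where a bin is empty. breaks has length n_bins + 1.
bin_means <- function(t, v, breaks) {
  idx <- findInterval(t, breaks, rightmost.closed = TRUE)
  ok <- idx >= 1L & idx <= (length(breaks) - 1L) & is.finite(v)
  out <- rep(NA_real_, length(breaks) - 1L)
  if (any(ok)) {
    s <- tapply(v[ok], idx[ok], mean)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}
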