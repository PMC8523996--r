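# Internal numeric helpers shared across modules.

# Evaluate an expression under a temporary RNG state; the caller's
# .Random.seed is restored afterwards so library code never perturbs
# user-level reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Cumulative trapezoidal integral of y over x; returns vector of same length,
# starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 1L)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' Dense evaluation grid
#'
#' The 1-s-resolution time grid (in minutes) over the 30-min acquisition on
#' which fitted curves, ratios and curve summaries (time-to-peak, late
#' slope) are evaluated.
#'
#' @param from_s,to_s,by_s Grid extent and step in seconds.
#' @return Numeric vector of times in minutes.
#' @export
dense_grid_min <- function(from_s = 0, to_s = 1800, by_s = 1) {
  seq(from_s, to_s, by = by_s) / 60
}

# Evaluate a "curve": either a function of time in minutes or a data.frame
# with columns time_min and value (already densely sampled).
eval_curve <- function(curve, t_min) {
  if (is.function(curve)) return(curve(t_min))
  stop("`curve` must be a function of time in minutes")
}

curve_samples <- function(curve, default_grid = dense_grid_min()) {
  if (is.function(curve)) {
    data.frame(time_min = default_grid, value = curve(default_grid))
  } else if (is.data.frame(curve) && all(c("time_min", "value") %in% names(curve))) {
    curve
  } else {
    stop("`curve` must be a function(t_min) or a data.frame(time_min, value)")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
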