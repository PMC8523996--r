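#' Tumor vascularization fit function
#'
#' The parametric curve used to de-noise tumor and healthy-brain TACs
#' before extracting semiquantitative parameters: zero before tracer
#' arrival, then
#' \deqn{a_0 + (a_1 - a_0) \frac{A + x^p}{B + x^q}, \quad x = (t - t^*)/a_2,}
#' with the baseline \eqn{a_0} fixed at 0, \eqn{a_1} the uptake scale (SUV),
#' \eqn{a_2} a time scale in seconds, \eqn{p, q} rise/decay shape exponents
#' and \eqn{A, B} dimensionless constants (\eqn{B > 0}). \eqn{t^*} is the
#' delay from injection to tracer arrival, in minutes.
#'
#' @param t_min Time(s) in minutes.
#' @param params Named list/vector with `a1`, `a2`, `p`, `q`, `A`, `B`,
#'   `t_star` (and optionally `a0`, fixed at 0).
#' @return SUV values.
#' @export
vasc_function <- function(t_min, params) {
  p <- as.list(params)
  a0 <- p$a0 %||% 0
  check_vasc_params(p)
  out <- numeric(length(t_min))
  on_t <- t_min >= p$t_star
  x <- (t_min[on_t] - p$t_star) * 60 / p$a2     # a2 carries seconds
  out[on_t] <- a0 + (p$a1 - a0) * (p$A + x^p$p) / (p$B + x^p$q)
  out
}

check_vasc_params <- function(p) {
  need <- c("a1", "a2", "p", "q", "A", "B", "t_star")
  if (!all(need %in% names(p))) stop("missing vascularization parameter(s)")
  if (p$a2 <= 0 || p$p <= 0 || p$q <= 0 || p$B <= 0 || p$t_star < 0)
    stop("invalid vascularization parameters: need a2 > 0, p > 0, q > 0, B > 0, t_star >= 0")
  invisible(TRUE)
}

#' Fit the vascularization function to a TAC
#'
#' Nonlinear least squares on the frame values of a uniform-protocol TAC,
#' with the baseline fixed at 0 and a multistart over shape-exponent
#' combinations (p, q in \{0.5, 1, 2\}), the scale initialised at the
#' observed maximum and the time scale at the observed peak time.
#'
#' @param x A `tac` (tumor or brain reference) on the uniform schedule.
#' @param n_multistarts Number of starts (the 9 shape combinations are
#'   cycled, with seeded jitter beyond the first 9).
#' @param seed Seed for jitter.
#' @return A `vasc_fit` with `params`, `rss` and methods `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @export
fit_vascularization <- function(x, n_multistarts = 9, seed = 1L) {
  stopifnot(inherits(x, "tac"))
  t <- frame_midpoints(x$schedule)
  v <- x$values
  vmax <- max(v, 1e-6)
  tpk <- t[which.max(v)] * 60          # seconds
  pq <- expand.grid(p = c(0.5, 1, 2), q = c(0.5, 1, 2))
  model <- function(par) {
    vasc_function(t, list(a1 = par[1], a2 = par[2], p = par[3], q = par[4],
                          A = par[5], B = par[6], t_star = par[7]))
  }
  resid_fn <- function(par) model(par) - v
  lower <- c(0, 1, 1e-2, 1e-2, -100, 1e-4, 0)
  upper <- c(50 * vmax, 36000, 20, 20, 100, 1e3, 5)
  starts <- with_seed(seed, {
    lapply(seq_len(n_multistarts), function(k) {
      i <- (k - 1L) %% nrow(pq) + 1L
      s <- c(a1 = vmax, a2 = max(tpk, 30), p = pq$p[i], q = pq$q[i],
             A = 0, B = 1, t_star = 0.25)
      if (k > nrow(pq))
        s <- s * exp(c(stats::runif(4, -0.2, 0.2), 0, stats::runif(1, -0.2, 0.2), 0))
      pmin(pmax(s, lower), upper)
    })
  })
  fits <- lapply(starts, function(p0) {
    tryCatch(minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                                upper = upper,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500, ftol = 1e-13, ptol = 1e-13)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("vascularization fit failed from every start")
  fits <- fits[ok]
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(rss)]]
  par <- stats::setNames(best$par, c("a1", "a2", "p", "q", "A", "B", "t_star"))
  structure(list(params = as.list(par), rss = min(rss), data = data.frame(
    time_min = t, value = v), region = x$region), class = "vasc_fit")
}

#' @export
coef.vasc_fit <- function(object, ...) unlist(object$params)

#' @export
predict.vasc_fit <- function(object, t_min = dense_grid_min(), ...) {
  vasc_function(t_min, object$params)
}

#' @export
fitted.vasc_fit <- function(object, ...) predict(object, object$data$time_min)

#' @export
residuals.vasc_fit <- function(object, ...) object$data$value - fitted(object)

#' @export
print.vasc_fit <- function(x, ...) {
  cat(sprintf("Vascularization-function fit (%s), RSS %.4g\n", x$region, x$rss))
  print(signif(unlist(x$params), 4))
  invisible(x)
}

#' @export
plot.vasc_fit <- function(x, ...) {
  g <- dense_grid_min()
  plot(x$data$time_min, x$data$value, xlab = "time (min)", ylab = "SUV",
       main = sprintf("%s TAC and fit", x$region), ...)
  lines(g, predict(x, g))
  invisible(x)
}

#' Time-to-peak of a fitted curve
#'
#' Argmax of the curve on the dense 1-s grid over the 30-min acquisition,
#' in minutes; ties resolved toward the earliest time.
#'
#' @param curve A function of time in minutes, or a dense
#'   `data.frame(time_min, value)` such as a [tac_ratio()] result.
#' @return Time-to-peak in minutes.
#' @export
compute_ttp <- function(curve) {
  s <- curve_samples(curve)
  s$time_min[which.max(s$value)]
}

#' Late slope of a fitted curve
#'
#' Ordinary-least-squares slope of the curve sampled on the dense grid
#' restricted to the 10-30 min window, reported per hour (SUV h^-1 for SUV
#' curves, h^-1 for ratio curves).
#'
#' @inheritParams compute_ttp
#' @param window Regression window in minutes.
#' @return Slope in units per hour.
#' @export
compute_slope <- function(curve, window = c(10, 30)) {
  s <- curve_samples(curve)
  s <- s[s$time_min >= window[1] & s$time_min <= window[2], , drop = FALSE]
  if (nrow(s) < 2L) stop("slope window contains fewer than 2 samples")
  stats::cov(s$time_min, s$value) / stats::var(s$time_min) * 60
}

#' Semiquantitative parameters of a fitted tumor TAC
#'
#' @param fit A `vasc_fit`.
#' @param window Slope window in minutes.
#' @return A list with `ttp` (min) and `slope` (SUV h^-1).
#' @export
sq_params <- function(fit, window = c(10, 30)) {
  f <- function(t) predict(fit, t)
  list(ttp = compute_ttp(f), slope = compute_slope(f, window))
}

#' Reference-normalised semiquantitative parameters
#'
#' Computes the tumor-to-healthy-brain ratio of the two fitted curves and
#' extracts its time-to-peak and late slope. The ratio is evaluated from
#' one minute after the later of the two fitted tracer-arrival times (both
#' curves are identically zero before arrival) to the end of acquisition.
#'
#' @param tumor_fit,reference_fit `vasc_fit` objects.
#' @param window Slope window in minutes.
#' @return A list with `ttp_ratio` (min) and `slope_ratio` (h^-1).
#' @export
ref_sq <- function(tumor_fit, reference_fit, window = c(10, 30)) {
  onset <- max(tumor_fit$params$t_star, reference_fit$params$t_star)
  from_s <- ceiling(onset * 60) + 60
  grid <- dense_grid_min(from_s = min(from_s, 540), to_s = 1800)
  ratio <- tac_ratio(function(t) predict(tumor_fit, t),
                     function(t) predict(reference_fit, t), grid)
  list(ttp_ratio = compute_ttp(ratio), slope_ratio = compute_slope(ratio, window))
}
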