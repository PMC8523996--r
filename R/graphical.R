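#' Logan-plot coordinates for a tumor TAC and plasma input
#'
#' At each frame midpoint \eqn{t_k}, computes
#' \eqn{y_k = \int_0^{t_k} C_T \, d\tau / C_T(t_k)} and
#' \eqn{x_k = \int_0^{t_k} C_p \, d\tau / C_T(t_k)}. The tumor integral is
#' trapezoidal on the measured grid augmented with an origin point (0, 0);
#' the continuous plasma input is integrated on the dense 1-s grid.
#'
#' @param tumor A `tac` on the uniform schedule, positive in the window.
#' @param plasma Function of time in minutes (the plasma FDOPA input).
#' @return A data frame with columns `t_min`, `x`, `y`.
#' @export
logan_transform <- function(tumor, plasma) {
  stopifnot(inherits(tumor, "tac"), is.function(plasma))
  t <- frame_midpoints(tumor$schedule)
  ct <- tumor$values
  int_ct <- cumtrapz(c(0, t), c(0, ct))[-1]
  g <- dense_grid_min()
  int_cp_grid <- cumtrapz(g, plasma(g))
  int_cp <- stats::approx(g, int_cp_grid, xout = t)$y
  data.frame(t_min = t, x = int_cp / ct, y = int_ct / ct)
}

#' Logan graphical fit
#'
#' OLS regression of the Logan coordinates over frames whose midpoint lies
#' in the regression window (closed interval). For a reversible tracer the
#' slope estimates the equilibrium volume of distribution.
#'
#' @param points Data frame from [logan_transform()] (columns `t_min`, `x`,
#'   `y`).
#' @param window Regression window in minutes (default 15-30).
#' @return A `logan_fit` with `ved` (slope), `int_logan` (intercept,
#'   minutes), `r_squared`, `n_points`, `window`.
#' @export
logan_fit <- function(points, window = c(15, 30)) {
  stopifnot(all(c("t_min", "x", "y") %in% names(points)))
  sel <- points$t_min >= window[1] & points$t_min <= window[2]
  if (sum(sel) < 3L) stop("Logan regression needs at least 3 points in the window")
  x <- points$x[sel]; y <- points$y[sel]
  if (stats::var(x) == 0) stop("degenerate Logan points: no spread in x")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  ssr <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  structure(list(ved = slope, int_logan = intercept, r_squared = r2,
                 n_points = sum(sel), window = window,
                 points = points[sel, , drop = FALSE]),
            class = "logan_fit")
}

#' @export
coef.logan_fit <- function(object, ...) {
  c(ved = object$ved, int_logan = object$int_logan)
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("Logan fit [%g, %g] min, %d points: Ved %.4g, intercept %.4g min (R^2 %.4f)\n",
              x$window[1], x$window[2], x$n_points, x$ved, x$int_logan,
              x$r_squared))
  invisible(x)
}

#' @export
plot.logan_fit <- function(x, ...) {
  plot(x$points$x, x$points$y, xlab = "normalised input integral",
       ylab = "normalised tissue integral", main = "Logan plot", ...)
  abline(x$int_logan, x$ved)
  invisible(x)
}

#' Reference-region Logan analysis
#'
#' Logan graphical analysis with the healthy-brain TAC replacing the plasma
#' input: \eqn{x_k = \int_0^{t_k} C_{ref} / C_T(t_k)},
#' \eqn{y_k = \int_0^{t_k} C_T / C_T(t_k)}, both trapezoidal with an origin
#' point. The slope is the distribution-volume ratio (DVR) and the negative
#' intercept the relative residence time (RRT, minutes). No population
#' efflux (k2') term is used: with a late regression onset its omitted-term
#' bias is absorbed into the intercept, itself reported as a parameter.
#'
#' @param tumor,reference `tac` objects on the same schedule.
#' @param window Regression window in minutes.
#' @return A `ref_logan_fit` with `dvr`, `rrt`, `r_squared`, `n_points`,
#'   `window`.
#' @export
ref_logan <- function(tumor, reference, window = c(15, 30)) {
  stopifnot(inherits(tumor, "tac"), inherits(reference, "tac"))
  if (!isTRUE(all.equal(tumor$schedule, reference$schedule)))
    stop("tumor and reference TACs must share a schedule")
  t <- frame_midpoints(tumor$schedule)
  ct <- tumor$values; cr <- reference$values
  sel_chk <- t >= window[1] & t <= window[2]
  if (any(ct[sel_chk] <= 0))
    stop(sprintf("non-positive tumor value at frame midpoint %.2f min",
                 t[sel_chk][which(ct[sel_chk] <= 0)[1]]))
  pts <- data.frame(t_min = t,
                    x = cumtrapz(c(0, t), c(0, cr))[-1] / ct,
                    y = cumtrapz(c(0, t), c(0, ct))[-1] / ct)
  lf <- logan_fit(pts, window)
  structure(list(dvr = lf$ved, rrt = -lf$int_logan, r_squared = lf$r_squared,
                 n_points = lf$n_points, window = window, points = lf$points),
            class = "ref_logan_fit")
}

#' @export
coef.ref_logan_fit <- function(object, ...) c(dvr = object$dvr, rrt = object$rrt)

#' @export
print.ref_logan_fit <- function(x, ...) {
  cat(sprintf("Reference Logan fit [%g, %g] min, %d points: DVR %.4g, RRT %.4g min (R^2 %.4f)\n",
              x$window[1], x$window[2], x$n_points, x$dvr, x$rrt, x$r_squared))
  invisible(x)
}

#' Full Logan analysis of a tumor TAC against a plasma input
#'
#' Convenience wrapper chaining [logan_transform()] and [logan_fit()], with
#' a positivity check on tumor values inside the window.
#'
#' @inheritParams logan_transform
#' @inheritParams logan_fit
#' @return A `logan_fit`.
#' @export
logan_analysis <- function(tumor, plasma, window = c(15, 30)) {
  t <- frame_midpoints(tumor$schedule)
  sel <- t >= window[1] & t <= window[2]
  if (any(tumor$values[sel] <= 0))
    stop(sprintf("non-positive tumor value at frame midpoint %.2f min",
                 t[sel][which(tumor$values[sel] <= 0)[1]]))
  logan_fit(logan_transform(tumor, plasma), window)
}
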