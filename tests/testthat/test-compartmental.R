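test_that("net influx rate follows its closed form and guards its domain", {
  expect_equal(compute_ki(tcm_params(0.1, 0.2, 0.2, 0.01)), 0.05)
  expect_equal(compute_ki(tcm_params(0.13, 0.4, 0, 0)), 0)
  expect_equal(compute_ki(list(K1 = 0.13, k2 = 0.4, k3 = 0.18)),
               0.13 * 0.18 / 0.58)
  expect_error(compute_ki(list(K1 = 0.1, k2 = 0, k3 = 0)), "k2 \\+ k3")
  expect_true(is.na(tcm_params(0.1, 0, 0, 0)$ki))
  expect_error(tcm_params(-0.1, 0.2, 0.1, 0.01), "non-negative")
})

test_that("forward model limits: no uptake, pure blood, pure trapping", {
  s <- make_schedule("input_function")
  zero <- tcm_forward(tcm_params(0, 0, 0, 0, 0), test_input, NULL, s)
  expect_equal(zero$values, rep(0, 33))
  # Vb = 1: measured signal is the frame-averaged blood curve; a linear
  # blood curve makes the trapezoidal frame average exact
  lin <- function(t) 1 + 2 * t
  vb1 <- tcm_forward(tcm_params(0, 0, 0, 0, 1), test_input, lin, s)
  mid <- frame_midpoints(s)
  expect_equal(vb1$values, lin(mid), tolerance = 1e-10)
  # theta = 0 with K1 > 0: the signal is K1 * int_0^t Cp = 0.1 (t + t^2),
  # whose frame average has the closed form below
  trap <- tcm_forward(tcm_params(0.1, 0, 0, 0, 0), lin, NULL, s)
  int_meas <- function(t) 0.1 * (t^2 / 2 + t^3 / 3)   # int of 0.1 (s + s^2)
  ends <- (s$frame_start_s + s$frame_duration_s) / 60
  starts <- s$frame_start_s / 60
  expect_equal(trap$values,
               (int_meas(ends) - int_meas(starts)) / (ends - starts),
               tolerance = 1e-7)
})

test_that("analytic forward solution matches an independent RK4 integrator", {
  s_if <- make_schedule("input_function")
  s_u <- make_schedule("uniform")
  cases <- list(
    list(p = tcm_params(0.13, 0.40, 0.18, 0.03, 0.05), s = s_if),
    list(p = tcm_params(0.08, 0.25, 0.13, 0.025, 0.04), s = s_u),
    list(p = tcm_params(0.05, 0.0625, 0, 0, 0.04), s = s_u))
  for (cs in cases) {
    ana <- tcm_forward(cs$p, test_input, test_input, cs$s)$values
    ora <- rk4_tcm_frames(cs$p, test_input, test_input, cs$s)
    expect_equal(ana, ora, tolerance = 1e-4)
  }
})

test_that("repeated-eigenvalue kinetics remain well conditioned", {
  # k3 = 0 and k2 = k4 makes theta^2 - 4 k2 k4 = (k2 - k4)^2 = 0
  p <- tcm_params(0.1, 0.2, 0, 0.2, 0)
  s <- make_schedule("uniform")
  ana <- tcm_forward(p, test_input, NULL, s)$values
  expect_true(all(is.finite(ana)))
  ora <- rk4_tcm_frames(p, test_input, test_input, s)
  expect_equal(ana, ora, tolerance = 1e-4)
})

test_that("forward model is linear in the plasma input at Vb = 0", {
  p <- tcm_params(0.12, 0.35, 0.1, 0.02, 0)
  s <- make_schedule("uniform")
  a <- tcm_forward(p, test_input, NULL, s)$values
  b <- tcm_forward(p, function(t) 2.5 * test_input(t), NULL, s)$values
  expect_equal(b, 2.5 * a, tolerance = 1e-12)
})

test_that("noiseless 2TCM fits recover the generating parameters within 2%", {
  truth <- tcm_params(0.13, 0.40, 0.18, 0.03, 0.05)
  s <- make_schedule("input_function")
  tum <- tcm_forward(truth, test_input, test_input, s)
  input <- list(plasma_fdopa = test_input, whole_blood = test_input)
  fit <- fit_tcm(tum, input, n_multistarts = 4, seed = 2)
  est <- coef(fit)
  for (nm in c("K1", "k2", "k3", "k4", "Vb"))
    expect_equal(est[[nm]], truth[[nm]], tolerance = 0.02)
  expect_equal(est[["Ki"]], compute_ki(truth), tolerance = 0.02)
  expect_true(fit$converged)
  # fit quality: weighted RSS essentially zero on noiseless data
  expect_lt(fit$wrss, 1e-10)
  # bitwise determinism across repeated calls
  fit2 <- fit_tcm(tum, input, n_multistarts = 4, seed = 2)
  expect_identical(coef(fit), coef(fit2))
})

test_that("fitting a one-tissue truth drives the binding rate to zero", {
  truth <- tcm_params(0.1, 0.25, 0, 0, 0.04)
  s <- make_schedule("input_function")
  tum <- tcm_forward(truth, test_input, test_input, s)
  fit <- fit_tcm(tum, list(plasma_fdopa = test_input,
                           whole_blood = test_input),
                 n_multistarts = 4, seed = 3)
  expect_equal(coef(fit)[["K1"]], 0.1, tolerance = 0.02)
  expect_equal(coef(fit)[["k2"]], 0.25, tolerance = 0.05)
  expect_lt(coef(fit)[["k3"]], 1e-3)
})

test_that("fit methods are mutually consistent", {
  truth <- tcm_params(0.1, 0.3, 0.12, 0.04, 0.05)
  s <- make_schedule("input_function")
  tum <- tcm_forward(truth, test_input, test_input, s)
  fit <- fit_tcm(tum, list(plasma_fdopa = test_input,
                           whole_blood = test_input),
                 n_multistarts = 2, seed = 1)
  expect_equal(fitted(fit) + residuals(fit), tum$values)
  expect_equal(length(coef(fit)), 6L)
  expect_output(print(fit), "Two-tissue")
})

test_that("Logan Ved on reversible 2TCM curves is consistent with the fit", {
  p <- tcm_params(0.13, 0.5, 0.1, 0.1, 0)
  vd <- (p$K1 / p$k2) * (1 + p$k3 / p$k4)
  s <- make_schedule("uniform")
  tum <- tcm_forward(p, test_input, NULL, s)
  lf <- logan_fit(logan_transform(tum, test_input))
  expect_equal(lf$ved, vd, tolerance = 0.1)
})
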