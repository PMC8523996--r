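---
title: "Kinetic models and numerical conventions in dynfdopa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models and numerical conventions in dynfdopa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `dynfdopa`, the default
constants with their units, and the numerical conventions that determine
the exact values the package produces. It is a methods reference, not a
tutorial; see the README for a worked example.

## Units and conventions

* On disk and in `frame_schedule` objects, frame timing is in **seconds**
  from injection. Everywhere in the mathematics, time is in **minutes**;
  rate constants are in min⁻¹; late slopes are reported in SUV·h⁻¹
  (per-minute OLS slope × 60).
* A TAC value is the **frame average** of the underlying continuous curve,
  conventionally plotted and regressed at the frame **midpoint**.
* Two 30-minute (1800 s) protocols are supported: `"input_function"`
  (12×5 s, 6×10 s, 6×30 s, 5×60 s, 4×300 s; 33 frames), used whenever an
  image-derived input function is needed, and `"uniform"` (30×60 s), used
  for the semiquantitative and graphical models.
* Continuous curves (fitted blood and vascularization functions, ratio
  curves) are evaluated on a dense 1-s grid (`dense_grid_min()`); curve
  summaries (time-to-peak, late slope) are defined on that grid.
* Every stochastic step (noise, parameter draws, multistart jitter) flows
  from an explicit seed through an RNG-state-preserving wrapper, so library
  calls never perturb the caller's random stream and identical seeds give
  byte-identical results.

## Input function

`fit_blood_tac` models the carotid blood TAC as a linear rise from zero at
injection to the peak, followed by a tri-exponential decay
$\sum_{i=1}^3 A_i e^{-\lambda_i (t - t_p)}$. The decay is fitted to the
frames strictly after the peak frame as **frame-averaged** tri-exponentials
(not point samples), by bounded Levenberg–Marquardt least squares with a
multistart over rate combinations and separable linear amplitude solves.
Continuity at the junction is enforced by construction: the last node of
the linear segment is placed at the fitted tri-exponential's value at the
peak-frame midpoint, so the piecewise curve has no jump.

The plasma ¹⁸F-FDopa input is then assembled by `build_plasma_input` as a
chain of three corrections (`if_config` holds the constants):

1. **Spill-out**: the measured carotid curve underestimates true blood
   activity because of partial-volume losses; the fitted curve is
   *divided* by the recovery coefficient (default 0.51).
2. **Whole blood → plasma**: division by (1 − hematocrit), default
   hematocrit 0.40. This is the standard stand-in when no subject-specific
   plasma-to-whole-blood ratio is measured.
3. **Metabolite correction**: multiplication by the parent fraction
   $f_{\mathrm{DOPA}}(t) = 1 - 0.36902735\,(2 - e^{-0.03915133 t} -
   e^{-0.03915214 t})$, with the complementary OMFD and other-metabolite
   fractions also exposed by `metabolite_fractions`. At $t = 0$ the parent
   fraction is exactly 1; its asymptote is 0.26194530.

## Semiquantitative models

`fit_vascularization` fits
$$\mathrm{SUV}(t) = a_0 + (a_1 - a_0)\,\frac{A + x^{p}}{B + x^{q}},
\qquad x = \frac{(t - t^*)\,}{a_2/60},$$
with $a_0$ fixed at 0 and $\mathrm{SUV}(t) = 0$ before the arrival time
$t^*$; $a_2$ is in seconds, $t$ and $t^*$ in minutes. Fitting uses bounded
multistart Levenberg–Marquardt over $(a_1, a_2, p, q, A, B, t^*)$ with a
grid of $(p, q)$ starting shapes.

From the fitted continuous curve, `sq_params` extracts:

* **TTP** — the argmax on the dense 1-s grid over [0, 30] min, earliest
  time on ties;
* **slope** — the OLS slope of the fitted curve over the closed window
  [10, 30] min on the dense grid, converted to SUV·h⁻¹.

`ref_sq` forms the ratio of the fitted tumor curve to the fitted
healthy-brain curve (`tac_ratio`) on a grid that starts late enough to
avoid the indeterminate pre-arrival region, and extracts the same two
summaries from the ratio curve (TTP ratio, slope ratio).

## Graphical models

`logan_analysis` computes, at each frame midpoint $t_k$ of the uniform
protocol,
$$y_k = \frac{\int_0^{t_k} C_T\,d\tau}{C_T(t_k)}, \qquad
  x_k = \frac{\int_0^{t_k} C_p\,d\tau}{C_T(t_k)},$$
and regresses $y$ on $x$ by OLS over the frames whose midpoints lie in the
closed window [15, 30] min. Design choices that pin down the numbers:

* the tumor integral is trapezoidal on the midpoint grid augmented with an
  origin point (0, 0);
* the continuous plasma input is integrated on the dense 1-s grid and
  interpolated to the midpoints;
* the slope is reported as the equilibrium distribution volume `ved`, the
  intercept in minutes as `int_logan`.

`ref_logan` replaces the plasma integral with the trapezoidal integral of
the healthy-brain TAC (same origin-augmented rule for both curves). The
slope is the distribution-volume ratio `dvr` and the negative intercept
the relative residence time `rrt`. **No population efflux (k2′) term is
used**: with a late regression onset the omitted-term contribution is
absorbed into the intercept, which is itself reported as a parameter
rather than treated as a nuisance.

## Compartmental model

`tcm_forward` solves the reversible two-tissue model
$$C_1' = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2, \qquad
  C_2' = k_3 C_1 - k_4 C_2$$
analytically: the impulse response is a sum of two exponentials with rates
$\alpha_{1,2} = \tfrac12\big[\theta \mp \sqrt{\theta^2 - 4 k_2 k_4}\big]$,
$\theta = k_2 + k_3 + k_4$, and the convolution with the input is computed
on a 0.1-s grid by a per-step recursion that is **exact for
piecewise-linear inputs** (no quadrature error beyond the input's linear
interpolation). Two edge cases are handled explicitly: $\theta = 0$
degenerates to a pure integrator $K_1 \int C_p$, and a (near-)repeated
eigenvalue ($\theta^2 - 4k_2k_4 \to 0$) is nudged by a relative $10^{-6}$
perturbation of $k_4$, far below fitting noise, to keep the
two-exponential form well conditioned. The measured signal is
$(1 - V_b)(C_1 + C_2) + V_b\,C_{\mathrm{blood}}$, frame-averaged via the
cumulative trapezoid of the dense curve.

`fit_tcm` estimates $(K_1, k_2, k_3, k_4, V_b)$ by weighted nonlinear
least squares with weights $\sqrt{\Delta_k / \sum_j \Delta_j}$ (frame
duration $\Delta_k$ — the standard inverse-variance proxy for
decay-corrected SUV data), box bounds (rates in [0, 5] min⁻¹, $V_b$ in
[0, 2]), and a seeded 10-start multistart (5 fixed physiological starts
plus jittered copies). The compartments are driven by the
metabolite-corrected plasma curve and the vascular term by the
spill-out-corrected whole-blood curve. The net influx rate
$K_i = K_1 k_3/(k_2 + k_3)$ is attached to every parameter set.

## Synthetic cohort

`generate_subject` draws subject-level kinetics from truncated-normal
distributions around genotype means (`group_kinetics`, CV 0.20 by
default), simulates the tumor under **both** protocols, the healthy brain
(one-tissue kinetics) under the uniform protocol, and the carotid blood
curve under the input-function protocol, then adds Gaussian noise with
variance proportional to activity over frame duration (`noise_model`,
default 5% at 1 SUV in a 60-s frame). The tissue curves are driven by the
exact analytic input implied by the blood shape and the default correction
chain, so re-estimating the input from the noisy blood TAC mirrors real
processing. Blood frame averages are computed in closed form, including
the frame straddling the peak.

The default scenario was calibrated **once** and then frozen: group mean
kinetics were chosen so that, noiselessly at the group means, the
wild-type tumor peaks early (fitted TTP ≈ 4.7 min) with a declining late
phase, the mutant curve keeps rising (fitted TTP ≈ 20–25 min), the fitted
TTPs straddle ~18 min, and distribution volumes are of realistic magnitude
(≈1.5–2). The default class sizes (14 mutant / 23 wild-type) are the study
conditions of the generator, not tunable targets.

## Statistical comparison

* `roc_analysis` builds the empirical ROC over all observed thresholds;
  the AUC is the trapezoidal area, identical to the all-pairs Mann–Whitney
  probability with ties counted one half. Orientation is chosen so
  AUC ≥ 0.5 and reported. The operating point is the threshold closest to
  (0, 1) in (FPR, TPR) space, ties broken toward higher sensitivity —
  reported cutoffs, sensitivities and accuracies depend on this rule.
  Confidence intervals are DeLong-variance normal intervals, clipped to
  [0, 1].
* `delong_test` is the paired DeLong test from placement-value
  covariances; the default alternative is one-sided superiority. When the
  variance estimate degenerates with equal AUCs, the one-sided p is 0.5
  (no evidence in either direction).
* `stepwise_glm` performs bidirectional stepwise selection minimizing AIC
  from the intercept-only model, one best move per iteration, with a
  binomial family by default ("general linear model" with a binary outcome
  is taken as logistic regression; a Gaussian-identity family is exposed
  for strict literal replication). Perfectly separated logistic fits are
  detected (IRLS warning or diverging coefficients) and refitted with a
  small fixed ridge penalty (λ = 0.01) so the search stays deterministic;
  AIC then uses the unpenalized log-likelihood at the penalized estimate.
  Note an intrinsic property of AIC-minimizing selection: each independent
  pure-noise predictor is admitted with probability
  P(χ²₁ > 2) ≈ 0.157, so the intercept-only model is retained in only
  ≈ 0.843ᵏ of pure-noise replicates with k candidates. This is a property
  of the criterion, not of the implementation.
* `bh_adjust` is the exact Benjamini–Hochberg step-up (via
  `p.adjust`). The adjustment never decreases a p-value and preserves
  ordering; it is *not* idempotent in general.
* Multivariable model AUCs in `run_full_comparison` are **in-sample**
  (no cross-validation is performed); the pairwise one-sided DeLong matrix
  is computed between the six models' fitted scores in both directions,
  with BH adjustment over the 30 off-diagonal entries.

## Problem sizes and runtime

The default study (37 subjects, all six models, full comparison) runs in
about 4 minutes on one CPU; a single subject's full analysis takes roughly
8 s, dominated by the multistart compartmental fit. The test suite
includes independent oracles — a fixed-step RK4 integrator for the
compartmental ODEs, brute-force enumerations for AUC, DeLong variance and
BH, and `pROC`/`stats::step` cross-checks — that pin the numerical claims
above.

## Limitations

* The hematocrit conversion is a population stand-in, not a measured
  plasma-to-whole-blood ratio.
* Logan estimates carry the usual noise-dependent underestimation bias;
  the package reports the window so users can assess onset sensitivity.
* Multivariable AUCs are optimistic (in-sample, stepwise-selected); the
  package reports them as such and makes no cross-validated claims.
* The synthetic generator is a kinetic stand-in for a clinical cohort; its
  defaults are fixed study conditions, and absolute discrimination numbers
  depend on them.
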