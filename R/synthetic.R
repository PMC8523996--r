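#' TAC-level noise model
#'
#' Gaussian noise whose variance follows the standard PET count-statistics
#' proxy at the TAC level: variance proportional to activity divided by
#' frame duration. `scale` is the relative noise at a reference activity of
#' 1 SUV in a 60-s frame, so e.g. `scale = 0.05` gives a 5% standard
#' deviation there, larger in short early frames and smaller in long late
#' frames.
#'
#' @param scale Relative noise scale, >= 0.
#' @return A `noise_model`.
#' @export
noise_model <- function(scale = 0.05) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0)
  structure(list(scale = scale), class = "noise_model")
}

noise_sd <- function(values, duration_s, nm) {
  if (nm$scale == 0) return(rep(0, length(values)))
  nm$scale * sqrt(pmax(values, 0.01) * 60 / duration_s)
}

add_tac_noise <- function(x, nm) {
  if (nm$scale == 0) return(x)
  sd <- noise_sd(x$values, x$schedule$frame_duration_s, nm)
  x$values <- x$values + stats::rnorm(length(sd), 0, sd)
  x
}

#' Blood-curve shape specification
#'
#' Analytic arterial blood curve: linear rise from zero at injection to
#' `peak_value` at `peak_time`, followed by a tri-exponential decay whose
#' amplitudes are `peak_value * fractions` (fractions summing to 1 keep the
#' curve continuous at the peak).
#'
#' @param peak_time_min Peak time in minutes (default 42.5 s).
#' @param peak_value Peak SUV of the measured (pre-spill-out-correction)
#'   carotid curve.
#' @param fractions Amplitude fractions of the three exponentials.
#' @param rates Decay rates in min^-1, positive.
#' @return A `blood_shape`.
#' @export
blood_shape <- function(peak_time_min = 42.5 / 60, peak_value = 12,
                        fractions = c(0.55, 0.30, 0.15),
                        rates = c(4, 0.5, 0.015)) {
  stopifnot(peak_time_min > 0, peak_time_min < 30, peak_value > 0,
            length(fractions) == 3L, length(rates) == 3L, all(rates > 0),
            all(fractions >= 0))
  fractions <- fractions / sum(fractions)
  structure(list(peak_time = peak_time_min, peak_value = peak_value,
                 amplitudes = peak_value * fractions, rates = rates),
            class = "blood_shape")
}

#' Pointwise evaluation of the analytic blood curve
#'
#' @param shape A [blood_shape()].
#' @return A function of time in minutes returning SUV values.
#' @export
blood_shape_fn <- function(shape) {
  force(shape)
  function(t) {
    out <- numeric(length(t))
    rise <- t >= 0 & t <= shape$peak_time
    out[rise] <- shape$peak_value * t[rise] / shape$peak_time
    post <- t > shape$peak_time
    if (any(post)) {
      tau <- t[post] - shape$peak_time
      out[post] <- drop(exp(-outer(tau, shape$rates)) %*% shape$amplitudes)
    }
    out
  }
}

# exact frame averages of the analytic blood curve
blood_frame_averages <- function(shape, schedule) {
  tp <- shape$peak_time; pv <- shape$peak_value
  A <- shape$amplitudes; lam <- shape$rates
  s <- schedule$frame_start_s / 60
  e <- (schedule$frame_start_s + schedule$frame_duration_s) / 60
  tri_int <- function(a, b) {   # int_a^b of tri-exp, a,b >= tp
    sum_terms <- 0
    for (i in 1:3) sum_terms <- sum_terms +
        A[i] / lam[i] * (exp(-lam[i] * (a - tp)) - exp(-lam[i] * (b - tp)))
    sum_terms
  }
  vapply(seq_along(s), function(j) {
    a <- s[j]; b <- e[j]
    int <- if (b <= tp) {
      pv * (b^2 - a^2) / (2 * tp)
    } else if (a >= tp) {
      tri_int(a, b)
    } else {
      pv * (tp^2 - a^2) / (2 * tp) + tri_int(tp, b)
    }
    int / (b - a)
  }, numeric(1))
}

#' Generate a synthetic blood TAC
#'
#' Frame averages of the analytic blood curve on a schedule, with optional
#' count-statistics noise.
#'
#' @param shape A [blood_shape()].
#' @param schedule A `frame_schedule` (default the short-early-frame
#'   protocol).
#' @param noise A [noise_model()].
#' @param seed Seed for the noise draw.
#' @return A `tac` with region `"blood"`.
#' @export
generate_blood_curve <- function(shape = blood_shape(),
                                 schedule = make_schedule("input_function"),
                                 noise = noise_model(0), seed = NULL) {
  stopifnot(inherits(shape, "blood_shape"))
  x <- tac(schedule, blood_frame_averages(shape, schedule), region = "blood")
  with_seed(seed, add_tac_noise(x, noise))
}

#' Group-dependent kinetic distributions
#'
#' Scenario parameters of the synthetic cohort: per-genotype means and a
#' common coefficient of variation for the two-tissue rate constants and
#' blood-volume fraction of the tumor, plus fixed one-tissue parameters for
#' the healthy-brain reference region. The defaults are chosen so that (at
#' the group means, noiselessly) the IDH-wild-type tumor curve peaks early
#' and declines in the late phase while the IDH-mutant curve keeps rising,
#' with fitted time-to-peak values straddling ~18 min.
#'
#' @param wild_type,mutant Named vectors (K1, k2, k3, k4, Vb) of group mean
#'   kinetics, min^-1 (Vb dimensionless).
#' @param cv Coefficient of variation of the subject-level parameter draws
#'   (truncated-normal, resampled until positive).
#' @param reference Named vector (K1, k2) of the one-tissue reference-region
#'   kinetics.
#' @return A `group_kinetics`.
#' @export
group_kinetics <- function(
    wild_type = c(K1 = 0.13, k2 = 0.30, k3 = 0.12, k4 = 0.050, Vb = 0.05),
    mutant    = c(K1 = 0.08, k2 = 0.25, k3 = 0.13, k4 = 0.025, Vb = 0.04),
    cv = 0.20,
    reference = c(K1 = 0.05, k2 = 0.0625)) {
  stopifnot(all(wild_type > 0), all(mutant > 0), cv >= 0, all(reference > 0))
  structure(list(wild_type = wild_type, mutant = mutant, cv = cv,
                 reference = reference), class = "group_kinetics")
}

draw_positive <- function(mean, cv) {
  if (cv == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, cv * mean)
    if (x > 0) return(x)
  }
}

#' Generate one synthetic subject
#'
#' Draws subject-level two-tissue parameters from the genotype's
#' distribution, simulates the tumor TAC under both temporal protocols and
#' the healthy-brain reference TAC (one-tissue kinetics) under the uniform
#' protocol, attaches a blood TAC on the short-early-frame protocol, and
#' labels the record by genotype. The tissue curves are driven by the
#' noiseless analytic plasma input implied by the blood shape and the
#' default correction chain, so that re-estimating the input from the blood
#' TAC mirrors the real processing.
#'
#' @param subject_id Character id.
#' @param group `"mutant"` or `"wild_type"`.
#' @param kinetics A [group_kinetics()].
#' @param noise A [noise_model()].
#' @param shape A [blood_shape()].
#' @param config An [if_config()] for the correction constants.
#' @param seed Seed controlling both the parameter draw and the noise.
#' @return A `subject_record` with attribute `"true_params"` (the drawn
#'   `tcm_params`).
#' @export
generate_subject <- function(subject_id, group = c("wild_type", "mutant"),
                             kinetics = group_kinetics(),
                             noise = noise_model(0.05),
                             shape = blood_shape(), config = if_config(),
                             seed = NULL) {
  group <- match.arg(group)
  with_seed(seed, {
    mu <- kinetics[[group]]
    p <- tcm_params(draw_positive(mu[["K1"]], kinetics$cv),
                    draw_positive(mu[["k2"]], kinetics$cv),
                    draw_positive(mu[["k3"]], kinetics$cv),
                    draw_positive(mu[["k4"]], kinetics$cv),
                    draw_positive(mu[["Vb"]], kinetics$cv))
    bf <- blood_shape_fn(shape)
    wb <- function(t) bf(t) / config$spill_out_coefficient
    cp <- function(t) wb(t) / (1 - config$hematocrit) *
      metabolite_fractions(pmax(t, 0))$f_dopa
    sched_if <- make_schedule("input_function")
    sched_u <- make_schedule("uniform")
    ref <- tcm_params(kinetics$reference[["K1"]], kinetics$reference[["k2"]],
                      0, 0, 0.04)
    tum_if <- tcm_forward(p, cp, wb, sched_if)
    tum_u <- tcm_forward(p, cp, wb, sched_u)
    brain <- tcm_forward(ref, cp, wb, sched_u)
    brain$region <- "brain_reference"
    blood <- tac(sched_if, blood_frame_averages(shape, sched_if), region = "blood")
    tacs <- lapply(list(tum_if, tum_u, brain, blood), add_tac_noise, nm = noise)
    rec <- subject_record(subject_id, idh_mutant = (group == "mutant"), tacs)
    attr(rec, "true_params") <- p
    rec
  })
}

#' Generate a synthetic cohort
#'
#' Reproducible cohort of subject records: per-subject seeds are derived
#' from the master seed, so the full cohort (and any file written from it)
#' is byte-identical across runs. The default class sizes (14 IDH-mutant /
#' 23 IDH-wild-type) mirror the per-class counts implied by the reported
#' sensitivities and specificities of the clinical cohort this generator
#' stands in for.
#'
#' @param n_mutant,n_wildtype Class sizes (>= 1 each for downstream ROC).
#' @inheritParams generate_subject
#' @param seed Master seed.
#' @return A list of `subject_record` objects (mutants first).
#' @export
generate_cohort <- function(n_mutant = 14, n_wildtype = 23,
                            kinetics = group_kinetics(),
                            noise = noise_model(0.05),
                            shape = blood_shape(), config = if_config(),
                            seed = 1L) {
  n <- n_mutant + n_wildtype
  stopifnot(n >= 1)
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  groups <- c(rep("mutant", n_mutant), rep("wild_type", n_wildtype))
  ids <- sprintf("S%03d", seq_len(n))
  lapply(seq_len(n), function(i)
    generate_subject(ids[i], groups[i], kinetics, noise, shape, config,
                     seed = subseeds[i]))
}
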