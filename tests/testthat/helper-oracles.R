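# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical machinery: fixed-step RK4 for the compartmental
# ODEs, explicit double loops for placement values, brute-force definitions
# for AUC and BH.

# Fixed-step RK4 integration of the two-tissue ODE system
#   C1' = K1 Cp - (k2+k3) C1 + k4 C2 ; C2' = k3 C1 - k4 C2
# followed by frame-averaging of (1-Vb)(C1+C2) + Vb Cb. h_s is the step in
# seconds. The one-step map of the linear system is precomputed so the loop
# stays scalar.
rk4_tcm_frames <- function(params, plasma, blood, schedule, h_s = 0.01) {
  p <- as.list(params)
  h <- h_s / 60
  end_min <- max(schedule$frame_start_s + schedule$frame_duration_s) / 60
  n <- round(end_min / h)
  A <- matrix(c(-(p$k2 + p$k3), p$k3, p$k4, -p$k4), 2, 2)
  I <- diag(2)
  M <- I + h * A + h^2 / 2 * A %*% A + h^3 / 6 * A %*% A %*% A +
    h^4 / 24 * A %*% A %*% A %*% A
  e1 <- c(p$K1, 0)
  # weights of cp(t_n), cp(t_n + h/2), cp(t_n + h) in the RK4 update
  W1 <- h / 6 * (I + h * A + h^2 / 2 * A %*% A + h^3 / 4 * A %*% A %*% A) %*% e1
  W2 <- h / 6 * (4 * I + 2 * h * A + h^2 / 2 * A %*% A) %*% e1
  W3 <- h / 6 * e1
  t0 <- (0:(n - 1)) * h
  cp0 <- plasma(t0); cph <- plasma(t0 + h / 2); cp1 <- plasma(t0 + h)
  d1 <- W1[1] * cp0 + W2[1] * cph + W3[1] * cp1
  d2 <- W1[2] * cp0 + W2[2] * cph + W3[2] * cp1
  c1 <- numeric(n + 1); c2 <- numeric(n + 1)
  m11 <- M[1, 1]; m12 <- M[1, 2]; m21 <- M[2, 1]; m22 <- M[2, 2]
  y1 <- 0; y2 <- 0
  for (i in seq_len(n)) {
    t1 <- m11 * y1 + m12 * y2 + d1[i]
    y2 <- m21 * y1 + m22 * y2 + d2[i]
    y1 <- t1
    c1[i + 1] <- y1; c2[i + 1] <- y2
  }
  tg <- (0:n) * h
  meas <- (1 - p$Vb) * (c1 + c2) + p$Vb * blood(tg)
  M_int <- c(0, cumsum(diff(tg) * (meas[-length(meas)] + meas[-1]) / 2))
  i0 <- round(schedule$frame_start_s / 60 / h) + 1L
  i1 <- round((schedule$frame_start_s + schedule$frame_duration_s) / 60 / h) + 1L
  (M_int[i1] - M_int[i0]) / (schedule$frame_duration_s / 60)
}

# all-pairs Mann-Whitney AUC (ties count one half), by explicit loops
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# DeLong variance of the paired AUC difference via explicit placement-value
# enumeration (structural components), no vectorized shortcuts
delong_var_bruteforce <- function(a, b, labels) {
  ia <- which(labels); ib <- which(!labels)
  m <- length(ia); n <- length(ib)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  v10 <- function(s) vapply(ia, function(i)
    mean(vapply(ib, function(j) psi(s[i], s[j]), numeric(1))), numeric(1))
  v01 <- function(s) vapply(ib, function(j)
    mean(vapply(ia, function(i) psi(s[i], s[j]), numeric(1))), numeric(1))
  va10 <- v10(a); vb10 <- v10(b); va01 <- v01(a); vb01 <- v01(b)
  cv <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  (cv(va10, va10) + cv(vb10, vb10) - 2 * cv(va10, vb10)) / m +
    (cv(va01, va01) + cv(vb01, vb01) - 2 * cv(va01, vb01)) / n
}

# Benjamini-Hochberg step-up by direct definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# simple deterministic synthetic subject for pipeline tests
make_test_subject <- function(id = "T1", group = "wild_type", noise = 0,
                              seed = 11) {
  generate_subject(id, group, noise = noise_model(noise), seed = seed)
}

# analytic plasma-like test input: smooth bolus plus slow tail, zero at t = 0
test_input <- function(t) {
  tt <- pmax(t, 0)
  30 * tt * exp(-2 * tt) + 2 * (1 - exp(-1.5 * tt)) * exp(-0.02 * tt)
}
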