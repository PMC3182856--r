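# Independent fixed-step RK4 oracle. The right-hand side below is written
# from scratch against the model equations and shares no code with the
# package's R or C++ implementations; it is the reference the adaptive
# integrator is checked against.

# y = c(OP, G, R, Ap, U, Aout, C_R, C_G, Y), p = plain named list
oracle_rhs <- function(y, p, variant, ko_op, ko_R, ko_K) {
  OP <- y[1]; G <- y[2]; R <- y[3]; Ap <- y[4]; Aout <- y[6]
  CR <- y[7]; CG <- y[8]; Y <- y[9]
  has_reg <- variant != "first"
  k5e <- if (variant == "reg_binding") p$k5 else 0
  if (ko_R) R <- 0
  if (ko_K) Ap <- 0
  if (!has_reg) G <- 0

  hillR <- if (R > 0) 1 / (1 + (R / p$k1)^p$nOP) else 1
  hillG <- if (has_reg && G > 0) 1 / (1 + (G / p$k4)^p$nG) else 1
  P <- p$k_op * hillR * hillG
  hillRR <- if (R > 0) 1 / (1 + (R / p$k2)^p$nR) else 1
  imp <- (p$k_imp * OP + p$k_f) * Aout

  c(
    (if (ko_op) 0 else P) - p$k_deg * OP,
    if (has_reg) (if (ko_op) 0 else P) - p$k_deg * G - k5e * G * Ap else 0,
    if (ko_R) 0 else p$k_r * hillRR - p$k_deg * R - p$k3 * R * Ap,
    if (ko_K) 0 else imp - p$k3 * R * Ap - k5e * G * Ap,
    if (ko_K) imp else 0,
    -imp,
    p$k3 * R * Ap - p$k_deg * CR,
    if (has_reg) k5e * G * Ap - p$k_deg * CG else 0,
    P - p$k_deg * Y
  )
}

# classic RK4 with fixed step dt, sampled at `times`; returns matrix like
# integrate_timecourse()$states
rk4_oracle <- function(params, variant = "reg_binding",
                       knockouts = character(0), dose = 0,
                       times = seq(0, 500, by = 1), dt = 0.01, y0 = NULL) {
  p <- unclass(as_kinetic_params(params))
  ko <- c("lsr_operon", "lsrR", "lsrK") %in% knockouts
  y <- if (is.null(y0)) c(0, 0, 0, 0, 0, dose, 0, 0, 0) else as.numeric(y0)
  out <- matrix(NA_real_, length(times), 9,
                dimnames = list(NULL, c("OP", "G", "R", "Ap", "U", "Aout",
                                        "C_R", "C_G", "Y")))
  f <- function(y) oracle_rhs(y, p, variant, ko[1], ko[2], ko[3])
  t <- times[1]
  out[1, ] <- y
  for (j in seq_along(times)[-1]) {
    span <- times[j] - t
    n <- max(1L, ceiling(span / dt))
    h <- span / n
    for (s in seq_len(n)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- times[j]
    out[j, ] <- y
  }
  out
}
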