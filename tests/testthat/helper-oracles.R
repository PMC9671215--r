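# Independent oracles kept deliberately separate from the package internals.

# Structure factor, transcribed independently of evaluate_model()
oracle_structure_factor <- function(r, S0, k, D, delta, alpha, baseline) {
  phase <- pi * r / (D * (1 + delta * r))
  baseline + S0 * exp(-k * r) * (abs(sin(phase)))^alpha
}

# FWHM of |sin(pi x / D)|^alpha by root bracketing (independent of the
# closed form used in dense_layer_thickness)
oracle_fwhm <- function(D, alpha) {
  f <- function(x) abs(sin(pi * x / D))^alpha - 0.5
  left <- uniroot(f, c(1e-9, D / 2), tol = 1e-12)$root
  right <- uniroot(f, c(D / 2, D - 1e-9), tol = 1e-12)$root
  right - left
}

# Intensity-weighted cumulants of a discrete diffusivity mixture
oracle_cumulants <- function(weights, diffusion, q) {
  w <- weights / sum(weights)
  m1 <- sum(w * diffusion) * q^2
  m2 <- (sum(w * diffusion^2) - sum(w * diffusion)^2) * q^4
  list(mu1 = m1, mu2 = m2, pdi = 1 + m2 / m1^2)
}

# Brute-force nonlinear fit of g2 = 1 + beta*exp(-2 mu1 t + mu2 t^2)
oracle_cumulant_nls <- function(lags, g2, beta, mu1_init) {
  obj <- function(p) {
    pred <- 1 + beta * exp(-2 * p[1] * lags + p[2] * lags^2)
    sum((pred - g2)^2)
  }
  optim(c(mu1_init, 0), obj, method = "BFGS",
        control = list(reltol = 1e-14, maxit = 2000))$par
}

expected_label <- c(A1 = "A1_compact", A2 = "A2_core_shell", B = "B_hollow")
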