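# Independent oracles and shared fixtures.
#
# `oracle_rhs()` re-derives the coupled balances from scratch, term by
# term (property correlations, dimensionless groups, saturation quartic,
# Arrhenius surface humidity, mass and energy balances), deliberately not
# calling any package function, so that `oracle_rk4()` is an independent
# fixed-step integrator against which the adaptive solver is checked.

oracle_rhs <- function(X, T_K, amb, cf, X_b, z_max, m_s,
                       l0, l1, a0, a1, cp_fn, dHv_fn, norm = amb) {
  L <- l0 + l1 * X
  A <- a0 + a1 * X
  Tf <- (amb$T_b + T_K) / 2
  rho <- 101325 / (287.058 * Tf)
  mu <- 1.458e-6 * Tf^1.5 / (Tf + 110.4)
  k <- 0.02624 * (Tf / 300)^0.8646
  D <- 2.26e-5 * (Tf / 273.15)^1.81
  cpa <- 1002.5 + 2.75e-4 * (Tf - 200)^2
  Re <- rho * amb$u * L / mu
  Sc <- mu / (rho * D)
  Pr <- mu * cpa / k
  h_m <- 0.511 * Re^0.5 * Sc^0.37 * D / L
  h <- 0.511 * Re^0.5 * Pr^0.37 * k / L
  z <- min(X - X_b, z_max)
  dER <- cf[1] * z^3 + cf[2] * z^2 + cf[3] * z + cf[4]
  dER <- min(max(dER, 0), 1)
  dEvb <- -8.314 * norm$T_b * log(norm$RH_b)
  x <- T_K - 273
  rvsat <- 4.844e-9 * x^4 - 1.4807e-7 * x^3 + 2.6572e-5 * x^2 -
    4.8613e-5 * x + 8.342e-3
  xb <- amb$T_b - 273
  rvsatb <- 4.844e-9 * xb^4 - 1.4807e-7 * xb^3 + 2.6572e-5 * xb^2 -
    4.8613e-5 * xb + 8.342e-3
  RHs <- exp(-dER * dEvb / (8.314 * T_K))
  dX <- -h_m * A * (RHs * rvsat - amb$RH_b * rvsatb) / m_s
  dT <- (h * A * (amb$T_b - T_K) + m_s * dX * dHv_fn(T_K)) /
    (m_s * (1 + X) * cp_fn(X))
  c(dX, dT)
}

# Fixed-step classical RK4 over [0, t_end] under a constant ambient.
oracle_rk4 <- function(y0, t_end, dt, amb, model, material, geometry) {
  f <- function(y) oracle_rhs(y[1], y[2], amb, model$coeffs, model$X_b,
                              model$z_range[2], material$m_s,
                              geometry$shrink_L[1], geometry$shrink_L[2],
                              geometry$shrink_A[1], geometry$shrink_A[2],
                              material$cp_fn, material$dHv_fn)
  y <- y0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

eval_cubic <- function(cf, z) cf[1] * z^3 + cf[2] * z^2 + cf[3] * z + cf[4]

# Trapezoidal evaporative-flux integral of a simulated curve, phase by
# phase (the integrand is discontinuous at phase boundaries; the boundary
# sample is re-evaluated under the incoming phase's ambient).
flux_integral <- function(curve) {
  geo <- attr(curve, "geometry")
  mat <- attr(curve, "material")
  mod <- attr(curve, "model")
  pt <- attr(curve, "phase_table")
  sch <- attr(curve, "schedule")
  total <- 0
  for (i in seq_len(nrow(pt))) {
    amb <- sch$phases[[i]]$ambient
    rows <- which(curve$t_s >= pt$t_start[i] & curve$t_s <= pt$t_end[i])
    if (length(rows) < 2L) next
    # re-evaluate the flux at every sample under this phase's ambient
    # (a boundary sample's stored diagnostics belong to the phase it
    # closes, and the integrand jumps at the ambient switch)
    g <- vapply(rows, function(j) {
      st <- sample_state(max(curve$X_db[j], 0), curve$T_K[j], curve$t_s[j])
      rea_diagnostics(st, amb, mod, mat, geo)$flux
    }, numeric(1))
    tt <- curve$t_s[rows]
    total <- total + sum(diff(tt) * (head(g, -1) + tail(g, -1)) / 2)
  }
  total
}

# Shorthand fixtures used across files.
default_world <- function() {
  list(model = soybean_fingerprint(), material = soybean_material(),
       geometry = soybean_geometry(), dry = drying_ambient(),
       temp = tempering_ambient())
}

sup_vs_truth <- function(fitted_model, truth_model, z_lo, z_hi) {
  zg <- seq(z_lo, z_hi, length.out = 200)
  max(abs(eval_cubic(fitted_model$coeffs, zg) -
            eval_cubic(truth_model$coeffs, zg)))
}
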