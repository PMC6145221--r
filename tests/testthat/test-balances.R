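test_that("mass balance vanishes at zero driving force and is linear in A", {
  w <- default_world()
  # dE_R = 1 at the bulk temperature makes the surface humidity equal the
  # bulk humidity, so the driving force is exactly zero
  const <- activation_energy_model(c(0, 0, 0, 1), X_b = 0.06)
  st <- sample_state(0.20, 308.15)
  expect_equal(mass_balance_rhs(st, w$dry, const, w$material, w$geometry), 0,
               tolerance = 1e-18)

  # doubling the exchange area doubles the rate exactly
  g1 <- w$geometry
  g2 <- grain_geometry(g1$axes0, g1$n_grains, g1$shrink_L, 2 * g1$shrink_A)
  st <- sample_state(0.20, 300)
  r1 <- mass_balance_rhs(st, w$dry, w$model, w$material, g1)
  r2 <- mass_balance_rhs(st, w$dry, w$model, w$material, g2)
  expect_lt(r1, 0)
  expect_equal(r2 / r1, 2, tolerance = 1e-12)
})

test_that("mass balance matches an independent hand-chained evaluation", {
  w <- default_world()
  st <- sample_state(w$material$X0, w$material$T0)  # t = 0 of default run
  got <- mass_balance_rhs(st, w$dry, w$model, w$material, w$geometry)
  want <- oracle_rhs(st$X, st$T, w$dry, w$model$coeffs, w$model$X_b,
                     w$model$z_range[2], w$material$m_s,
                     w$geometry$shrink_L[1], w$geometry$shrink_L[2],
                     w$geometry$shrink_A[1], w$geometry$shrink_A[2],
                     w$material$cp_fn, w$material$dHv_fn)[1]
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(got, 0)  # drying at the initial state
})

test_that("energy balance has the right equilibria and signs", {
  w <- default_world()
  st_eq <- sample_state(0.2, 308.15)
  expect_equal(energy_balance_rhs(st_eq, w$dry, 0, w$material, w$geometry), 0)
  st_cold <- sample_state(0.2, 298.15)
  expect_gt(energy_balance_rhs(st_cold, w$dry, 0, w$material, w$geometry), 0)
  # evaporation cools
  r_dry <- energy_balance_rhs(st_eq, w$dry, -1e-5, w$material, w$geometry)
  expect_lt(r_dry, 0)
  # the expanded form differs from the simplified one but only slightly
  # at a small drying rate
  r_s <- energy_balance_rhs(st_cold, w$dry, -1e-6, w$material, w$geometry)
  r_e <- energy_balance_rhs(st_cold, w$dry, -1e-6, w$material, w$geometry,
                            expanded = TRUE)
  expect_false(isTRUE(all.equal(r_s, r_e)))
  expect_lt(abs(r_s - r_e) / abs(r_s), 0.2)
})

test_that("with latent heat disabled, T(t) is Newtonian heating", {
  # a scenario engineered for constant properties: constant cp, constant
  # geometry, near-zero vapor exchange (very dry air + dE_R = 1), dHv = 0
  amb <- ambient_state(308.15, 0.001, 3)
  material <- material_props(m_s = 0.024, X0 = 0.25, T0 = 306.15,
                             X_b = 0.05, cp_fn = function(X) 2000,
                             dHv_fn = function(T) 0)
  geometry <- grain_geometry(c(7.2e-3, 6.3e-3, 5.5e-3), 1,
                             shrink_L = c(6.3e-3, 0),
                             shrink_A = c(7.8e-4, 0))
  const <- activation_energy_model(c(0, 0, 0, 1), X_b = 0.05)
  sch <- drying_schedule(list(schedule_phase("drying", 3600, amb)))
  cv <- simulate_drying(sch, const, material, geometry)

  # closed form at constant properties, h evaluated at the mean film
  # temperature of the run
  m_cp <- material$m_s * 1.25 * 2000
  Tf <- 0.5 * (amb$T_b + mean(cv$T_K))
  h <- transfer_coefficients(amb, 6.3e-3, T_film = Tf)$h
  closed <- amb$T_b - (amb$T_b - 306.15) * exp(-h * 7.8e-4 * cv$t_s / m_cp)
  expect_lt(max(abs(cv$T_K - closed)), 0.05)
  # and essentially no moisture change occurred
  expect_lt(abs(cv$X_db[nrow(cv)] - 0.25), 1e-4)
})
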