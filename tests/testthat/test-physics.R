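test_that("rho_v_sat reproduces the printed quartic and its domain", {
  # at 273 K every power of (T - 273) vanishes, leaving the constant term
  expect_identical(rho_v_sat(273), 8.342e-3)

  # term-by-term evaluation of the printed quartic as the oracle
  x <- 25
  byhand <- 4.844e-9 * x^4 - 1.4807e-7 * x^3 + 2.6572e-5 * x^2 -
    4.8613e-5 * x + 8.342e-3
  expect_equal(rho_v_sat(298), byhand, tolerance = 1e-14)
  expect_equal(rho_v_sat(298), 0.02331, tolerance = 1e-3)

  # tabulated saturation vapor density of water at 35 degC
  expect_lt(abs(rho_v_sat(308) - 0.0396) / 0.0396, 0.05)

  expect_error(rho_v_sat(272), "valid")
  expect_error(rho_v_sat(431), "valid")
})

test_that("rho_v_sat is strictly increasing and tracks steam tables", {
  # the printed quartic has a shallow negative slope right at its 273 K
  # origin (the linear coefficient is negative) and only turns increasing
  # near 274 K; monotonicity is asserted on the physically used range
  Tg <- seq(275, 430, length.out = 500)
  expect_true(all(diff(rho_v_sat(Tg)) > 0))

  # saturation vapor densities of water, kg/m^3 (standard steam tables);
  # the printed quartic holds to 5 % only above about 288 K -- below that
  # it degrades rapidly (72 % high at 273 K), so the check covers the
  # range where the correlation is actually usable
  tbl <- data.frame(
    T_K = c(288.15, 293.15, 298.15, 303.15, 313.15, 323.15, 333.15,
            343.15, 353.15, 363.15),
    rho = c(0.01283, 0.01729, 0.02308, 0.03037, 0.05116, 0.0830, 0.1302,
            0.1982, 0.2933, 0.4235))
  expect_true(all(abs(rho_v_sat(tbl$T_K) - tbl$rho) / tbl$rho < 0.05))
})

test_that("rho_v_bulk follows the bulk-humidity identity", {
  expect_identical(rho_v_bulk(list(T_b = 298, RH_b = 0)), 0)
  expect_equal(rho_v_bulk(list(T_b = 298, RH_b = 1)), rho_v_sat(298))
  expect_equal(rho_v_bulk(ambient_state(308.15, 0.20, 3)),
               0.20 * rho_v_sat(308.15))
  expect_error(rho_v_bulk(list(T_b = 298, RH_b = 1.2)), "RH_b")
})

test_that("air properties match standard dry-air tables at 300 K", {
  ap <- air_properties(300)
  expect_lt(abs(ap$rho - 1.1614) / 1.1614, 0.02)
  expect_lt(abs(ap$k - 0.0263) / 0.0263, 0.02)
  expect_lt(abs(ap$mu - 1.846e-5) / 1.846e-5, 0.02)
  expect_lt(abs(ap$cp_air - 1007) / 1007, 0.02)
  expect_gt(air_properties(350)$mu, air_properties(300)$mu)
  expect_error(air_properties(250), "270")
})

test_that("transfer coefficients follow the Sh/Nu correlations", {
  expect_equal(sherwood_number(100, 1), 5.11)
  expect_equal(nusselt_number(100, 1), 5.11)
  # with Sc = Pr the two correlations coincide exactly
  expect_identical(sherwood_number(123.4, 0.71), nusselt_number(123.4, 0.71))

  amb <- ambient_state(308.15, 0.20, 3)
  tc <- transfer_coefficients(amb, L = 6e-3)
  ap <- air_properties(308.15)
  expect_equal(tc$Re, ap$rho * 3 * 6e-3 / ap$mu, tolerance = 1e-7)
  expect_equal(tc$Sh, 0.511 * tc$Re^0.5 * tc$Sc^0.37, tolerance = 1e-12)
  expect_equal(tc$h_m, tc$Sh * ap$D / 6e-3, tolerance = 1e-12)
  expect_equal(tc$h, tc$Nu * ap$k / 6e-3, tolerance = 1e-12)

  # doubling the air speed scales both coefficients by sqrt(2) exactly
  tc2 <- transfer_coefficients(ambient_state(308.15, 0.20, 6), L = 6e-3)
  expect_equal(tc2$h / tc$h, sqrt(2), tolerance = 1e-12)
  expect_equal(tc2$h_m / tc$h_m, sqrt(2), tolerance = 1e-12)

  expect_error(transfer_coefficients(ambient_state(308.15, 0.2, 0), 6e-3),
               "still air")
})

test_that("ambient_state validates its invariants", {
  expect_error(ambient_state(250, 0.2, 3), "273")
  expect_error(ambient_state(308, 0, 3), "0, 1")
  expect_error(ambient_state(308, 1.1, 3), "0, 1")
  expect_error(ambient_state(308, 0.2, -1), "non-negative")
})
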