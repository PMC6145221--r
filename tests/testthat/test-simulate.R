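test_that("a zero-duration schedule yields only the initial state", {
  w <- default_world()
  cv <- simulate_drying(drying_schedule(list()), w$model, w$material,
                        w$geometry)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$t_s, 0)
  expect_equal(cv$X_db, w$material$X0)
  expect_equal(cv$T_K, w$material$T0)
})

test_that("adaptive trajectories agree with the fixed-step RK4 oracle", {
  w <- default_world()
  sch <- drying_schedule(list(schedule_phase("drying", 3600, w$dry)))
  cv <- simulate_drying(sch, w$model, w$material, w$geometry)
  y_rk4 <- oracle_rk4(c(w$material$X0, w$material$T0), 3600, dt = 0.1,
                      w$dry, w$model, w$material, w$geometry)
  n <- nrow(cv)
  expect_lt(abs(cv$X_db[n] - y_rk4[1]), 1e-4)
  expect_lt(abs(cv$T_K[n] - y_rk4[2]), 0.01)
})

test_that("the surface-vapor identity holds at every output sample", {
  w <- default_world()
  sch <- build_periodic_schedule(1200, 1800, w$dry, w$temp, max_total = 12000)
  cv <- simulate_drying(sch, w$model, w$material, w$geometry)
  expect_equal(cv$rho_v_s, cv$RH_s * cv$rho_v_sat, tolerance = 1e-14)
  expect_true(all(cv$RH_s > 0 & cv$RH_s <= 1))
})

test_that("moisture is conserved against the integrated evaporative flux", {
  w <- default_world()
  for (tt in list(c(1800, 0), c(1200, 1800))) {
    sch <- build_periodic_schedule(tt[1], tt[2], w$dry, w$temp,
                                   max_total = 4e5)
    cv <- simulate_drying(sch, w$model, w$material, w$geometry,
                          solver_control(stop_at_X = 0.134))
    lost <- w$material$m_s * (cv$X_db[1] - cv$X_db[nrow(cv)])
    expect_lt(abs(flux_integral(cv) - lost) / lost, 0.005)
  }
})

test_that("constant-ambient drying is strictly monotone and bounded", {
  w <- default_world()
  sch <- drying_schedule(list(schedule_phase("drying", 20000, w$dry)))
  cv <- simulate_drying(sch, w$model, w$material, w$geometry)
  expect_true(all(diff(cv$X_db) < 0))
  expect_lt(max(cv$T_K), max(w$material$T0, w$dry$T_b) + 1e-9)
})

test_that("a long constant-ambient run settles where dE_R reaches 1", {
  w <- default_world()
  # bisection-style oracle: the root of dE_R(z) = 1 just below z = 0
  zstar <- uniroot(function(z) eval_cubic(w$model$coeffs, z) - 1,
                   c(-0.01, 0), tol = 1e-10)$root
  sch <- drying_schedule(list(schedule_phase("drying", 3e5, w$dry)))
  cv <- simulate_drying(sch, w$model, w$material, w$geometry,
                        solver_control(dt_out = 600))
  x_end <- cv$X_db[nrow(cv)]
  expect_lt(abs(x_end - w$model$X_b), 0.005)
  expect_lt(abs(x_end - (w$model$X_b + zstar)), 1e-3)
})

test_that("tempering raises the surface humidity relative to drying", {
  w <- default_world()
  sch <- build_periodic_schedule(1800, 1800, w$dry, w$temp, max_total = 4e5)
  cv <- simulate_drying(sch, w$model, w$material, w$geometry,
                        solver_control(stop_at_X = 0.134))
  pt <- attr(cv, "phase_table")
  tp <- pt[pt$kind == "tempering", , drop = FALSE]
  expect_gt(nrow(tp), 3)
  for (i in seq_len(nrow(tp))) {
    # the boundary sample closes the preceding drying phase
    rs_start <- cv$RH_s[which.min(abs(cv$t_s - tp$t_start[i]))]
    rows <- which(cv$t_s > tp$t_start[i] & cv$t_s <= tp$t_end[i])
    if (!length(rows)) next
    expect_gt(cv$RH_s[max(rows)], rs_start)
  }
})

test_that("temperature never exceeds the hottest boundary condition", {
  w <- default_world()
  sch <- build_periodic_schedule(600, 1800, w$dry, w$temp, max_total = 24000)
  cv <- simulate_drying(sch, w$model, w$material, w$geometry)
  expect_lt(max(cv$T_K), max(w$material$T0, w$dry$T_b, w$temp$T_b) + 1e-9)
})

test_that("stopping below the equilibrium moisture is rejected", {
  w <- default_world()
  sch <- drying_schedule(list(schedule_phase("drying", 100, w$dry)))
  expect_error(
    simulate_drying(sch, w$model, w$material, w$geometry,
                    solver_control(stop_at_X = 0.01)),
    "never be reached")
})

test_that("fixed-equilibrium normalization is available and differs", {
  w <- default_world()
  sch <- build_periodic_schedule(1200, 1800, w$dry, w$temp, max_total = 9000)
  cv_pp <- simulate_drying(sch, w$model, w$material, w$geometry,
                           solver_control(renormalize_per_phase = TRUE))
  cv_fx <- simulate_drying(sch, w$model, w$material, w$geometry,
                           solver_control(renormalize_per_phase = FALSE))
  # identical during the first drying phase, different during tempering
  i_dry <- cv_pp$phase == "drying" & cv_pp$t_s <= 1200
  expect_equal(cv_pp$X_db[i_dry], cv_fx$X_db[i_dry], tolerance = 1e-9)
  i_tmp <- which(cv_pp$phase == "tempering")
  expect_false(isTRUE(all.equal(cv_pp$RH_s[i_tmp], cv_fx$RH_s[i_tmp])))
})
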