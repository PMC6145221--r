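# Coupled REA mass/energy balances and the forward simulation.
#
# State vector y = c(X, T): dry-basis moisture (kg/kg) and lumped sample
# temperature (K, taken as the surface temperature). Integration uses an
# embedded Dormand-Prince 5(4) pair with PI-free step control and cubic
# Hermite dense output; phase boundaries are hard restarts.

#' Sample state
#'
#' @param X Moisture content, kg/kg dry basis (non-negative).
#' @param T_K Lumped sample temperature (surface temperature), K.
#' @param t Elapsed time, s.
#' @return An object of class `"sample_state"` with fields `X`, `T`, `t`.
#' @export
sample_state <- function(X, T_K, t = 0) {
  if (!is.numeric(X) || length(X) != 1L || !is.finite(X) || X < 0)
    stop("`X` must be a single non-negative moisture content", call. = FALSE)
  if (!is.numeric(T_K) || length(T_K) != 1L || T_K < 273 || T_K > 430)
    stop("`T_K` must lie in [273, 430] K", call. = FALSE)
  structure(list(X = X, T = T_K, t = t), class = "sample_state")
}

# Single-point evaluation of everything the balances need. `norm_ambient`
# is the ambient used to scale the fingerprint back to an absolute
# activation energy (per-phase by default; a fixed reference ambient when
# renormalize_per_phase = FALSE).
.rea_point <- function(X, T_K, ambient, model, material, geometry,
                       norm_ambient = ambient) {
  L <- geometry$shrink_L[1] + geometry$shrink_L[2] * X
  A <- geometry$shrink_A[1] + geometry$shrink_A[2] * X
  Tf <- 0.5 * (ambient$T_b + T_K)
  ap <- .air_props(Tf)
  Re <- ap$rho * ambient$u * L / ap$mu
  Sc <- ap$mu / (ap$rho * ap$D)
  Pr <- ap$mu * ap$cp_air / ap$k
  h_m <- 0.511 * sqrt(Re) * Sc^0.37 * ap$D / L
  h <- 0.511 * sqrt(Re) * Pr^0.37 * ap$k / L
  dEvb <- -R_GAS * norm_ambient$T_b * log(norm_ambient$RH_b)
  der <- .dER_balance(model, X)
  dEv <- der$value * dEvb
  rvsat <- rho_v_sat(T_K)
  RH_s <- exp(-dEv / (R_GAS * T_K))
  rho_vs <- RH_s * rvsat
  rho_vb <- ambient$RH_b * rho_v_sat(ambient$T_b)
  flux <- h_m * A * (rho_vs - rho_vb)  # kg water/s, > 0 when evaporating
  list(L = L, A = A, h = h, h_m = h_m, dEvb = dEvb, dER = der$value,
       dEv = dEv, RH_s = RH_s, rho_v_s = rho_vs, rho_v_sat = rvsat,
       rho_v_b = rho_vb, flux = flux, clipped = der$clipped)
}

#' REA mass-balance rate
#'
#' Instantaneous drying rate of the lumped batch,
#' \deqn{\frac{dX}{dt} = -\frac{h_m A(X)}{m_s}
#'   \left(RH_s\,\rho_{v,sat}(T_s) - \rho_{v,b}\right),}
#' with \eqn{RH_s = \exp(-\Delta E_v / (R T_s))} and
#' \eqn{\Delta E_v = \Delta E_R(X - X_b)\,\Delta E_{v,b}}. Negative while
#' the surface vapor concentration exceeds the bulk one (drying); positive
#' when below it (condensation is permitted: evaporation and condensation
#' are competing processes and the rate is never floored at zero).
#'
#' @param state A [sample_state()].
#' @param ambient The current [ambient_state()].
#' @param model An [activation_energy_model()].
#' @param material A [material_props()].
#' @param geometry A [grain_geometry()].
#' @param norm_ambient Ambient used to compute the equilibrium activation
#'   energy that rescales the fingerprint (defaults to `ambient`).
#' @return `dX/dt`, 1/s.
#' @export
mass_balance_rhs <- function(state, ambient, model, material, geometry,
                             norm_ambient = ambient) {
  p <- .rea_point(state$X, state$T, ambient, model, material, geometry,
                  norm_ambient)
  -p$flux / material$m_s
}

#' REA energy-balance rate
#'
#' Lumped batch energy balance
#' \deqn{m C_p \frac{dT}{dt} = h A(X) (T_b - T) + m_s \frac{dX}{dt}\,
#'   \Delta H_v(T),}
#' with `m = m_s (1 + X)`. Evaporation (`dX/dt < 0`) cools the sample,
#' condensation heats it. By default the thermal-mass drift term
#' `T d(m Cp)/dt` is neglected (the balance is solved in the simplified
#' form above); `expanded = TRUE` subtracts it, computing
#' `d(m Cp)/dX` by a central finite difference.
#'
#' @inheritParams mass_balance_rhs
#' @param dXdt The mass-balance rate, 1/s.
#' @param expanded Use the fully expanded product-rule form.
#' @return `dT/dt`, K/s.
#' @export
energy_balance_rhs <- function(state, ambient, dXdt, material, geometry,
                               expanded = FALSE) {
  X <- state$X; T_K <- state$T
  A <- area_at(geometry, X)
  L <- length_at(geometry, X)
  tc <- transfer_coefficients(ambient, L, T_film = 0.5 * (ambient$T_b + T_K))
  m <- material$m_s * (1 + X)
  cp <- material$cp_fn(X)
  rhs <- tc$h * A * (ambient$T_b - T_K) +
    material$m_s * dXdt * material$dHv_fn(T_K)
  if (expanded) {
    eps <- 1e-6
    mcp <- function(x) material$m_s * (1 + x) * material$cp_fn(x)
    dmcp_dX <- (mcp(X + eps) - mcp(X - eps)) / (2 * eps)
    rhs <- rhs - T_K * dmcp_dX * dXdt
  }
  rhs / (m * cp)
}

#' REA diagnostics at a state
#'
#' The observables of the model at a single state: surface relative
#' humidity, surface/saturated/bulk vapor concentrations, apparent and
#' equilibrium activation energies, transfer coefficients and geometry.
#' The identity `rho_v_s = RH_s * rho_v_sat` holds to round-off by
#' construction.
#'
#' @inheritParams mass_balance_rhs
#' @return A list of diagnostics (see Details).
#' @export
rea_diagnostics <- function(state, ambient, model, material, geometry,
                            norm_ambient = ambient) {
  .rea_point(state$X, state$T, ambient, model, material, geometry,
             norm_ambient)
}

#' Solver settings for [simulate_drying()]
#'
#' @param rtol Relative tolerance of the embedded pair.
#' @param atol_X,atol_T Absolute tolerances for moisture (kg/kg) and
#'   temperature (K).
#' @param dt_out Output sampling interval, s.
#' @param max_step Largest internal step, s.
#' @param stop_at_X Optional moisture target; integration stops when `X`
#'   first reaches it (located by bisection on the dense output).
#' @param renormalize_per_phase If `TRUE` (default) the fingerprint is
#'   rescaled by each phase's own equilibrium activation energy; if
#'   `FALSE` the reference (first drying phase) ambient is used for the
#'   rescaling throughout, while transfer coefficients and the bulk vapor
#'   concentration still follow the current phase.
#' @param expanded_energy Use the fully expanded energy balance (see
#'   [energy_balance_rhs()]).
#' @return A list of class `"solver_control"`.
#' @export
solver_control <- function(rtol = 1e-6, atol_X = 1e-8, atol_T = 1e-5,
                           dt_out = 60, max_step = 300, stop_at_X = NULL,
                           renormalize_per_phase = TRUE,
                           expanded_energy = FALSE) {
  stopifnot(rtol > 0, atol_X > 0, atol_T > 0, dt_out > 0, max_step > 0)
  structure(list(rtol = rtol, atol_X = atol_X, atol_T = atol_T,
                 dt_out = dt_out, max_step = max_step, stop_at_X = stop_at_X,
                 renormalize_per_phase = isTRUE(renormalize_per_phase),
                 expanded_energy = isTRUE(expanded_energy)),
            class = "solver_control")
}

# Cubic Hermite interpolation of the state between two accepted steps.
.hermite <- function(tau, t0, t1, y0, y1, f0, f1) {
  h <- t1 - t0
  s <- (tau - t0) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y0 + h10 * h * f0 + h01 * y1 + h11 * h * f1
}

# Dormand-Prince 5(4) over one phase. `f(t, y)` returns c(dX, dT).
# Returns accepted nodes (t, Y, F), plus event info when `stop_at` (an X
# threshold) is crossed.
.integrate_phase <- function(f, t0, t1, y0, control, stop_at = NULL) {
  a21 <- 1 / 5
  a31 <- 3 / 40;        a32 <- 9 / 40
  a41 <- 44 / 45;       a42 <- -56 / 15;      a43 <- 32 / 9
  a51 <- 19372 / 6561;  a52 <- -25360 / 2187; a53 <- 64448 / 6561
  a54 <- -212 / 729
  a61 <- 9017 / 3168;   a62 <- -355 / 33;     a63 <- 46732 / 5247
  a64 <- 49 / 176;      a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192
  b5 <- -2187 / 6784; b6 <- 11 / 84
  e1 <- 71 / 57600; e3 <- -71 / 16695; e4 <- 71 / 1920
  e5 <- -17253 / 339200; e6 <- 22 / 525; e7 <- -1 / 40

  atol <- c(control$atol_X, control$atol_T)
  rtol <- control$rtol
  cap <- 4096L
  ts <- numeric(cap); Ys <- matrix(0, cap, 2); Fs <- matrix(0, cap, 2)
  n <- 1L
  t <- t0; y <- y0; k1 <- f(t, y)
  ts[1] <- t; Ys[1, ] <- y; Fs[1, ] <- k1
  h <- min(control$max_step, max(1e-3, (t1 - t0) / 50), 30)
  stopped <- FALSE
  nreject <- 0L
  while (t < t1) {
    h <- min(h, t1 - t)
    k2 <- f(t + h / 5, y + h * a21 * k1)
    k3 <- f(t + 3 * h / 10, y + h * (a31 * k1 + a32 * k2))
    k4 <- f(t + 4 * h / 5, y + h * (a41 * k1 + a42 * k2 + a43 * k3))
    k5 <- f(t + 8 * h / 9, y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
    k6 <- f(t + h, y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5))
    ynew <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
    k7 <- f(t + h, ynew)
    err <- h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    errnorm <- sqrt(mean((err / sc)^2))
    if (is.finite(errnorm) && errnorm <= 1) {
      tnew <- t + h
      if (n == cap) {  # grow storage
        cap <- cap * 2L
        ts <- c(ts, numeric(cap / 2L))
        Ys <- rbind(Ys, matrix(0, cap / 2L, 2))
        Fs <- rbind(Fs, matrix(0, cap / 2L, 2))
      }
      n <- n + 1L
      ts[n] <- tnew; Ys[n, ] <- ynew; Fs[n, ] <- k7
      if (!is.null(stop_at) && ynew[1] <= stop_at && y[1] > stop_at) {
        # bisect the dense output for X(tau) = stop_at
        g <- function(tau) .hermite(tau, t, tnew, y, ynew, k1, k7)[1] - stop_at
        r <- uniroot(g, c(t, tnew), tol = 1e-6)
        tstop <- r$root
        ystop <- .hermite(tstop, t, tnew, y, ynew, k1, k7)
        ts[n] <- tstop; Ys[n, ] <- ystop; Fs[n, ] <- f(tstop, ystop)
        stopped <- TRUE
        t <- tstop
        break
      }
      t <- tnew; y <- ynew; k1 <- k7
      h <- h * min(5, max(0.2, 0.9 * errnorm^-0.2))
      h <- min(h, control$max_step)
    } else {
      nreject <- nreject + 1L
      if (nreject > 10000L)
        stop(sprintf(
          "integrator failed near t = %.1f s (X = %.5g, T = %.2f K): step size underflow",
          t, y[1], y[2]), call. = FALSE)
      h <- h * max(0.1, 0.9 * (if (is.finite(errnorm)) errnorm else 10)^-0.2)
      if (h < 1e-10)
        stop(sprintf(
          "integrator failed near t = %.1f s (X = %.5g, T = %.2f K): step size underflow",
          t, y[1], y[2]), call. = FALSE)
    }
  }
  list(t = ts[seq_len(n)], Y = Ys[seq_len(n), , drop = FALSE],
       F = Fs[seq_len(n), , drop = FALSE], stopped = stopped, t_end = t)
}

# Dense-output sampling of one integrated phase at the requested times.
.sample_phase <- function(sol, times) {
  m <- length(times)
  out <- matrix(0, m, 2)
  idx <- findInterval(times, sol$t, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= length(sol$t)] <- length(sol$t) - 1L
  if (length(sol$t) == 1L) {
    out[, 1] <- sol$Y[1, 1]; out[, 2] <- sol$Y[1, 2]
    return(out)
  }
  for (j in seq_len(m)) {
    i <- idx[j]
    out[j, ] <- .hermite(times[j], sol$t[i], sol$t[i + 1],
                         sol$Y[i, ], sol$Y[i + 1, ], sol$F[i, ], sol$F[i + 1, ])
  }
  out
}

#' Simulate a drying schedule
#'
#' Integrates the coupled REA mass and energy balances phase by phase,
#' switching the ambient at each phase boundary (a hard integrator
#' restart, no smoothing of the ambient step), and records the state and
#' model diagnostics on a regular output grid plus every phase boundary.
#' A boundary sample carries the label and ambient of the phase it
#' closes; the first sample of the next phase lies `dt_out` later.
#'
#' When `control$stop_at_X` is set, integration ends at the first time the
#' moisture reaches the target (located on the dense solver output).
#'
#' @param schedule A [drying_schedule()]. An empty schedule returns a
#'   one-row curve holding only the initial state (diagnostics `NA`).
#' @param model An [activation_energy_model()].
#' @param material A [material_props()] (provides `X0`, `T0`).
#' @param geometry A [grain_geometry()].
#' @param control A [solver_control()].
#' @return A `data.frame` of class `"drying_curve"` with columns
#'   `t_s`, `X_db`, `T_K`, `phase`, `RH_s`, `rho_v_s`, `rho_v_sat`,
#'   `dEv_J_mol`, and attributes `phase_table`, `schedule`, `clip_count`
#'   (number of fingerprint clippings during integration), `stopped_at`.
#' @export
simulate_drying <- function(schedule, model, material, geometry,
                            control = solver_control()) {
  stopifnot(inherits(schedule, "drying_schedule"),
            inherits(model, "activation_energy_model"),
            inherits(material, "material_props"),
            inherits(geometry, "grain_geometry"),
            inherits(control, "solver_control"))
  if (material$X0 <= model$X_b)
    stop("initial moisture X0 must exceed the model's X_b", call. = FALSE)
  if (!isTRUE(all.equal(material$X_b, model$X_b)))
    warning("material X_b and fingerprint X_b differ; the fingerprint's ",
            "X_b is used in the balances", call. = FALSE)
  if (!is.null(control$stop_at_X) && control$stop_at_X < model$X_b)
    stop("`stop_at_X` lies below the equilibrium moisture X_b = ",
         model$X_b, " and can never be reached", call. = FALSE)

  y <- c(material$X0, material$T0)
  phases <- schedule$phases
  if (length(phases) == 0L) {
    curve <- data.frame(t_s = 0, X_db = y[1], T_K = y[2], phase = "none",
                        RH_s = NA_real_, rho_v_s = NA_real_,
                        rho_v_sat = NA_real_, dEv_J_mol = NA_real_,
                        stringsAsFactors = FALSE)
    return(.as_curve(curve, NULL, schedule, 0L, NULL, model, material,
                     geometry, control))
  }

  ref_ambient <- phases[[1]]$ambient  # fixed-normalization reference
  clip_count <- 0L
  rows <- vector("list", length(phases))
  t0 <- 0
  stopped_at <- NULL
  pt_kind <- character(0); pt_start <- numeric(0); pt_end <- numeric(0)

  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    amb <- ph$ambient
    norm_amb <- if (control$renormalize_per_phase) amb else ref_ambient
    # scalars hoisted out of the inner loop
    T_b <- amb$T_b; u <- amb$u
    rho_vb <- amb$RH_b * rho_v_sat(amb$T_b)
    dEvb <- -R_GAS * norm_amb$T_b * log(norm_amb$RH_b)
    cf <- model$coeffs; X_b <- model$X_b; z_max <- model$z_range[2]
    l0 <- geometry$shrink_L[1]; l1 <- geometry$shrink_L[2]
    a0 <- geometry$shrink_A[1]; a1 <- geometry$shrink_A[2]
    m_s <- material$m_s
    cp_fn <- material$cp_fn; dHv_fn <- material$dHv_fn
    expanded <- control$expanded_energy

    f <- function(t, yv) {
      X <- yv[1]; T_K <- yv[2]
      if (T_K < 273 || T_K > 430)
        stop(sprintf(
          "sample temperature %.2f K left the psychrometric validity range near t = %.1f s",
          T_K, t), call. = FALSE)
      L <- l0 + l1 * X
      A <- a0 + a1 * X
      Tf <- 0.5 * (T_b + T_K)
      rho <- 101325 / (287.058 * Tf)
      mu <- 1.458e-6 * Tf^1.5 / (Tf + 110.4)
      k <- 0.02624 * (Tf / 300)^0.8646
      D <- 2.26e-5 * (Tf / 273.15)^1.81
      cpa <- 1002.5 + 2.75e-4 * (Tf - 200)^2
      Re <- rho * u * L / mu
      Sc <- mu / (rho * D)
      Pr <- mu * cpa / k
      s <- 0.511 * sqrt(Re)
      h_m <- s * Sc^0.37 * D / L
      h <- s * Pr^0.37 * k / L
      z <- X - X_b
      if (z > z_max) { z <- z_max; clip_count <<- clip_count + 1L }
      dER <- ((cf[1] * z + cf[2]) * z + cf[3]) * z + cf[4]
      if (dER < 0) { dER <- 0; clip_count <<- clip_count + 1L }
      else if (dER > 1) { dER <- 1; clip_count <<- clip_count + 1L }
      x <- T_K - 273
      rvsat <- (((4.844e-9 * x - 1.4807e-7) * x + 2.6572e-5) * x -
                  4.8613e-5) * x + 8.342e-3
      RH_s <- exp(-dER * dEvb / (R_GAS * T_K))
      flux <- h_m * A * (RH_s * rvsat - rho_vb)
      dX <- -flux / m_s
      rhs_E <- h * A * (T_b - T_K) + m_s * dX * dHv_fn(T_K)
      if (expanded) {
        eps <- 1e-6
        dmcp <- (m_s * (1 + X + eps) * cp_fn(X + eps) -
                   m_s * (1 + X - eps) * cp_fn(X - eps)) / (2 * eps)
        rhs_E <- rhs_E - T_K * dmcp * dX
      }
      c(dX, rhs_E / (m_s * (1 + X) * cp_fn(X)))
    }

    t1 <- t0 + ph$duration
    sol <- .integrate_phase(f, t0, t1, y, control, stop_at = control$stop_at_X)
    t_end <- sol$t_end

    # output times strictly inside the phase plus its (possibly truncated)
    # end; t = 0 is included for the first phase
    times <- seq(t0, t_end, by = control$dt_out)
    times <- if (i == 1L) times else times[-1]
    if (length(times) == 0L || times[length(times)] < t_end)
      times <- c(times, t_end)
    st <- .sample_phase(sol, times)
    rows[[i]] <- list(t = times, Y = st, phase = ph$kind,
                      ambient = amb, norm_ambient = norm_amb)

    pt_kind <- c(pt_kind, ph$kind)
    pt_start <- c(pt_start, t0); pt_end <- c(pt_end, t_end)
    y <- sol$Y[nrow(sol$Y), ]
    t0 <- t_end
    if (sol$stopped) { stopped_at <- t_end; break }
  }

  rows <- rows[!vapply(rows, is.null, logical(1))]
  curve <- do.call(rbind, lapply(rows, function(r) {
    n <- length(r$t)
    dg <- matrix(0, n, 4)
    for (j in seq_len(n)) {
      p <- .rea_point(r$Y[j, 1], r$Y[j, 2], r$ambient, model, material,
                      geometry, r$norm_ambient)
      dg[j, ] <- c(p$RH_s, p$rho_v_s, p$rho_v_sat, p$dEv)
    }
    data.frame(t_s = r$t, X_db = r$Y[, 1], T_K = r$Y[, 2], phase = r$phase,
               RH_s = dg[, 1], rho_v_s = dg[, 2], rho_v_sat = dg[, 3],
               dEv_J_mol = dg[, 4], stringsAsFactors = FALSE)
  }))
  pt <- data.frame(kind = pt_kind, t_start = pt_start, t_end = pt_end,
                   stringsAsFactors = FALSE)
  .as_curve(curve, pt, schedule, clip_count, stopped_at, model, material,
            geometry, control)
}

.as_curve <- function(df, phase_table, schedule, clip_count, stopped_at,
                      model, material, geometry, control) {
  rownames(df) <- NULL
  attr(df, "phase_table") <- phase_table
  attr(df, "schedule") <- schedule
  attr(df, "clip_count") <- clip_count
  attr(df, "stopped_at") <- stopped_at
  attr(df, "model") <- model
  attr(df, "material") <- material
  attr(df, "geometry") <- geometry
  attr(df, "control") <- control
  class(df) <- c("drying_curve", "data.frame")
  df
}

#' Mark a data frame as a drying curve
#'
#' Wraps a measured (or hand-built) time series so that accounting
#' functions such as [time_accounting()] accept it. The data frame must
#' carry at least `t_s`, `X_db` and `phase`; phase intervals are derived
#' from the labels, with a boundary sample closing the outgoing phase.
#'
#' @param df A data frame with columns `t_s`, `X_db`, `phase` (and
#'   optionally `T_K` plus diagnostics).
#' @param schedule Optional [drying_schedule()]; when given, exact phase
#'   intervals are taken from it instead of from the sample labels.
#' @return The data frame with class `"drying_curve"`.
#' @export
as_drying_curve <- function(df, schedule = NULL) {
  need <- c("t_s", "X_db", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(diff(df$t_s) <= 0))
    stop("`t_s` must be strictly increasing", call. = FALSE)
  pt <- if (!is.null(schedule)) .phase_table(schedule) else NULL
  .as_curve(df, pt, schedule, NA_integer_, NULL, NULL, NULL, NULL, NULL)
}

#' @export
print.drying_curve <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<drying_curve> %d samples over %.0f s; X: %.4g -> %.4g kg/kg d.b.; T: %.2f -> %.2f K\n",
    n, x$t_s[n], x$X_db[1], x$X_db[n], x$T_K[1], x$T_K[n]))
  if (!is.null(attr(x, "stopped_at")))
    cat(sprintf("  stopped at moisture target, t = %.1f s\n",
                attr(x, "stopped_at")))
  cc <- attr(x, "clip_count")
  if (!is.null(cc) && !is.na(cc) && cc > 0L)
    cat(sprintf("  fingerprint clipped %d time(s) during integration\n", cc))
  invisible(x)
}
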