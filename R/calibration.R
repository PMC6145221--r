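# Inverse pipeline: extract the apparent activation energy from a measured
# drying curve, normalize to the relative activation energy, and fit the
# cubic fingerprint.

#' Goodness-of-fit metrics
#'
#' Coefficient of determination `R^2 = 1 - SS_res/SS_tot` and root mean
#' squared error of a predicted series against an observed one.
#'
#' @param observed,predicted Equal-length numeric series (n >= 2).
#' @return A list with `r_squared` and `rmse`.
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("`observed` and `predicted` must be equal-length series of >= 2 points",
         call. = FALSE)
  res <- observed - predicted
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("R^2 is undefined: `observed` has zero variance", call. = FALSE)
  list(r_squared = 1 - sum(res^2) / ss_tot,
       rmse = sqrt(mean(res^2)))
}

#' Extract the apparent activation energy from a drying curve
#'
#' Inverts the REA mass balance pointwise along a measured (or synthetic)
#' drying series:
#' \deqn{\Delta E_v = -R\,T_s \ln\!\left(\frac{-m_s\,\frac{dX}{dt}\,/(h_m A)
#'   + \rho_{v,b}}{\rho_{v,sat}(T_s)}\right),}
#' where the log argument is exactly the surface relative humidity implied
#' by the measured flux. Transfer coefficients and the exchange area are
#' evaluated per sample from the ambient, the (smoothed) moisture and the
#' temperature via the film-temperature convention.
#'
#' Three estimators of the evaporative flux `dX/dt` are available:
#' \describe{
#'   \item{`"calorimetric"` (default)}{inverts the batch energy balance,
#'     `dX/dt = (m C_p dT/dt - h A (T_b - T)) / (m_s \Delta H_v)`, with
#'     `dT/dt` from an analytically differentiated smoothing spline on the
#'     measured temperature. A temperature probe resolves the flux far
#'     better than the balance does: the gravimetric derivative of a noisy
#'     mass series is unavoidably biased during the initial thermal
#'     transient (any smoother wide enough to tame the noise is one-sided
#'     and too stiff at the boundary), while the temperature channel's
#'     signal-to-noise ratio is two orders of magnitude higher there.}
#'   \item{`"spline"`}{analytically differentiated cubic smoothing spline
#'     on `X(t)` (generalized cross-validation unless `df` is given).}
#'   \item{`"central"`}{central differences on the raw `X(t)`.}
#' }
#'
#' Samples whose log argument falls outside `(0, 1.5]` are physically
#' impossible (or grossly noise-corrupted) and are excluded, each with a
#' recorded reason; arguments in `(1, 1.5]` are kept (they yield small
#' negative activation energies and are informative noise around a
#' saturated surface).
#'
#' Only drying-phase samples are used: the fingerprint is defined on the
#' continuous (reference) drying process.
#'
#' @param curve A `drying_curve` or data frame with columns `t_s`, `X_db`,
#'   `T_K` and optionally `phase` (at least 5 samples, strictly increasing
#'   time).
#' @param ambient The drying [ambient_state()] of the measurement.
#' @param material A [material_props()] (provides `m_s` and `X_b`).
#' @param geometry A [grain_geometry()].
#' @param method Flux estimator: `"calorimetric"` (default), `"spline"`
#'   or `"central"` (see Details).
#' @param df Optional equivalent degrees of freedom for the smoothing
#'   spline; default lets generalized cross-validation choose.
#' @return An object of class `"activation_extraction"`: list with
#'   `pairs` (data frame `t_s`, `X_db`, `z`, `arg`, `dEv_J_mol` of
#'   retained samples), `excluded` (with a `reason` column), `method`,
#'   `n_total`.
#' @export
extract_activation_energy <- function(curve, ambient, material, geometry,
                                      method = c("calorimetric", "spline",
                                                 "central"),
                                      df = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ambient, "ambient_state"),
            inherits(material, "material_props"),
            inherits(geometry, "grain_geometry"))
  need <- c("t_s", "X_db", "T_K")
  miss <- setdiff(need, names(curve))
  if (length(miss))
    stop("curve is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("phase" %in% names(curve))
    curve <- curve[curve$phase == "drying", , drop = FALSE]
  t <- curve$t_s
  if (length(t) < 5L)
    stop("need at least 5 drying-phase samples", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("`t_s` must be strictly increasing", call. = FALSE)
  X <- curve$X_db
  T_K <- curve$T_K

  if (method == "calorimetric") {
    ssX <- if (is.null(df)) smooth.spline(t, X) else smooth.spline(t, X, df = df)
    Xs <- predict(ssX, t)$y
    ssT <- smooth.spline(t, T_K)
    Ts <- predict(ssT, t)$y
    dTdt <- predict(ssT, t, deriv = 1)$y
  } else if (method == "spline") {
    ss <- if (is.null(df)) smooth.spline(t, X) else smooth.spline(t, X, df = df)
    Xs <- predict(ss, t)$y
    dXdt <- predict(ss, t, deriv = 1)$y
    Ts <- T_K
  } else {
    Xs <- X
    Ts <- T_K
    n <- length(t)
    dXdt <- numeric(n)
    dXdt[1] <- (X[2] - X[1]) / (t[2] - t[1])
    dXdt[n] <- (X[n] - X[n - 1]) / (t[n] - t[n - 1])
    i <- 2:(n - 1)
    dXdt[i] <- (X[i + 1] - X[i - 1]) / (t[i + 1] - t[i - 1])
  }

  rho_vb <- rho_v_bulk(ambient)
  n <- length(t)
  arg <- numeric(n)
  for (j in seq_len(n)) {
    tc <- transfer_coefficients(ambient, length_at(geometry, Xs[j]),
                                T_film = 0.5 * (ambient$T_b + Ts[j]))
    A <- area_at(geometry, Xs[j])
    if (method == "calorimetric") {
      mcp <- material$m_s * (1 + Xs[j]) * material$cp_fn(Xs[j])
      dXdt_j <- (mcp * dTdt[j] - tc$h * A * (ambient$T_b - Ts[j])) /
        (material$m_s * material$dHv_fn(Ts[j]))
    } else {
      dXdt_j <- dXdt[j]
    }
    arg[j] <- (-material$m_s * dXdt_j / (tc$h_m * A) + rho_vb) /
      rho_v_sat(Ts[j])
  }
  dEv <- ifelse(arg > 0, -R_GAS * Ts * log(arg), NA_real_)
  keep <- is.finite(arg) & arg > 0 & arg <= 1.5
  reason <- ifelse(arg <= 0, "log argument <= 0 (flux exceeds saturation deficit)",
                   ifelse(arg > 1.5, "log argument > 1.5 (unphysical condensation)",
                          NA_character_))
  all_df <- data.frame(t_s = t, X_db = Xs, z = Xs - material$X_b,
                       arg = arg, dEv_J_mol = dEv,
                       stringsAsFactors = FALSE)
  excluded <- all_df[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  if (nrow(excluded) > 0L)
    message(sprintf("extract_activation_energy(): excluded %d of %d samples (%s)",
                    nrow(excluded), n,
                    paste(unique(excluded$reason), collapse = "; ")))
  if (!any(keep))
    stop("calibration failed: every sample was excluded", call. = FALSE)
  structure(list(pairs = all_df[keep, , drop = FALSE], excluded = excluded,
                 method = method, n_total = n),
            class = "activation_extraction")
}

#' @export
print.activation_extraction <- function(x, ...) {
  cat(sprintf(
    "<activation_extraction> %d retained pairs (of %d samples, %s derivative)\n  z in [%.4g, %.4g], dEv in [%.4g, %.4g] J/mol\n",
    nrow(x$pairs), x$n_total, x$method,
    min(x$pairs$z), max(x$pairs$z),
    min(x$pairs$dEv_J_mol), max(x$pairs$dEv_J_mol)))
  invisible(x)
}

#' Fit the relative-activation-energy fingerprint
#'
#' Normalizes extracted apparent activation energies by the drying air's
#' equilibrium activation energy and fits the cubic
#' \eqn{\Delta E_R = c_3 z^3 + c_2 z^2 + c_1 z + c_0} in the free moisture
#' `z = X - X_b` by ordinary (unweighted) least squares.
#'
#' @param extraction An `"activation_extraction"` (from
#'   [extract_activation_energy()]) or a data frame with columns `z` and
#'   `dEv_J_mol`.
#' @param ambient The drying [ambient_state()] defining the normalization
#'   \eqn{\Delta E_{v,b}}.
#' @param X_b Equilibrium moisture content attached to the fitted model,
#'   kg/kg d.b.
#' @param X0 Optional initial moisture; when given, the retained pairs
#'   must span at least half of `[0, X0 - X_b]`.
#' @return A list of class `"rea_calibration"`: `model` (an
#'   [activation_energy_model()] with the fitted coefficients and
#'   `z_range = range(z)`) and `fit` (class `"rea_fit"`: `coeffs`,
#'   `r_squared`, `rmse`, `n_points`, `residuals`). `r_squared` is `NA`
#'   for degenerate constant data.
#' @export
fit_relative_activation_energy <- function(extraction, ambient, X_b,
                                           X0 = NULL) {
  pairs <- if (inherits(extraction, "activation_extraction"))
    extraction$pairs else extraction
  if (!all(c("z", "dEv_J_mol") %in% names(pairs)))
    stop("`extraction` must provide columns `z` and `dEv_J_mol`",
         call. = FALSE)
  z <- pairs$z
  if (length(z) < 8L)
    stop("need at least 8 retained (z, dEv) pairs", call. = FALSE)
  if (!is.null(X0) && diff(range(z)) < 0.5 * (X0 - X_b))
    stop(sprintf(
      "retained pairs span %.3g of the free-moisture range [0, %.3g]; at least half is required",
      diff(range(z)), X0 - X_b), call. = FALSE)
  dEvb <- equilibrium_activation_energy(ambient)
  dER <- pairs$dEv_J_mol / dEvb
  fit <- lm(dER ~ z + I(z^2) + I(z^3))
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient design: the z values do not span a cubic",
         call. = FALSE)
  coeffs <- unname(cf[c(4, 3, 2, 1)])  # c3, c2, c1, c0
  pred <- fitted(fit)
  res <- dER - pred
  ss_tot <- sum((dER - mean(dER))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  model <- activation_energy_model(coeffs, X_b, z_range = range(z),
                                   check = FALSE)
  structure(list(
    model = model,
    fit = structure(list(coeffs = coeffs, r_squared = r2,
                         rmse = sqrt(mean(res^2)),
                         n_points = length(z), residuals = res),
                    class = "rea_fit")),
    class = "rea_calibration")
}

#' @export
print.rea_calibration <- function(x, ...) {
  cat("Fitted relative-activation-energy fingerprint\n")
  print(x$model)
  cat(sprintf("  R^2 = %s, RMSE = %.4g on %d points\n",
              ifelse(is.na(x$fit$r_squared), "NA",
                     sprintf("%.5f", x$fit$r_squared)),
              x$fit$rmse, x$fit$n_points))
  invisible(x)
}
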