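# Activation-energy laws of the REA model: the Arrhenius surface relative
# humidity, the equilibrium activation energy of the drying air, and the
# relative-activation-energy fingerprint polynomial.

#' Equilibrium (maximum) activation energy of the drying air
#'
#' The largest apparent activation energy the sample can reach under a
#' given drying air, attained when the sample equilibrates with it:
#' \deqn{\Delta E_{v,b} = -R\,T_b \ln(RH_b).}
#'
#' @param ambient An [ambient_state()] (requires `RH_b` in (0, 1]; dry air
#'   with `RH_b = 0` would give an infinite barrier).
#' @return Equilibrium activation energy, J/mol (non-negative).
#' @examples
#' equilibrium_activation_energy(drying_ambient())  # ~ 4123 J/mol
#' @export
equilibrium_activation_energy <- function(ambient) {
  if (is.null(ambient$T_b) || is.null(ambient$RH_b))
    stop("`ambient` must carry fields `T_b` and `RH_b`", call. = FALSE)
  if (ambient$RH_b <= 0)
    stop("`RH_b` must be > 0: perfectly dry air has an infinite ",
         "equilibrium activation energy", call. = FALSE)
  if (ambient$RH_b > 1)
    stop("`RH_b` must be <= 1", call. = FALSE)
  -R_GAS * ambient$T_b * log(ambient$RH_b)
}

#' Surface relative humidity from the apparent activation energy
#'
#' Arrhenius-type closure of the REA model:
#' \deqn{RH_s = \exp(-\Delta E_v / (R\,T_s)).}
#' A zero barrier gives a saturated surface (`RH_s = 1`); the barrier equal
#' to the drying air's equilibrium activation energy, evaluated at the air
#' temperature, returns the bulk relative humidity.
#'
#' @param dEv Apparent activation energy, J/mol (non-negative; vectorized).
#' @param T_s Sample (surface) temperature, K.
#' @return Surface relative humidity, a fraction in (0, 1].
#' @export
surface_relative_humidity <- function(dEv, T_s) {
  if (!is.numeric(dEv) || any(!is.finite(dEv)) || any(dEv < 0))
    stop("`dEv` must be non-negative (J/mol)", call. = FALSE)
  if (!is.numeric(T_s) || any(!is.finite(T_s)) || any(T_s <= 0))
    stop("`T_s` must be a positive absolute temperature (K)", call. = FALSE)
  exp(-dEv / (R_GAS * T_s))
}

#' Relative-activation-energy fingerprint model
#'
#' The material's drying fingerprint: the relative activation energy
#' \eqn{\Delta E_R = \Delta E_v / \Delta E_{v,b}} as a cubic polynomial in
#' the free moisture content \eqn{z = X - X_b},
#' \deqn{\Delta E_R(z) = c_3 z^3 + c_2 z^2 + c_1 z + c_0.}
#' Once fitted on a single (continuous) drying run, the same curve is
#' reused under other ambients by rescaling with that ambient's
#' equilibrium activation energy.
#'
#' @param coeffs Numeric length-4 vector `c(c3, c2, c1, c0)` (descending
#'   powers).
#' @param X_b Equilibrium moisture content at the reference drying
#'   condition, kg/kg dry basis.
#' @param z_range Fitted range of the free moisture content, length-2.
#'   Evaluations above the upper edge are clamped to the edge value
#'   (cubic extrapolation is unphysical). Defaults to `c(0, Inf)`.
#' @param check If `TRUE`, warn when the polynomial is increasing or
#'   leaves `[0, 1.05]` somewhere on a grid over a finite `z_range`
#'   (soft sanity checks; fitted fingerprints should be non-increasing).
#' @return An object of class `"activation_energy_model"`.
#' @seealso [soybean_fingerprint()], [relative_activation_energy()]
#' @export
activation_energy_model <- function(coeffs, X_b, z_range = c(0, Inf),
                                    check = TRUE) {
  if (!is.numeric(coeffs) || length(coeffs) != 4L || any(!is.finite(coeffs)))
    stop("`coeffs` must be four finite numbers c(c3, c2, c1, c0)",
         call. = FALSE)
  if (!is.numeric(X_b) || length(X_b) != 1L || !is.finite(X_b) || X_b < 0)
    stop("`X_b` must be a single non-negative moisture content (kg/kg d.b.)",
         call. = FALSE)
  if (!is.numeric(z_range) || length(z_range) != 2L || z_range[1] > z_range[2])
    stop("`z_range` must be an increasing length-2 range", call. = FALSE)
  m <- structure(list(coeffs = unname(coeffs), X_b = X_b,
                      z_range = z_range),
                 class = "activation_energy_model")
  if (check && is.finite(z_range[2]) && z_range[2] > z_range[1]) {
    z <- seq(z_range[1], z_range[2], length.out = 101)
    v <- .eval_cubic(coeffs, z)
    if (any(v < -0.05) || any(v > 1.05))
      warning("fingerprint polynomial leaves [0, 1.05] on its fitted range",
              call. = FALSE)
    if (any(diff(v) > 1e-9))
      warning("fingerprint polynomial is not non-increasing on its fitted range",
              call. = FALSE)
  }
  m
}

#' @export
print.activation_energy_model <- function(x, ...) {
  cat(sprintf(
    "<activation_energy_model> dE_R(z) = %.5g z^3 + %.5g z^2 + %.5g z + %.5g\n  X_b = %.4g kg/kg d.b., fitted z range [%.4g, %.4g]\n",
    x$coeffs[1], x$coeffs[2], x$coeffs[3], x$coeffs[4],
    x$X_b, x$z_range[1], x$z_range[2]))
  invisible(x)
}

.eval_cubic <- function(cf, z) ((cf[1] * z + cf[2]) * z + cf[3]) * z + cf[4]

#' Fitted soybean fingerprint
#'
#' The relative-activation-energy cubic fitted to continuous soybean
#' drying at 35 degC / 20 % RH:
#' \deqn{\Delta E_R = -213.38 z^3 + 38.831 z^2 - 4.2124 z + 0.9958,}
#' with \eqn{z = X - X_b}. The fitted range spans the free moisture of the
#' reference experiment, `[0, X0 - X_b]` with `X0 = 0.25` kg/kg d.b.
#'
#' @param X_b Equilibrium moisture content attached to the fingerprint,
#'   kg/kg d.b. The reference value is not published; 0.06 kg/kg d.b. is
#'   the package's documented assumption for the 35 degC / 20 % RH air.
#' @return An [activation_energy_model()].
#' @export
soybean_fingerprint <- function(X_b = 0.06) {
  activation_energy_model(c(-213.38, 38.831, -4.2124, 0.9958), X_b,
                          z_range = c(0, 0.25 - X_b), check = FALSE)
}

#' Evaluate the relative activation energy
#'
#' Evaluates the fingerprint polynomial at a moisture content.
#' Moisture above the fitted range is clamped to the range edge;
#' moisture below `X_b` is a domain error for this user-facing evaluator
#' (inside the balances a small excursion below `X_b` is handled by
#' clipping, see [simulate_drying()]).
#'
#' @param model An [activation_energy_model()].
#' @param X Moisture content(s), kg/kg dry basis; must be `>= model$X_b`.
#' @return Relative activation energy (dimensionless), vectorized over `X`.
#' @examples
#' relative_activation_energy(soybean_fingerprint(), 0.06)  # 0.9958
#' @export
relative_activation_energy <- function(model, X) {
  stopifnot(inherits(model, "activation_energy_model"))
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("`X` must be finite numeric moisture content(s)", call. = FALSE)
  if (any(X < model$X_b))
    stop("`X` must be >= X_b = ", model$X_b,
         " (no extrapolation below the equilibrium moisture)", call. = FALSE)
  z <- pmin(X - model$X_b, model$z_range[2])
  .eval_cubic(model$coeffs, z)
}

# Clipped evaluation used inside the balances: allows a small excursion of
# X below X_b (the printed fingerprints have dE_R(0) slightly below 1, so
# the model equilibrium sits marginally below X_b), clamps z above the
# fitted range, and clips the value into [0, 1]. Returns value + clip flag.
.dER_balance <- function(model, X) {
  z <- X - model$X_b
  clipped <- FALSE
  if (z > model$z_range[2]) { z <- model$z_range[2]; clipped <- TRUE }
  v <- .eval_cubic(model$coeffs, z)
  if (v < 0) { v <- 0; clipped <- TRUE }
  else if (v > 1) { v <- 1; clipped <- TRUE }
  list(value = v, clipped = clipped)
}
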