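# Psychrometrics of humid air and convective transfer coefficients.

#' Drying-medium state
#'
#' Bundles the bulk condition of the drying (or tempering) air: absolute
#' temperature, relative humidity and air speed over the sample. These three
#' numbers fix the bulk vapor concentration and the equilibrium activation
#' energy of the REA model, and (together with a characteristic length) the
#' convective transfer coefficients.
#'
#' @param T_K Bulk air temperature, K. Must lie in the validity window of
#'   the saturation polynomial, (273, 430) K.
#' @param RH Bulk relative humidity, a fraction in (0, 1].
#' @param u Air speed over the sample, m/s (non-negative). A strictly
#'   positive speed is required by the forced-convection correlations; for
#'   tempering outside the dryer use a small residual draught
#'   (0.3 m/s is the package default in [tempering_ambient()]).
#'
#' @return An object of class `"ambient_state"` with fields `T_b`, `RH_b`
#'   and `u`.
#' @examples
#' ambient_state(308.15, 0.20, 3)   # 35 degC, 20 % RH, 3 m/s
#' @seealso [drying_ambient()], [tempering_ambient()]
#' @export
ambient_state <- function(T_K, RH, u) {
  if (!is.numeric(T_K) || length(T_K) != 1L || !is.finite(T_K) ||
      T_K <= 273 || T_K >= 430)
    stop("`T_K` must be a single temperature in (273, 430) K", call. = FALSE)
  if (!is.numeric(RH) || length(RH) != 1L || !is.finite(RH) ||
      RH <= 0 || RH > 1)
    stop("`RH` must be a single fraction in (0, 1]", call. = FALSE)
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0)
    stop("`u` must be a single non-negative air speed in m/s", call. = FALSE)
  structure(list(T_b = T_K, RH_b = RH, u = u), class = "ambient_state")
}

#' @export
print.ambient_state <- function(x, ...) {
  cat(sprintf("<ambient_state> T_b = %.2f K (%.1f degC), RH_b = %.3f, u = %.2f m/s\n",
              x$T_b, x$T_b - 273.15, x$RH_b, x$u))
  invisible(x)
}

#' Reference drying and tempering air states
#'
#' Convenience constructors for the default soybean drying experiment:
#' drying air at 35 degC, 20 % RH and 3 m/s; tempering (rest) air at
#' 25 degC and 43 % RH. Tempering takes place outside the dryer where the
#' air movement is unreported; a residual draught of 0.3 m/s keeps the
#' forced-convection correlations applicable.
#'
#' @param u Air speed, m/s.
#' @return An [ambient_state()].
#' @export
drying_ambient <- function(u = 3) ambient_state(308.15, 0.20, u)

#' @rdname drying_ambient
#' @export
tempering_ambient <- function(u = 0.3) ambient_state(298.15, 0.43, u)

#' Saturated water-vapor concentration at a surface temperature
#'
#' Quartic polynomial in `(T_s - 273)` fitted to saturation vapor density
#' data of water, valid between 273 K and 430 K:
#' \deqn{\rho_{v,sat} = 4.844\times10^{-9} x^4 - 1.4807\times10^{-7} x^3
#'   + 2.6572\times10^{-5} x^2 - 4.8613\times10^{-5} x + 8.342\times10^{-3}}
#' with \eqn{x = T_s - 273} and the result in kg/m^3.
#'
#' @param T_s Absolute temperature(s), K, in `[273, 430]`. The polynomial's
#'   origin is 273 K, so that endpoint is admitted and returns the constant
#'   term exactly.
#' @return Saturated vapor concentration(s), kg/m^3.
#' @examples
#' rho_v_sat(298)     # about 0.0233 kg/m^3 at 25 degC
#' @export
rho_v_sat <- function(T_s) {
  if (!is.numeric(T_s) || length(T_s) < 1L || any(!is.finite(T_s)))
    stop("`T_s` must be finite numeric temperature(s) in K", call. = FALSE)
  if (any(T_s < 273 | T_s > 430))
    stop("rho_v_sat() is only valid for 273 K <= T_s <= 430 K (got ",
         paste(signif(T_s[T_s < 273 | T_s > 430], 6), collapse = ", "),
         ")", call. = FALSE)
  x <- T_s - 273
  (((4.844e-9 * x - 1.4807e-7) * x + 2.6572e-5) * x - 4.8613e-5) * x +
    8.342e-3
}

#' Bulk vapor concentration of the drying air
#'
#' The bulk relative humidity is defined against saturation at the bulk
#' temperature, `RH_b = rho_v_b / rho_v_sat(T_b)`, so the bulk vapor
#' concentration is `RH_b * rho_v_sat(T_b)`.
#'
#' @param ambient An [ambient_state()], or any list with fields `T_b` (K)
#'   and `RH_b` (fraction). A plain list may carry `RH_b = 0` (perfectly
#'   dry air), which is excluded from `ambient_state` proper because it
#'   implies an infinite equilibrium activation energy.
#' @return Bulk vapor concentration, kg/m^3.
#' @export
rho_v_bulk <- function(ambient) {
  if (is.null(ambient$T_b) || is.null(ambient$RH_b))
    stop("`ambient` must carry fields `T_b` and `RH_b`", call. = FALSE)
  if (ambient$RH_b < 0 || ambient$RH_b > 1)
    stop("`RH_b` must lie in [0, 1]", call. = FALSE)
  ambient$RH_b * rho_v_sat(ambient$T_b)
}

# Raw dry-air property correlations; `T` in K. Shared by the exported
# wrapper and the simulation inner loop (which needs plain doubles).
.air_props <- function(T_K) {
  list(
    rho    = 101325 / (287.058 * T_K),            # ideal gas at 1 atm
    mu     = 1.458e-6 * T_K^1.5 / (T_K + 110.4),  # Sutherland's law
    k      = 0.02624 * (T_K / 300)^0.8646,        # power-law fit
    D      = 2.26e-5 * (T_K / 273.15)^1.81,       # water vapor in air
    cp_air = 1002.5 + 2.75e-4 * (T_K - 200)^2     # quadratic fit
  )
}

#' Thermophysical properties of dry air
#'
#' Property correlations for the drying medium, evaluated at the film
#' temperature. The correlations are explicit fits to standard dry-air
#' property tables at 1 atm (the tabulations in Incropera & DeWitt,
#' *Fundamentals of Heat and Mass Transfer*):
#' density from the ideal-gas law at 101325 Pa (R = 287.058 J/(kg K));
#' dynamic viscosity from Sutherland's law
#' (`1.458e-6 T^1.5 / (T + 110.4)` Pa s); thermal conductivity
#' `0.02624 (T/300)^0.8646` W/(m K); water-vapor-in-air diffusivity
#' `2.26e-5 (T/273.15)^1.81` m^2/s (Marrero-Mason-type power law); and
#' specific heat `1002.5 + 2.75e-4 (T - 200)^2` J/(kg K). All agree with
#' the tables to within about 2 % over 270-430 K.
#'
#' @param T_film Film temperature, K, in `[270, 430]`.
#' @return An object of class `"air_properties"`: a list with fields
#'   `rho` (kg/m^3), `mu` (Pa s), `k` (W/(m K)), `D` (m^2/s) and
#'   `cp_air` (J/(kg K)).
#' @examples
#' air_properties(300)
#' @export
air_properties <- function(T_film) {
  if (!is.numeric(T_film) || length(T_film) != 1L || !is.finite(T_film) ||
      T_film < 270 || T_film > 430)
    stop("`T_film` must be a single temperature in [270, 430] K",
         call. = FALSE)
  structure(c(.air_props(T_film), list(T_film = T_film)),
            class = "air_properties")
}

#' @export
print.air_properties <- function(x, ...) {
  cat(sprintf(
    "<air_properties> at %.1f K: rho = %.4f kg/m^3, mu = %.3e Pa s,\n  k = %.4f W/(m K), D = %.3e m^2/s, cp = %.1f J/(kg K)\n",
    x$T_film, x$rho, x$mu, x$k, x$D, x$cp_air))
  invisible(x)
}

#' Sherwood and Nusselt correlations for flow over the grain sample
#'
#' Forced-convection correlations of the form
#' `Sh = 0.511 Re^0.5 Sc^0.37` and `Nu = 0.511 Re^0.5 Pr^0.37`.
#'
#' @param Re Reynolds number.
#' @param Sc Schmidt number.
#' @param Pr Prandtl number.
#' @return The dimensionless Sherwood (resp. Nusselt) number.
#' @examples
#' sherwood_number(100, 1)  # 5.11
#' @export
sherwood_number <- function(Re, Sc) 0.511 * sqrt(Re) * Sc^0.37

#' @rdname sherwood_number
#' @export
nusselt_number <- function(Re, Pr) 0.511 * sqrt(Re) * Pr^0.37

#' Convective heat and mass transfer coefficients
#'
#' Evaluates the dimensionless groups `Re = rho u L / mu`,
#' `Sc = mu / (rho D)` and `Pr = mu cp / k` from the dry-air property
#' correlations at the film temperature, applies the Sherwood/Nusselt
#' correlations, and converts to dimensional coefficients
#' `h_m = Sh D / L` (m/s) and `h = Nu k / L` (W/(m^2 K)).
#'
#' @param ambient An [ambient_state()]; its `u` must be strictly positive
#'   (the correlations are forced-convection forms). For still air use a
#'   small residual draught such as [tempering_ambient()]'s 0.3 m/s.
#' @param L Characteristic length of the sample, m.
#' @param T_film Film temperature at which air properties are evaluated,
#'   K. Defaults to the bulk air temperature; during a simulation the
#'   mean of bulk and sample temperature is used.
#' @return An object of class `"transfer_coefficients"`: list with
#'   `Re`, `Sc`, `Pr`, `Sh`, `Nu`, `h` (W/(m^2 K)), `h_m` (m/s), `L` (m).
#' @export
transfer_coefficients <- function(ambient, L, T_film = ambient$T_b) {
  stopifnot(inherits(ambient, "ambient_state"))
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("`L` must be a single positive length in m", call. = FALSE)
  if (ambient$u <= 0)
    stop("forced-convection correlations need `u` > 0; for still air use ",
         "a residual draught (e.g. tempering_ambient(u = 0.3))",
         call. = FALSE)
  ap <- .air_props(T_film)
  Re <- ap$rho * ambient$u * L / ap$mu
  Sc <- ap$mu / (ap$rho * ap$D)
  Pr <- ap$mu * ap$cp_air / ap$k
  Sh <- sherwood_number(Re, Sc)
  Nu <- nusselt_number(Re, Pr)
  structure(list(Re = Re, Sc = Sc, Pr = Pr, Sh = Sh, Nu = Nu,
                 h = Nu * ap$k / L, h_m = Sh * ap$D / L, L = L),
            class = "transfer_coefficients")
}

#' @export
print.transfer_coefficients <- function(x, ...) {
  cat(sprintf(
    "<transfer_coefficients> Re = %.1f, Sc = %.3f, Pr = %.3f\n  Sh = %.2f, Nu = %.2f, h = %.2f W/(m^2 K), h_m = %.4f m/s (L = %.2e m)\n",
    x$Re, x$Sc, x$Pr, x$Sh, x$Nu, x$h, x$h_m, x$L))
  invisible(x)
}
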