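# Readers and writers. One declared dialect at the file boundary:
# seconds, grams, kelvin in CSV; everything SI internally. Header comment
# lines (starting with '#') document the units in every file written.

.write_series_csv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# drying-curve series: t_s [s], mass_g [g] or X_db [kg/kg d.b.], T_K [K], phase", con)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read a measured drying-curve CSV
#'
#' Reads the package's curve dialect: comma-separated with optional `#`
#' comment lines, columns `t_s` (s), `T_K` (K), `phase`, and either
#' `X_db` (kg/kg dry basis) or `mass_g` (g). When only `mass_g` is
#' present the dry solid mass must be supplied and the moisture is
#' computed as `X = (m - m_s) / m_s`.
#'
#' @param path Path to the CSV file.
#' @param m_s_kg Dry solid mass, kg (required when the file carries
#'   `mass_g` but no `X_db`; the laboratory value comes from the final
#'   oven assay).
#' @return A data frame with columns `t_s`, `X_db`, `T_K`, `phase` (plus
#'   `mass_g` when present).
#' @export
read_curve_csv <- function(path, m_s_kg = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"t_s" %in% names(df))
    stop("missing required column `t_s` in ", path, call. = FALSE)
  if (!"X_db" %in% names(df) && !"mass_g" %in% names(df))
    stop("need a moisture column: either `X_db` or `mass_g` in ", path,
         call. = FALSE)
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad))
    stop("`t_s` is not strictly increasing at row ", bad[1] + 1L,
         call. = FALSE)
  if ("mass_g" %in% names(df)) {
    neg <- which(df$mass_g <= 0)
    if (length(neg))
      stop("non-positive `mass_g` at row ", neg[1], call. = FALSE)
    if (!"X_db" %in% names(df)) {
      if (is.null(m_s_kg))
        stop("file has `mass_g` but no `X_db`: supply `m_s_kg` to convert",
             call. = FALSE)
      df$X_db <- (df$mass_g / 1000 - m_s_kg) / m_s_kg
    }
  }
  df
}

#' Write a drying curve to CSV
#'
#' Writes the curve dialect (see [read_curve_csv()]) including the model
#' diagnostics columns when present: `RH_s`, `rho_v_s`, `rho_v_sat`,
#' `dEv_J_mol`.
#'
#' @param curve A `drying_curve` or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  .write_series_csv(df, path)
  invisible(path)
}

#' Default run configuration
#'
#' The nested configuration list describing the reference soybean
#' experiment: drying at 35 degC / 20 % RH / 3 m/s, tempering at
#' 25 degC / 43 % RH / 0.3 m/s, a continuous schedule capped at
#' 400 000 s, the default material/geometry, the published soybean
#' fingerprint, solver settings and the 0.134 kg/kg d.b. moisture target.
#' Temperatures in configuration files carry an explicit `_C` suffix and
#' are converted to kelvin on load.
#'
#' @return A nested list serializable to JSON with [write_run_config()].
#' @export
default_run_config <- function() {
  mat <- soybean_material()
  geo <- soybean_geometry()
  fp <- soybean_fingerprint()
  list(
    ambient = list(
      drying = list(T_C = 35, RH_frac = 0.20, u_m_s = 3),
      tempering = list(T_C = 25, RH_frac = 0.43, u_m_s = 0.3)),
    schedule = list(t_D_s = 1800, t_T_s = 0, max_total_s = 4e5),
    material = list(m_s_kg = mat$m_s, X0_db = mat$X0, T0_C = mat$T0 - 273.15,
                    X_b_db = mat$X_b, cp_solid_J_kgK = 1650,
                    cp_water_J_kgK = 4187),
    geometry = list(axes0_mm = geo$axes0 * 1e3, n_grains = geo$n_grains,
                    shrink_L_m = geo$shrink_L, shrink_A_m2 = geo$shrink_A),
    activation_energy = list(coeffs = fp$coeffs, X_b_db = fp$X_b,
                             z_max = fp$z_range[2]),
    solver = list(rtol = 1e-6, atol_X = 1e-8, atol_T = 1e-5, dt_out_s = 60,
                  renormalize_per_phase = TRUE, expanded_energy = FALSE),
    targets = list(X_target_db = 0.134),
    synth = list(sampling_dt_s = 60, noise_mass_rel = 0.001, noise_T_K = 0.2))
}

#' Read / write a run configuration (JSON)
#'
#' @param path Path to a JSON configuration file.
#' @return `read_run_config()` returns the validated nested list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("ambient.drying.T_C", "ambient.drying.RH_frac",
                "ambient.drying.u_m_s", "schedule.t_D_s", "schedule.t_T_s",
                "schedule.max_total_s", "material.m_s_kg", "material.X0_db",
                "material.T0_C", "material.X_b_db",
                "geometry.shrink_L_m", "geometry.shrink_A_m2",
                "activation_energy.coeffs", "activation_energy.X_b_db")
  for (key in required) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    for (p in parts) {
      node <- node[[p]]
      if (is.null(node))
        stop("config key `", key, "` is required (missing at `", p, "`)",
             call. = FALSE)
    }
  }
  if (cfg$schedule$t_T_s > 0) {
    for (k in c("T_C", "RH_frac", "u_m_s"))
      if (is.null(cfg$ambient$tempering[[k]]))
        stop("config key `ambient.tempering.", k,
             "` is required when schedule.t_T_s > 0", call. = FALSE)
  }
  cfg
}

#' @param cfg A configuration list such as [default_run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Turn a validated configuration list into model objects.
.build_run <- function(cfg) {
  a <- cfg$ambient$drying
  dry_amb <- ambient_state(a$T_C + 273.15, a$RH_frac, a$u_m_s)
  tmp_amb <- if (!is.null(cfg$ambient$tempering)) {
    b <- cfg$ambient$tempering
    ambient_state(b$T_C + 273.15, b$RH_frac, b$u_m_s)
  } else NULL
  m <- cfg$material
  material <- material_props(
    m_s = m$m_s_kg, X0 = m$X0_db, T0 = m$T0_C + 273.15, X_b = m$X_b_db,
    cp_solid = if (is.null(m$cp_solid_J_kgK)) 1650 else m$cp_solid_J_kgK,
    cp_water = if (is.null(m$cp_water_J_kgK)) 4187 else m$cp_water_J_kgK)
  g <- cfg$geometry
  geometry <- grain_geometry(
    axes0 = if (is.null(g$axes0_mm)) soybean_geometry()$axes0
            else g$axes0_mm / 1e3,
    n_grains = if (is.null(g$n_grains)) 200 else g$n_grains,
    shrink_L = g$shrink_L_m, shrink_A = g$shrink_A_m2)
  ae <- cfg$activation_energy
  z_max <- if (is.null(ae$z_max)) m$X0_db - ae$X_b_db else ae$z_max
  model <- activation_energy_model(ae$coeffs, ae$X_b_db,
                                   z_range = c(0, z_max), check = FALSE)
  schedule <- build_periodic_schedule(cfg$schedule$t_D_s, cfg$schedule$t_T_s,
                                      dry_amb, tmp_amb,
                                      max_total = cfg$schedule$max_total_s)
  s <- if (is.null(cfg$solver)) list() else cfg$solver
  control <- solver_control(
    rtol = if (is.null(s$rtol)) 1e-6 else s$rtol,
    atol_X = if (is.null(s$atol_X)) 1e-8 else s$atol_X,
    atol_T = if (is.null(s$atol_T)) 1e-5 else s$atol_T,
    dt_out = if (is.null(s$dt_out_s)) 60 else s$dt_out_s,
    stop_at_X = if (is.null(cfg$targets$X_target_db)) NULL
                else cfg$targets$X_target_db,
    renormalize_per_phase = if (is.null(s$renormalize_per_phase)) TRUE
                            else s$renormalize_per_phase,
    expanded_energy = if (is.null(s$expanded_energy)) FALSE
                      else s$expanded_energy)
  list(drying_ambient = dry_amb, tempering_ambient = tmp_amb,
       material = material, geometry = geometry, model = model,
       schedule = schedule, control = control, targets = cfg$targets,
       synth = cfg$synth)
}
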