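# Synthetic drying experiments with known ground truth. Stands in for the
# laboratory protocol: ~30 g of soybeans at 0.25 kg/kg d.b. and 25 degC,
# dried at 35 degC / 20 % RH / 3 m/s (tempering at 25 degC / 43 % RH),
# with the sample mass and temperature logged at a fixed interval and
# corrupted by instrument noise.

#' Configuration of a synthetic drying experiment
#'
#' Bundles the ground truth (fingerprint, material, geometry, schedule)
#' and the measurement model: sampling interval, multiplicative mass noise
#' (the balance reads `m * (1 + e)`, `e ~ N(0, noise_mass)`; a 0.01 g
#' balance on a 30 g sample motivates the 0.1 % default) and additive
#' Gaussian temperature noise (0.2 K default, typical of a fibre-optic
#' probe).
#'
#' @param seed Integer RNG seed; the generated experiment is a pure
#'   function of the configuration including this seed.
#' @param truth The ground-truth [activation_energy_model()].
#' @param material A [material_props()].
#' @param geometry A [grain_geometry()].
#' @param schedule A [drying_schedule()]. Default: continuous drying at
#'   the reference ambient, capped at 400 000 s.
#' @param sampling_dt Sampling interval of the data logger, s.
#' @param noise_mass Relative standard deviation of mass readings.
#' @param noise_T Standard deviation of temperature readings, K.
#' @param stop_at_X Moisture target ending the experiment (the protocol
#'   dries to 0.134 kg/kg d.b.); `NULL` runs the whole schedule.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             truth = soybean_fingerprint(),
                             material = soybean_material(),
                             geometry = soybean_geometry(),
                             schedule = NULL,
                             sampling_dt = 60,
                             noise_mass = 0.001,
                             noise_T = 0.2,
                             stop_at_X = 0.134) {
  if (is.null(schedule))
    schedule <- build_periodic_schedule(1800, 0, drying_ambient(),
                                        tempering_ambient(),
                                        max_total = 4e5)
  stopifnot(inherits(truth, "activation_energy_model"),
            inherits(material, "material_props"),
            inherits(geometry, "grain_geometry"),
            inherits(schedule, "drying_schedule"),
            sampling_dt > 0, noise_mass >= 0, noise_T >= 0)
  structure(list(seed = as.integer(seed), truth = truth,
                 material = material, geometry = geometry,
                 schedule = schedule, sampling_dt = sampling_dt,
                 noise_mass = noise_mass, noise_T = noise_T,
                 stop_at_X = stop_at_X),
            class = "synthetic_config")
}

#' Generate a synthetic drying experiment
#'
#' Forward-simulates the configured schedule with the ground-truth
#' fingerprint, samples the trajectory at the logger interval, applies
#' the measurement noise, and returns the "measured" series together with
#' a truth record. Deterministic for a fixed seed (the RNG state of the
#' session is saved and restored).
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `measured.csv`
#'   (columns `t_s, mass_g, T_K, phase`) and `truth.json`.
#' @return A list with `measured` (data frame `t_s`, `mass_g`, `T_K`,
#'   `phase`), `truth` (list: seed, fingerprint coefficients, `X_b`,
#'   material/geometry/noise values), and `curve` (the noise-free
#'   simulated `drying_curve`).
#' @export
generate_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  control <- solver_control(dt_out = cfg$sampling_dt,
                            stop_at_X = cfg$stop_at_X)
  curve <- simulate_drying(cfg$schedule, cfg$truth, cfg$material,
                           cfg$geometry, control)
  n <- nrow(curve)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  mass_kg <- cfg$material$m_s * (1 + curve$X_db)
  mass_g <- 1000 * mass_kg * (1 + rnorm(n, 0, cfg$noise_mass))
  T_K <- curve$T_K + rnorm(n, 0, cfg$noise_T)
  measured <- data.frame(t_s = curve$t_s, mass_g = mass_g, T_K = T_K,
                         phase = curve$phase, stringsAsFactors = FALSE)
  truth <- list(
    seed = cfg$seed,
    fingerprint = list(coeffs = cfg$truth$coeffs, X_b = cfg$truth$X_b,
                       z_range = cfg$truth$z_range),
    material = list(m_s_kg = cfg$material$m_s, X0_db = cfg$material$X0,
                    T0_K = cfg$material$T0, X_b_db = cfg$material$X_b),
    geometry = list(axes0_m = cfg$geometry$axes0,
                    n_grains = cfg$geometry$n_grains,
                    shrink_L = cfg$geometry$shrink_L,
                    shrink_A = cfg$geometry$shrink_A),
    noise = list(mass_rel_sd = cfg$noise_mass, T_sd_K = cfg$noise_T,
                 sampling_dt_s = cfg$sampling_dt),
    stop_at_X_db = cfg$stop_at_X)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_series_csv(measured, file.path(out_dir, "measured.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(measured = measured, truth = truth, curve = curve)
}

#' Cracking percentage of a dried batch
#'
#' \deqn{C = 100\,S_C / S_T,} the percentage of grains with visible seed
#' coat cracks after drying.
#'
#' @param S_C Number of cracked grains (`0 <= S_C <= S_T`).
#' @param S_T Total number of grains (positive).
#' @return Cracking percentage.
#' @examples
#' cracking_ratio(2, 92)  # ~ 2.17 %
#' @export
cracking_ratio <- function(S_C, S_T) {
  if (!is.numeric(S_T) || any(S_T <= 0))
    stop("`S_T` must be a positive count", call. = FALSE)
  if (!is.numeric(S_C) || any(S_C < 0) || any(S_C > S_T))
    stop("`S_C` must satisfy 0 <= S_C <= S_T", call. = FALSE)
  100 * S_C / S_T
}

#' Reference soybean intermittent-drying measurements
#'
#' Experimentally reported values for soybean batches dried to
#' 0.134 kg/kg d.b. at 35 degC / 20 % RH (drying) and 25 degC / 43 % RH
#' (tempering, 1800 s per cycle) at intermittencies 1, 0.5, 0.4 and 0.25:
#' the measured cracking percentages (mean and sd over replicates) and
#' the reported total and operating drying times. These are *labelled
#' experimental fixture data* for reports and comparisons; the package
#' does not model crack formation and never produces these numbers as
#' model output.
#'
#' @return A data frame with columns `alpha`, `t_D_s`, `t_T_s`,
#'   `cracking_pct`, `cracking_sd`, `total_time_s`, `operating_time_s`.
#' @export
soybean_reference_data <- function() {
  data.frame(
    alpha = c(1, 0.5, 0.4, 0.25),
    t_D_s = c(NA, 1800, 1200, 600),
    t_T_s = c(0, 1800, 1800, 1800),
    cracking_pct = c(9.88, 6.32, 3.16, 2.17),
    cracking_sd = c(0.34, 0.33, 0.31, 0.07),
    total_time_s = c(30600, 37800, 40200, 53400),
    operating_time_s = c(30600, 19800, 16800, 13800))
}
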