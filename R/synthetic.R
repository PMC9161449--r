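#' Generate a synthetic glycosyltransferase kinetics dataset
#'
#' Emulates a luminescence-based GDP-release assay: velocities follow the
#' Michaelis-Menten hyperbola `v(S) = Vmax*S/(Km+S)` plus a constant
#' donor-hydrolysis background, are perturbed by multiplicative Gaussian noise,
#' converted to pmol GDP through the assay geometry (enzyme concentration,
#' reaction volume, incubation time), and reported as raw luminescence through
#' a linear standard curve. No-acceptor blank rows carrying only the hydrolysis
#' background are included, and the GDP standard curve itself is emitted so the
#' downstream calibration/correction stages can invert the whole construction.
#'
#' @param Km Michaelis constant (uM). Must be > 0.
#' @param Vmax maximal velocity (nmol min^-1 mg^-1). Must be >= 0; `Vmax = 0`
#'   is the degenerate zero-signal case where every velocity equals the
#'   hydrolysis background.
#' @param acceptor_concs acceptor substrate concentrations (uM), non-empty and
#'   positive. The study design spans 5 uM to 1 mM.
#' @param hydrolysis_rate constant no-acceptor hydrolysis background, same
#'   units as `Vmax`.
#' @param config a [scenario_config()].
#' @param substrate_id label carried through to the output table.
#' @param enzyme_conc_nM,reaction_volume_uL,incubation_time_min,enzyme_molar_mass
#'   assay geometry used to convert velocities to pmol GDP (defaults: 100 nM
#'   enzyme, 10 uL, 30 min, 58 kg/mol).
#' @param cal_slope,cal_intercept parameters of the linear luminescence ~ pmol
#'   GDP standard curve used to render luminescence.
#' @param standard_gdp_pmol GDP amounts at which the standard curve is sampled.
#' @return a list of class `kinetics_dataset` with elements `data` (columns
#'   `substrate_id`, `acceptor_conc_uM`, `replicate`, `luminescence`,
#'   `is_blank`), `standard_curve` (columns `gdp_pmol`, `luminescence`), the
#'   assay metadata, and `ground_truth`.
#' @examples
#' cfg <- scenario_config(seed = 1, noise_cv = 0)
#' ds <- gen_kinetics_dataset(Km = 113.1, Vmax = 282.1,
#'                            acceptor_concs = c(5, 10, 50, 100, 500, 1000),
#'                            hydrolysis_rate = 5, config = cfg)
#' @export
gen_kinetics_dataset <- function(Km, Vmax, acceptor_concs, hydrolysis_rate = 0,
                                 config = scenario_config(1),
                                 substrate_id = "substrate",
                                 enzyme_conc_nM = 100,
                                 reaction_volume_uL = 10,
                                 incubation_time_min = 30,
                                 enzyme_molar_mass = 58000,
                                 cal_slope = 2, cal_intercept = 50,
                                 standard_gdp_pmol = seq(0, 1000, by = 125)) {
  if (!is.finite(Km) || Km <= 0) stop("Km must be positive")
  if (!is.finite(Vmax) || Vmax < 0) stop("Vmax must be non-negative")
  if (length(acceptor_concs) == 0 || any(acceptor_concs <= 0))
    stop("acceptor_concs must be non-empty and positive")
  stopifnot(inherits(config, "scenario_config"))

  mass_mg <- enzyme_conc_nM * reaction_volume_uL * enzyme_molar_mass * 1e-12
  reps <- config$replicate_count

  with_seed(config$seed, {
    grid <- expand.grid(acceptor_conc_uM = acceptor_concs,
                        replicate = seq_len(reps))
    v_true <- Vmax * grid$acceptor_conc_uM / (Km + grid$acceptor_conc_uM) +
      hydrolysis_rate
    v_obs <- mult_noise(v_true, config$noise_cv)
    blank_v <- mult_noise(rep(hydrolysis_rate, reps), config$noise_cv)

    to_lum <- function(v) {
      pmol <- v * incubation_time_min * mass_mg * 1000  # nmol -> pmol
      cal_slope * pmol + cal_intercept
    }
    data <- rbind(
      data.frame(substrate_id = substrate_id,
                 acceptor_conc_uM = grid$acceptor_conc_uM,
                 replicate = grid$replicate,
                 luminescence = to_lum(v_obs), is_blank = FALSE),
      data.frame(substrate_id = substrate_id, acceptor_conc_uM = 0,
                 replicate = seq_len(reps),
                 luminescence = to_lum(blank_v), is_blank = TRUE))

    std <- data.frame(gdp_pmol = standard_gdp_pmol,
                      luminescence = mult_noise(
                        cal_slope * standard_gdp_pmol + cal_intercept,
                        config$noise_cv))

    gt <- list(generator = "kinetics", Km = Km, Vmax = Vmax,
               hydrolysis_rate = hydrolysis_rate, cal_slope = cal_slope,
               cal_intercept = cal_intercept, enzyme_conc_nM = enzyme_conc_nM,
               reaction_volume_uL = reaction_volume_uL,
               incubation_time_min = incubation_time_min,
               enzyme_molar_mass = enzyme_molar_mass,
               seed = config$seed, noise_cv = config$noise_cv)

    out <- structure(list(data = data, standard_curve = std,
                          enzyme_conc_nM = enzyme_conc_nM,
                          reaction_volume_uL = reaction_volume_uL,
                          incubation_time_min = incubation_time_min,
                          enzyme_molar_mass = enzyme_molar_mass,
                          ground_truth = gt),
                     class = "kinetics_dataset")
    if (!is.null(config$output_dir)) {
      write_dataset(data, gt, paste0("kinetics_", substrate_id),
                    config$output_dir)
      write_dataset(std, list(generator = "gdp_standard_curve",
                              slope = cal_slope, intercept = cal_intercept),
                    paste0("kinetics_", substrate_id, "_standard_curve"),
                    config$output_dir)
    }
    out
  })
}

#' Generate a synthetic ITC titration
#'
#' Produces integrated per-injection heats from the one-site Wiseman binding
#' model (the same closed form [fit_one_site()] fits), with optional constant
#' dilution heat and additive Gaussian noise scaled to the largest heat.
#'
#' @param Kd dissociation constant (uM).
#' @param dH binding enthalpy (kcal/mol).
#' @param n binding stoichiometry (sites per macromolecule).
#' @param cell_conc macromolecule concentration in the cell (uM).
#' @param syringe_conc ligand concentration in the syringe (uM).
#' @param injection_volumes per-injection volumes (uL); at least 10 injections.
#' @param cell_volume calorimeter cell volume (uL); default 200 uL.
#' @param temperature_K experiment temperature; default 298.15 K (25 C).
#' @param dilution_offset constant dilution heat (kcal per mol of injectant).
#' @param config a [scenario_config()]; `noise_cv` scales additive heat noise
#'   as a fraction of the largest absolute heat.
#' @return list of class `titration_series` (see [titration_series()]) with a
#'   `ground_truth` element. A c-value (`n*cell_conc/Kd`) outside `[0.01, 1e4]`
#'   is recorded as a warning flag in the ground truth.
#' @examples
#' cfg <- scenario_config(seed = 1, noise_cv = 0)
#' ser <- gen_itc_titration(Kd = 6.1, dH = -5.02, n = 0.60, cell_conc = 70,
#'                          syringe_conc = 1000, config = cfg)
#' @export
gen_itc_titration <- function(Kd, dH, n, cell_conc, syringe_conc,
                              injection_volumes = rep(2, 19),
                              cell_volume = 200, temperature_K = 298.15,
                              dilution_offset = 0,
                              config = scenario_config(1)) {
  if (any(c(Kd, cell_conc, syringe_conc) <= 0))
    stop("Kd and concentrations must be positive")
  if (length(injection_volumes) < 10) stop("at least 10 injections required")
  stopifnot(inherits(config, "scenario_config"))

  heats <- wiseman_heats(Kd, dH, n, cell_conc, syringe_conc,
                         injection_volumes, cell_volume, dilution_offset)
  cval <- n * cell_conc / Kd
  with_seed(config$seed, {
    if (config$noise_cv > 0)
      heats <- heats + rnorm(length(heats), 0,
                             config$noise_cv * max(abs(heats)))
    gt <- list(generator = "itc", Kd = Kd, dH = dH, n = n,
               cell_conc = cell_conc, syringe_conc = syringe_conc,
               cell_volume = cell_volume, dilution_offset = dilution_offset,
               c_value = cval,
               c_value_warning = (cval < 0.01 || cval > 1e4),
               seed = config$seed, noise_cv = config$noise_cv)
    ser <- titration_series(heats_ucal = heats,
                            injection_volumes_uL = injection_volumes,
                            cell_volume_uL = cell_volume,
                            cell_conc_uM = cell_conc,
                            syringe_conc_uM = syringe_conc,
                            temperature_K = temperature_K)
    ser$ground_truth <- gt
    if (!is.null(config$output_dir)) {
      df <- data.frame(injection_index = seq_along(heats),
                       injection_volume_uL = injection_volumes,
                       heat_ucal = heats)
      write_dataset(df, gt, "itc_titration", config$output_dir)
    }
    ser
  })
}

#' Generate synthetic STD NMR build-up curves
#'
#' One mono-exponential build-up `STD(t) = STDmax*(1 - exp(-ksat*t))` per
#' proton, sampled at the given saturation times with multiplicative noise.
#'
#' @param protons character vector of proton labels.
#' @param STDmax named or positional vector of plateau STD amplitudes
#'   (fractions), one per proton.
#' @param ksat saturation rate constants (s^-1), one per proton.
#' @param sat_times saturation times (s); the assay default is
#'   `c(0.5, 1, 1.5, 2, 3, 4, 5)`. At least 4 points.
#' @param condition condition label, `"apo"` or `"plus_GDP"`.
#' @param config a [scenario_config()].
#' @return named list of [buildup_series()] objects plus attribute
#'   `ground_truth`.
#' @export
gen_std_buildup <- function(protons, STDmax, ksat,
                            sat_times = c(0.5, 1, 1.5, 2, 3, 4, 5),
                            condition = "apo",
                            config = scenario_config(1)) {
  if (length(sat_times) < 4 || any(sat_times <= 0))
    stop("sat_times must be positive with at least 4 points")
  stopifnot(length(STDmax) == length(protons),
            length(ksat) == length(protons),
            inherits(config, "scenario_config"))
  with_seed(config$seed, {
    series <- setNames(lapply(seq_along(protons), function(i) {
      amp <- STDmax[i] * (1 - exp(-ksat[i] * sat_times))
      buildup_series(proton_id = protons[i], condition = condition,
                     sat_times = sat_times,
                     std_amplitude = pmax(0, mult_noise(amp, config$noise_cv)))
    }), protons)
    gt <- list(generator = "std_buildup", protons = protons,
               STDmax = as.numeric(STDmax), ksat = as.numeric(ksat),
               condition = condition, seed = config$seed,
               noise_cv = config$noise_cv)
    attr(series, "ground_truth") <- gt
    if (!is.null(config$output_dir)) {
      df <- do.call(rbind, lapply(series, as.data.frame))
      write_dataset(df, gt, paste0("std_buildup_", condition),
                    config$output_dir)
    }
    series
  })
}

#' Generate synthetic NOESY build-up curves
#'
#' Cross-peak integrals grow linearly with mixing time at an initial slope
#' proportional to `r^-6` of the inter-proton distance, then saturate: inside
#' the configurable linear window the curve is exactly `sigma * t`; beyond it,
#' `sigma * (w + tau*(1 - exp(-(t - w)/tau)))`, which is C1-continuous and
#' emulates the cross-relaxation roll-off at long mixing times.
#'
#' @param pairs proton-pair labels.
#' @param distances true inter-proton distances (Angstrom), one per pair.
#' @param ref_pair label of the reference pair (must be among `pairs`).
#' @param ref_distance known distance of the reference pair (Angstrom).
#' @param mixing_times mixing times (ms); the experiment default is
#'   `c(100, 150, 200, 250, 300, 400, 600, 800, 1000, 1500)`.
#' @param linear_window_ms end of the exactly linear regime (default 300 ms).
#' @param sat_tau_ms curvature time constant beyond the window (default 300 ms).
#' @param slope_scale initial slope of the reference pair (units per ms).
#' @param config a [scenario_config()].
#' @return named list of [noe_buildup()] objects plus attribute
#'   `ground_truth`.
#' @export
gen_noe_buildup <- function(pairs, distances, ref_pair, ref_distance,
                            mixing_times = c(100, 150, 200, 250, 300, 400,
                                             600, 800, 1000, 1500),
                            linear_window_ms = 300, sat_tau_ms = 300,
                            slope_scale = 1,
                            config = scenario_config(1)) {
  if (any(distances <= 0)) stop("distances must be positive")
  if (!ref_pair %in% pairs) stop("ref_pair must be among pairs")
  stopifnot(length(distances) == length(pairs),
            inherits(config, "scenario_config"))
  slopes <- slope_scale * (ref_distance / distances)^6
  shape <- ifelse(mixing_times <= linear_window_ms, mixing_times,
                  linear_window_ms + sat_tau_ms *
                    (1 - exp(-(mixing_times - linear_window_ms) / sat_tau_ms)))
  with_seed(config$seed, {
    series <- setNames(lapply(seq_along(pairs), function(i) {
      noe_buildup(pair_id = pairs[i], mixing_times = mixing_times,
                  integrals = mult_noise(slopes[i] * shape, config$noise_cv))
    }), pairs)
    gt <- list(generator = "noe_buildup", pairs = pairs,
               distances = as.numeric(distances), slopes = as.numeric(slopes),
               ref_pair = ref_pair, ref_distance = ref_distance,
               linear_window_ms = linear_window_ms, sat_tau_ms = sat_tau_ms,
               seed = config$seed, noise_cv = config$noise_cv)
    attr(series, "ground_truth") <- gt
    if (!is.null(config$output_dir)) {
      df <- do.call(rbind, lapply(series, as.data.frame))
      write_dataset(df, gt, "noe_buildup", config$output_dir)
    }
    series
  })
}

#' Generate a synthetic glycopeptide precursor feature table
#'
#' Builds deisotoped precursor features (m/z, charge, intensity) from known
#' per-glycosite glycoform composition profiles: the theoretical neutral mass
#' is peptide mass + summed building-block residue masses; m/z follows the
#' protonated-species convention at each requested charge state, perturbed by
#' Gaussian ppm error; intensities are the requested fractions of a base
#' intensity (split evenly across charge states) under log-normal noise.
#'
#' @param site_profiles named list: glycosite id -> named numeric vector of
#'   glycoform fractions, names being composition strings such as
#'   `"Hex5HexNAc2dHex1"`. Fractions per site must sum to 1.
#' @param peptide_masses named numeric vector: glycosite id -> backbone peptide
#'   monoisotopic mass (Da).
#' @param ppm_error_sd standard deviation of the mass error (ppm).
#' @param charge_states charge states emitted per glycoform; default `c(2, 3)`.
#' @param base_intensity total intensity budget per site.
#' @param config a [scenario_config()]; `noise_cv` sets the log-normal
#'   intensity scatter.
#' @param blocks building-block set used to validate and mass the
#'   compositions; see [default_building_blocks()].
#' @return data frame of class `glyco_features` with columns `feature_id`,
#'   `mz`, `charge`, `rt_min`, `intensity`, `sample_id`, `glycosite`,
#'   `glycoform` plus attribute `ground_truth`.
#' @examples
#' cfg <- scenario_config(seed = 1, noise_cv = 0)
#' ft <- gen_glycopeptide_features(
#'   site_profiles = list(N65 = c(Hex5HexNAc2dHex1 = 0.9, Hex5HexNAc2 = 0.1)),
#'   peptide_masses = c(N65 = 659.39661), ppm_error_sd = 0, config = cfg)
#' @export
gen_glycopeptide_features <- function(site_profiles, peptide_masses,
                                      ppm_error_sd = 0,
                                      charge_states = c(2, 3),
                                      base_intensity = 1e8,
                                      config = scenario_config(1),
                                      blocks = default_building_blocks()) {
  stopifnot(inherits(config, "scenario_config"), length(site_profiles) > 0)
  for (site in names(site_profiles)) {
    fr <- site_profiles[[site]]
    if (abs(sum(fr) - 1) > 1e-9)
      stop("glycoform fractions for site ", site, " must sum to 1")
    if (!site %in% names(peptide_masses))
      stop("no peptide mass for site ", site)
  }
  with_seed(config$seed, {
    rows <- list()
    for (site in names(site_profiles)) {
      fr <- site_profiles[[site]]
      for (gf in names(fr)) {
        counts <- parse_composition(gf, blocks)  # errors on unknown block
        mass <- peptide_masses[[site]] +
          sum(counts * blocks$mass[match(names(counts), blocks$block)])
        for (z in charge_states) {
          mz0 <- (mass + z * .PROTON_MASS) / z
          mz <- mz0 * (1 + rnorm(1, 0, ppm_error_sd) * 1e-6)
          inten <- fr[[gf]] * base_intensity / length(charge_states)
          if (config$noise_cv > 0) {
            sdlog <- sqrt(log(1 + config$noise_cv^2))
            inten <- inten * exp(rnorm(1, -sdlog^2 / 2, sdlog))
          }
          rows[[length(rows) + 1]] <- data.frame(
            mz = mz, charge = z, intensity = inten, sample_id = "synthetic",
            glycosite = site, glycoform = gf)
        }
      }
    }
    out <- do.call(rbind, rows)
    out <- cbind(feature_id = sprintf("F%04d", seq_len(nrow(out))), out)
    out$rt_min <- 10 + 30 * seq_len(nrow(out)) / nrow(out)
    out <- out[, c("feature_id", "mz", "charge", "rt_min", "intensity",
                   "sample_id", "glycosite", "glycoform")]
    gt <- list(generator = "glyco_features", site_profiles = site_profiles,
               peptide_masses = as.list(peptide_masses),
               ppm_error_sd = ppm_error_sd, charge_states = charge_states,
               seed = config$seed, noise_cv = config$noise_cv)
    attr(out, "ground_truth") <- gt
    class(out) <- c("glyco_features", "data.frame")
    if (!is.null(config$output_dir))
      write_dataset(as.data.frame(out), gt, "glyco_features",
                    config$output_dir)
    out
  })
}
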