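scenario_schema <- list(
  blood = c("mass_density_kg_m3", "molar_density_mol_m3",
            "plasma_viscosity_pa_s", "systemic_hematocrit",
            "hematocrit_table"),
  drug = c("half_life_s", "molecular_radius_m", "inlet_mole_fraction",
           "bolus_duration_s"),
  graph = c("n_alveoli", "tumor_ids", "root_order",
            "arterial_pressure_pa", "venous_pressure_pa"),
  dcm_healthy = c("r_inner_m", "r_outer_m", "capillary_layer_thickness_m",
                  "resolution", "cap_half_angle_deg",
                  "tissue_outer_pressure_pa", "porosity", "eps_tissue",
                  "eps_capillary", "tortuosity", "permeability_tissue_m2",
                  "viscosity_interstitial_pa_s",
                  "mass_density_interstitial_kg_m3",
                  "molar_density_interstitial_mol_m3",
                  "capillary_viscosity_pa_s", "capillary_K_tangential_m2",
                  "capillary_K_normal_m2", "lymph_conductivity_m_pa_s",
                  "lymph_surface_density_per_m", "lymph_pressure_pa"),
  dcm_tumor = c("r_outer_m", "resolution", "cap_half_angle_deg",
                "tissue_outer_pressure_pa", "porosity", "eps_tissue",
                "eps_capillary", "tortuosity", "permeability_tissue_m2",
                "viscosity_interstitial_pa_s",
                "mass_density_interstitial_kg_m3",
                "molar_density_interstitial_mol_m3",
                "capillary_viscosity_pa_s", "tumor_capillary_radius_m",
                "receptor_concentration_mol_m3", "k_on_m3_mol_s",
                "k_off_per_s"),
  transfer_healthy = c("hydraulic_conductivity_m_pa_s",
                       "surface_density_per_m", "osmotic_reflection",
                       "solvent_drag_reflection",
                       "diffusive_permeability_m_s", "oncotic_capillary_pa",
                       "oncotic_interstitial_pa",
                       "molar_density_transfer_mol_m3"),
  transfer_tumor = c("hydraulic_conductivity_m_pa_s",
                     "surface_density_per_m", "osmotic_reflection",
                     "solvent_drag_reflection",
                     "diffusive_permeability_m_s", "oncotic_capillary_pa",
                     "oncotic_interstitial_pa",
                     "molar_density_transfer_mol_m3"),
  coupling = c("n_substeps", "lymph_clamp", "newton_tol"),
  run = c("t_end_s", "courant", "max_dt_s", "output_interval_s"))

#' Default scenario configuration
#'
#' The shipped parameter registry of the coupled example: boundary
#' pressures 1064 / 199.5 Pa, a 21-alveolus network with 3 tumorous
#' upscaled nodes, and the healthy/tumor parameter sets of the alveolus
#' model.  Identical to `inst/extdata/default_scenario.yaml`.
#'
#' @return a validated `scenario_config` list.
#' @export
default_scenario <- function() {
  path <- system.file("extdata", "default_scenario.yaml",
                      package = "pulmosim")
  if (!nzchar(path)) stop("shipped default_scenario.yaml not found")
  load_config(path)
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file, checks that every required key of every
#' section is present and that no unknown keys are given, and returns the
#' validated configuration.  All keys carry SI unit suffixes (`_pa`, `_m`,
#' `_s`, `_per_m`, ...).
#'
#' @param path YAML file path.
#' @return list of class `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param config a configuration list (as from [yaml::read_yaml()]).
#' @export
validate_config <- function(config) {
  unknown_sec <- setdiff(names(config), names(scenario_schema))
  if (length(unknown_sec))
    stop("unknown config section(s): ", paste(unknown_sec, collapse = ", "))
  for (sec in names(scenario_schema)) {
    if (is.null(config[[sec]])) stop("missing config section: ", sec)
    keys <- names(config[[sec]])
    miss <- setdiff(scenario_schema[[sec]], keys)
    if (length(miss))
      stop("config section '", sec, "' missing key(s): ",
           paste(paste0(sec, ".", miss), collapse = ", "))
    unk <- setdiff(keys, scenario_schema[[sec]])
    if (length(unk))
      stop("config section '", sec, "' has unknown key(s): ",
           paste(paste0(sec, ".", unk), collapse = ", "))
  }
  # numeric scalars occasionally survive YAML parsing as strings
  # (e.g. exponents without a sign); coerce and reject non-numbers
  non_numeric <- c("hematocrit_table", "tumor_ids", "resolution",
                   "lymph_clamp")
  for (sec in names(scenario_schema)) {
    for (key in names(config[[sec]])) {
      if (key %in% non_numeric) next
      v <- config[[sec]][[key]]
      if (is.character(v)) {
        vn <- suppressWarnings(as.numeric(v))
        if (is.na(vn) && !identical(v, ".inf"))
          stop("config key '", sec, ".", key, "' is not numeric: ", v)
        config[[sec]][[key]] <- if (identical(v, ".inf")) Inf else vn
      }
    }
  }
  ht <- config$blood$hematocrit_table
  if (is.null(ht$diameter_um) || is.null(ht$hematocrit) ||
      length(ht$diameter_um) != length(ht$hematocrit))
    stop("blood.hematocrit_table needs parallel 'diameter_um' and ",
         "'hematocrit' lists")
  if (config$drug$half_life_s <= 0) stop("drug.half_life_s must be > 0")
  if (is.null(config$drug$bolus_duration_s))
    config$drug$bolus_duration_s <- Inf
  structure(config, class = "scenario_config")
}

#' Write a scenario configuration to YAML
#' @param config a `scenario_config`. @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname load_config
#' @export
config_blood <- function(config) {
  b <- config$blood
  blood_properties(
    mass_density = b$mass_density_kg_m3,
    molar_density = b$molar_density_mol_m3,
    plasma_viscosity = b$plasma_viscosity_pa_s,
    hematocrit_table = data.frame(
      diameter_um = as.numeric(b$hematocrit_table$diameter_um),
      hematocrit = as.numeric(b$hematocrit_table$hematocrit)),
    systemic_hematocrit = b$systemic_hematocrit)
}

#' @rdname load_config
#' @export
config_drug <- function(config) {
  d <- config$drug
  bd <- d$bolus_duration_s
  if (is.character(bd)) bd <- Inf
  drug_properties(half_life = d$half_life_s,
                  molecular_radius = d$molecular_radius_m,
                  inlet_mole_fraction = d$inlet_mole_fraction,
                  bolus_duration = bd)
}

#' @rdname load_config
#' @param kind `"healthy"` or `"tumor"`.
#' @export
config_transfer <- function(config, kind = c("healthy", "tumor")) {
  kind <- match.arg(kind)
  s <- config[[paste0("transfer_", kind)]]
  transfer_parameters(
    L_p = s$hydraulic_conductivity_m_pa_s,
    S_V = s$surface_density_per_m,
    sigma = s$osmotic_reflection,
    sigma_f = s$solvent_drag_reflection,
    P = s$diffusive_permeability_m_s,
    pi_c = s$oncotic_capillary_pa,
    pi_t = s$oncotic_interstitial_pa,
    rhomol_transfer = s$molar_density_transfer_mol_m3)
}
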