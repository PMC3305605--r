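#' Tissue-continuum parameters
#'
#' Defaults are the healthy-lung parameter set of the alveolus model;
#' `tissue_parameters_tumor()` gives the tumor set.  Entries without an
#' established printed value (lymphatic wall conductivity, interstitial
#' permeability and viscosity, receptor kinetics) default to mid-range
#' literature values for macromolecule transport in normal and neoplastic
#' tissue; all are plain list entries and freely overridable.
#'
#' @param porosity interstitial porosity (fraction of tissue volume
#'   accessible to free fluid).
#' @param eps_t volume fraction of the model domain occupied by tissue.
#' @param K_t interstitial permeability, m^2 (isotropic scalar).
#' @param tortuosity diffusive tortuosity factor (<= 1, multiplicative).
#' @param mu_int interstitial-fluid viscosity, Pa·s.
#' @param rho_int,rhomol_int interstitial-fluid mass (kg/m^3) and molar
#'   (mol/m^3) densities.
#' @param lymph list `L_p_ly` (m/(Pa·s)), `S_ly_V` (1/m), `p_ly` (Pa), or
#'   `NULL` when the tissue has no functional lymphatics (tumor).
#' @param receptor list `C_R0` (mol/m^3), `k_on` (m^3/(mol·s)), `k_off`
#'   (1/s), or `NULL` outside tumor tissue.
#' @return list of class `tissue_parameters`.
#' @export
tissue_parameters <- function(porosity = 0.13, eps_t = 0.9,
                              K_t = 3.7e-17, tortuosity = 0.28,
                              mu_int = 1.2e-3, rho_int = 1030,
                              rhomol_int = 303.5,
                              lymph = list(L_p_ly = 2.6e-9, S_ly_V = 3.0,
                                           p_ly = -1200),
                              receptor = NULL) {
  stopifnot(porosity > 0, porosity <= 1, eps_t > 0, eps_t <= 1,
            tortuosity > 0, tortuosity <= 1, K_t >= 0, mu_int > 0)
  structure(list(porosity = porosity, eps_t = eps_t, K_t = K_t,
                 tortuosity = tortuosity, mu_int = mu_int,
                 rho_int = rho_int, rhomol_int = rhomol_int,
                 lymph = lymph, receptor = receptor),
            class = "tissue_parameters")
}

#' @rdname tissue_parameters
#' @export
tissue_parameters_tumor <- function() {
  tissue_parameters(porosity = 0.27, eps_t = 0.8, K_t = 2.2e-16,
                    tortuosity = 0.71, lymph = NULL,
                    receptor = list(C_R0 = 1e-4, k_on = 100, k_off = 1e-4))
}

#' Capillary-continuum parameters
#'
#' Porosity and tortuosity of the capillary continuum are identically one
#' (the vessel lumen is all pore space).  The permeability is given as the
#' tangential (in-sheet) and normal components of the shell-local tensor:
#' for the healthy sheet the normal component is zero (planar capillary
#' mesh), for the tumor both equal the isotropic Poiseuille-derived value.
#'
#' @param eps_c capillary volume fraction of the model domain.
#' @param K_tangential,K_normal shell-local permeability components, m^2.
#' @param mu_c capillary blood viscosity, Pa·s.
#' @param rho_c,rhomol_c blood mass/molar densities.
#' @return list of class `capillary_parameters`.
#' @export
capillary_parameters <- function(eps_c = 0.1,
                                 K_tangential = 5.18e-14,
                                 K_normal = 0,
                                 mu_c = 0.0021, rho_c = 1050,
                                 rhomol_c = 284) {
  stopifnot(eps_c > 0, eps_c <= 1, K_tangential >= 0, K_normal >= 0,
            mu_c > 0)
  structure(list(eps_c = eps_c, K_tangential = K_tangential,
                 K_normal = K_normal, mu_c = mu_c, rho_c = rho_c,
                 rhomol_c = rhomol_c, porosity = 1, tortuosity = 1),
            class = "capillary_parameters")
}

#' @rdname capillary_parameters
#' @export
capillary_parameters_tumor <- function() {
  K <- tumor_permeability(10e-6, as_tensor = FALSE)
  capillary_parameters(eps_c = 0.2, K_tangential = K, K_normal = K)
}

#' Transvascular transfer parameters
#'
#' Parameters of the Starling and Stavermann-Kedem-Katchalsky coupling
#' functions between the capillary and tissue continua.  The transfer molar
#' density is the arithmetic mean of the blood and interstitial-fluid molar
#' densities.
#'
#' @param L_p hydraulic conductivity of the capillary wall, m/(Pa·s).
#' @param S_V capillary surface area per unit volume of tissue, 1/m.
#' @param sigma osmotic reflection coefficient.
#' @param sigma_f solvent-drag reflection coefficient.
#' @param P diffusive permeability of the capillary wall, m/s.
#' @param pi_c,pi_t capillary and interstitial oncotic pressures, Pa.
#' @param rhomol_transfer molar density used in the transfer terms,
#'   mol/m^3.
#' @return list of class `transfer_parameters`.
#' @export
transfer_parameters <- function(L_p = 2.7e-12,
                                S_V = capillary_surface_density(
                                  1800, 4e-6, 1e-5, 182e-6, 70e-6),
                                sigma = 0.8, sigma_f = 0.91,
                                P = 5.7e-10,
                                pi_c = 3724, pi_t = 1862,
                                rhomol_transfer = (303.5 + 284) / 2) {
  stopifnot(L_p >= 0, S_V >= 0, sigma >= 0, sigma <= 1,
            sigma_f >= 0, sigma_f <= 1, P >= 0)
  structure(list(L_p = L_p, S_V = S_V, sigma = sigma, sigma_f = sigma_f,
                 P = P, pi_c = pi_c, pi_t = pi_t,
                 rhomol_transfer = rhomol_transfer),
            class = "transfer_parameters")
}

#' @rdname transfer_parameters
#' @export
transfer_parameters_tumor <- function() {
  transfer_parameters(L_p = 2.1e-11, S_V = 2e4, sigma = 0.8,
                      sigma_f = 0.82, P = 5.7e-9,
                      pi_c = 2660, pi_t = 1995)
}

#' Effective filtration pressure (Starling driving force)
#'
#' `p_eff = (p_c - p_t) - sigma (pi_c - pi_t)`.
#'
#' @param p_c,p_t hydrostatic pressures, Pa. @param sigma osmotic
#'   reflection coefficient. @param pi_c,pi_t oncotic pressures, Pa.
#' @return effective filtration pressure, Pa (positive = filtration).
#' @export
effective_filtration_pressure <- function(p_c, p_t, sigma, pi_c, pi_t) {
  (p_c - p_t) - sigma * (pi_c - pi_t)
}

#' Starling transvascular fluid flux
#'
#' Volumetric exchange rate `J_v = L_p (S/V) p_eff` (1/s) and the molar
#' fluid source `q_v = J_v rhomol_transfer` (mol/(m^3·s)), positive from
#' capillary to tissue.
#'
#' @param p_eff effective filtration pressure, Pa.
#' @param L_p hydraulic conductivity, m/(Pa·s). @param S_V surface density,
#'   1/m. @param rhomol_transfer transfer molar density, mol/m^3.
#' @return list with `q_v` (mol/(m^3·s)) and `J_v` (1/s).
#' @export
starling_flux <- function(p_eff, L_p, S_V, rhomol_transfer) {
  stopifnot(L_p >= 0, S_V >= 0, rhomol_transfer >= 0)
  J_v <- L_p * S_V * p_eff
  list(q_v = J_v * rhomol_transfer, J_v = J_v)
}

#' Stavermann-Kedem-Katchalsky transvascular solute flux
#'
#' Diffusive plus solvent-drag transport of the drug across the capillary
#' wall: `q_x = P (S/V) rhomol (x_c - x_t) + (1 - sigma_f) J_v rhomol
#' (x_c + x_t)/2`, positive from capillary to tissue.
#'
#' @param x_c,x_t mole fractions in the capillary and tissue continuum.
#' @param J_v volumetric Starling exchange rate, 1/s.
#' @param P wall diffusive permeability, m/s. @param sigma_f solvent-drag
#'   reflection coefficient. @param S_V surface density, 1/m.
#' @param rhomol_transfer transfer molar density, mol/m^3.
#' @return molar exchange rate, mol/(m^3·s).
#' @export
kedem_katchalsky_flux <- function(x_c, x_t, J_v, P, sigma_f, S_V,
                                  rhomol_transfer) {
  stopifnot(all(x_c >= 0), all(x_t >= 0))
  P * S_V * rhomol_transfer * (x_c - x_t) +
    (1 - sigma_f) * J_v * rhomol_transfer * (x_c + x_t) / 2
}

#' Lymphatic fluid and drug sinks
#'
#' Lymph forms when the interstitial pressure exceeds the lymphatic
#' pressure; the sink is clamped at zero otherwise (no reverse lymph flow;
#' `clamp = FALSE` gives the unclamped linear form).  Both sinks are zero
#' in tumor tissue (`lymph = NULL`).
#'
#' @param p_t interstitial pressure, Pa. @param x_t tissue mole fraction.
#' @param lymph lymph parameter list (`L_p_ly`, `S_ly_V`, `p_ly`) or `NULL`.
#' @param rhomol_int interstitial molar density, mol/m^3.
#' @param clamp logical.
#' @return list with `fluid` and `drug` sinks, mol/(m^3·s).
#' @export
lymphatic_sinks <- function(p_t, x_t, lymph, rhomol_int, clamp = TRUE) {
  if (is.null(lymph))
    return(list(fluid = 0 * p_t, drug = 0 * p_t))
  dp <- p_t - lymph$p_ly
  if (clamp) dp <- pmax(dp, 0)
  fluid <- lymph$L_p_ly * lymph$S_ly_V * dp * rhomol_int
  list(fluid = fluid, drug = fluid * x_t)
}

#' Implicit receptor-ligand binding update
#'
#' Ligand-receptor kinetics `dC_RL/dt = k_on c C_R - k_off C_RL` with free
#' drug concentration `c = x_t rhomol_int` and free receptors
#' `C_R = C_R0 - C_RL`.  The update is implicit in `C_RL` over `dt` (the
#' balance is linear in `C_RL` at fixed `c`), so receptor conservation
#' `C_R + C_RL = C_R0` holds exactly.  The returned sink is the bound-drug
#' accumulation rate, removed from the free tissue drug (negative when net
#' unbinding releases drug).
#'
#' @param x_t tissue mole fraction. @param C_RL bound-complex
#'   concentration, mol/m^3. @param rhomol_int molar density, mol/m^3.
#' @param k_on forward rate, m^3/(mol·s). @param k_off backward rate, 1/s.
#' @param C_R0 total receptor concentration, mol/m^3. @param dt step, s.
#' @return list with `sink` (mol/(m^3·s)) and `C_RL` (updated, mol/m^3).
#' @export
receptor_binding_update <- function(x_t, C_RL, rhomol_int, k_on, k_off,
                                    C_R0, dt) {
  stopifnot(all(C_RL >= -1e-300), all(C_RL <= C_R0 * (1 + 1e-12)))
  conc <- x_t * rhomol_int
  C_new <- (C_RL + dt * k_on * conc * C_R0) /
    (1 + dt * (k_on * conc + k_off))
  list(sink = (C_new - C_RL) / dt, C_RL = C_new)
}
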