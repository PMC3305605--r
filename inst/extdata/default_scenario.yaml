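# Default scenario of the coupled vascular-graph / double-continuum lung
# transport model.  All values SI; every key carries its unit suffix.
# Parameter provenance:
#   - printed registry values of the alveolus model (densities, porosities,
#     tortuosities, oncotic pressures, reflection coefficients, boundary
#     pressures, drug half-life)
#   - entries whose printed values are unavailable (lymphatic wall
#     conductivity, interstitial permeability/viscosity, capillary-wall
#     hydraulic conductivity and diffusive permeability, receptor kinetics,
#     inlet mole fraction) use mid-range literature values for macromolecule
#     transport in normal and neoplastic tissue; see the methods vignette.
blood:
  mass_density_kg_m3: 1050.0
  molar_density_mol_m3: 284.0
  plasma_viscosity_pa_s: 1.0e-3
  systemic_hematocrit: 0.45
  hematocrit_table:            # in-vivo tube hematocrit vs vessel diameter
    diameter_um: [4, 6, 8, 10, 15, 20, 30, 40, 60, 100, 200]
    hematocrit: [0.10, 0.14, 0.18, 0.21, 0.26, 0.30, 0.35, 0.38, 0.41, 0.43, 0.45]

drug:
  half_life_s: 21600.0         # 6 h bolus-injection half-life
  molecular_radius_m: 3.7e-9
  inlet_mole_fraction: 1.0e-6  # Dirichlet value at the arterial root
  bolus_duration_s: .inf       # continuous infusion

graph:
  n_alveoli: 21
  tumor_ids: [5, 11, 17]       # upscaled nodes carrying tumor properties
  root_order: 4
  arterial_pressure_pa: 1064.0
  venous_pressure_pa: 199.5

dcm_healthy:
  r_inner_m: 70.0e-6           # alveolar air space radius (140 um diameter)
  r_outer_m: 182.0e-6          # outer shell radius (364 um diameter)
  capillary_layer_thickness_m: 12.0e-6
  resolution: [4, 8, 6]        # (n_r, n_theta, n_phi)
  cap_half_angle_deg: 25.0
  tissue_outer_pressure_pa: -1064.0
  porosity: 0.13
  eps_tissue: 0.9
  eps_capillary: 0.1
  tortuosity: 0.28
  permeability_tissue_m2: 3.7e-17
  viscosity_interstitial_pa_s: 1.2e-3
  mass_density_interstitial_kg_m3: 1030.0
  molar_density_interstitial_mol_m3: 303.5
  capillary_viscosity_pa_s: 2.1e-3
  capillary_K_tangential_m2: 5.18e-14   # mean of the x/y REV permeabilities
                                        # of the default honeycomb bed
  capillary_K_normal_m2: 0.0            # planar sheet: zero normal K
  lymph_conductivity_m_pa_s: 2.6e-9
  lymph_surface_density_per_m: 3.0
  lymph_pressure_pa: -1200.0

dcm_tumor:
  r_outer_m: 182.0e-6
  resolution: [4, 8, 6]
  cap_half_angle_deg: 25.0
  tissue_outer_pressure_pa: 133.0
  porosity: 0.27
  eps_tissue: 0.8
  eps_capillary: 0.2
  tortuosity: 0.71
  permeability_tissue_m2: 2.2e-16
  viscosity_interstitial_pa_s: 1.2e-3
  mass_density_interstitial_kg_m3: 1030.0
  molar_density_interstitial_mol_m3: 303.5
  capillary_viscosity_pa_s: 2.1e-3
  tumor_capillary_radius_m: 10.0e-6     # K = r^2/8, isotropic
  receptor_concentration_mol_m3: 1.0e-4
  k_on_m3_mol_s: 100.0
  k_off_per_s: 1.0e-4

transfer_healthy:
  hydraulic_conductivity_m_pa_s: 2.7e-12
  surface_density_per_m: 1.8998e+4       # from the shell geometry
  osmotic_reflection: 0.8
  solvent_drag_reflection: 0.91
  diffusive_permeability_m_s: 5.7e-10
  oncotic_capillary_pa: 3724.0
  oncotic_interstitial_pa: 1862.0
  molar_density_transfer_mol_m3: 293.75

transfer_tumor:
  hydraulic_conductivity_m_pa_s: 2.1e-11
  surface_density_per_m: 2.0e+4
  osmotic_reflection: 0.8
  solvent_drag_reflection: 0.82
  diffusive_permeability_m_s: 5.7e-9
  oncotic_capillary_pa: 2660.0
  oncotic_interstitial_pa: 1995.0
  molar_density_transfer_mol_m3: 293.75

coupling:
  n_substeps: 1
  lymph_clamp: true
  newton_tol: 1.0e-8

run:
  t_end_s: 11.0
  courant: 0.9
  max_dt_s: 0.25
  output_interval_s: 1.0
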