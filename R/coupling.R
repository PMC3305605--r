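#' Locate an upscaled node's arterial and venous neighbors
#'
#' @param graph a [vascular_graph()].
#' @param vgm_node_id id of an upscaled node.
#' @return list `arterial` and `venous` neighbor node ids, and the ids of
#'   the two upscaled edges (`edge_arterial`, `edge_venous`).
#' @export
upscaled_neighbors <- function(graph, vgm_node_id) {
  n <- graph$nodes; e <- graph$edges
  kind <- n$kind[match(vgm_node_id, n$id)]
  if (is.na(kind) || !startsWith(kind, "upscaled"))
    stop("node ", vgm_node_id, " is not an upscaled node")
  inc <- e[e$node_a == vgm_node_id | e$node_b == vgm_node_id, ]
  if (nrow(inc) != 2L) stop("upscaled node must have exactly 2 edges")
  side_of <- function(nb) {
    cls <- e$vessel_class[(e$node_a == nb | e$node_b == nb) &
                            e$vessel_class != "upscaled_edge"]
    if (any(cls %in% c("artery", "arteriole"))) "arterial"
    else if (any(cls %in% c("vein", "venule"))) "venous"
    else NA_character_
  }
  nb <- ifelse(inc$node_a == vgm_node_id, inc$node_b, inc$node_a)
  sides <- vapply(nb, side_of, "")
  if (!setequal(sides, c("arterial", "venous")))
    stop("upscaled node ", vgm_node_id,
         " lacks a distinct arterial/venous neighbor pair")
  list(arterial = nb[sides == "arterial"], venous = nb[sides == "venous"],
       edge_arterial = inc$id[sides == "arterial"],
       edge_venous = inc$id[sides == "venous"])
}

#' Capillary boundary conditions for an upscaled node from the VGM state
#'
#' Dirichlet pressures and mole fractions for the DCM capillary continuum
#' are copied from the two VGM nodes adjacent to the upscaled node.
#'
#' @param graph a [vascular_graph()]. @param flow a `flow_solution`.
#' @param state a [transport_state()]. @param vgm_node_id upscaled node id.
#' @return list `p_art`, `p_ven` (Pa), `x_art`, `x_ven`.
#' @export
capillary_bcs_from_vgm <- function(graph, flow, state, vgm_node_id) {
  nb <- upscaled_neighbors(graph, vgm_node_id)
  list(p_art = unname(flow$pressures[as.character(nb$arterial)]),
       p_ven = unname(flow$pressures[as.character(nb$venous)]),
       x_art = unname(state$x[as.character(nb$arterial)]),
       x_ven = unname(state$x[as.character(nb$venous)]))
}

# Build the DCM problems for the two upscaled-node kinds from a scenario
# configuration (see default_scenario()).
build_upscaled_problems <- function(config, drug = config_drug(config)) {
  h <- config$dcm_healthy; t <- config$dcm_tumor
  mesh_h <- build_dcm_mesh("shell", h$r_inner_m, h$r_outer_m,
                           resolution = h$resolution,
                           cap_half_angle = h$cap_half_angle_deg,
                           inner_layer_thickness =
                             h$capillary_layer_thickness_m)
  mesh_t <- build_dcm_mesh("sphere", 0, t$r_outer_m,
                           resolution = t$resolution,
                           cap_half_angle = t$cap_half_angle_deg)
  ctl <- list(newton_tol = config$coupling$newton_tol,
              lymph_clamp = config$coupling$lymph_clamp)
  list(
    healthy = dcm_problem(
      mesh_h,
      tissue = tissue_parameters(
        porosity = h$porosity, eps_t = h$eps_tissue,
        K_t = h$permeability_tissue_m2, tortuosity = h$tortuosity,
        mu_int = h$viscosity_interstitial_pa_s,
        rho_int = h$mass_density_interstitial_kg_m3,
        rhomol_int = h$molar_density_interstitial_mol_m3,
        lymph = list(L_p_ly = h$lymph_conductivity_m_pa_s,
                     S_ly_V = h$lymph_surface_density_per_m,
                     p_ly = h$lymph_pressure_pa)),
      capillary = capillary_parameters(
        eps_c = h$eps_capillary,
        K_tangential = h$capillary_K_tangential_m2,
        K_normal = h$capillary_K_normal_m2,
        mu_c = h$capillary_viscosity_pa_s),
      transfer = config_transfer(config, "healthy"),
      drug = drug, p_t_outer = h$tissue_outer_pressure_pa,
      control = ctl),
    tumor = dcm_problem(
      mesh_t,
      tissue = tissue_parameters(
        porosity = t$porosity, eps_t = t$eps_tissue,
        K_t = t$permeability_tissue_m2, tortuosity = t$tortuosity,
        mu_int = t$viscosity_interstitial_pa_s,
        rho_int = t$mass_density_interstitial_kg_m3,
        rhomol_int = t$molar_density_interstitial_mol_m3,
        lymph = NULL,
        receptor = list(C_R0 = t$receptor_concentration_mol_m3,
                        k_on = t$k_on_m3_mol_s,
                        k_off = t$k_off_per_s)),
      capillary = {
        K <- tumor_permeability(t$tumor_capillary_radius_m,
                                as_tensor = FALSE)
        capillary_parameters(eps_c = t$eps_capillary, K_tangential = K,
                             K_normal = K,
                             mu_c = t$capillary_viscosity_pa_s)
      },
      transfer = config_transfer(config, "tumor"),
      drug = drug, p_t_outer = t$tissue_outer_pressure_pa,
      control = ctl))
}

#' Run the coupled VGM/DCM simulation
#'
#' The sequential coupling loop: at every step the graph pressure and flow
#' fields are solved with the previous step's fluid sinks, a CFL-stable
#' transport step advects the drug with the previous step's molar sinks,
#' and each upscaled node's double-continuum model is advanced over the
#' same interval with boundary conditions taken from its adjacent graph
#' nodes.  The volume-integrated transvascular exchange of each node
#' becomes the sink pair applied to the graph in the next step (lagged
#' coupling; the first step uses zero sinks).
#'
#' @param graph a [vascular_graph()] with at least one upscaled node
#'   (default: the example network of [build_coupled_example()]).
#' @param config scenario configuration (see [default_scenario()]).
#' @param t_end final time, s (default from `config$run$t_end_s`).
#' @param output_dir when non-`NULL`, writes the run manifest, CSV time
#'   series and VTK field snapshots there.
#' @param progress print progress every ~10% of the run.
#' @return list of class `coupled_run`: `times`, `node_series` (long
#'   data.frame: time, node, x, p), `upscaled_series` (time, node, kind,
#'   q_mass, q_x, tissue/bound moles), `audit` (global drug ledger),
#'   `final` (flow solution, transport state, DCM states), `config`.
#' @export
run_coupled <- function(graph = build_coupled_example(),
                        config = default_scenario(), t_end = NULL,
                        output_dir = NULL, progress = FALSE) {
  validate_graph(graph)
  if (is.null(t_end)) t_end <- config$run$t_end_s
  blood <- config_blood(config)
  drug <- config_drug(config)
  k <- decay_rate(drug$half_life)
  n <- graph$nodes
  ups <- n$id[startsWith(n$kind, "upscaled")]
  if (!length(ups)) stop("graph has no upscaled node")
  kinds <- ifelse(n$kind[match(ups, n$id)] == "upscaled_tumor",
                  "tumor", "healthy")
  probs <- build_upscaled_problems(config, drug)
  # effective resistances (one per kind; cached)
  R_eff <- vapply(c(healthy = "healthy", tumor = "tumor"), function(kk)
    effective_upscaled_resistance(probs[[kk]]), numeric(1))
  nbrs <- lapply(ups, upscaled_neighbors, graph = graph)
  names(nbrs) <- as.character(ups)
  R_override <- numeric(0)
  for (i in seq_along(ups)) {
    rr <- R_eff[[kinds[i]]] / 2
    R_override[as.character(nbrs[[i]]$edge_arterial)] <- rr
    R_override[as.character(nbrs[[i]]$edge_venous)] <- rr
  }
  # Dirichlet pressures at the boundary nodes
  bcs <- c(
    stats::setNames(rep(config$graph$arterial_pressure_pa,
                        sum(n$kind == "boundary_arterial")),
                    n$id[n$kind == "boundary_arterial"]),
    stats::setNames(rep(config$graph$venous_pressure_pa,
                        sum(n$kind == "boundary_venous")),
                    n$id[n$kind == "boundary_venous"]))
  art_bnd <- n$id[n$kind == "boundary_arterial"]
  all_bnd <- n$id[startsWith(n$kind, "boundary")]
  state <- transport_state(graph, 0)
  q_mass <- stats::setNames(rep(0, length(ups)), ups)
  q_x <- q_mass
  dcm_states <- stats::setNames(vector("list", length(ups)), ups)
  t_now <- 0; times <- numeric(0)
  node_series <- list(); ups_series <- list()
  ledger <- list(injected = 0, returned = 0, decayed = 0, transferred = 0,
                 dcm_gained = 0, fluid_extracted_kg = 0, lymph_cleared = 0,
                 boundary_outflow = 0, clipped = 0, effluent = 0)
  m0 <- 0
  out_next <- 0
  step_no <- 0L
  n_sub <- max(1L, as.integer(config$coupling$n_substeps))
  flow <- NULL
  prev_dir <- character(0)
  while (t_now < t_end - 1e-12) {
    flow <- solve_pressure(graph, blood, bcs,
                           q_mass = q_mass, R_override = R_override)
    dt <- min(cfl_timestep(flow, config$run$courant,
                           outlet_nodes = all_bnd),
              t_end - t_now, config$run$max_dt_s)
    if (!is.finite(dt) || dt <= 0) stop("no admissible time step (no flow?)")
    dir_x <- if (t_now < drug$bolus_duration)
      stats::setNames(rep(drug$inlet_mole_fraction, length(art_bnd)), art_bnd)
    else NULL
    # nodes leaving the Dirichlet set (bolus end) release their content
    # into the freely-balanced pool
    released <- setdiff(prev_dir, names(dir_x))
    if (length(released))
      ledger$injected <- ledger$injected +
        sum(state$x[released] * blood$molar_density *
              flow$node_volumes[released])
    prev_dir <- names(dir_x) %||% character(0)
    free_ids <- setdiff(names(state$x), names(dir_x))
    outlets <- setdiff(as.character(all_bnd), names(dir_x))
    # graph ledger terms computed with the pre-step state
    decay_step <- dt * k *
      sum(state$x[free_ids] * blood$molar_density *
            flow$node_volumes[free_ids])
    io <- dirichlet_exchange(flow, state, names(dir_x), blood)
    clipped_before <- state$clipped_moles
    effluent_before <- state$effluent_moles
    state <- advance_transport(graph, flow, state, dt, q_x = q_x, k = k,
                               blood = blood, dirichlet_x = dir_x,
                               outlet_nodes = outlets)
    ledger$injected <- ledger$injected + dt * io$out
    ledger$returned <- ledger$returned + dt * io$back
    ledger$decayed <- ledger$decayed + decay_step
    ledger$transferred <- ledger$transferred + dt * sum(q_x)
    ledger$fluid_extracted_kg <- ledger$fluid_extracted_kg + dt * sum(q_mass)
    ledger$clipped <- ledger$clipped + (state$clipped_moles - clipped_before)
    ledger$effluent <- ledger$effluent +
      (state$effluent_moles - effluent_before)
    # advance every upscaled node's DCM over dt with current BCs
    q_mass_new <- q_mass; q_x_new <- q_x
    for (i in seq_along(ups)) {
      id <- as.character(ups[i])
      prob <- probs[[kinds[i]]]
      bc <- capillary_bcs_from_vgm(graph, flow, state, ups[i])
      if (is.null(dcm_states[[id]]))
        dcm_states[[id]] <- initial_dcm_state(prob, bc$p_art, bc$p_ven,
                                              bc$x_art, bc$x_ven,
                                              time = t_now)
      st <- dcm_states[[id]]
      exch <- NULL
      for (ss in seq_len(n_sub)) {
        stp <- step_implicit(st, dt / n_sub, prob, bc)
        st <- stp$state
        exch <- stp$exchange
        ledger$dcm_gained <- ledger$dcm_gained +
          dt / n_sub * stp$exchange$q_x
        ledger$lymph_cleared <- ledger$lymph_cleared +
          dt / n_sub * stp$diag$lymph_drug_rate
        ledger$boundary_outflow <- ledger$boundary_outflow +
          dt / n_sub * stp$diag$tissue_boundary_outflow
      }
      dcm_states[[id]] <- st
      q_mass_new[id] <- exch$q_mass
      q_x_new[id] <- exch$q_x
      ups_series[[length(ups_series) + 1L]] <- data.frame(
        time = t_now + dt, node = ups[i], kind = kinds[i],
        q_mass = exch$q_mass, q_x = exch$q_x,
        tissue_moles = dcm_tissue_moles(prob, st)$free,
        bound_moles = dcm_tissue_moles(prob, st)$bound,
        max_p_t = max(st$p_t), max_x_t = max(st$x_t),
        max_x_c = max(st$x_c[prob$act]))
    }
    q_mass <- q_mass_new; q_x <- q_x_new
    t_now <- t_now + dt
    step_no <- step_no + 1L
    if (t_now >= out_next - 1e-12 || t_now >= t_end - 1e-12) {
      node_series[[length(node_series) + 1L]] <- data.frame(
        time = t_now, node = n$id,
        x = unname(state$x[as.character(n$id)]),
        p = unname(flow$pressures[as.character(n$id)]))
      out_next <- out_next + config$run$output_interval_s
    }
    times <- c(times, t_now)
    if (progress && step_no %% 25L == 0L)
      message(sprintf("t = %.3f / %.3f s (step %d, dt = %.3g s)",
                      t_now, t_end, step_no, dt))
  }
  # close the ledger over the freely-balanced nodes
  m_end <- graph_drug_moles(state, flow, blood, exclude = prev_dir)
  tissue_end <- 0; bound_end <- 0
  for (i in seq_along(ups)) {
    tm <- dcm_tissue_moles(probs[[kinds[i]]], dcm_states[[as.character(ups[i])]])
    tissue_end <- tissue_end + tm$free
    bound_end <- bound_end + tm$bound
  }
  audit <- drug_audit(ledger, m0, m_end, tissue_end, bound_end)
  out <- structure(list(
    times = times,
    node_series = do.call(rbind, node_series),
    upscaled_series = do.call(rbind, ups_series),
    audit = audit, ledger = ledger,
    final = list(flow = flow, transport = state, dcm_states = dcm_states,
                 problems = probs, R_eff = R_eff, q_x = q_x,
                 q_mass = q_mass),
    config = config), class = "coupled_run")
  if (!is.null(output_dir)) write_run_outputs(out, graph, output_dir)
  out
}

# molar exchange with the Dirichlet-x nodes: `out` = moles/s leaving them
# into the free graph, `back` = moles/s flowing back into them.
dirichlet_exchange <- function(flow, state, dir_ids, blood) {
  if (is.null(dir_ids) || !length(dir_ids)) return(list(out = 0, back = 0))
  e <- flow$edges
  out <- 0; back <- 0
  for (kk in seq_len(nrow(e))) {
    q <- e$flow[kk]
    a <- as.character(e$node_a[kk]); b <- as.character(e$node_b[kk])
    if (q > 0) { up <- a; dn <- b } else if (q < 0) { up <- b; dn <- a
    } else next
    if (up %in% dir_ids && !(dn %in% dir_ids))
      out <- out + abs(q) * state$x[up] * blood$molar_density
    if (dn %in% dir_ids && !(up %in% dir_ids))
      back <- back + abs(q) * state$x[up] * blood$molar_density
  }
  list(out = unname(out), back = unname(back))
}

# Two-ledger global drug balance.  Graph ledger: net moles supplied by the
# bolus inlet must equal the graph storage change plus degradation plus the
# coupling sinks actually applied (lagged by one step).  Tissue ledger: the
# exchange the DCMs computed must equal the tissue + bound storage change
# plus lymphatic clearance and tissue-boundary outflow.  `in_transit` is
# the exchange computed in the final step that the lagged scheme has not
# yet charged to the graph.
drug_audit <- function(ledger, m0, m_end, tissue_end, bound_end) {
  supplied <- ledger$injected - ledger$returned + ledger$clipped
  accounted <- (m_end - m0) + ledger$decayed + ledger$transferred +
    ledger$effluent
  graph_closure <- abs(supplied - accounted) /
    max(abs(supplied), abs(accounted), 1e-300)
  tissue_accounted <- tissue_end + bound_end + ledger$lymph_cleared +
    ledger$boundary_outflow
  tissue_closure <- if (ledger$dcm_gained > 0)
    abs(ledger$dcm_gained - tissue_accounted) / ledger$dcm_gained else 0
  list(injected = ledger$injected, returned = ledger$returned,
       net_supplied = supplied,
       graph_delta = m_end - m0, decayed = ledger$decayed,
       transferred = ledger$transferred, dcm_gained = ledger$dcm_gained,
       in_transit = ledger$dcm_gained - ledger$transferred,
       tissue_stored = tissue_end, bound = bound_end,
       lymph_cleared = ledger$lymph_cleared,
       tissue_boundary_outflow = ledger$boundary_outflow,
       effluent = ledger$effluent, clipped = ledger$clipped,
       graph_closure = graph_closure, tissue_closure = tissue_closure,
       closure = max(graph_closure, tissue_closure))
}

#' @export
print.coupled_run <- function(x, ...) {
  cat("<coupled_run> ", length(x$times), " steps to t = ",
      signif(max(x$times), 4), " s\n", sep = "")
  cat("  drug ledger closure (relative): ",
      format(x$audit$closure, digits = 3), "\n", sep = "")
  cat("  net supplied ", format(x$audit$net_supplied, digits = 4),
      " mol; transferred to tissue ",
      format(x$audit$transferred, digits = 4), " mol\n", sep = "")
  invisible(x)
}
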