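#' Therapeutic-agent properties
#'
#' @param half_life first-order degradation half-life, s.
#' @param molecular_radius hydrodynamic radius of the drug molecule, m.
#' @param inlet_mole_fraction Dirichlet mole fraction held at the arterial
#'   root during the bolus.
#' @param bolus_duration duration of the bolus injection, s (`Inf` =
#'   continuous infusion).
#' @param diffusivity_blood,diffusivity_interstitial aqueous diffusion
#'   coefficients, m^2/s; when `NULL` they are computed from the
#'   Stokes-Einstein relation at body temperature with the respective fluid
#'   viscosity.
#' @return object of class `drug_properties`.
#' @export
drug_properties <- function(half_life = 21600,
                            molecular_radius = 3.7e-9,
                            inlet_mole_fraction = 1e-6,
                            bolus_duration = Inf,
                            diffusivity_blood = NULL,
                            diffusivity_interstitial = NULL) {
  stopifnot(half_life > 0, molecular_radius > 0,
            inlet_mole_fraction >= 0, inlet_mole_fraction <= 1)
  if (is.null(diffusivity_blood))
    diffusivity_blood <-
      stokes_einstein_diffusivity(310.15, 0.0021, molecular_radius)
  if (is.null(diffusivity_interstitial))
    diffusivity_interstitial <-
      stokes_einstein_diffusivity(310.15, 1.2e-3, molecular_radius)
  structure(list(half_life = half_life, molecular_radius = molecular_radius,
                 inlet_mole_fraction = inlet_mole_fraction,
                 bolus_duration = bolus_duration,
                 diffusivity_blood = diffusivity_blood,
                 diffusivity_interstitial = diffusivity_interstitial),
            class = "drug_properties")
}

#' First-order decay rate from half-life
#'
#' `k = ln(2) / t_half`.
#'
#' @param half_life s (may be `Inf` for a non-degrading agent).
#' @return rate constant, 1/s.
#' @export
decay_rate <- function(half_life) {
  if (any(!(half_life > 0))) stop("half_life must be positive")
  log(2) / half_life
}

#' Transport state on the vascular graph
#'
#' @param graph a [vascular_graph()].
#' @param x0 initial mole fraction: scalar or named vector (node ids).
#' @param time initial time, s.
#' @return object of class `transport_state` with fields `x` (named per
#'   node), `time`, and `clipped_moles` (cumulative moles zero-floored).
#' @export
transport_state <- function(graph, x0 = 0, time = 0) {
  ids <- as.character(graph$nodes$id)
  x <- if (length(x0) == 1L && is.null(names(x0)))
    stats::setNames(rep(as.numeric(x0), length(ids)), ids)
  else {
    stopifnot(all(names(x0) %in% ids))
    out <- stats::setNames(numeric(length(ids)), ids)
    out[names(x0)] <- x0
    out
  }
  if (any(x < 0)) stop("mole fractions must be non-negative")
  structure(list(x = x, time = time, clipped_moles = 0,
                 effluent_moles = 0),
            class = "transport_state")
}

#' CFL-stable time step for the explicit upwind advection
#'
#' `dt = courant * min_i V_i / (total volumetric outflow from i)`; infinite
#' when there is no flow.
#'
#' @param flow a `flow_solution` from [solve_pressure()].
#' @param courant Courant number in `(0, 1]`.
#' @param outlet_nodes node ids through which flow leaves the domain
#'   (boundary nodes); their exterior outflow (equal to their net edge
#'   inflow) counts toward the CFL bound.
#' @return time step, s.
#' @export
cfl_timestep <- function(flow, courant = 0.9, outlet_nodes = NULL) {
  stopifnot(courant > 0, courant <= 1)
  V <- flow$node_volumes
  if (any(V <= 0)) stop("all node volumes must be positive")
  fl <- node_flow_split(flow)
  out <- fl$outflow
  if (!is.null(outlet_nodes)) {
    oc <- as.character(outlet_nodes)
    out[oc] <- out[oc] + pmax(fl$inflow[oc] - fl$outflow[oc], 0)
  }
  active <- out > 0
  if (!any(active)) return(Inf)
  courant * min(V[active] / out[active])
}

node_flow_split <- function(flow) {
  V <- flow$node_volumes
  outflow <- stats::setNames(numeric(length(V)), names(V))
  inflow <- outflow
  e <- flow$edges
  for (k in seq_len(nrow(e))) {
    q <- e$flow[k]
    a <- as.character(e$node_a[k]); b <- as.character(e$node_b[k])
    if (q > 0) { outflow[a] <- outflow[a] + q; inflow[b] <- inflow[b] + q }
    else if (q < 0) { outflow[b] <- outflow[b] - q
                      inflow[a] <- inflow[a] - q }
  }
  list(outflow = outflow, inflow = inflow)
}

#' Advance the drug mole fraction on the graph by one explicit step
#'
#' First-order upwind advection with the signed edge flows, first-order
#' degradation, and the upscaled-node coupling sinks:
#' `x_i' = x_i + dt/V_i (sum_in Q x_up - sum_out Q x_i) - dt k x_i
#'  - dt q_x,i / (rhomol V_i)`.
#' Dirichlet mole fractions (the bolus inlet) are re-imposed after the
#' update.  Negative values arising from coupling-sink overdraw are floored
#' at zero and the clipped moles are accumulated on the state.
#'
#' @param graph a [vascular_graph()].
#' @param flow a `flow_solution`.
#' @param state a [transport_state()].
#' @param dt time step, s; must not exceed [cfl_timestep()] at courant 1.
#' @param q_x named molar sinks at upscaled nodes, mol/s (may be `NULL`).
#' @param k decay rate, 1/s.
#' @param blood a [blood_properties()] (molar density).
#' @param dirichlet_x named mole fractions held fixed (e.g. the arterial
#'   root during the bolus).
#' @param outlet_nodes boundary node ids through which the blood (and with
#'   it the drug) leaves the domain; their exterior outflow equals their
#'   net edge inflow and the removed moles accumulate in
#'   `state$effluent_moles`.
#' @return updated `transport_state`.
#' @export
advance_transport <- function(graph, flow, state, dt, q_x = NULL,
                              k = 0, blood = blood_properties(),
                              dirichlet_x = NULL, outlet_nodes = NULL) {
  V <- flow$node_volumes
  x <- state$x
  dt_max <- cfl_timestep(flow, courant = 1, outlet_nodes = outlet_nodes)
  if (dt > dt_max * (1 + 1e-12))
    stop("dt = ", dt, " exceeds the CFL limit ", dt_max)
  e <- flow$edges
  ids <- names(x)
  inflow_m <- stats::setNames(numeric(length(ids)), ids)  # mol fraction * m^3/s
  outflow <- inflow_m
  for (kk in seq_len(nrow(e))) {
    q <- e$flow[kk]
    a <- as.character(e$node_a[kk]); b <- as.character(e$node_b[kk])
    if (q > 0) { outflow[a] <- outflow[a] + q
                 inflow_m[b] <- inflow_m[b] + q * x[a] }
    else if (q < 0) { outflow[b] <- outflow[b] - q
                      inflow_m[a] <- inflow_m[a] - q * x[b] }
  }
  effluent <- 0
  if (!is.null(outlet_nodes) && length(outlet_nodes)) {
    oc <- as.character(outlet_nodes)
    fl <- node_flow_split(flow)
    out_ext <- pmax(fl$inflow[oc] - fl$outflow[oc], 0)
    outflow[oc] <- outflow[oc] + out_ext
    effluent <- dt * sum(out_ext * x[oc]) * blood$molar_density
  }
  xn <- x + dt / V * (inflow_m - outflow * x) - dt * k * x
  if (!is.null(q_x) && length(q_x)) {
    qi <- as.character(names(q_x))
    kinds <- graph$nodes$kind[match(as.integer(qi), graph$nodes$id)]
    if (any(!startsWith(kinds, "upscaled") & q_x != 0))
      stop("q_x must be zero except at upscaled nodes")
    xn[qi] <- xn[qi] - dt * q_x / (blood$molar_density * V[qi])
  }
  clipped <- 0
  neg <- xn < 0
  if (any(neg)) {
    clipped <- -sum(xn[neg] * blood$molar_density * V[neg])
    xn[neg] <- 0
  }
  if (!is.null(dirichlet_x) && length(dirichlet_x))
    xn[as.character(names(dirichlet_x))] <- dirichlet_x
  structure(list(x = xn, time = state$time + dt,
                 clipped_moles = state$clipped_moles + clipped,
                 effluent_moles = state$effluent_moles + effluent),
            class = "transport_state")
}

#' Total moles of drug held in the graph
#'
#' `sum_i x_i rhomol V_i`.
#'
#' @param state a [transport_state()]. @param flow a `flow_solution`.
#' @param blood a [blood_properties()].
#' @param exclude node ids to leave out (e.g. Dirichlet inlet nodes when
#'   balancing the freely-evolving moles).
#' @return moles.
#' @export
graph_drug_moles <- function(state, flow, blood = blood_properties(),
                             exclude = NULL) {
  keep <- names(state$x)
  if (!is.null(exclude)) keep <- setdiff(keep, as.character(exclude))
  sum(state$x[keep] * blood$molar_density * flow$node_volumes[keep])
}
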