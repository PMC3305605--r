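#' Gravity model for the blood-pressure head correction
#'
#' When enabled, the nodal pressure entering the flow equation is corrected
#' by `rho g z_offset`, where `z_offset` is the signed distance of the node
#' to the pulmonary-artery entry along the gravity axis.  Disabled in the
#' shipped example scenario.
#'
#' @param enabled logical. @param g gravitational acceleration, m/s^2.
#' @param direction unit 3-vector (default negative z).
#' @return object of class `gravity_model`.
#' @export
gravity_model <- function(enabled = FALSE, g = 9.81,
                          direction = c(0, 0, -1)) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-8) stop("gravity direction must be a unit vector")
  structure(list(enabled = enabled, g = g, direction = direction),
            class = "gravity_model")
}

edge_hydraulics <- function(graph, blood, R_override = NULL,
                            area_scale = NULL) {
  e <- graph$edges
  H <- hematocrit_from_diameter(e$diameter, blood)
  mu <- viscosity_from_hematocrit_diameter(H, e$diameter, blood)
  R <- segment_resistance(e$diameter, e$length, mu)
  if (!is.null(area_scale)) R <- R / area_scale^2  # R ~ A^-2 at fixed length
  if (!is.null(R_override)) {
    idx <- match(as.integer(names(R_override)), e$id)
    if (anyNA(idx)) stop("R_override names unknown edge id")
    R[idx] <- as.numeric(R_override)
  }
  list(H = H, mu = mu, R = R)
}

#' Solve the nodal pressure/flow system of the vascular graph
#'
#' Builds per-edge Poiseuille resistances from the hematocrit- and
#' diameter-dependent viscosity, then solves the sparse linear continuity
#' system: at every free node the signed edge flows balance the (volumetric)
#' coupling sink `q_mass / rho`.  Dirichlet pressures are imposed at the
#' boundary nodes.  Optional pressure-dependent cross-sections are handled
#' by a fixed-point iteration (area to resistance to pressure).
#'
#' @param graph a [vascular_graph()].
#' @param blood a [blood_properties()].
#' @param bcs named numeric vector of Dirichlet pressures, Pa (names are
#'   node ids); at least one entry is required.
#' @param q_mass named numeric vector of mass sinks at upscaled nodes, kg/s
#'   (positive = fluid leaving the graph into the tissue); may be `NULL`.
#' @param gravity a [gravity_model()].
#' @param R_override named numeric vector of per-edge resistance overrides,
#'   Pa·s/m^3 (names are edge ids); used by the coupling layer to give
#'   upscaled edges their effective capillary-bed resistance.
#' @param compliance_tol,compliance_maxit fixed-point controls for the
#'   compliant-area iteration (only entered when any edge has `compliance
#'   > 0`).
#' @return object of class `flow_solution`: `pressures` (named, Pa),
#'   `edges` (data.frame with signed `flow` m^3/s positive from `node_a` to
#'   `node_b`, `viscosity`, `hematocrit`, `resistance`), `node_volumes`
#'   (named, m^3), and `residual` (max relative nodal imbalance).
#' @export
solve_pressure <- function(graph, blood = blood_properties(), bcs,
                           q_mass = NULL, gravity = gravity_model(),
                           R_override = NULL,
                           compliance_tol = 1e-8, compliance_maxit = 50L) {
  n <- graph$nodes; e <- graph$edges
  if (is.null(names(bcs)) || !length(bcs))
    stop("bcs must be a non-empty named vector (node id -> Pa)")
  if (any(!is.finite(bcs))) stop("non-finite Dirichlet pressure")
  bc_ids <- as.integer(names(bcs))
  if (!all(bc_ids %in% n$id)) stop("bcs name unknown node id")
  qv <- stats::setNames(numeric(nrow(n)), as.character(n$id))
  if (!is.null(q_mass) && length(q_mass)) {
    if (any(!is.finite(q_mass))) stop("non-finite q_mass")
    qi <- as.character(names(q_mass))
    kinds <- n$kind[match(as.integer(qi), n$id)]
    if (any(!startsWith(kinds, "upscaled") & q_mass != 0))
      stop("q_mass must be zero except at upscaled nodes")
    qv[qi] <- q_mass / blood$mass_density
  }
  hyd <- edge_hydraulics(graph, blood, R_override)
  use_compliance <- any(e$compliance > 0)
  p_ref <- mean(bcs)
  area_scale <- NULL
  A_ref <- pi * (e$diameter / 2)^2
  p <- NULL
  for (it in seq_len(if (use_compliance) compliance_maxit else 1L)) {
    hyd_it <- if (is.null(area_scale)) hyd else
      edge_hydraulics(graph, blood, R_override, area_scale)
    p_new <- solve_pressure_linear(graph, hyd_it$R, bcs, qv, blood, gravity)
    if (use_compliance) {
      p_edge <- (p_new[as.character(e$node_a)] + p_new[as.character(e$node_b)]) / 2
      A <- compliant_area(A_ref, e$compliance, p_edge, p_ref)
      area_scale_new <- A / A_ref
      if (!is.null(p) &&
          max(abs(p_new - p)) <= compliance_tol * max(abs(p_new), 1))
        { p <- p_new; area_scale <- area_scale_new; break }
      p <- p_new; area_scale <- area_scale_new
      if (it == compliance_maxit)
        warning("compliance fixed point did not converge in ",
                compliance_maxit, " iterations")
    } else p <- p_new
  }
  hyd_fin <- if (is.null(area_scale)) hyd else
    edge_hydraulics(graph, blood, R_override, area_scale)
  head <- if (gravity$enabled)
    blood$mass_density * gravity$g *
      (n$z_offset[match(e$node_a, n$id)] - n$z_offset[match(e$node_b, n$id)])
  else 0
  flow <- (p[as.character(e$node_a)] - p[as.character(e$node_b)] + head) /
    hyd_fin$R
  edges_out <- data.frame(id = e$id, node_a = e$node_a, node_b = e$node_b,
                          flow = as.numeric(flow),
                          viscosity = hyd_fin$mu, hematocrit = hyd_fin$H,
                          resistance = hyd_fin$R)
  # nodal balance residual (free nodes only), relative to local flow scale
  net <- stats::setNames(numeric(nrow(n)), as.character(n$id))
  absf <- net
  for (k in seq_len(nrow(e))) {
    a <- as.character(e$node_a[k]); b <- as.character(e$node_b[k])
    net[a] <- net[a] - flow[k]; net[b] <- net[b] + flow[k]
    absf[a] <- absf[a] + abs(flow[k]); absf[b] <- absf[b] + abs(flow[k])
  }
  free <- setdiff(as.character(n$id), as.character(bc_ids))
  rel <- abs(net[free] - qv[free]) / pmax(absf[free], 1e-300)
  structure(list(pressures = p, edges = edges_out,
                 node_volumes = node_volume(graph),
                 residual = if (length(free)) max(rel) else 0),
            class = "flow_solution")
}

solve_pressure_linear <- function(graph, R, bcs, qv, blood, gravity) {
  n <- graph$nodes; e <- graph$edges
  ids <- as.character(n$id)
  idx <- stats::setNames(seq_along(ids), ids)
  bc_ids <- as.character(as.integer(names(bcs)))
  is_bc <- ids %in% bc_ids
  free <- which(!is_bc)
  if (!length(free)) return(stats::setNames(bcs[ids], ids))
  fidx <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  fidx[free] <- seq_along(free)
  g <- 1 / R
  head <- if (gravity$enabled)
    blood$mass_density * gravity$g *
      (n$z_offset[match(e$node_a, n$id)] - n$z_offset[match(e$node_b, n$id)])
  else rep(0, nrow(e))
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- -qv[ids[free]]  # continuity: sum_j (p_j - p_i)/R_ij = q_i
  rhs <- as.numeric(rhs)
  pvals <- stats::setNames(rep(NA_real_, length(ids)), ids)
  pvals[bc_ids] <- bcs[as.character(as.integer(names(bcs)))][bc_ids]
  # assemble Laplacian rows for free nodes
  ia <- idx[as.character(e$node_a)]; ib <- idx[as.character(e$node_b)]
  for (k in seq_len(nrow(e))) {
    a <- ia[k]; b <- ib[k]; gk <- g[k]
    if (!is_bc[a]) {
      trip_i <- c(trip_i, fidx[a]); trip_j <- c(trip_j, fidx[a])
      trip_x <- c(trip_x, gk)
      if (!is_bc[b]) {
        trip_i <- c(trip_i, fidx[a]); trip_j <- c(trip_j, fidx[b])
        trip_x <- c(trip_x, -gk)
      } else rhs[fidx[a]] <- rhs[fidx[a]] + gk * pvals[b]
      rhs[fidx[a]] <- rhs[fidx[a]] - gk * head[k]
    }
    if (!is_bc[b]) {
      trip_i <- c(trip_i, fidx[b]); trip_j <- c(trip_j, fidx[b])
      trip_x <- c(trip_x, gk)
      if (!is_bc[a]) {
        trip_i <- c(trip_i, fidx[b]); trip_j <- c(trip_j, fidx[a])
        trip_x <- c(trip_x, -gk)
      } else rhs[fidx[b]] <- rhs[fidx[b]] + gk * pvals[a]
      rhs[fidx[b]] <- rhs[fidx[b]] + gk * head[k]
    }
  }
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(free), length(free)))
  sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                  error = function(err)
                    stop("singular pressure system (is every component ",
                         "anchored by a Dirichlet node?): ",
                         conditionMessage(err)))
  pvals[free] <- sol
  pvals
}
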