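#' Blood properties and empirical rheology
#'
#' Bundles the fluid properties of blood used by the vascular graph model:
#' densities, plasma viscosity, the diameter-dependent microvessel
#' hematocrit lookup, and the parameters of the hematocrit/diameter
#' relative-viscosity relation.
#'
#' @param mass_density blood mass density, kg/m^3.
#' @param molar_density blood molar density, mol/m^3.
#' @param plasma_viscosity plasma (cell-free) viscosity, Pa·s.
#' @param hematocrit_table data.frame (`diameter_um`, `hematocrit`):
#'   monotone lookup of tube hematocrit versus vessel diameter.  The default
#'   is a representative in-vivo microvessel table (strong Fahraeus
#'   reduction below ~20 um, systemic 0.45 in large vessels).
#' @param systemic_hematocrit value used beyond the largest tabulated
#'   diameter.
#' @return object of class `blood_properties`.
#' @export
blood_properties <- function(mass_density = 1050,
                             molar_density = 284,
                             plasma_viscosity = 1e-3,
                             hematocrit_table = default_hematocrit_table(),
                             systemic_hematocrit = 0.45) {
  stopifnot(mass_density > 0, molar_density > 0, plasma_viscosity > 0)
  if (!nrow(hematocrit_table)) stop("hematocrit table must not be empty")
  if (any(hematocrit_table$hematocrit < 0 | hematocrit_table$hematocrit > 1))
    stop("hematocrit values must lie in [0, 1]")
  structure(list(mass_density = mass_density,
                 molar_density = molar_density,
                 plasma_viscosity = plasma_viscosity,
                 hematocrit_table =
                   hematocrit_table[order(hematocrit_table$diameter_um), ],
                 systemic_hematocrit = systemic_hematocrit),
            class = "blood_properties")
}

#' @rdname blood_properties
#' @export
default_hematocrit_table <- function() {
  data.frame(
    diameter_um = c(4, 6, 8, 10, 15, 20, 30, 40, 60, 100, 200),
    hematocrit  = c(0.10, 0.14, 0.18, 0.21, 0.26, 0.30, 0.35, 0.38,
                    0.41, 0.43, 0.45))
}

#' Tube hematocrit from vessel diameter
#'
#' Piecewise-linear interpolation of the configured hematocrit-versus-
#' diameter table, with constant extrapolation beyond the table range.
#'
#' @param d vessel diameter, m (vectorised).
#' @param blood a [blood_properties()].
#' @return hematocrit fraction in `[0, 1]`.
#' @export
hematocrit_from_diameter <- function(d, blood = blood_properties()) {
  stopifnot(all(d > 0))
  tab <- blood$hematocrit_table
  if (!nrow(tab)) stop("hematocrit table must not be empty")
  if (nrow(tab) == 1L) return(rep(tab$hematocrit, length(d)))
  stats::approx(tab$diameter_um * 1e-6, tab$hematocrit, xout = d,
                rule = 2)$y
}

#' Apparent blood viscosity from hematocrit and diameter
#'
#' Empirical relative-viscosity relation for blood flowing in narrow tubes
#' (Pries-type): the relative viscosity at 45% discharge hematocrit has a
#' pronounced minimum near 7-8 um (Fahraeus-Lindqvist effect) and the
#' hematocrit dependence enters through a diameter-dependent shape exponent.
#' At `H = 0` the apparent viscosity equals the plasma viscosity exactly.
#'
#' @param H hematocrit fraction in `[0, 1]`.
#' @param d vessel diameter, m.
#' @param blood a [blood_properties()]; supplies the plasma viscosity.
#' @return apparent viscosity, Pa·s (always `>= plasma_viscosity`).
#' @export
viscosity_from_hematocrit_diameter <- function(H, d,
                                               blood = blood_properties()) {
  stopifnot(all(H >= 0), all(H <= 1), all(d > 0))
  d_um <- d * 1e6
  mu45 <- 6 * exp(-0.085 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
  s <- 1 / (1 + 1e-11 * d_um^12)
  C <- (0.8 + exp(-0.075 * d_um)) * (s - 1) + s
  frac <- ifelse(H == 0, 0, ((1 - H)^C - 1) / ((1 - 0.45)^C - 1))
  mu_rel <- 1 + (mu45 - 1) * frac
  pmax(blood$plasma_viscosity * mu_rel, blood$plasma_viscosity)
}

#' Hagen-Poiseuille resistance of a vessel segment
#'
#' `R = 8 mu l / (pi (d/2)^4)`.
#'
#' @param d diameter, m. @param l length, m. @param mu viscosity, Pa·s.
#' @return resistance, Pa·s/m^3.
#' @export
segment_resistance <- function(d, l, mu) {
  if (any(!(d > 0)) || any(!(l > 0)) || any(!(mu > 0)))
    stop("segment_resistance: d, l and mu must all be positive")
  8 * mu * l / (pi * (d / 2)^4)
}

#' Volume associated with a graph node
#'
#' Half the volume of every incident vessel segment is attributed to the
#' node, `V_i = sum_j A_ij l_ij / 2`.
#'
#' @param graph a [vascular_graph()].
#' @param node node id (scalar) or `NULL` for all nodes.
#' @return volume(s), m^3 (named by node id when `node` is `NULL`).
#' @export
node_volume <- function(graph, node = NULL) {
  e <- graph$edges
  half <- pi * (e$diameter / 2)^2 * e$length / 2
  ids <- graph$nodes$id
  v <- stats::setNames(numeric(length(ids)), as.character(ids))
  for (k in seq_len(nrow(e))) {
    v[as.character(e$node_a[k])] <- v[as.character(e$node_a[k])] + half[k]
    v[as.character(e$node_b[k])] <- v[as.character(e$node_b[k])] + half[k]
  }
  if (is.null(node)) return(v)
  if (!node %in% ids) stop("node ", node, " not in graph")
  out <- v[[as.character(node)]]
  if (out <= 0) stop("node ", node, " is isolated (no incident edges)")
  out
}

#' Pressure-dependent vessel cross-section
#'
#' Linear compliance law `A(p) = A_ref + C (p - p_ref)`, floored at a
#' minimum fraction of the reference area.  With `C = 0` (the default in
#' the example scenario) the reference area is returned unchanged.
#'
#' @param A_ref reference cross-sectional area, m^2.
#' @param C cross-sectional compliance, m^2/Pa.
#' @param p local pressure, Pa. @param p_ref reference pressure, Pa.
#' @param min_fraction lower bound on `A/A_ref` (default 0.1).
#' @return area, m^2.
#' @export
compliant_area <- function(A_ref, C, p, p_ref, min_fraction = 0.1) {
  stopifnot(all(A_ref > 0))
  pmax(A_ref + C * (p - p_ref), min_fraction * A_ref)
}
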