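#' Discrete capillary network inside a cuboid
#'
#' Container for the explicit capillary segments used by the
#' representative-elementary-volume (REV) permeability upscaling.
#'
#' @param nodes data.frame `id`, `x`, `y`, `z` (m).
#' @param segments data.frame `id`, `node_a`, `node_b`, `radius` (m),
#'   `length` (m).
#' @param cuboid_dims numeric length-3, `(Lx, Ly, Lz)` m; the cuboid spans
#'   `[0, Lx] x [0, Ly] x [0, Lz]`.
#' @param metadata named list.
#' @return object of class `capillary_network`.
#' @export
capillary_network <- function(nodes, segments, cuboid_dims,
                              metadata = list()) {
  stopifnot(length(cuboid_dims) == 3, all(cuboid_dims > 0),
            all(segments$radius > 0), all(segments$length > 0))
  eps <- 1e-9
  inside <- nodes$x >= -eps & nodes$x <= cuboid_dims[1] + eps &
    nodes$y >= -eps & nodes$y <= cuboid_dims[2] + eps &
    nodes$z >= -eps & nodes$z <= cuboid_dims[3] + eps
  if (!all(inside)) stop("capillary nodes must lie inside the cuboid")
  structure(list(nodes = nodes, segments = segments,
                 cuboid_dims = cuboid_dims, metadata = metadata),
            class = "capillary_network")
}

#' @export
print.capillary_network <- function(x, ...) {
  cat("<capillary_network> ", nrow(x$segments), " segments, ",
      nrow(x$nodes), " nodes; cuboid ",
      paste(signif(x$cuboid_dims * 1e6, 4), collapse = " x "), " um\n",
      sep = "")
  invisible(x)
}

#' Generate the planar hexagonal (honeycomb) alveolar capillary bed
#'
#' Builds a honeycomb lattice of capillary segments of uniform diameter in
#' the mid-plane `z = Lz/2` of the cuboid, clipped to the x-y extent:
#' segments crossing the lateral boundary are trimmed so that their
#' endpoints lie exactly on the cuboid face (these face endpoints later
#' receive the REV pressure boundary conditions).  The lattice pitch equals
#' `seg_length`, so the achievable segment count is set by the cuboid area;
#' the exact count is reported in `metadata$n_segments_actual` and is
#' required to lie within a documented tolerance (default 20%) of
#' `n_segments`.
#'
#' @param n_segments requested segment count (default 1800).
#' @param diameter capillary diameter, m (default 8e-6).
#' @param seg_length capillary segment (hexagon edge) length, m (1e-5).
#' @param cuboid `(Lx, Ly, Lz)` m; default `c(364e-6, 364e-6, 112e-6)`.
#' @param count_tolerance accepted relative deviation of the actual from
#'   the requested segment count.
#' @return a [capillary_network()].
#' @export
build_hexagonal_capillary_bed <- function(n_segments = 1800L,
                                          diameter = 8e-6,
                                          seg_length = 1e-5,
                                          cuboid = c(364e-6, 364e-6, 112e-6),
                                          count_tolerance = 0.20) {
  stopifnot(all(cuboid > 0), diameter > 0, seg_length > 0, n_segments >= 6)
  a <- seg_length
  Lx <- cuboid[1]; Ly <- cuboid[2]; Lz <- cuboid[3]
  if (Lx < sqrt(3) * a || Ly < 2 * a)
    stop("cuboid too small to hold a single hexagon of edge ", a)
  # pointy-top hexagons: centers on a triangular lattice, vertex circum-
  # radius a, horizontal pitch sqrt(3) a, vertical pitch 1.5 a
  nj <- ceiling(Ly / (1.5 * a)) + 2L
  ni <- ceiling(Lx / (sqrt(3) * a)) + 2L
  verts <- list(); edges_raw <- list()
  for (j in seq(-1L, nj)) {
    cy <- 1.5 * a * j
    for (i in seq(-1L, ni)) {
      cx <- sqrt(3) * a * (i + 0.5 * (j %% 2))
      ang <- pi / 180 * (90 + 60 * (0:5))
      vx <- cx + a * cos(ang); vy <- cy + a * sin(ang)
      for (kk in 1:6) {
        k2 <- if (kk == 6) 1L else kk + 1L
        edges_raw[[length(edges_raw) + 1L]] <-
          c(vx[kk], vy[kk], vx[k2], vy[k2])
      }
    }
  }
  em <- do.call(rbind, edges_raw)
  # dedupe shared hexagon edges via rounded endpoint keys
  keyp <- function(x, y) paste(round(x / a, 6), round(y / a, 6))
  k1 <- keyp(em[, 1], em[, 2]); k2 <- keyp(em[, 3], em[, 4])
  ekey <- ifelse(k1 < k2, paste(k1, k2), paste(k2, k1))
  em <- em[!duplicated(ekey), , drop = FALSE]
  # clip to [0,Lx] x [0,Ly]: keep interior edges, trim boundary-crossing ones
  clip_seg <- function(p, q) {
    # Liang-Barsky style clipping of segment p->q to the rectangle
    d <- q - p; t0 <- 0; t1 <- 1
    for (dim in 1:2) {
      lo <- 0; hi <- if (dim == 1) Lx else Ly
      if (abs(d[dim]) < 1e-18) {
        if (p[dim] < lo - 1e-15 || p[dim] > hi + 1e-15) return(NULL)
      } else {
        ta <- (lo - p[dim]) / d[dim]; tb <- (hi - p[dim]) / d[dim]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) return(NULL)
      }
    }
    rbind(p + t0 * d, p + t1 * d)
  }
  segs <- list()
  for (r in seq_len(nrow(em))) {
    cl <- clip_seg(em[r, 1:2], em[r, 3:4])
    if (is.null(cl)) next
    len <- sqrt(sum((cl[2, ] - cl[1, ])^2))
    if (len < 1e-2 * a) next  # degenerate sliver from clipping
    segs[[length(segs) + 1L]] <- c(cl[1, ], cl[2, ], len)
  }
  sm <- do.call(rbind, segs)
  # build unique node table
  nkey <- function(x, y) paste(round(x / a, 6), round(y / a, 6))
  allk <- c(nkey(sm[, 1], sm[, 2]), nkey(sm[, 3], sm[, 4]))
  allx <- c(sm[, 1], sm[, 3]); ally <- c(sm[, 2], sm[, 4])
  first <- !duplicated(allk)
  nodes <- data.frame(id = seq_len(sum(first)),
                      x = allx[first], y = ally[first], z = Lz / 2)
  idmap <- stats::setNames(nodes$id, allk[first])
  ns <- nrow(sm)
  segments <- data.frame(
    id = seq_len(ns),
    node_a = as.integer(idmap[nkey(sm[, 1], sm[, 2])]),
    node_b = as.integer(idmap[nkey(sm[, 3], sm[, 4])]),
    radius = diameter / 2,
    length = sm[, 5])
  segments <- segments[segments$node_a != segments$node_b, , drop = FALSE]
  segments$id <- seq_len(nrow(segments))
  actual <- nrow(segments)
  if (abs(actual - n_segments) > count_tolerance * n_segments)
    warning("generated ", actual, " segments; requested ", n_segments,
            " (outside the ", 100 * count_tolerance, "% tolerance)")
  capillary_network(nodes, segments, cuboid,
                    metadata = list(generator = "build_hexagonal_capillary_bed",
                                    n_segments_requested = n_segments,
                                    n_segments_actual = actual,
                                    count_tolerance = count_tolerance,
                                    seg_length = a, diameter = diameter))
}

face_nodes <- function(network, axis, eps = 1e-9) {
  ax <- match(axis, c("x", "y", "z"))
  co <- network$nodes[[c("x", "y", "z")[ax]]]
  L <- network$cuboid_dims[ax]
  list(lo = network$nodes$id[abs(co - 0) <= eps],
       hi = network$nodes$id[abs(co - L) <= eps])
}

#' Directional REV permeability of a capillary network
#'
#' Applies fixed pressures to all vessel endpoints crossing the two cuboid
#' faces normal to `axis` (no-flow at the remaining four faces, i.e. no
#' boundary condition at their nodes), solves the discrete network flow at
#' constant viscosity, and converts the integral flow to a Darcy
#' permeability: `K = Q mu L_axis / (A_axis dp)` with `A_axis` the face
#' area normal to the axis.  Linearity makes the result independent of the
#' probing pressures.
#'
#' @param network a [capillary_network()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param p_hi,p_lo probing pressures, Pa (default 100/0).
#' @param mu blood viscosity in the capillaries, Pa·s (default 0.0021).
#' @param eps face-crossing detection tolerance, m.
#' @return permeability, m^2 (0 with a warning when no endpoint reaches a
#'   face).
#' @export
rev_permeability <- function(network, axis = c("x", "y", "z"),
                             p_hi = 100, p_lo = 0, mu = 0.0021,
                             eps = 1e-9) {
  axis <- match.arg(axis)
  if (p_hi == p_lo) stop("p_hi must differ from p_lo")
  fn <- face_nodes(network, axis, eps)
  ax <- match(axis, c("x", "y", "z"))
  L_axis <- network$cuboid_dims[ax]
  A_axis <- prod(network$cuboid_dims[-ax])
  if (!length(fn$lo) || !length(fn$hi)) {
    warning("no vessel endpoint crosses the ", axis,
            "-normal faces; K_", axis, axis, " = 0")
    return(0)
  }
  e <- network$segments
  R <- 8 * mu * e$length / (pi * e$radius^4)
  bcs <- c(stats::setNames(rep(p_hi, length(fn$hi)), fn$hi),
           stats::setNames(rep(p_lo, length(fn$lo)), fn$lo))
  gshim <- list(nodes = data.frame(id = network$nodes$id, z_offset = 0),
                edges = data.frame(node_a = e$node_a, node_b = e$node_b))
  qv <- stats::setNames(numeric(nrow(network$nodes)),
                        as.character(network$nodes$id))
  p <- solve_pressure_linear(gshim, R, bcs, qv,
                             blood_properties(), gravity_model())
  # integral flow entering at the high-pressure face
  Q <- 0
  for (k in seq_len(nrow(e))) {
    a <- e$node_a[k]; b <- e$node_b[k]
    q <- (p[as.character(a)] - p[as.character(b)]) / R[k]
    if (a %in% fn$hi && !(b %in% fn$hi)) Q <- Q + q
    if (b %in% fn$hi && !(a %in% fn$hi)) Q <- Q - q
  }
  as.numeric(Q * mu * L_axis / (A_axis * (p_hi - p_lo)))
}

#' Symmetric positive-semidefinite permeability tensor
#'
#' @param K 3x3 symmetric matrix, m^2 (a scalar is promoted to an isotropic
#'   tensor).
#' @param frame `"cuboid"` or `"shell_local"`.
#' @return object of class `permeability_tensor`.
#' @export
permeability_tensor <- function(K, frame = c("cuboid", "shell_local")) {
  frame <- match.arg(frame)
  if (length(K) == 1L) K <- diag(3) * as.numeric(K)
  K <- as.matrix(K)
  stopifnot(all(dim(K) == c(3, 3)))
  if (max(abs(K - t(K))) > 1e-12 * max(abs(K), 1e-300))
    stop("permeability tensor must be symmetric")
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1e-300))
    stop("permeability tensor must be positive semidefinite")
  structure(list(K = (K + t(K)) / 2, frame = frame),
            class = "permeability_tensor")
}

#' Rotate a cuboid-frame permeability tensor onto the shell surface
#'
#' `K' = R K R^T`, where `R` is the rotation taking the cuboid z-axis onto
#' the local outward surface normal of the spherical shell.  For the planar
#' capillary sheet (`K_zz = 0`) the rotated tensor has zero permeability
#' normal to the shell.
#'
#' @param K_cuboid a [permeability_tensor()] in the cuboid frame.
#' @param surface_normal unit 3-vector.
#' @return a [permeability_tensor()] with `frame = "shell_local"`.
#' @export
rotate_tensor_to_shell <- function(K_cuboid, surface_normal) {
  stopifnot(inherits(K_cuboid, "permeability_tensor"))
  n <- surface_normal / sqrt(sum(surface_normal^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * n[3] - z[3] * n[2],
         z[3] * n[1] - z[1] * n[3],
         z[1] * n[2] - z[2] * n[1])
  c_ <- sum(z * n); s <- sqrt(sum(v^2))
  if (s < 1e-15) {
    R <- if (c_ > 0) diag(3) else diag(c(1, -1, -1))  # n = -z: flip about x
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                 3, 3, byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  }
  permeability_tensor(R %*% K_cuboid$K %*% t(R), frame = "shell_local")
}

#' Isotropic permeability of the tumor capillary bed
#'
#' Hagen-Poiseuille flow in a tube of radius r compared with Darcy's law
#' over the tube's own cross-section gives `K = r^2 / 8`.
#'
#' @param mean_capillary_radius mean tumor capillary radius, m.
#' @param as_tensor return a [permeability_tensor()] (default) or a scalar.
#' @return isotropic permeability (tensor or scalar), m^2.
#' @export
tumor_permeability <- function(mean_capillary_radius = 10e-6,
                               as_tensor = TRUE) {
  stopifnot(mean_capillary_radius > 0)
  K <- mean_capillary_radius^2 / 8
  if (as_tensor) permeability_tensor(K, "shell_local") else K
}

#' Stokes-Einstein diffusivity of a spherical molecule
#'
#' `D = k_B T / (6 pi mu r)` (equivalently `R T / (6 pi mu r N_A)`).
#'
#' @param T_K temperature, K. @param mu fluid viscosity, Pa·s.
#' @param r_mol molecular radius, m.
#' @return diffusion coefficient, m^2/s.
#' @export
stokes_einstein_diffusivity <- function(T_K, mu, r_mol) {
  stopifnot(all(T_K >= 0), all(mu > 0), all(r_mol > 0))
  kB <- 1.380649e-23
  kB * T_K / (6 * pi * mu * r_mol)
}

#' Capillary surface area per unit volume of the shell domain
#'
#' `S/V = N 2 pi r L / ((4/3) pi (R_out^3 - R_in^3))`.
#'
#' @param N number of capillary segments. @param r_cap capillary radius, m.
#' @param L_cap segment length, m. @param R_out,R_in shell radii, m.
#' @return surface density, 1/m.
#' @export
capillary_surface_density <- function(N, r_cap, L_cap, R_out, R_in) {
  if (!(R_out > R_in) || R_in < 0) stop("degenerate shell: need R_out > R_in >= 0")
  N * 2 * pi * r_cap * L_cap / ((4 / 3) * pi * (R_out^3 - R_in^3))
}
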