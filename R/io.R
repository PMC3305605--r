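#' Write simulation fields as legacy-VTK files
#'
#' Methods exist for the spherical DCM mesh (unstructured grid of
#' hexahedral cells with cell-data arrays) and the vascular graph
#' (polydata lines with point-data arrays).  Files are plain ASCII and
#' readable by standard VTK viewers.
#'
#' @param x a `dcm_mesh` or `vascular_graph`.
#' @param fields named list of per-cell (mesh) or per-node (graph) numeric
#'   vectors.
#' @param path output file path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, fields, path, ...) UseMethod("write_vtk")

#' @export
write_vtk.dcm_mesh <- function(x, fields, path, ...) {
  cells <- x$cells
  nc <- nrow(cells)
  for (nm in names(fields))
    if (length(fields[[nm]]) != nc)
      stop("field '", nm, "' length ", length(fields[[nm]]),
           " != cell count ", nc)
  sph <- function(r, t, p) c(r * cos(t), r * sin(t) * cos(p),
                             r * sin(t) * sin(p))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pulmosim DCM fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", 8L * nc), con)
  pts <- matrix(0, 8L * nc, 3)
  for (i in seq_len(nc)) {
    r1 <- x$r_edges[cells$ir[i]]; r2 <- x$r_edges[cells$ir[i] + 1L]
    t1 <- x$theta_edges[cells$it[i]]; t2 <- x$theta_edges[cells$it[i] + 1L]
    p1 <- x$phi_edges[cells$ip[i]]; p2 <- x$phi_edges[cells$ip[i] + 1L]
    corner <- rbind(sph(r1, t1, p1), sph(r2, t1, p1), sph(r2, t2, p1),
                    sph(r1, t2, p1), sph(r1, t1, p2), sph(r2, t1, p2),
                    sph(r2, t2, p2), sph(r1, t2, p2))
    pts[8L * (i - 1L) + 1:8, ] <- corner
  }
  writeLines(apply(pts, 1, function(p)
    paste(formatC(p, format = "e", digits = 9), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nc, 9L * nc), con)
  writeLines(vapply(seq_len(nc), function(i)
    paste(c(8L, 8L * (i - 1L) + 0:7), collapse = " "), ""), con)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(rep("12", nc), con)  # VTK_HEXAHEDRON
  writeLines(sprintf("CELL_DATA %d", nc), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(fields[[nm]], format = "e", digits = 9), con)
  }
  invisible(path)
}

#' @export
write_vtk.vascular_graph <- function(x, fields, path, ...) {
  n <- x$nodes; e <- x$edges
  for (nm in names(fields))
    if (length(fields[[nm]]) != nrow(n))
      stop("field '", nm, "' length != node count")
  idx <- stats::setNames(seq_len(nrow(n)) - 1L, as.character(n$id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pulmosim vascular graph", "ASCII", "DATASET POLYDATA"), con)
  writeLines(sprintf("POINTS %d double", nrow(n)), con)
  writeLines(sprintf("%.9e %.9e %.9e", n$x, n$y, n$z), con)
  writeLines(sprintf("LINES %d %d", nrow(e), 3L * nrow(e)), con)
  writeLines(sprintf("2 %d %d", idx[as.character(e$node_a)],
                     idx[as.character(e$node_b)]), con)
  writeLines(sprintf("POINT_DATA %d", nrow(n)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(fields[[nm]], format = "e", digits = 9), con)
  }
  invisible(path)
}

#' Write a time-series table as CSV
#'
#' Plain CSV with a header row (column names carry SI units); an empty
#' record list yields a header-only file.
#'
#' @param records data.frame (possibly 0 rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

# Results bundle of a coupled run: manifest, CSV series, VTK snapshots.
write_run_outputs <- function(run, graph, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(output_dir, "config.yaml")
  write_config(run$config, cfg_path)
  manifest <- list(
    package = "pulmosim",
    version = as.character(utils::packageVersion("pulmosim")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_steps = length(run$times),
    t_end_s = max(run$times),
    audit = run$audit)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_timeseries(run$node_series,
                   file.path(output_dir, "node_series.csv"))
  write_timeseries(run$upscaled_series,
                   file.path(output_dir, "upscaled_series.csv"))
  x <- run$final$transport$x[as.character(graph$nodes$id)]
  p <- run$final$flow$pressures[as.character(graph$nodes$id)]
  write_vtk(graph, list(mole_fraction = unname(x), pressure_pa = unname(p)),
            file.path(output_dir, "graph_final.vtk"))
  for (kind in c("healthy", "tumor")) {
    ids <- names(run$final$dcm_states)
    kmatch <- vapply(ids, function(id) {
      kk <- graph$nodes$kind[match(as.integer(id), graph$nodes$id)]
      (kind == "tumor") == (kk == "upscaled_tumor")
    }, logical(1))
    if (!any(kmatch)) next
    id <- ids[which(kmatch)[1]]
    st <- run$final$dcm_states[[id]]
    prob <- run$final$problems[[kind]]
    write_vtk(prob$mesh,
              list(p_t_pa = st$p_t, x_t = st$x_t, p_c_pa = st$p_c,
                   x_c = st$x_c, c_rl_mol_m3 = st$C_RL),
              file.path(output_dir, sprintf("dcm_%s_node%s_final.vtk",
                                            kind, id)))
  }
  invisible(output_dir)
}
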