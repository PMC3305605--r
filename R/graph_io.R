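GRAPH_SCHEMA <- "pulmosim-graph"
GRAPH_SCHEMA_VERSION <- 1L

#' Write a vascular graph to file
#'
#' Native format is a versioned JSON schema (all lengths in meters,
#' declared in the header); GraphML is provided as an interoperability
#' export with typed node/edge attributes.
#'
#' @param graph a [vascular_graph()].
#' @param path output file path.
#' @param format `"json"` (native) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(schema = GRAPH_SCHEMA, version = GRAPH_SCHEMA_VERSION,
                units = list(length = "m", compliance = "m^2/Pa"),
                metadata = graph$metadata,
                nodes = graph$nodes, edges = graph$edges)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
  } else {
    write_graphml(graph, path)
  }
  invisible(path)
}

#' Read a vascular graph from file
#'
#' @param path input file path.
#' @param format `"json"` or `"graphml"`.
#' @return a [vascular_graph()].
#' @export
read_graph <- function(path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(doc$schema) || doc$schema != GRAPH_SCHEMA)
      stop("not a ", GRAPH_SCHEMA, " file: ", path)
    if (is.null(doc$units$length) || doc$units$length != "m")
      stop("unit mismatch: field 'units.length' must be 'm', got '",
           doc$units$length, "'")
    nodes <- as.data.frame(doc$nodes); edges <- as.data.frame(doc$edges)
    for (f in c("id", "x", "y", "z", "kind", "z_offset"))
      if (is.null(nodes[[f]]) || anyNA(nodes[[f]]))
        stop("node attribute '", f, "' missing",
             if (!is.null(nodes[[f]]))
               paste0(" on node id ", nodes$id[which(is.na(nodes[[f]]))[1]]))
    for (f in c("id", "node_a", "node_b", "diameter", "length",
                "strahler_order", "vessel_class", "compliance"))
      if (is.null(edges[[f]]) || anyNA(edges[[f]]))
        stop("edge attribute '", f, "' missing",
             if (!is.null(edges[[f]]))
               paste0(" on edge id ", edges$id[which(is.na(edges[[f]]))[1]]))
    md <- doc$metadata
    if (is.data.frame(md)) md <- as.list(md)
    vascular_graph(nodes, edges, metadata = as.list(md))
  } else {
    read_graphml(path)
  }
}

graphml_keys <- list(
  node = list(kind = "string", x = "double", y = "double", z = "double",
              z_offset = "double"),
  edge = list(diameter = "double", length = "double",
              strahler_order = "int", vessel_class = "string",
              compliance = "double"))

write_graphml <- function(graph, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (dom in names(graphml_keys))
    for (nm in names(graphml_keys[[dom]]))
      xml2::xml_add_child(doc, "key", id = paste0(dom, "_", nm), "for" = dom,
                          attr.name = nm,
                          attr.type = graphml_keys[[dom]][[nm]])
  gx <- xml2::xml_add_child(doc, "graph", id = "vascular_graph",
                            edgedefault = "undirected")
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  for (i in seq_len(nrow(graph$nodes))) {
    r <- graph$nodes[i, ]
    nd <- xml2::xml_add_child(gx, "node", id = paste0("n", r$id))
    for (nm in names(graphml_keys$node)) {
      val <- r[[nm]]
      xml2::xml_add_child(nd, "data", key = paste0("node_", nm),
                          if (is.numeric(val)) fmt(val) else as.character(val))
    }
  }
  for (i in seq_len(nrow(graph$edges))) {
    r <- graph$edges[i, ]
    ed <- xml2::xml_add_child(gx, "edge", id = paste0("e", r$id),
                              source = paste0("n", r$node_a),
                              target = paste0("n", r$node_b))
    for (nm in names(graphml_keys$edge)) {
      val <- r[[nm]]
      xml2::xml_add_child(ed, "data", key = paste0("edge_", nm),
                          if (is.numeric(val)) fmt(val) else as.character(val))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nx <- xml2::xml_find_all(doc, ".//graph/node")
  ex <- xml2::xml_find_all(doc, ".//graph/edge")
  get_data <- function(el, key) {
    d <- xml2::xml_find_first(el, sprintf(".//data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nid <- as.integer(sub("^n", "", xml2::xml_attr(nx, "id")))
  nodes <- data.frame(
    id = nid,
    x = as.numeric(vapply(nx, get_data, "", key = "node_x")),
    y = as.numeric(vapply(nx, get_data, "", key = "node_y")),
    z = as.numeric(vapply(nx, get_data, "", key = "node_z")),
    kind = vapply(nx, get_data, "", key = "node_kind"),
    z_offset = as.numeric(vapply(nx, get_data, "", key = "node_z_offset")))
  edges <- data.frame(
    id = as.integer(sub("^e", "", xml2::xml_attr(ex, "id"))),
    node_a = as.integer(sub("^n", "", xml2::xml_attr(ex, "source"))),
    node_b = as.integer(sub("^n", "", xml2::xml_attr(ex, "target"))),
    diameter = as.numeric(vapply(ex, get_data, "", key = "edge_diameter")),
    length = as.numeric(vapply(ex, get_data, "", key = "edge_length")),
    strahler_order =
      as.integer(vapply(ex, get_data, "", key = "edge_strahler_order")),
    vessel_class = vapply(ex, get_data, "", key = "edge_vessel_class"),
    compliance = as.numeric(vapply(ex, get_data, "", key = "edge_compliance")))
  for (f in names(edges))
    if (anyNA(edges[[f]]))
      stop("edge attribute '", f, "' missing on edge id ",
           edges$id[which(is.na(edges[[f]]))[1]])
  for (f in names(nodes))
    if (anyNA(nodes[[f]]))
      stop("node attribute '", f, "' missing on node id ",
           nodes$id[which(is.na(nodes[[f]]))[1]])
  vascular_graph(nodes, edges,
                 metadata = list(source = "graphml", units = "SI (m)"))
}
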