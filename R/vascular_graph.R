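#' Vascular graph data model
#'
#' A `vascular_graph` holds the discrete representation of the non-capillary
#' pulmonary vasculature: nodes (bifurcation points, vessel endpoints,
#' upscaled alveolar nodes) and edges (vessel segments with a mean diameter,
#' a length and a Strahler order).  All geometry is in SI meters.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`,
#'   `z` (position, m), `kind` (one of `"regular"`, `"boundary_arterial"`,
#'   `"boundary_venous"`, `"upscaled_healthy"`, `"upscaled_tumor"`) and
#'   `z_offset` (signed distance to the pulmonary-artery entry along the
#'   gravity axis, m).
#' @param edges data.frame with columns `id` (integer, unique), `node_a`,
#'   `node_b` (node ids), `diameter`, `length` (m), `strahler_order`
#'   (integer >= 1), `vessel_class` (one of `"artery"`, `"arteriole"`,
#'   `"venule"`, `"vein"`, `"upscaled_edge"`) and `compliance`
#'   (cross-sectional compliance, m^2/Pa; 0 disables it).
#' @param metadata free-form named list (generation parameters, units).
#' @param validate check the graph invariants (default `TRUE`).
#' @return object of class `vascular_graph`.
#' @export
vascular_graph <- function(nodes, edges, metadata = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("id", "x", "y", "z", "kind", "z_offset")
  need_e <- c("id", "node_a", "node_b", "diameter", "length",
              "strahler_order", "vessel_class", "compliance")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("nodes missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_e, names(edges))
  if (length(miss)) stop("edges missing column(s): ", paste(miss, collapse = ", "))
  nodes$id <- as.integer(nodes$id)
  for (f in c("x", "y", "z", "z_offset")) nodes[[f]] <- as.double(nodes[[f]])
  edges$id <- as.integer(edges$id)
  edges$node_a <- as.integer(edges$node_a)
  edges$node_b <- as.integer(edges$node_b)
  edges$strahler_order <- as.integer(edges$strahler_order)
  for (f in c("diameter", "length", "compliance"))
    edges[[f]] <- as.double(edges[[f]])
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges, metadata = metadata),
                 class = "vascular_graph")
  if (validate) validate_graph(g)
  g
}

node_kinds <- c("regular", "boundary_arterial", "boundary_venous",
                "upscaled_healthy", "upscaled_tumor")
vessel_classes <- c("artery", "arteriole", "venule", "vein", "upscaled_edge")

#' Validate the invariants of a vascular graph
#'
#' Checks id uniqueness, positive geometry, absence of self-loops and
#' duplicate edges, boundary-node degree 1, upscaled-node degree 2 with
#' `upscaled_edge` incident classes, and connectedness.
#'
#' @param graph a [vascular_graph()].
#' @return the graph, invisibly; stops with a diagnostic on violation.
#' @export
validate_graph <- function(graph) {
  n <- graph$nodes; e <- graph$edges
  if (anyDuplicated(n$id)) stop("duplicate node ids")
  if (anyDuplicated(e$id)) stop("duplicate edge ids")
  if (!all(n$kind %in% node_kinds))
    stop("invalid node kind: ", paste(setdiff(n$kind, node_kinds), collapse = ", "))
  if (!all(e$vessel_class %in% vessel_classes))
    stop("invalid vessel class: ",
         paste(setdiff(e$vessel_class, vessel_classes), collapse = ", "))
  if (any(!is.finite(e$diameter)) || any(e$diameter <= 0))
    stop("edge diameters must be positive: edge id ",
         e$id[which(!(e$diameter > 0))[1]])
  if (any(!is.finite(e$length)) || any(e$length <= 0))
    stop("edge lengths must be positive: edge id ",
         e$id[which(!(e$length > 0))[1]])
  if (any(e$node_a == e$node_b)) stop("self-loop edge: id ",
                                      e$id[which(e$node_a == e$node_b)[1]])
  if (!all(c(e$node_a, e$node_b) %in% n$id)) stop("edge references unknown node id")
  key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
  if (anyDuplicated(key)) stop("duplicate edge between a node pair")
  deg <- node_degrees(graph)
  bnd <- n$id[startsWith(n$kind, "boundary")]
  if (length(bnd) && any(deg[as.character(bnd)] != 1))
    stop("boundary nodes must have degree 1")
  ups <- n$id[startsWith(n$kind, "upscaled")]
  if (length(ups)) {
    if (any(deg[as.character(ups)] != 2))
      stop("upscaled nodes must have exactly 2 incident edges")
    inc <- e$vessel_class[e$node_a %in% ups | e$node_b %in% ups]
    if (!all(inc == "upscaled_edge"))
      stop("edges incident to upscaled nodes must be of class 'upscaled_edge'")
  }
  if (nrow(e) && !graph_is_connected(graph)) stop("graph is not connected")
  invisible(graph)
}

node_degrees <- function(graph) {
  ids <- graph$nodes$id
  deg <- table(factor(c(graph$edges$node_a, graph$edges$node_b), levels = ids))
  stats::setNames(as.integer(deg), as.character(ids))
}

graph_adjacency <- function(graph) {
  # list: node id (as character) -> integer vector of edge row indices
  ids <- as.character(graph$nodes$id)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  if (!nrow(graph$edges)) return(adj)
  for (k in seq_len(nrow(graph$edges))) {
    a <- as.character(graph$edges$node_a[k])
    b <- as.character(graph$edges$node_b[k])
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }
  adj
}

graph_is_connected <- function(graph) {
  ids <- graph$nodes$id
  if (length(ids) <= 1L) return(TRUE)
  adj <- graph_adjacency(graph)
  seen <- stats::setNames(logical(length(ids)), as.character(ids))
  queue <- ids[1]
  seen[as.character(ids[1])] <- TRUE
  e <- graph$edges
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (k in adj[[as.character(v)]]) {
      w <- if (e$node_a[k] == v) e$node_b[k] else e$node_a[k]
      cw <- as.character(w)
      if (!seen[cw]) { seen[cw] <- TRUE; queue <- c(queue, w) }
    }
  }
  all(seen)
}

#' @export
print.vascular_graph <- function(x, ...) {
  cat("<vascular_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  kinds <- table(x$nodes$kind)
  cat("  node kinds: ", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (nrow(x$edges))
    cat("  Strahler orders: ", paste(sort(unique(x$edges$strahler_order)),
                                     collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign Strahler orders on a rooted vessel tree
#'
#' Labels every edge with its Strahler order: terminal (leaf) vessels are
#' order 1; where two vessels of equal order n meet, the confluent vessel is
#' order n+1; where unequal orders meet, the confluent vessel keeps the
#' larger order.
#'
#' @param graph a [vascular_graph()] that is a tree (no cycles).
#' @param root node id at which the tree is rooted (e.g. the arterial inlet).
#' @return list with `edge_orders` (named by edge id) and `node_orders`
#'   (named by node id; the maximum order over incident edges).
#' @export
assign_strahler_orders <- function(graph, root) {
  n <- graph$nodes; e <- graph$edges
  if (!root %in% n$id) stop("root node ", root, " not in graph")
  if (nrow(e) != nrow(n) - 1L || !graph_is_connected(graph))
    stop("Strahler ordering requires a tree: got ", nrow(n), " nodes and ",
         nrow(e), " edges", if (nrow(e) >= nrow(n)) " (cycle detected)" else
           " (disconnected)")
  adj <- graph_adjacency(graph)
  # iterative post-order over edges, rooted at `root`
  parent_edge <- rep(NA_integer_, nrow(n))     # row index of edge to parent
  names(parent_edge) <- as.character(n$id)
  order_out <- rep(NA_integer_, nrow(e))
  stack <- list(list(node = root, from_edge = NA_integer_, stage = 1L))
  post <- integer(0)  # node visit order (children before parents)
  visited <- character(0)
  # simple DFS recording traversal; tree so no cycle checks needed beyond count
  dfs <- function(v, from_edge) {
    res <- integer(0)
    st <- list(c(v, from_edge))
    out <- list()
    while (length(st)) {
      top <- st[[length(st)]]; st[[length(st)]] <- NULL
      out[[length(out) + 1L]] <- top
      for (k in adj[[as.character(top[1])]]) {
        if (!is.na(top[2]) && k == top[2]) next
        w <- if (e$node_a[k] == top[1]) e$node_b[k] else e$node_a[k]
        st[[length(st) + 1L]] <- c(w, k)
      }
    }
    out
  }
  ord <- dfs(root, NA_integer_)
  # process in reverse (children first)
  child_orders <- vector("list", nrow(n))
  names(child_orders) <- as.character(n$id)
  for (i in rev(seq_along(ord))) {
    v <- ord[[i]][1]; k <- ord[[i]][2]
    if (is.na(k)) next  # root has no parent edge
    co <- child_orders[[as.character(v)]]
    o <- if (length(co) == 0L) 1L
         else if (sum(co == max(co)) >= 2L) max(co) + 1L
         else max(co)
    order_out[k] <- o
    # register on the parent node
    p <- if (e$node_a[k] == v) e$node_b[k] else e$node_a[k]
    child_orders[[as.character(p)]] <- c(child_orders[[as.character(p)]], o)
  }
  edge_orders <- stats::setNames(order_out, as.character(e$id))
  node_orders <- vapply(as.character(n$id), function(id) {
    ks <- adj[[id]]
    if (!length(ks)) return(NA_integer_)
    max(order_out[ks])
  }, integer(1))
  list(edge_orders = edge_orders, node_orders = node_orders)
}

#' Morphometry of the human pulmonary arterial tree
#'
#' Strahler-ordered mean diameters and lengths of the pulmonary arterial
#' vessels (Horsfield-type morphometry), in meters.  Order 1 are the
#' smallest pre-capillary arterioles.
#'
#' @return data.frame with columns `order`, `diameter` (m), `length` (m).
#' @export
horsfield_arterial <- function() {
  d_mm <- c(0.013, 0.021, 0.034, 0.054, 0.086, 0.138, 0.224, 0.351, 0.525,
            0.850, 1.330, 2.090, 3.650, 5.820, 8.060, 14.830, 30.000)
  l_mm <- c(0.13, 0.20, 0.29, 0.44, 0.65, 0.91, 1.38, 2.10, 3.16,
            4.69, 6.60, 10.50, 17.90, 20.70, 10.90, 32.00, 90.50)
  data.frame(order = 1:17, diameter = d_mm * 1e-3, length = l_mm * 1e-3)
}

#' Morphometry of the human pulmonary venous tree
#'
#' @return data.frame with columns `order`, `diameter` (m), `length` (m).
#' @export
horsfield_venous <- function() {
  d_mm <- c(0.013, 0.019, 0.029, 0.043, 0.064, 0.096, 0.14, 0.22, 0.39,
            0.61, 1.21, 1.90, 2.90, 5.23, 13.88)
  l_mm <- c(0.130, 0.192, 0.283, 0.418, 0.617, 0.910, 1.34, 1.98, 2.54,
            3.20, 11.0, 18.5, 25.4, 39.0, 36.7)
  data.frame(order = 1:15, diameter = d_mm * 1e-3, length = l_mm * 1e-3)
}

# Recursive plan for a Strahler-consistent subtree fed by one edge of the
# given order that terminates in exactly n_leaves order-1 terminals.  An
# order-n parent may bifurcate into two order-(n-1) children, or (order 2
# only) continue as order 2 while spawning an order-1 side branch; this
# asymmetry is what allows leaf counts other than powers of two.
strahler_plan <- function(order, n_leaves) {
  if (order == 1L) {
    if (n_leaves != 1L) stop("an order-1 vessel is terminal (1 leaf)")
    return(list(order = 1L, children = list()))
  }
  min_leaves <- 2L^(order - 1L)
  if (n_leaves < min_leaves)
    stop("infeasible: an order-", order, " tree needs at least ", min_leaves,
         " order-1 terminals, requested ", n_leaves)
  if (order == 2L) {
    # chain of (n_leaves - 2) continuations, then a terminal bifurcation
    node <- list(order = 2L,
                 children = list(strahler_plan(1L, 1L), strahler_plan(1L, 1L)))
    for (i in seq_len(n_leaves - 2L))
      node <- list(order = 2L, children = list(node, strahler_plan(1L, 1L)))
    return(node)
  }
  t1 <- n_leaves %/% 2L; t2 <- n_leaves - t1
  list(order = order,
       children = list(strahler_plan(order - 1L, t1),
                       strahler_plan(order - 1L, t2)))
}

#' Generate a Strahler-ordered dichotomous vessel tree
#'
#' Builds a planar (z = 0) binary tree whose edges carry the diameter and
#' length of their Strahler order from a morphometry table.  Because a
#' strictly halving dichotomy can only produce power-of-two leaf counts, the
#' generator admits Strahler-consistent continuations (an order-2 vessel may
#' spawn an order-1 side branch and continue as order 2), so any
#' `n_leaves >= 2^(root_order-1)` is reachable.
#'
#' @param root_order Strahler order of the root vessel.
#' @param morphometry data.frame (`order`, `diameter`, `length`), e.g.
#'   [horsfield_arterial()]; must cover orders `1..root_order`.
#' @param n_leaves number of order-1 terminals to generate.
#' @param side `"arterial"` or `"venous"`; sets vessel classes, the boundary
#'   node kind at the root, and the layout direction (arterial trees grow
#'   downward from y > 0, venous trees upward from y < 0).
#' @param leaf_spacing horizontal distance between adjacent terminals (m).
#' @param id_offset first node/edge id to use (for composing graphs).
#' @return a [vascular_graph()]; leaves are `regular` nodes at y = 0 side.
#' @export
build_strahler_tree <- function(root_order, morphometry, n_leaves,
                                side = c("arterial", "venous"),
                                leaf_spacing = 5e-4, id_offset = 1L) {
  side <- match.arg(side)
  if (root_order < 1L) stop("root_order must be >= 1")
  if (!all(seq_len(root_order) %in% morphometry$order))
    stop("morphometry must cover orders 1..", root_order)
  if (n_leaves < 2L^(root_order - 1L))
    stop("infeasible: an order-", root_order, " tree needs at least ",
         2L^(root_order - 1L), " order-1 terminals (requested ", n_leaves,
         "); lower root_order or raise n_leaves")
  plan <- strahler_plan(as.integer(root_order), as.integer(n_leaves))
  geom <- stats::setNames(morphometry$diameter, morphometry$order)
  lens <- stats::setNames(morphometry$length, morphometry$order)
  sgn <- if (side == "arterial") 1 else -1
  vclass <- function(o) {
    if (side == "arterial") { if (o <= 2) "arteriole" else "artery" }
    else { if (o <= 2) "venule" else "vein" }
  }
  nodes <- list(); edges <- list()
  nid <- id_offset - 1L; eid <- id_offset - 1L
  new_node <- function(x, y, kind) {
    nid <<- nid + 1L
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = nid, x = x, y = y, z = 0, kind = kind, z_offset = 0,
      stringsAsFactors = FALSE)
    nid
  }
  new_edge <- function(a, b, o) {
    eid <<- eid + 1L
    edges[[length(edges) + 1L]] <<- data.frame(
      id = eid, node_a = a, node_b = b, diameter = geom[[as.character(o)]],
      length = lens[[as.character(o)]], strahler_order = o,
      vessel_class = vclass(o), compliance = 0, stringsAsFactors = FALSE)
    eid
  }
  count_leaves <- function(p) {
    if (!length(p$children)) return(1L)
    sum(vapply(p$children, count_leaves, integer(1)))
  }
  # recursive layout: each subtree occupies a contiguous x-range of leaves
  leaf_x0 <- 0
  emit <- function(p, parent_node, x_lo, x_hi, y_top) {
    # edge of order p$order from parent_node down to a new node
    y_bot <- y_top - sgn * lens[[as.character(p$order)]]
    x_mid <- (x_lo + x_hi) / 2
    if (!length(p$children)) {
      v <- new_node(x_mid, 0, "regular")  # terminals land on the y = 0 line
      new_edge(parent_node, v, p$order)
      return(invisible(NULL))
    }
    v <- new_node(x_mid, y_bot, "regular")
    new_edge(parent_node, v, p$order)
    nl <- vapply(p$children, count_leaves, integer(1))
    w <- (x_hi - x_lo) * nl / sum(nl)
    lo <- x_lo
    for (i in seq_along(p$children)) {
      emit(p$children[[i]], v, lo, lo + w[i], y_bot)
      lo <- lo + w[i]
    }
    invisible(NULL)
  }
  total_w <- (n_leaves - 1L) * leaf_spacing
  depth <- sum(vapply(seq_len(root_order), function(o) lens[[as.character(o)]],
                      numeric(1)))
  root_kind <- if (side == "arterial") "boundary_arterial" else "boundary_venous"
  rootn <- new_node(total_w / 2, sgn * (depth + lens[[as.character(root_order)]]),
                    root_kind)
  emit(plan, rootn, -leaf_spacing / 2, total_w + leaf_spacing / 2,
       sgn * (depth + lens[[as.character(root_order)]]))
  g <- vascular_graph(do.call(rbind, nodes), do.call(rbind, edges),
                      metadata = list(
                        generator = "build_strahler_tree",
                        side = side, root_order = root_order,
                        n_leaves = n_leaves, units = "SI (m)"))
  g
}

#' Build the coupled example network: two trees joined by upscaled nodes
#'
#' Generates the demonstration scenario: a dichotomous arterial tree from
#' Strahler order 4 down to `n_alveoli` order-1 pre-capillary arterioles, a
#' mirror-image venous tree, and `n_alveoli` upscaled nodes in between,
#' each connected by one arterial-side and one venous-side upscaled edge.
#' A subset of upscaled nodes is marked tumorous.
#'
#' @param n_alveoli number of upscaled (alveolar) nodes; default 21.
#' @param tumor_ids 1-based indices (counted left to right) of the upscaled
#'   nodes that carry tumor properties; `NULL` picks three spread-out nodes
#'   (`c(5, 11, 17)` for the default 21 alveoli).
#' @param root_order Strahler order of the root vessels (default 4); lowered
#'   automatically when `n_alveoli < 2^(root_order-1)`.
#' @return a [vascular_graph()] with `n_alveoli` upscaled nodes.
#' @export
build_coupled_example <- function(n_alveoli = 21L, tumor_ids = NULL,
                                  root_order = 4L) {
  n_alveoli <- as.integer(n_alveoli)
  if (n_alveoli < 1L) stop("n_alveoli must be >= 1")
  if (is.null(tumor_ids))
    tumor_ids <- unique(pmax(1L, as.integer(round(
      n_alveoli * c(0.25, 0.52, 0.8)))))
  tumor_ids <- as.integer(tumor_ids)
  if (length(tumor_ids) && (any(tumor_ids < 1L) || any(tumor_ids > n_alveoli)))
    stop("tumor_ids must lie in 1..n_alveoli")
  ro <- min(root_order, floor(log2(n_alveoli)) + 1L)
  art <- build_strahler_tree(ro, horsfield_arterial(), n_alveoli, "arterial")
  ven <- build_strahler_tree(ro, horsfield_venous(), n_alveoli, "venous",
                             id_offset = max(art$nodes$id) + 1L)
  nodes <- rbind(art$nodes, ven$nodes)
  edges <- rbind(art$edges, ven$edges)
  # order-1 terminals sit on y = 0; identify them left to right on each side
  leaf_of <- function(tree) {
    deg <- node_degrees(tree)
    ids <- tree$nodes$id[deg[as.character(tree$nodes$id)] == 1L &
                           tree$nodes$kind == "regular"]
    ids[order(tree$nodes$x[match(ids, tree$nodes$id)])]
  }
  a_leaves <- leaf_of(art); v_leaves <- leaf_of(ven)
  stopifnot(length(a_leaves) == n_alveoli, length(v_leaves) == n_alveoli)
  # lift the trees off the y = 0 line to make room for the upscaled edges
  am <- horsfield_arterial(); vm <- horsfield_venous()
  gap_a <- am$length[am$order == 1]; gap_v <- vm$length[vm$order == 1]
  nodes$y[nodes$id %in% art$nodes$id] <- nodes$y[nodes$id %in% art$nodes$id] + gap_a
  nodes$y[nodes$id %in% ven$nodes$id] <- nodes$y[nodes$id %in% ven$nodes$id] - gap_v
  nid <- max(nodes$id); eid <- max(edges$id)
  up_nodes <- data.frame(
    id = nid + seq_len(n_alveoli),
    x = nodes$x[match(a_leaves, nodes$id)], y = 0, z = 0,
    kind = ifelse(seq_len(n_alveoli) %in% tumor_ids,
                  "upscaled_tumor", "upscaled_healthy"),
    z_offset = 0, stringsAsFactors = FALSE)
  up_edges <- rbind(
    data.frame(id = eid + seq_len(n_alveoli),
               node_a = a_leaves, node_b = up_nodes$id,
               diameter = am$diameter[am$order == 1],
               length = gap_a, strahler_order = 1L,
               vessel_class = "upscaled_edge", compliance = 0,
               stringsAsFactors = FALSE),
    data.frame(id = eid + n_alveoli + seq_len(n_alveoli),
               node_a = up_nodes$id, node_b = v_leaves,
               diameter = vm$diameter[vm$order == 1],
               length = gap_v, strahler_order = 1L,
               vessel_class = "upscaled_edge", compliance = 0,
               stringsAsFactors = FALSE))
  vascular_graph(rbind(nodes, up_nodes), rbind(edges, up_edges),
                 metadata = list(generator = "build_coupled_example",
                                 n_alveoli = n_alveoli,
                                 tumor_ids = tumor_ids,
                                 root_order = ro, units = "SI (m)"))
}

#' Extract the arterial or venous tree from a coupled network
#'
#' Drops upscaled nodes/edges and the opposite side, returning the rooted
#' tree on which Strahler relabeling can be re-run (the coupled network
#' itself contains cycles through the upscaled nodes).
#'
#' @param graph a [vascular_graph()].
#' @param side `"arterial"` or `"venous"`.
#' @return a [vascular_graph()] that is a tree.
#' @export
extract_side_tree <- function(graph, side = c("arterial", "venous")) {
  side <- match.arg(side)
  cls <- if (side == "arterial") c("artery", "arteriole") else c("vein", "venule")
  e <- graph$edges[graph$edges$vessel_class %in% cls, , drop = FALSE]
  keep <- unique(c(e$node_a, e$node_b))
  n <- graph$nodes[graph$nodes$id %in% keep, , drop = FALSE]
  vascular_graph(n, e, metadata = c(graph$metadata, list(side_extract = side)),
                 validate = FALSE)
}
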