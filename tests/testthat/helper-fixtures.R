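# Small graph builders shared across tests (all SI units).

# straight chain of n equal segments between an arterial and a venous
# boundary node
chain_graph <- function(n = 2, diameter = 1e-5, length = 1e-4) {
  nodes <- data.frame(
    id = seq_len(n + 1L),
    x = seq(0, by = length, length.out = n + 1L), y = 0, z = 0,
    kind = c("boundary_arterial", rep("regular", n - 1L), "boundary_venous"),
    z_offset = 0)
  edges <- data.frame(
    id = seq_len(n), node_a = seq_len(n), node_b = seq_len(n) + 1L,
    diameter = diameter, length = length, strahler_order = 1L,
    vessel_class = "arteriole", compliance = 0)
  vascular_graph(nodes, edges)
}

# hand-built rooted tree from an edge list (parent, child, order)
tree_graph <- function(parents, children, orders,
                       diameter = 1e-5, length = 1e-4) {
  ids <- sort(unique(c(parents, children)))
  root <- setdiff(parents, children)
  leaves <- setdiff(children, parents)
  nodes <- data.frame(id = ids, x = as.numeric(ids), y = 0, z = 0,
                      kind = "regular", z_offset = 0)
  nodes$kind[nodes$id == root] <- "boundary_arterial"
  edges <- data.frame(id = seq_along(parents), node_a = parents,
                      node_b = children, diameter = diameter,
                      length = length, strahler_order = orders,
                      vessel_class = "artery", compliance = 0)
  vascular_graph(nodes, edges, validate = FALSE)
}

# a capillary network of collinear tube segments spanning the cuboid in x
straight_tube_network <- function(n_seg = 1, radius = 4e-6,
                                  cuboid = c(364e-6, 364e-6, 112e-6)) {
  xs <- seq(0, cuboid[1], length.out = n_seg + 1L)
  nodes <- data.frame(id = seq_len(n_seg + 1L), x = xs,
                      y = cuboid[2] / 2, z = cuboid[3] / 2)
  segs <- data.frame(id = seq_len(n_seg), node_a = seq_len(n_seg),
                     node_b = seq_len(n_seg) + 1L, radius = radius,
                     length = diff(xs))
  capillary_network(nodes, segs, cuboid)
}

# transfer parameter set with all exchange switched off
transfer_off <- function() {
  transfer_parameters(L_p = 0, S_V = 0, P = 0)
}

# scenario config with all transvascular exchange disabled
config_no_transfer <- function() {
  cfg <- default_scenario()
  for (sec in c("transfer_healthy", "transfer_tumor")) {
    cfg[[sec]]$hydraulic_conductivity_m_pa_s <- 0
    cfg[[sec]]$diffusive_permeability_m_s <- 0
  }
  cfg
}
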