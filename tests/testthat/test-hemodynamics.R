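test_that("hematocrit lookup interpolates and extrapolates as configured", {
  blood <- blood_properties()
  tab <- blood$hematocrit_table
  # tabulated point is reproduced exactly
  expect_equal(hematocrit_from_diameter(8e-6, blood),
               tab$hematocrit[tab$diameter_um == 8])
  # midway between two points gives the arithmetic mean
  expect_equal(hematocrit_from_diameter(5e-6, blood),
               mean(tab$hematocrit[tab$diameter_um %in% c(4, 6)]))
  # beyond the table: constant (systemic) value
  expect_equal(hematocrit_from_diameter(5e-3, blood),
               tab$hematocrit[nrow(tab)])
  expect_error(hematocrit_from_diameter(
    1e-5, blood_properties(hematocrit_table =
                             data.frame(diameter_um = numeric(0),
                                        hematocrit = numeric(0)))),
    "empty")
})

test_that("apparent viscosity follows the hematocrit/diameter relation", {
  blood <- blood_properties()
  # cell-free blood is plasma
  expect_equal(viscosity_from_hematocrit_diameter(0, 8e-6, blood),
               blood$plasma_viscosity)
  # capillary conditions reproduce the constant DCM value of 0.0021 Pa s
  H8 <- hematocrit_from_diameter(8e-6, blood)
  expect_equal(viscosity_from_hematocrit_diameter(H8, 8e-6, blood),
               0.0021, tolerance = 0.05)
  # monotone in hematocrit at fixed diameter
  for (d in c(6e-6, 8e-6, 30e-6, 200e-6)) {
    mus <- viscosity_from_hematocrit_diameter(seq(0, 0.6, by = 0.1), d,
                                              blood)
    expect_true(all(diff(mus) > 0))
    expect_true(all(mus >= blood$plasma_viscosity))
  }
})

test_that("Poiseuille resistance and node volumes match hand values", {
  # frozen hand evaluation: R = 8 mu l / (pi r^4) at d=8um, l=10um
  expect_equal(segment_resistance(8e-6, 1e-5, 0.0021), 2.0889e14,
               tolerance = 1e-4)
  # quartic diameter scaling
  expect_equal(segment_resistance(1.6e-5, 1e-5, 0.0021),
               segment_resistance(8e-6, 1e-5, 0.0021) / 16)
  expect_error(segment_resistance(0, 1, 1), "positive")
  # node volumes: half of each adjacent edge
  g <- chain_graph(2, diameter = 1e-5, length = 1e-4)
  A <- pi * (5e-6)^2
  expect_equal(node_volume(g, 2), A * 1e-4)          # two identical edges
  expect_equal(node_volume(g, 1), A * 1e-4 / 2)      # leaf: half an edge
  # order-1 arterial morphometry row, frozen hand arithmetic
  m <- horsfield_arterial()
  expect_equal(pi * (m$diameter[1] / 2)^2 * m$length[1] / 2, 8.628e-15,
               tolerance = 1e-3)
})

test_that("compliant cross-sections respond linearly and can be disabled", {
  expect_equal(compliant_area(1e-9, 0, 5000, 0), 1e-9)
  expect_equal(compliant_area(1e-9, 1e-14, 1064, 1064), 1e-9)
  expect_gt(compliant_area(1e-9, 1e-14, 2000, 1000), 1e-9)
  # floored at the minimum fraction
  expect_equal(compliant_area(1e-9, 1e-12, -1e6, 0), 1e-10)
})

test_that("the pressure solve reproduces closed-form flows", {
  # two equal segments in series: midpoint pressure is the mean of the BCs
  g <- chain_graph(2)
  fl <- solve_pressure(g, bcs = c("1" = 1064, "3" = 199.5))
  expect_equal(unname(fl$pressures["2"]), (1064 + 199.5) / 2)
  expect_lt(fl$residual, 1e-10)
  # single tube: Q = pi r^4 dp / (8 mu l) to machine precision
  g1 <- chain_graph(1)
  fl1 <- solve_pressure(g1, bcs = c("1" = 1064, "2" = 199.5))
  mu <- fl1$edges$viscosity[1]
  Qref <- pi * (5e-6)^4 * (1064 - 199.5) / (8 * mu * 1e-4)
  expect_equal(fl1$edges$flow[1], Qref, tolerance = 1e-14)
  # series law: the two-segment chain carries half the single-tube flow
  expect_equal(fl$edges$flow[1], Qref / 2, tolerance = 1e-12)
  # no Dirichlet anchor: singular
  expect_error(solve_pressure(g, bcs = c()), "named")
})

test_that("mass is conserved and trees drain monotonically", {
  g <- build_coupled_example()
  n <- g$nodes
  bcs <- c(stats::setNames(1064, n$id[n$kind == "boundary_arterial"]),
           stats::setNames(199.5, n$id[n$kind == "boundary_venous"]))
  fl <- solve_pressure(g, bcs = bcs)
  expect_lt(fl$residual, 1e-10)
  # global: arterial boundary inflow equals venous boundary outflow
  art <- as.integer(names(bcs)[1]); ven <- as.integer(names(bcs)[2])
  e <- fl$edges
  inflow <- sum(e$flow[e$node_a == art]) - sum(e$flow[e$node_b == art])
  outflow <- sum(e$flow[e$node_b == ven]) - sum(e$flow[e$node_a == ven])
  expect_equal(inflow, outflow, tolerance = 1e-10)
  # pressure is non-increasing from the arterial root toward the leaves:
  # every arterial-side edge (generated root -> leaf) carries forward flow
  art_e <- e[g$edges$vessel_class %in% c("artery", "arteriole"), ]
  expect_true(all(art_e$flow > 0))
  p_a <- fl$pressures[as.character(art_e$node_a)]
  p_b <- fl$pressures[as.character(art_e$node_b)]
  expect_true(all(p_a > p_b))
})

test_that("the flow solution is invariant under node relabeling", {
  g <- build_coupled_example(n_alveoli = 4, tumor_ids = 2)
  n <- g$nodes
  bcs <- c(stats::setNames(1064, n$id[n$kind == "boundary_arterial"]),
           stats::setNames(199.5, n$id[n$kind == "boundary_venous"]))
  fl <- solve_pressure(g, bcs = bcs)
  # permute ids deterministically
  set.seed(42)
  perm <- sample(n$id)
  remap <- stats::setNames(perm, n$id)
  g2 <- g
  g2$nodes$id <- unname(remap[as.character(g$nodes$id)])
  g2$edges$node_a <- unname(remap[as.character(g$edges$node_a)])
  g2$edges$node_b <- unname(remap[as.character(g$edges$node_b)])
  bcs2 <- stats::setNames(bcs, remap[names(bcs)])
  fl2 <- solve_pressure(g2, bcs = bcs2)
  expect_equal(unname(fl2$pressures[as.character(remap[names(fl$pressures)])]),
               unname(fl$pressures), tolerance = 1e-12)
  expect_equal(fl2$edges$flow, fl$edges$flow, tolerance = 1e-12)
})

test_that("gravity head drives flow between isobaric nodes", {
  nodes <- data.frame(id = 1:2, x = 0, y = 0, z = c(0, -1e-2),
                      kind = c("boundary_arterial", "boundary_venous"),
                      z_offset = c(0, -1e-2))
  edges <- data.frame(id = 1, node_a = 1, node_b = 2, diameter = 1e-4,
                      length = 1e-2, strahler_order = 1L,
                      vessel_class = "artery", compliance = 0)
  g <- vascular_graph(nodes, edges)
  fl_off <- solve_pressure(g, bcs = c("1" = 1000, "2" = 1000))
  expect_equal(fl_off$edges$flow[1], 0)
  fl_on <- solve_pressure(g, bcs = c("1" = 1000, "2" = 1000),
                          gravity = gravity_model(TRUE))
  expect_gt(fl_on$edges$flow[1], 0)  # downhill
  # the head equals rho g dz
  blood <- blood_properties()
  expect_equal(fl_on$edges$flow[1] * fl_on$edges$resistance[1],
               blood$mass_density * 9.81 * 1e-2, tolerance = 1e-12)
})

test_that("q_mass sinks are restricted to upscaled nodes and drain flow", {
  g <- build_coupled_example(n_alveoli = 2)
  n <- g$nodes
  bcs <- c(stats::setNames(1064, n$id[n$kind == "boundary_arterial"]),
           stats::setNames(199.5, n$id[n$kind == "boundary_venous"]))
  reg <- n$id[n$kind == "regular"][1]
  expect_error(solve_pressure(g, bcs = bcs,
                              q_mass = stats::setNames(1e-9, reg)),
               "upscaled")
  ups <- n$id[startsWith(n$kind, "upscaled")][1]
  fl0 <- solve_pressure(g, bcs = bcs)
  fl <- solve_pressure(g, bcs = bcs,
                       q_mass = stats::setNames(1e-10, ups))
  e <- fl$edges
  art <- as.integer(names(bcs)[1]); ven <- as.integer(names(bcs)[2])
  inflow <- sum(e$flow[e$node_a == art]) - sum(e$flow[e$node_b == art])
  outflow <- sum(e$flow[e$node_b == ven]) - sum(e$flow[e$node_a == ven])
  expect_equal(inflow - outflow, 1e-10 / blood_properties()$mass_density,
               tolerance = 1e-8)
})
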