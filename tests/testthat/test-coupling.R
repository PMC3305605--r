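test_that("capillary boundary conditions are copied from the neighbors", {
  g <- build_coupled_example(n_alveoli = 3, tumor_ids = 2)
  n <- g$nodes
  bcs <- c(stats::setNames(1064, n$id[n$kind == "boundary_arterial"]),
           stats::setNames(199.5, n$id[n$kind == "boundary_venous"]))
  fl <- solve_pressure(g, bcs = bcs)
  st <- transport_state(g, 0)
  ups <- n$id[startsWith(n$kind, "upscaled")][1]
  nb <- upscaled_neighbors(g, ups)
  st$x[as.character(nb$arterial)] <- 1e-6
  bc <- capillary_bcs_from_vgm(g, fl, st, ups)
  expect_equal(bc$p_art, unname(fl$pressures[as.character(nb$arterial)]))
  expect_equal(bc$p_ven, unname(fl$pressures[as.character(nb$venous)]))
  expect_equal(bc$x_art, 1e-6)
  expect_equal(bc$x_ven, 0)
  # changing a non-neighbor node changes nothing
  other <- setdiff(n$id[n$kind == "regular"], c(nb$arterial, nb$venous))[1]
  st$x[as.character(other)] <- 5e-7
  bc2 <- capillary_bcs_from_vgm(g, fl, st, ups)
  expect_identical(bc2, bc)
  expect_error(upscaled_neighbors(g, n$id[n$kind == "regular"][1]),
               "not an upscaled node")
})

test_that("the initial capillary profile is linear between the caps", {
  mesh <- build_dcm_mesh("shell", 70e-6, 182e-6, c(3, 8, 6), 25)
  # equal end values give a uniform field
  expect_equal(initial_concentration_profile(3e-7, 3e-7, mesh),
               rep(3e-7, nrow(mesh$cells)))
  prof <- initial_concentration_profile(1e-6, 0, mesh)
  expect_true(all(prof >= 0 & prof <= 1e-6))
  # cells at mid-plane (x ~ 0) get the mean of the two cap values
  mid <- abs(mesh$cells$x) < 1e-8
  expect_equal(unname(prof[mid]), rep(5e-7, sum(mid)), tolerance = 1e-6)
  # monotone along x from the arterial (-x) to the venous (+x) side
  o <- order(mesh$cells$x)
  expect_true(all(diff(prof[o]) <= 1e-20))
})

test_that("effective upscaled resistance is linear and kind-ordered", {
  cfg <- default_scenario()
  probs <- build_upscaled_problems(cfg)
  Rh <- effective_upscaled_resistance(probs$healthy)
  Rt <- effective_upscaled_resistance(probs$tumor)
  # a tumorous upscaled node presents a smaller resistance
  expect_lt(Rt, Rh)
  # independent of the probing pressure difference
  expect_equal(effective_upscaled_resistance(probs$healthy, dp = 50), Rh,
               tolerance = 1e-12)
  # doubling the capillary permeability halves the resistance
  cfg2 <- cfg
  cfg2$dcm_healthy$capillary_K_tangential_m2 <-
    2 * cfg$dcm_healthy$capillary_K_tangential_m2
  probs2 <- build_upscaled_problems(cfg2)
  expect_equal(effective_upscaled_resistance(probs2$healthy), Rh / 2,
               tolerance = 1e-10)
})

test_that("with zero transfer the coupled run reduces to pure advection", {
  cfg <- config_no_transfer()
  g <- build_coupled_example(n_alveoli = 2, tumor_ids = 1)
  run <- run_coupled(g, cfg, t_end = 0.3)
  expect_equal(run$audit$transferred, 0)
  expect_equal(max(abs(run$upscaled_series$q_x)), 0)
  # reference: uncoupled explicit advection with the same flow and steps
  blood <- config_blood(cfg)
  drug <- config_drug(cfg)
  n <- g$nodes
  bcs <- c(stats::setNames(cfg$graph$arterial_pressure_pa,
                           n$id[n$kind == "boundary_arterial"]),
           stats::setNames(cfg$graph$venous_pressure_pa,
                           n$id[n$kind == "boundary_venous"]))
  R_eff <- run$final$R_eff
  kinds <- ifelse(n$kind[startsWith(n$kind, "upscaled")] == "upscaled_tumor",
                  "tumor", "healthy")
  ups <- n$id[startsWith(n$kind, "upscaled")]
  R_override <- numeric(0)
  for (i in seq_along(ups)) {
    nb <- upscaled_neighbors(g, ups[i])
    R_override[as.character(c(nb$edge_arterial, nb$edge_venous))] <-
      R_eff[[kinds[i]]] / 2
  }
  fl <- solve_pressure(g, blood, bcs, R_override = R_override)
  st <- transport_state(g, 0)
  art <- n$id[n$kind == "boundary_arterial"]
  outlets <- n$id[n$kind == "boundary_venous"]
  t_now <- 0
  k <- decay_rate(drug$half_life)
  while (t_now < 0.3 - 1e-12) {
    dt <- min(cfl_timestep(fl, cfg$run$courant, outlet_nodes = outlets),
              0.3 - t_now, cfg$run$max_dt_s)
    st <- advance_transport(g, fl, st, dt, k = k, blood = blood,
                            dirichlet_x = stats::setNames(
                              drug$inlet_mole_fraction, art),
                            outlet_nodes = outlets)
    t_now <- t_now + dt
  }
  expect_equal(unname(run$final$transport$x[names(st$x)]), unname(st$x),
               tolerance = 1e-12)
})

test_that("identical configurations give bit-identical runs", {
  cfg <- default_scenario()
  g <- build_coupled_example(n_alveoli = 2, tumor_ids = 1)
  r1 <- run_coupled(g, cfg, t_end = 0.25)
  r2 <- run_coupled(g, cfg, t_end = 0.25)
  expect_identical(r1$node_series, r2$node_series)
  expect_identical(r1$upscaled_series, r2$upscaled_series)
  expect_identical(r1$audit, r2$audit)
})

test_that("the coupled run closes its global drug ledger", {
  cfg <- default_scenario()
  g <- build_coupled_example(n_alveoli = 4, tumor_ids = 2)
  run <- run_coupled(g, cfg, t_end = 1.0)
  expect_lt(run$audit$closure, 1e-3)
  # the lagged sink is at most one step behind the DCM-side exchange
  expect_gte(run$audit$dcm_gained, run$audit$transferred)
  # tumor nodes extract more drug than healthy ones
  us <- run$upscaled_series
  tot <- tapply(us$q_x, list(us$node), sum)
  kinds <- g$nodes$kind[match(as.integer(names(tot)), g$nodes$id)]
  expect_gt(min(tot[kinds == "upscaled_tumor"]),
            max(tot[kinds == "upscaled_healthy"]))
})

test_that("refining the coupling step changes compartment totals < 1%", {
  cfg <- default_scenario()
  g <- build_coupled_example(n_alveoli = 2, tumor_ids = 1)
  base <- run_coupled(g, cfg, t_end = 0.4)
  dt_base <- stats::median(diff(base$times))
  cfg_fine <- cfg
  cfg_fine$run$max_dt_s <- dt_base / 4
  fine <- run_coupled(g, cfg_fine, t_end = 0.4)
  expect_equal(base$audit$tissue_stored, fine$audit$tissue_stored,
               tolerance = 0.01)
  expect_equal(base$audit$dcm_gained, fine$audit$dcm_gained,
               tolerance = 0.01)
})

test_that("a coupled run writes a reproducible results bundle", {
  cfg <- default_scenario()
  g <- build_coupled_example(n_alveoli = 2, tumor_ids = 1)
  out <- withr::local_tempdir()
  run <- run_coupled(g, cfg, t_end = 0.1, output_dir = out)
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$config_md5,
               unname(tools::md5sum(file.path(out, "config.yaml"))))
  ns <- utils::read.csv(file.path(out, "node_series.csv"))
  expect_true(all(c("time", "node", "x", "p") %in% names(ns)))
  expect_true(file.exists(file.path(out, "graph_final.vtk")))
  expect_true(any(grepl("dcm_tumor", list.files(out))))
})
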