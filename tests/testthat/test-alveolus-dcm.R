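make_problem <- function(kind = c("healthy", "tumor"), transfer = NULL,
                         drug = drug_properties(), resolution = c(3, 8, 6),
                         control = list()) {
  kind <- match.arg(kind)
  if (kind == "healthy") {
    mesh <- build_dcm_mesh("shell", 70e-6, 182e-6, resolution, 25,
                           inner_layer_thickness = 12e-6)
    dcm_problem(mesh, tissue_parameters(), capillary_parameters(),
                transfer %||% transfer_parameters(), drug,
                p_t_outer = -1064, control = control)
  } else {
    mesh <- build_dcm_mesh("sphere", 0, 182e-6, resolution, 25)
    dcm_problem(mesh, tissue_parameters_tumor(),
                capillary_parameters_tumor(),
                transfer %||% transfer_parameters_tumor(), drug,
                p_t_outer = 133, control = control)
  }
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("spherical meshes have exact volumes and symmetric cap patches", {
  m <- build_dcm_mesh("shell", 70e-6, 182e-6, c(4, 8, 6), 25,
                      inner_layer_thickness = 12e-6)
  expect_equal(mesh_volume(m), 4 / 3 * pi * ((182e-6)^3 - (70e-6)^3),
               tolerance = 1e-12)
  expect_equal(mesh_volume(m), 2.38e-11, tolerance = 1e-2)
  ms <- build_dcm_mesh("sphere", 0, 182e-6, c(4, 8, 6), 25)
  expect_equal(mesh_volume(ms), 4 / 3 * pi * (182e-6)^3, tolerance = 1e-12)
  expect_equal(mesh_volume(ms), 2.52e-11, tolerance = 1e-2)
  # arterial and venous cap areas equal by mirror symmetry
  f <- m$faces
  expect_equal(sum(f$area[f$patch %in% "arterial_cap"]),
               sum(f$area[f$patch %in% "venous_cap"]), tolerance = 1e-12)
  # every interior face joins exactly two distinct cells
  fi <- f[!is.na(f$cell_a) & !is.na(f$cell_b), ]
  expect_true(all(fi$cell_a != fi$cell_b))
  expect_error(build_dcm_mesh("shell", 70e-6, 182e-6, c(1, 1, 2)),
               "resolution")
  expect_error(build_dcm_mesh("sphere", 70e-6, 182e-6), "R_in")
})

test_that("transfer functions reproduce their closed forms", {
  # frozen hand value for the healthy example conditions
  expect_equal(effective_filtration_pressure(1064, -1064, 0.8, 3724, 1862),
               638.4)
  # Starling equilibrium
  expect_equal(effective_filtration_pressure(1489.6, 0, 0.8, 3724, 1862), 0)
  expect_equal(effective_filtration_pressure(500, 200, 0, 3724, 1862), 300)
  sf <- starling_flux(638.4, 2.7e-12, 1.9e4, 293.75)
  expect_equal(sf$J_v, 2.7e-12 * 1.9e4 * 638.4)
  expect_equal(sf$q_v, sf$J_v * 293.75)
  expect_equal(starling_flux(0, 2.7e-12, 1.9e4, 293.75)$q_v, 0)
  expect_equal(starling_flux(-638.4, 2.7e-12, 1.9e4, 293.75)$q_v, -sf$q_v)
  expect_equal(starling_flux(638.4, 5.4e-12, 1.9e4, 293.75)$q_v, 2 * sf$q_v)
  # Kedem-Katchalsky limits
  expect_equal(kedem_katchalsky_flux(1e-6, 0, 0, 5.7e-10, 0.91, 1.9e4,
                                     293.75),
               5.7e-10 * 1.9e4 * 293.75 * 1e-6)
  expect_equal(kedem_katchalsky_flux(1e-6, 1e-6, 1e-5, 0, 1, 1.9e4,
                                     293.75), 0)
  expect_equal(kedem_katchalsky_flux(1e-6, 1e-6, 1e-5, 0, 0.91, 1.9e4,
                                     293.75),
               0.09 * 1e-5 * 293.75 * 1e-6)
})

test_that("lymphatic sinks clamp and vanish in tumor tissue", {
  lymph <- list(L_p_ly = 2.6e-9, S_ly_V = 3.0, p_ly = -1200)
  # tumor: no functional lymphatics
  s0 <- lymphatic_sinks(100, 1e-6, NULL, 303.5)
  expect_equal(s0$fluid, 0); expect_equal(s0$drug, 0)
  # drainage proportional to p_t - p_ly = 136 Pa
  s <- lymphatic_sinks(-1064, 1e-6, lymph, 303.5)
  expect_equal(s$fluid, 2.6e-9 * 3.0 * 136 * 303.5)
  expect_equal(s$drug, s$fluid * 1e-6)
  # below lymphatic pressure: clamped (no reverse lymph)
  s2 <- lymphatic_sinks(-1300, 1e-6, lymph, 303.5)
  expect_equal(s2$fluid, 0)
  # unclamped linear form on request
  s3 <- lymphatic_sinks(-1300, 1e-6, lymph, 303.5, clamp = FALSE)
  expect_lt(s3$fluid, 0)
})

test_that("receptor binding conserves receptors and reaches equilibrium", {
  rc <- list(C_R0 = 1e-4, k_on = 100, k_off = 1e-4)
  x <- 1e-6; rhomol <- 303.5
  C_RL <- 0
  for (i in 1:500) {
    up <- receptor_binding_update(x, C_RL, rhomol, rc$k_on, rc$k_off,
                                  rc$C_R0, 10)
    C_RL <- up$C_RL
    expect_lte(C_RL, rc$C_R0)
  }
  # equilibrium: C_RL / (c C_R) = k_on / k_off
  conc <- x * rhomol
  ratio <- C_RL / (conc * (rc$C_R0 - C_RL))
  expect_equal(ratio, rc$k_on / rc$k_off, tolerance = 1e-6)
  # drug-free tissue releases bound complex (negative sink)
  up0 <- receptor_binding_update(0, C_RL, rhomol, rc$k_on, rc$k_off,
                                 rc$C_R0, 1)
  expect_lt(up0$sink, 0)
})

test_that("an equilibrium state is a fixed point of the implicit step", {
  drug0 <- drug_properties(half_life = Inf)
  mesh <- build_dcm_mesh("shell", 70e-6, 182e-6, c(3, 8, 6), 25,
                         inner_layer_thickness = 12e-6)
  # all transfer, lymphatic and degradation processes off
  prob <- dcm_problem(mesh, tissue_parameters(lymph = NULL),
                      capillary_parameters(), transfer_off(), drug0,
                      p_t_outer = -1064)
  # uniform pressures equal to every Dirichlet value, no drug anywhere
  bc <- list(p_art = -1064, p_ven = -1064, x_art = 0, x_ven = 0)
  st <- initial_dcm_state(prob, bc$p_art, bc$p_ven, 0, 0)
  st$p_t <- rep(-1064, prob$nc)
  s <- step_implicit(st, 10, prob, bc)
  expect_equal(s$diag$newton_iters, 1L)
  expect_equal(s$state$p_t, st$p_t, tolerance = 1e-10)
  expect_equal(s$state$x_t, st$x_t)
  expect_equal(s$exchange$q_x, 0)
  expect_equal(s$exchange$q_mass, 0)
})

test_that("each implicit step closes the tissue drug balance exactly", {
  for (kind in c("healthy", "tumor")) {
    prob <- make_problem(kind)
    bc <- list(p_art = 1000, p_ven = 300, x_art = 1e-6, x_ven = 5e-7)
    st <- initial_dcm_state(prob, bc$p_art, bc$p_ven, bc$x_art, bc$x_ven)
    dt <- 0.05
    for (i in 1:5) {
      before <- dcm_tissue_moles(prob, st)
      s <- step_implicit(st, dt, prob, bc)
      after <- dcm_tissue_moles(prob, s$state)
      gained <- dt * s$exchange$q_x
      lost <- dt * (s$diag$lymph_drug_rate + s$diag$tissue_boundary_outflow)
      dm <- (after$free + after$bound) - (before$free + before$bound)
      # transfer antisymmetry + implicit bookkeeping: balance to solver tol
      expect_equal(dm, gained - lost, tolerance = 1e-6)
      st <- s$state
    }
    # filtration near the arterial cap, reabsorption near the venous cap
    tr <- prob$transfer
    acells <- which(prob$act)
    p_eff <- effective_filtration_pressure(st$p_c[acells], st$p_t[acells],
                                           tr$sigma, tr$pi_c, tr$pi_t)
    th <- prob$mesh$cells$theta[acells]
    expect_gt(mean(p_eff[th > pi * 0.75]), 0)   # arterial side filters
    expect_lt(mean(p_eff[th < pi * 0.25]), 0)   # venous side reabsorbs
  }
})

test_that("integrate_exchange equals the cell-wise transfer summation", {
  prob <- make_problem("tumor")
  bc <- list(p_art = 1000, p_ven = 300, x_art = 1e-6, x_ven = 5e-7)
  st <- initial_dcm_state(prob, bc$p_art, bc$p_ven, bc$x_art, bc$x_ven)
  s <- step_implicit(st, 0.05, prob, bc)
  # independent summation over active cells
  tr <- prob$transfer
  acells <- which(prob$act)
  stn <- s$state
  p_eff <- effective_filtration_pressure(stn$p_c[acells], stn$p_t[acells],
                                         tr$sigma, tr$pi_c, tr$pi_t)
  sf <- starling_flux(p_eff, tr$L_p, tr$S_V, tr$rhomol_transfer)
  qx <- kedem_katchalsky_flux(stn$x_c[acells], stn$x_t[acells], sf$J_v,
                              tr$P, tr$sigma_f, tr$S_V, tr$rhomol_transfer)
  ex <- integrate_exchange(st, s$state, 0.05, prob, bc)
  expect_equal(ex$q_x, sum(prob$V[acells] * qx), tolerance = 1e-12)
  expect_equal(ex$q_volume, sum(prob$V[acells] * sf$J_v), tolerance = 1e-12)
  expect_equal(ex$q_mass, ex$q_volume * prob$capillary$rho_c)
  # zero-transfer parameters give identically zero exchange
  prob0 <- make_problem("healthy", transfer = transfer_off())
  st0 <- initial_dcm_state(prob0, 1000, 300, 1e-6, 0)
  s0 <- step_implicit(st0, 0.05, prob0, list(p_art = 1000, p_ven = 300,
                                             x_art = 1e-6, x_ven = 0))
  expect_equal(s0$exchange$q_x, 0)
  expect_equal(s0$exchange$q_mass, 0)
})

test_that("tumor parameters extract more drug than healthy under equal BCs", {
  bc <- list(p_art = 1000, p_ven = 300, x_art = 1e-6, x_ven = 5e-7)
  q <- sapply(c("healthy", "tumor"), function(kind) {
    prob <- make_problem(kind)
    st <- initial_dcm_state(prob, bc$p_art, bc$p_ven, bc$x_art, bc$x_ven)
    for (i in 1:10) { s <- step_implicit(st, 0.05, prob, bc); st <- s$state }
    s$exchange$q_x
  })
  expect_gt(q[["tumor"]], q[["healthy"]])
})

test_that("tumor interstitial pressure rises above its boundary value", {
  prob <- make_problem("tumor")
  bc <- list(p_art = 900, p_ven = 300, x_art = 0, x_ven = 0)
  st <- initial_dcm_state(prob, bc$p_art, bc$p_ven, 0, 0)
  s <- step_implicit(st, 1, prob, bc)
  expect_gt(max(s$state$p_t), 133)
})

test_that("one-step implicit-Euler error shrinks as O(dt^2)", {
  prob <- make_problem("healthy")
  bc <- list(p_art = 1000, p_ven = 300, x_art = 1e-6, x_ven = 5e-7)
  st0 <- initial_dcm_state(prob, bc$p_art, bc$p_ven, bc$x_art, bc$x_ven)
  # warm up so the fields are smooth
  for (i in 1:3) st0 <- step_implicit(st0, 0.05, prob, bc)$state
  one_vs_two <- function(h) {
    a <- step_implicit(st0, h, prob, bc)$state
    b1 <- step_implicit(st0, h / 2, prob, bc)$state
    b2 <- step_implicit(b1, h / 2, prob, bc)$state
    max(abs(a$x_t - b2$x_t))
  }
  d1 <- one_vs_two(0.2)
  d2 <- one_vs_two(0.1)
  expect_gt(d1 / d2, 2.5)   # ~4 for a first-order scheme's local error
  expect_lt(d1 / d2, 6)
})

test_that("steady pressure fields are stable under grid refinement", {
  bc <- list(p_art = 1000, p_ven = 300, x_art = 0, x_ven = 0)
  stats_for <- function(resolution) {
    prob <- make_problem("healthy", resolution = resolution)
    st <- initial_dcm_state(prob, bc$p_art, bc$p_ven, 0, 0)
    s <- step_implicit(st, 10, prob, bc)  # p fields are elliptic: 1 step
    w <- prob$V / sum(prob$V)
    c(p_t = sum(s$state$p_t * w),
      p_c = sum(s$state$p_c[prob$act] * prob$V[prob$act]) /
        sum(prob$V[prob$act]))
  }
  coarse <- stats_for(c(3, 8, 6))
  fine <- stats_for(c(3, 16, 12))
  expect_equal(unname(coarse["p_t"]), unname(fine["p_t"]),
               tolerance = 0.02)
  expect_lt(abs(coarse[["p_c"]] - fine[["p_c"]]) /
              abs(fine[["p_c"]] - 0), 0.02)
})
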