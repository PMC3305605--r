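#' Assemble a double-continuum problem on a spherical mesh
#'
#' Precomputes the finite-volume machinery for the four coupled fields
#' (tissue pressure and mole fraction, capillary pressure and mole
#' fraction): two-point transmissibilities for Darcy flow and diffusion,
#' the capillary-active cell set (the innermost radial layer for the
#' healthy shell, every cell for the tumor sphere), and the Dirichlet cell
#' and face sets.  The tissue continuum carries a Dirichlet pressure on the
#' whole outer boundary; the capillary continuum carries Dirichlet pressure
#' and mole fraction on the arterial and venous cone cells fed by the
#' adjacent graph nodes.
#'
#' @param mesh a [build_dcm_mesh()] mesh.
#' @param tissue a [tissue_parameters()] set.
#' @param capillary a [capillary_parameters()] set.
#' @param transfer a [transfer_parameters()] set.
#' @param drug a [drug_properties()].
#' @param p_t_outer tissue Dirichlet pressure on the outer boundary, Pa.
#' @param control list: `newton_tol` (relative residual, default 1e-8),
#'   `newton_maxit`, `max_halvings`, `lymph_clamp`.
#' @return object of class `dcm_problem`.
#' @export
dcm_problem <- function(mesh, tissue, capillary, transfer, drug,
                        p_t_outer,
                        control = list()) {
  ctl <- utils::modifyList(list(newton_tol = 1e-8, newton_maxit = 25L,
                                max_halvings = 5L, lymph_clamp = TRUE),
                           control)
  cells <- mesh$cells; faces <- mesh$faces
  nc <- nrow(cells)
  interior <- !is.na(faces$cell_a) & !is.na(faces$cell_b)
  fi <- faces[interior, ]
  # capillary-active cells
  act <- if (mesh$kind == "shell") cells$ir == 1L else rep(TRUE, nc)
  aidx <- integer(nc); aidx[act] <- seq_len(sum(act))  # cell -> active index
  nact <- sum(act)
  cap <- mesh$cap_half_angle * pi / 180
  dir_layer <- if (mesh$kind == "shell") 1L else mesh$resolution[1]
  art_cells <- which(act & cells$ir == dir_layer & cells$theta >= pi - cap)
  ven_cells <- which(act & cells$ir == dir_layer & cells$theta <= cap)
  if (!length(art_cells) || !length(ven_cells))
    stop("cap_half_angle too small: no capillary Dirichlet cells in a cone")
  # tissue transmissibilities (isotropic homogeneous K_t)
  Tt <- fi$area * tissue$K_t / (tissue$mu_int * (fi$dist_a + fi$dist_b))
  D_t <- tissue$porosity * tissue$tortuosity * drug$diffusivity_interstitial
  Tdt <- fi$area * D_t / (fi$dist_a + fi$dist_b)
  # capillary transmissibilities (faces between two active cells)
  capf <- interior & act[ifelse(is.na(faces$cell_a), 1L, faces$cell_a)] &
    act[ifelse(is.na(faces$cell_b), 1L, faces$cell_b)]
  fc <- faces[capf, ]
  Kn <- ifelse(fc$type == "r", capillary$K_normal, capillary$K_tangential)
  Tc <- fc$area * Kn / (capillary$mu_c * (fc$dist_a + fc$dist_b))
  Tdc <- fc$area * drug$diffusivity_blood / (fc$dist_a + fc$dist_b)
  # tissue Dirichlet boundary faces: the entire outer boundary
  bt <- faces[!interior & !is.na(faces$patch) &
                faces$patch %in% c("outer", "arterial_cap", "venous_cap"), ]
  bcell <- ifelse(is.na(bt$cell_a), bt$cell_b, bt$cell_a)
  bdist <- ifelse(is.na(bt$cell_a), bt$dist_b, bt$dist_a)
  Tbt <- bt$area * tissue$K_t / (tissue$mu_int * bdist)
  structure(list(
    mesh = mesh, tissue = tissue, capillary = capillary,
    transfer = transfer, drug = drug, p_t_outer = p_t_outer,
    control = ctl, nc = nc, nact = nact, act = act, aidx = aidx,
    art_cells = art_cells, ven_cells = ven_cells,
    fi_a = fi$cell_a, fi_b = fi$cell_b, Tt = Tt, Tdt = Tdt,
    fc_a = fc$cell_a, fc_b = fc$cell_b, Tc = Tc, Tdc = Tdc,
    bcell = bcell, Tbt = Tbt,
    V = cells$volume,
    k_decay = decay_rate(drug$half_life),
    is_tumor = !is.null(tissue$receptor)),
    class = "dcm_problem")
}

#' Initial DCM state
#'
#' Tissue pressure starts at the boundary value, capillary pressure varies
#' linearly between the arterial and venous values, the tissue drug is
#' zero, and the capillary drug follows the linear profile between the two
#' feeding nodes.
#'
#' @param problem a [dcm_problem()].
#' @param p_art,p_ven capillary Dirichlet pressures, Pa.
#' @param x_art,x_ven capillary Dirichlet mole fractions.
#' @param time initial time, s.
#' @return object of class `dcm_state`.
#' @export
initial_dcm_state <- function(problem, p_art, p_ven, x_art = 0, x_ven = 0,
                              time = 0) {
  nc <- problem$nc
  structure(list(
    p_t = rep(problem$p_t_outer, nc),
    x_t = rep(0, nc),
    p_c = initial_concentration_profile(p_art, p_ven, problem$mesh),
    x_c = initial_concentration_profile(x_art, x_ven, problem$mesh),
    C_RL = rep(0, nc), time = time),
    class = "dcm_state")
}

#' Linear initial profile between the arterial (-x) and venous (+x) caps
#'
#' @param v_art value at the arterial side. @param v_ven value at the
#'   venous side. @param mesh a [build_dcm_mesh()] mesh.
#' @return per-cell values varying linearly with the x-coordinate.
#' @export
initial_concentration_profile <- function(v_art, v_ven, mesh) {
  s <- (mesh$cells$x + mesh$R_out) / (2 * mesh$R_out)  # 0 at -x, 1 at +x
  v_art + (v_ven - v_art) * pmin(pmax(s, 0), 1)
}

# Assemble the frozen-coefficient linear form of the residual:
# residual(u) = M u + c0, exact at the current iterate's frozen states
# (upwind directions, lymph clamp, Starling flux in the solvent-drag term,
# receptor linearization point).  Returns M (sparse), c0, and the
# evaluated residual and its scale.
dcm_assemble <- function(prob, u, old, dt, bc) {
  nc <- prob$nc; nact <- prob$nact
  o_xt <- nc; o_pc <- 2L * nc; o_xc <- 2L * nc + nact
  ntot <- 2L * nc + 2L * nact
  p_t <- u[seq_len(nc)]; x_t <- u[o_xt + seq_len(nc)]
  p_c_a <- u[o_pc + seq_len(nact)]; x_c_a <- u[o_xc + seq_len(nact)]
  act <- prob$act; ai <- prob$aidx
  V <- prob$V
  ts <- prob$tissue; cp <- prob$capillary; tr <- prob$transfer
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  c0 <- numeric(ntot)
  addM <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  ## --- tissue flow -------------------------------------------------------
  et_rho <- ts$eps_t * ts$rhomol_int
  a_f <- prob$fi_a; b_f <- prob$fi_b; Tt <- prob$Tt
  addM(a_f, a_f,  et_rho * Tt); addM(a_f, b_f, -et_rho * Tt)
  addM(b_f, b_f,  et_rho * Tt); addM(b_f, a_f, -et_rho * Tt)
  # outer-boundary Dirichlet
  addM(prob$bcell, prob$bcell, et_rho * prob$Tbt)
  c0[seq_len(nc)] <- c0[seq_len(nc)] -
    as.numeric(tapply_add(et_rho * prob$Tbt * prob$p_t_outer, prob$bcell, nc))
  # lymphatic fluid sink (frozen clamp state)
  if (!is.null(ts$lymph)) {
    ly <- ts$lymph
    open <- if (prob$control$lymph_clamp) p_t > ly$p_ly else rep(TRUE, nc)
    coef <- V * ly$L_p_ly * ly$S_ly_V * ts$rhomol_int * as.numeric(open)
    addM(seq_len(nc), seq_len(nc), coef)
    c0[seq_len(nc)] <- c0[seq_len(nc)] - coef * ly$p_ly
  }
  # Starling source (tissue gains): residual -= V q_v on active cells
  acells <- which(act)
  a_st <- V[acells] * tr$L_p * tr$S_V * tr$rhomol_transfer
  dpi <- tr$sigma * (tr$pi_c - tr$pi_t)
  addM(acells, acells, a_st)                       # +a p_t
  addM(acells, o_pc + ai[acells], -a_st)           # -a p_c
  c0[acells] <- c0[acells] + a_st * dpi
  ## --- capillary flow ----------------------------------------------------
  dir_cells <- c(prob$art_cells, prob$ven_cells)
  dir_p <- c(rep(bc$p_art, length(prob$art_cells)),
             rep(bc$p_ven, length(prob$ven_cells)))
  dir_x <- c(rep(bc$x_art, length(prob$art_cells)),
             rep(bc$x_ven, length(prob$ven_cells)))
  free_cap <- setdiff(acells, dir_cells)
  ec_rho <- cp$eps_c * cp$rhomol_c
  ca <- prob$fc_a; cb <- prob$fc_b; Tc <- prob$Tc
  ra <- o_pc + ai[ca]; rb <- o_pc + ai[cb]
  # only add rows for free capillary cells; Dirichlet rows replaced below
  dirset <- logical(nc); dirset[dir_cells] <- TRUE
  wa <- !dirset[ca]; wb <- !dirset[cb]
  addM(ra[wa], ra[wa],  ec_rho * Tc[wa]); addM(ra[wa], rb[wa], -ec_rho * Tc[wa])
  addM(rb[wb], rb[wb],  ec_rho * Tc[wb]); addM(rb[wb], ra[wb], -ec_rho * Tc[wb])
  # Starling sink (capillary loses): residual += V q_v
  fc_free <- free_cap
  a_st_f <- V[fc_free] * tr$L_p * tr$S_V * tr$rhomol_transfer
  addM(o_pc + ai[fc_free], o_pc + ai[fc_free], a_st_f)
  addM(o_pc + ai[fc_free], fc_free, -a_st_f)
  c0[o_pc + ai[fc_free]] <- c0[o_pc + ai[fc_free]] - a_st_f * dpi
  # Dirichlet rows: p_c - p_bc = 0
  addM(o_pc + ai[dir_cells], o_pc + ai[dir_cells], rep(1, length(dir_cells)))
  c0[o_pc + ai[dir_cells]] <- c0[o_pc + ai[dir_cells]] - dir_p
  ## --- frozen fluxes for upwinding --------------------------------------
  Qt <- Tt * (p_t[a_f] - p_t[b_f])                   # m^3/s, a -> b
  Qbt <- prob$Tbt * (p_t[prob$bcell] - prob$p_t_outer)
  Qc <- Tc * (p_c_a[ai[ca]] - p_c_a[ai[cb]])
  p_eff <- effective_filtration_pressure(p_c_a[ai[acells]], p_t[acells],
                                         tr$sigma, tr$pi_c, tr$pi_t)
  J_v <- tr$L_p * tr$S_V * p_eff                      # 1/s, per active cell
  ## --- tissue transport --------------------------------------------------
  r_xt <- o_xt + seq_len(nc)
  stor_t <- ts$eps_t * ts$porosity * ts$rhomol_int * V / dt
  addM(r_xt, r_xt, stor_t)
  c0[r_xt] <- c0[r_xt] - stor_t * old$x_t
  # upwind advection on interior faces (frozen Qt)
  up <- ifelse(Qt >= 0, a_f, b_f)
  addM(o_xt + a_f, o_xt + up,  et_rho * Qt)
  addM(o_xt + b_f, o_xt + up, -et_rho * Qt)
  # diffusion
  addM(o_xt + a_f, o_xt + a_f,  et_rho * 0 + ts$eps_t * ts$rhomol_int * prob$Tdt)
  addM(o_xt + a_f, o_xt + b_f, -ts$eps_t * ts$rhomol_int * prob$Tdt)
  addM(o_xt + b_f, o_xt + b_f,  ts$eps_t * ts$rhomol_int * prob$Tdt)
  addM(o_xt + b_f, o_xt + a_f, -ts$eps_t * ts$rhomol_int * prob$Tdt)
  # boundary advection: outflow carries x_cell, inflow carries x = 0
  outb <- Qbt > 0
  if (any(outb))
    addM(o_xt + prob$bcell[outb], o_xt + prob$bcell[outb],
         et_rho * Qbt[outb])
  # lymphatic drug sink (frozen fluid rate)
  if (!is.null(ts$lymph)) {
    ly <- ts$lymph
    dp_ly <- p_t - ly$p_ly
    if (prob$control$lymph_clamp) dp_ly <- pmax(dp_ly, 0)
    lyr <- V * ly$L_p_ly * ly$S_ly_V * ts$rhomol_int * dp_ly
    addM(r_xt, r_xt, lyr)
  }
  # receptor binding (tumor): linearize sink(x_t) at the current iterate
  if (prob$is_tumor) {
    rc <- ts$receptor
    rb <- receptor_sink_lin(x_t, old$C_RL, ts$rhomol_int, rc, dt)
    addM(r_xt, r_xt, V * rb$dsdx)
    c0[r_xt] <- c0[r_xt] + V * (rb$s - rb$dsdx * x_t)
  }
  # Kedem-Katchalsky source (tissue gains): residual -= V q_x
  kk_d <- tr$P * tr$S_V * tr$rhomol_transfer
  kk_a <- (1 - tr$sigma_f) * J_v * tr$rhomol_transfer / 2   # frozen J_v
  Va <- V[acells]
  addM(o_xt + acells, o_xc + ai[acells], -Va * (kk_d + kk_a))
  addM(o_xt + acells, o_xt + acells,      Va * (kk_d - kk_a))
  ## --- capillary transport -----------------------------------------------
  r_xc_all <- o_xc + ai[acells]
  stor_c <- cp$eps_c * cp$rhomol_c * V[acells] / dt
  freex <- !dirset[acells]
  addM(r_xc_all[freex], r_xc_all[freex], stor_c[freex])
  c0[r_xc_all[freex]] <- c0[r_xc_all[freex]] -
    stor_c[freex] * old$x_c[acells][freex]
  upc <- ifelse(Qc >= 0, ca, cb)
  if (length(Qc)) {
    addM((o_xc + ai[ca])[wa], o_xc + ai[upc][wa],  ec_rho * Qc[wa])
    addM((o_xc + ai[cb])[wb], o_xc + ai[upc][wb], -ec_rho * Qc[wb])
    addM((o_xc + ai[ca])[wa], (o_xc + ai[ca])[wa],  ec_rho * prob$Tdc[wa])
    addM((o_xc + ai[ca])[wa], (o_xc + ai[cb])[wa], -ec_rho * prob$Tdc[wa])
    addM((o_xc + ai[cb])[wb], (o_xc + ai[cb])[wb],  ec_rho * prob$Tdc[wb])
    addM((o_xc + ai[cb])[wb], (o_xc + ai[ca])[wb], -ec_rho * prob$Tdc[wb])
  }
  # degradation
  addM(r_xc_all[freex], r_xc_all[freex],
       cp$eps_c * cp$rhomol_c * prob$k_decay * V[acells][freex])
  # K-K sink (capillary loses): residual += V q_x
  fx <- acells[freex]
  addM(o_xc + ai[fx], o_xc + ai[fx],
       V[fx] * (kk_d + kk_a[freex]))
  addM(o_xc + ai[fx], o_xt + fx, -V[fx] * (kk_d - kk_a[freex]))
  # Dirichlet rows: x_c - x_bc = 0
  addM(o_xc + ai[dir_cells], o_xc + ai[dir_cells], rep(1, length(dir_cells)))
  c0[o_xc + ai[dir_cells]] <- c0[o_xc + ai[dir_cells]] - dir_x
  ## -----------------------------------------------------------------------
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ntot, ntot))
  res <- as.numeric(M %*% u) + c0
  # reference magnitudes per block for the relative residual
  p_ref <- max(abs(c(bc$p_art, bc$p_ven, prob$p_t_outer)), 1)
  x_ref <- max(abs(c(bc$x_art, bc$x_ven)), max(abs(x_t)), max(abs(x_c_a)),
               1e-15)
  uref <- c(rep(p_ref, nc), rep(x_ref, nc), rep(p_ref, nact),
            rep(x_ref, nact))
  scale <- as.numeric(abs(M) %*% uref) + abs(c0)
  list(M = M, c0 = c0, res = res, scale = pmax(scale, 1e-300))
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- tapply(vals, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

receptor_sink_lin <- function(x_t, C_RL_old, rhomol, rc, dt) {
  Bc <- dt * rc$k_on * rhomol                 # coefficient of x in numerator
  num <- C_RL_old + Bc * x_t * rc$C_R0
  den <- 1 + Bc * x_t + dt * rc$k_off
  C_new <- num / den
  s <- (C_new - C_RL_old) / dt
  dsdx <- (Bc * rc$C_R0 * den - Bc * num) / den^2 / dt
  list(s = s, dsdx = dsdx, C_new = C_new)
}

#' Advance the double-continuum model by one implicit step
#'
#' Implicit-Euler step of the fully coupled four-field system, solved by a
#' Newton-type iteration on the nonlinear residual (frozen-coefficient
#' linearization of the upwind directions, lymphatic clamp, solvent-drag
#' coupling and receptor kinetics), converged when the relative residual
#' drops below `control$newton_tol`.  On non-convergence the step is
#' retried with halved dt (up to `control$max_halvings` times).
#'
#' @param state a `dcm_state`. @param dt step, s. @param problem a
#'   [dcm_problem()]. @param bc list `p_art`, `p_ven`, `x_art`, `x_ven`.
#' @return list: `state` (advanced `dcm_state`), `exchange` (end-of-step
#'   rates: `q_volume` m^3/s, `q_mass` kg/s, `q_x` mol/s, positive out of
#'   the blood), `diag` (lymph drug removal rate mol/s, receptor net
#'   binding rate mol/s, tissue boundary drug outflow mol/s, capillary
#'   degradation rate mol/s, Newton iterations).
#' @export
step_implicit <- function(state, dt, problem, bc) {
  res <- step_implicit_try(state, dt, problem, bc, problem$control$max_halvings)
  res
}

step_implicit_try <- function(state, dt, problem, bc, halvings_left) {
  nc <- problem$nc; nact <- problem$nact
  o_xt <- nc; o_pc <- 2L * nc; o_xc <- 2L * nc + nact
  act <- problem$act; ai <- problem$aidx
  u <- c(state$p_t, state$x_t, state$p_c[act], state$x_c[act])
  old <- state
  converged <- FALSE; iters <- 0L
  for (it in seq_len(problem$control$newton_maxit)) {
    A <- dcm_assemble(problem, u, old, dt, bc)
    iters <- it
    if (max(abs(A$res) / A$scale) <= problem$control$newton_tol) {
      converged <- TRUE; break
    }
    u_new <- tryCatch(as.numeric(Matrix::solve(A$M, -A$c0)),
                      error = function(e) NULL)
    if (is.null(u_new) || any(!is.finite(u_new))) break
    u <- u_new
  }
  if (!converged) {
    if (halvings_left <= 0L)
      stop("DCM Newton iteration failed to converge (dt = ", dt, ")")
    s1 <- step_implicit_try(state, dt / 2, problem, bc, halvings_left - 1L)
    s2 <- step_implicit_try(s1$state, dt / 2, problem, bc, halvings_left - 1L)
    # rates reported for the full step: average of the two half-steps
    ex <- mapply(function(a, b) (a + b) / 2, s1$exchange, s2$exchange,
                 SIMPLIFY = FALSE)
    dg <- mapply(function(a, b) if (is.numeric(a)) (a + b) / 2 else b,
                 s1$diag, s2$diag, SIMPLIFY = FALSE)
    return(list(state = s2$state, exchange = ex, diag = dg))
  }
  p_t <- u[seq_len(nc)]; x_t <- u[o_xt + seq_len(nc)]
  p_c <- state$p_c; x_c <- state$x_c
  p_c[act] <- u[o_pc + seq_len(nact)]; x_c[act] <- u[o_xc + seq_len(nact)]
  x_t <- pmax(x_t, 0); x_c <- pmax(x_c, 0)
  C_RL <- state$C_RL
  if (problem$is_tumor) {
    rb <- receptor_sink_lin(x_t, old$C_RL, problem$tissue$rhomol_int,
                            problem$tissue$receptor, dt)
    C_RL <- rb$C_new
  }
  new_state <- structure(list(p_t = p_t, x_t = x_t, p_c = p_c, x_c = x_c,
                              C_RL = C_RL, time = state$time + dt),
                         class = "dcm_state")
  ex <- dcm_exchange_rates(problem, new_state, bc)
  dg <- dcm_diagnostics(problem, new_state, old, dt)
  dg$newton_iters <- iters
  list(state = new_state, exchange = ex, diag = dg)
}

# End-of-step (implicit-Euler-consistent) transfer rates, integrated over
# the capillary-active cells: positive = leaving the blood compartment.
dcm_exchange_rates <- function(problem, state, bc) {
  tr <- problem$transfer
  acells <- which(problem$act)
  p_eff <- effective_filtration_pressure(state$p_c[acells],
                                         state$p_t[acells],
                                         tr$sigma, tr$pi_c, tr$pi_t)
  sf <- starling_flux(p_eff, tr$L_p, tr$S_V, tr$rhomol_transfer)
  qx <- kedem_katchalsky_flux(state$x_c[acells], state$x_t[acells],
                              sf$J_v, tr$P, tr$sigma_f, tr$S_V,
                              tr$rhomol_transfer)
  Va <- problem$V[acells]
  q_vol <- sum(Va * sf$J_v)
  list(q_volume = q_vol,
       q_mass = q_vol * problem$capillary$rho_c,
       q_x = sum(Va * qx))
}

dcm_diagnostics <- function(problem, state, old, dt) {
  ts <- problem$tissue
  lymph_rate <- 0
  if (!is.null(ts$lymph)) {
    ly <- lymphatic_sinks(state$p_t, state$x_t, ts$lymph, ts$rhomol_int,
                          clamp = problem$control$lymph_clamp)
    lymph_rate <- sum(problem$V * ly$drug)
  }
  bind_rate <- if (problem$is_tumor)
    sum(problem$V * (state$C_RL - old$C_RL)) / dt else 0
  Qbt <- problem$Tbt * (state$p_t[problem$bcell] - problem$p_t_outer)
  outb <- Qbt > 0
  bnd_rate <- ts$eps_t * ts$rhomol_int *
    sum(Qbt[outb] * state$x_t[problem$bcell][outb])
  cp <- problem$capillary
  deg_rate <- cp$eps_c * cp$rhomol_c * problem$k_decay *
    sum(problem$V[problem$act] * state$x_c[problem$act])
  list(lymph_drug_rate = lymph_rate, receptor_bind_rate = bind_rate,
       tissue_boundary_outflow = bnd_rate, capillary_degradation = deg_rate)
}

#' Moles of drug held in the DCM tissue compartment (free + bound)
#'
#' @param problem a [dcm_problem()]. @param state a `dcm_state`.
#' @return list `free`, `bound` (moles).
#' @export
dcm_tissue_moles <- function(problem, state) {
  ts <- problem$tissue
  list(free = sum(ts$eps_t * ts$porosity * ts$rhomol_int *
                    state$x_t * problem$V),
       bound = sum(state$C_RL * problem$V))
}

#' Volume-integrated transfer rates between two consecutive states
#'
#' Integrates the Starling and Kedem-Katchalsky transfer over the
#' capillary-active cells.  With `quadrature = "end"` (default) the rates
#' are evaluated at the new state, the quadrature consistent with the
#' implicit-Euler step, so the reported exchange matches the step's
#' internal balance exactly; `"trapezoid"` averages the two endpoint
#' evaluations.
#'
#' @param state_old,state_new consecutive `dcm_state`s.
#' @param dt step between them, s.
#' @param problem a [dcm_problem()].
#' @param bc boundary-condition list (as in [step_implicit()]).
#' @param quadrature `"end"` or `"trapezoid"`.
#' @return list `q_mass` (kg/s), `q_x` (mol/s), `q_volume` (m^3/s),
#'   positive = leaving the blood.
#' @export
integrate_exchange <- function(state_old, state_new, dt, problem, bc,
                               quadrature = c("end", "trapezoid")) {
  quadrature <- match.arg(quadrature)
  en <- dcm_exchange_rates(problem, state_new, bc)
  if (quadrature == "end") return(en)
  eo <- dcm_exchange_rates(problem, state_old, bc)
  mapply(function(a, b) (a + b) / 2, eo, en, SIMPLIFY = FALSE)
}

#' Effective flow resistance of an upscaled node's capillary bed
#'
#' Solves the capillary-continuum Darcy flow alone with a unit pressure
#' difference between the arterial and venous cones and returns
#' `R_eff = dp / Q`.  This is the resistance the upscaled node presents to
#' the vascular graph (split over its two upscaled edges).
#'
#' @param problem a [dcm_problem()].
#' @param dp probing pressure difference, Pa (result is independent of it).
#' @return resistance, Pa·s/m^3.
#' @export
effective_upscaled_resistance <- function(problem, dp = 1) {
  ai <- problem$aidx; nact <- problem$nact
  dir_cells <- c(problem$art_cells, problem$ven_cells)
  dir_p <- c(rep(dp, length(problem$art_cells)),
             rep(0, length(problem$ven_cells)))
  ca <- ai[problem$fc_a]; cb <- ai[problem$fc_b]; Tc <- problem$Tc
  dirset <- logical(nact); dirset[ai[dir_cells]] <- TRUE
  pv <- numeric(nact); pv[ai[dir_cells]] <- dir_p
  free <- which(!dirset)
  if (!length(free)) stop("no free capillary cells between the cones")
  fmap <- integer(nact); fmap[free] <- seq_along(free)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(length(free))
  for (side in 1:2) {
    aa <- if (side == 1) ca else cb
    bb <- if (side == 1) cb else ca
    w <- !dirset[aa]
    ii <- c(ii, fmap[aa[w]]); jj <- c(jj, fmap[aa[w]]); xx <- c(xx, Tc[w])
    wb2 <- w & !dirset[bb]
    ii <- c(ii, fmap[aa[wb2]]); jj <- c(jj, fmap[bb[wb2]])
    xx <- c(xx, -Tc[wb2])
    wb1 <- w & dirset[bb]
    if (any(wb1)) {
      agg <- tapply(Tc[wb1] * pv[bb[wb1]], fmap[aa[wb1]], sum)
      rhs[as.integer(names(agg))] <- rhs[as.integer(names(agg))] + agg
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(free), length(free)))
  sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                  error = function(e)
                    stop("capillary bed has zero conductance between the ",
                         "cones: ", conditionMessage(e)))
  pv[free] <- sol
  # flow leaving the arterial Dirichlet cells
  art <- logical(nact); art[ai[problem$art_cells]] <- TRUE
  Q <- sum(Tc[art[ca] & !art[cb]] *
             (pv[ca[art[ca] & !art[cb]]] - pv[cb[art[ca] & !art[cb]]])) +
    sum(Tc[art[cb] & !art[ca]] *
          (pv[cb[art[cb] & !art[ca]]] - pv[ca[art[cb] & !art[ca]]]))
  if (!(Q > 0)) stop("zero conductance across the capillary bed")
  dp / Q
}
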