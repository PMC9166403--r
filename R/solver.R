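#' Solver configuration
#'
#' Mesh resolution, time-grid and Newton settings for the finite-element
#' engine. Three presets are provided: `"default"` (production runs),
#' `"fit"` (coarsened mesh and time grid for use inside the inverse
#' optimization loop), and `"fine"` (refined runs for convergence checks).
#'
#' The time grid is `n_ramp_steps` uniform steps over the compression ramp
#' followed by geometrically growing steps (`dt_ratio`, capped at `dt_max`
#' seconds) over the relaxation phase.
#'
#' @param fidelity One of `"default"`, `"fit"`, `"fine"`; sets all defaults,
#'   which the remaining arguments then override.
#' @param nr,nz Elements radially / through thickness.
#' @param grading Mesh grading, see [make_specimen_mesh()].
#' @param n_ramp_steps Time steps over the ramp.
#' @param dt_ratio Geometric growth factor of the relaxation time step.
#' @param dt_max Maximum time step, s.
#' @param newton_tol Convergence tolerance on the max-norm of the Newton
#'   increment (mm / MPa / N).
#' @param newton_maxit Maximum Newton iterations per (sub)step.
#' @param max_set_iter Maximum contact active-set sweeps per step.
#' @param max_halve Maximum step halvings (a step may be split into up to
#'   `2^max_halve` substeps before the solver gives up).
#' @param store_states Keep the full nodal state history (memory-heavy).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(fidelity = c("default", "fit", "fine"),
                          nr = NULL, nz = NULL, grading = "contact",
                          n_ramp_steps = NULL, dt_ratio = NULL, dt_max = NULL,
                          newton_tol = 1e-9, newton_maxit = 60,
                          max_set_iter = 40, max_halve = 8,
                          store_states = FALSE) {
  fidelity <- match.arg(fidelity)
  preset <- switch(fidelity,
    default = list(nr = 14, nz = 10, n_ramp_steps = 20, dt_ratio = 1.2, dt_max = 20),
    fit     = list(nr = 8,  nz = 5,  n_ramp_steps = 6,  dt_ratio = 1.8, dt_max = 80),
    fine    = list(nr = 28, nz = 20, n_ramp_steps = 30, dt_ratio = 1.15, dt_max = 10))
  out <- list(
    fidelity = fidelity,
    nr = nr %||% preset$nr, nz = nz %||% preset$nz, grading = grading,
    n_ramp_steps = n_ramp_steps %||% preset$n_ramp_steps,
    dt_ratio = dt_ratio %||% preset$dt_ratio,
    dt_max = dt_max %||% preset$dt_max,
    newton_tol = newton_tol, newton_maxit = newton_maxit,
    max_set_iter = max_set_iter, max_halve = max_halve,
    store_states = store_states)
  class(out) <- "solver_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ramp-and-hold time grid (internal)
time_grid <- function(ramp_time, total_time, config) {
  if (ramp_time <= 0) {
    tt <- c(0)
  } else {
    tt <- seq(0, ramp_time, length.out = config$n_ramp_steps + 1)
  }
  t <- tt[length(tt)]
  dt <- if (ramp_time > 0) ramp_time / config$n_ramp_steps else total_time / 100
  while (t < total_time - 1e-9) {
    dt <- min(dt * config$dt_ratio, config$dt_max, total_time - t)
    t <- t + dt
    tt <- c(tt, t)
  }
  tt
}

# per-element material arrays for the C++ core (internal)
build_fe_material <- function(params, mesh, arch_config = architecture_config()) {
  m <- derived_moduli(params$E_nf, params$nu_nf)
  ne <- nrow(mesh$elements)
  totf <- arch_config$n_primary + arch_config$n_secondary
  elem_mat <- matrix(0, ne, 5)
  dirs <- array(0, dim = c(totf, 3, ne))
  w <- matrix(0, totf, ne)
  for (e in seq_len(ne)) {
    h <- mesh$elem_h[e]
    arch <- build_cartilage_architecture(h, arch_config)
    dw <- arch_dirs_weights(arch, params, h)
    dirs[, , e] <- dw$dirs
    w[, e] <- dw$w
    elem_mat[e, ] <- c(m$K_nf, m$G_nf, params$E_f, params$k_0, params$M)
  }
  list(elem_mat = elem_mat, dirs = dirs, w = w)
}

#' State-vector indices of nodal unknowns
#'
#' The global state vector interleaves `(u_r, u_z, p)` per node. These helpers
#' return the indices of each unknown for a set of node numbers (1-based).
#'
#' @param nodes Integer node indices.
#' @return Integer indices into the state vector.
#' @export
dof_u_r <- function(nodes) 3 * (nodes - 1) + 1

#' @rdname dof_u_r
#' @export
dof_u_z <- function(nodes) 3 * (nodes - 1) + 2

#' @rdname dof_u_r
#' @export
dof_p   <- function(nodes) 3 * (nodes - 1) + 3

# boundary-condition dof sets per protocol mode (internal)
fe_bcs <- function(mesh, mode = c("indent", "unconfined", "confined")) {
  mode <- match.arg(mode)
  s <- mesh$sets
  switch(mode,
    indent = list(
      fixed_u = c(dof_u_r(s$base), dof_u_z(s$base), dof_u_r(setdiff(s$axis, s$base))),
      driven_uz = integer(0),
      p_fixed = dof_p(s$outer),
      p_surface = dof_p(setdiff(s$surface, s$outer)),
      contact_nodes = s$surface),
    unconfined = list(
      # frictionless impermeable platens: uz fixed/driven, ur free, p free
      fixed_u = c(dof_u_z(s$base), dof_u_r(s$axis)),
      driven_uz = dof_u_z(s$surface),
      p_fixed = dof_p(s$outer),
      p_surface = integer(0),
      contact_nodes = integer(0)),
    confined = list(
      # rigid impermeable lateral wall; porous rigid top platen
      fixed_u = c(dof_u_r(seq_len(nrow(mesh$nodes))), dof_u_z(s$base)),
      driven_uz = dof_u_z(s$surface),
      p_fixed = dof_p(s$surface),
      p_surface = integer(0),
      contact_nodes = integer(0)))
}

# low-level simulation driver (internal)
run_fe <- function(params, mesh, times, sched, mode, config,
                   sphere_r = 0.175, drained = FALSE,
                   arch_config = architecture_config()) {
  mat <- build_fe_material(params, mesh, arch_config)
  bc <- fe_bcs(mesh, mode)
  ctrl <- list(newton_tol = config$newton_tol, newton_maxit = config$newton_maxit,
               max_set_iter = config$max_set_iter, max_halve = config$max_halve,
               store_states = config$store_states)
  nodes <- as.matrix(mesh$nodes[, c("r", "z")])
  out <- cpp_simulate(nodes, mesh$elements, mat$elem_mat, mat$dirs, mat$w,
                      times, sched,
                      as.integer(bc$fixed_u), as.integer(bc$driven_uz),
                      as.integer(bc$p_fixed), as.integer(bc$p_surface),
                      as.integer(bc$contact_nodes),
                      sphere_r, mesh$thickness, drained, ctrl, numeric(0))
  if (out$status != 0)
    stop(sprintf(
      "FE solver failed to converge at t = %.4g s (step %d of %d); last converged t = %.4g s",
      times[out$last_ok + 2], out$last_ok + 1, length(times) - 1,
      times[out$last_ok + 1]), call. = FALSE)
  for (nm in c("time", "force_contact", "force_top", "force_base", "p_base",
               "max_abs_p", "checkerboard", "vol_change", "efflux_cum", "U"))
    out[[nm]] <- as.numeric(out[[nm]])
  out$mesh <- mesh
  out$mode <- mode
  out
}

#' Assemble the discrete residual and Jacobian
#'
#' Assembles the unconstrained global residual (momentum rows: divergence of
#' the total stress; continuity rows: backward-Euler volume rate balanced by
#' Darcy conduction) and its Jacobian for a given nodal state. Intended for
#' inspection and verification; the time-stepping driver assembles internally.
#'
#' The state vectors interleave nodal unknowns as
#' `(u_r, u_z, p)` per node: `U[3i-2] = u_r`, `U[3i-1] = u_z`, `U[3i] = p`.
#'
#' @param state Current nodal state vector (length `3 * n_nodes`).
#' @param state_prev Converged state at the previous time (same layout).
#' @param mesh An [make_specimen_mesh()] mesh.
#' @param params An [frpe_params()] object.
#' @param dt Time step, s (> 0).
#' @param jacobian Return the Jacobian as well (default TRUE).
#' @return A list with `residual` (length `3 n`) and, if requested,
#'   `jacobian` (`3n` x `3n` dense matrix).
#' @export
assemble_system <- function(state, state_prev, mesh, params, dt,
                            jacobian = TRUE) {
  stopifnot(dt > 0)
  nd <- 3 * nrow(mesh$nodes)
  if (length(state) != nd || length(state_prev) != nd)
    stop("state vectors must have length 3 * n_nodes", call. = FALSE)
  mat <- build_fe_material(params, mesh)
  nodes <- as.matrix(mesh$nodes[, c("r", "z")])
  cpp_assemble(nodes, mesh$elements, mat$elem_mat, mat$dirs, mat$w,
               state, state_prev, dt, jacobian)
}

#' Advance the poroelastic system by one backward-Euler step
#'
#' Solves one implicit time step of the u-p system with Newton iteration,
#' holding the platen/boundary conditions of the chosen protocol mode, and a
#' prescribed indenter depth for `"indent"`. On Newton failure the step is
#' bisected internally (up to `2^max_halve` substeps).
#'
#' @inheritParams assemble_system
#' @param mode Boundary-condition set: `"indent"`, `"unconfined"` or
#'   `"confined"`.
#' @param delta Prescribed indenter depth / platen displacement at the end of
#'   the step, mm.
#' @param delta_prev Value at the start of the step (default 0).
#' @param config A [solver_config()].
#' @param sphere_r Indenter radius, mm (indent mode).
#' @return A list with the converged `state` vector, the reaction `force` (N)
#'   and solver diagnostics.
#' @export
backward_euler_step <- function(state_prev, mesh, params, dt,
                                mode = "indent", delta = 0, delta_prev = 0,
                                config = solver_config(), sphere_r = 0.175) {
  stopifnot(dt > 0)
  sched <- rbind(c(0, delta_prev), c(dt, delta))
  mat <- build_fe_material(params, mesh)
  bc <- fe_bcs(mesh, mode)
  ctrl <- list(newton_tol = config$newton_tol, newton_maxit = config$newton_maxit,
               max_set_iter = config$max_set_iter, max_halve = config$max_halve,
               store_states = FALSE)
  nodes <- as.matrix(mesh$nodes[, c("r", "z")])
  out <- cpp_simulate(nodes, mesh$elements, mat$elem_mat, mat$dirs, mat$w,
                      c(0, dt), sched,
                      as.integer(bc$fixed_u), as.integer(bc$driven_uz),
                      as.integer(bc$p_fixed), as.integer(bc$p_surface),
                      as.integer(bc$contact_nodes),
                      sphere_r, mesh$thickness, FALSE, ctrl,
                      as.numeric(state_prev))
  if (out$status != 0)
    stop("time step failed to converge after maximum bisection", call. = FALSE)
  force <- if (mode == "indent") out$force_contact[2] else out$force_top[2]
  list(state = as.numeric(out$U), force = as.numeric(force),
       newton_iters = out$newton_iters[2], converged = TRUE)
}
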