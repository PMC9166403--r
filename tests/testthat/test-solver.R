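# axisymmetric u-p finite-element engine: assembly, stepping, contact

test_that("reference state is in discrete equilibrium", {
  mesh <- make_specimen_mesh(1.5, 0.13, 3, 3, "uniform")
  nd <- 3 * nrow(mesh$nodes)
  out <- assemble_system(rep(0, nd), rep(0, nd), mesh, ref_params(), dt = 0.1,
                         jacobian = FALSE)
  expect_lt(max(abs(out$residual)), 1e-12)
})

test_that("uniform pore pressure with no displacement gives zero flux residual", {
  mesh <- make_specimen_mesh(1.5, 0.13, 3, 3, "uniform")
  nn <- nrow(mesh$nodes)
  state <- rep(0, 3 * nn)
  state[3 * seq_len(nn)] <- 0.25   # constant p everywhere
  out <- assemble_system(state, rep(0, 3 * nn), mesh, ref_params(), dt = 0.1,
                         jacobian = FALSE)
  p_rows <- 3 * seq_len(nn)
  expect_lt(max(abs(out$residual[p_rows])), 1e-12)
})

test_that("assembled Jacobian agrees with global finite differences", {
  mesh <- make_specimen_mesh(0.5, 0.2, 2, 2, "uniform")
  p <- ref_params()
  nn <- nrow(mesh$nodes)
  nd <- 3 * nn
  set.seed(8)
  # random admissible state: small displacements and pressures
  state <- rep(0, nd)
  state[dof_u_r(seq_len(nn))] <- runif(nn, -5e-3, 5e-3)
  state[dof_u_z(seq_len(nn))] <- runif(nn, -5e-3, 5e-3)
  state[dof_p(seq_len(nn))] <- runif(nn, -0.05, 0.05)
  prev <- rep(0, nd)
  dt <- 0.05
  out <- assemble_system(state, prev, mesh, p, dt, jacobian = TRUE)
  h <- 1e-6
  K_fd <- matrix(0, nd, nd)
  for (d in seq_len(nd)) {
    sp <- state; sp[d] <- sp[d] + h
    sm <- state; sm[d] <- sm[d] - h
    rp <- assemble_system(sp, prev, mesh, p, dt, jacobian = FALSE)$residual
    rm <- assemble_system(sm, prev, mesh, p, dt, jacobian = FALSE)$residual
    K_fd[, d] <- (rp - rm) / (2 * h)
  }
  scale <- max(abs(K_fd))
  expect_lt(max(abs(out$jacobian - K_fd)) / scale, 1e-5)
})

test_that("a step with no boundary motion leaves the state unchanged", {
  mesh <- make_specimen_mesh(1.5, 0.13, 3, 3, "uniform")
  nd <- 3 * nrow(mesh$nodes)
  st <- backward_euler_step(rep(0, nd), mesh, ref_params(), dt = 1,
                            mode = "indent", delta = 0)
  expect_equal(st$state, rep(0, nd), tolerance = 1e-12)
  expect_equal(st$force, 0)
})

test_that("internal step bisection reproduces the explicit fine-step path", {
  # a deliberately tight Newton budget forces internal halving; the bisected
  # path must match an explicit grid of the same substeps exactly
  p <- ref_params()
  prot <- indentation_protocol()
  mesh <- make_specimen_mesh(1.5, 0.13, 5, 3, "uniform")
  mat <- frpefit:::build_fe_material(p, mesh)
  bc <- frpefit:::fe_bcs(mesh, "indent")
  nodes <- as.matrix(mesh$nodes[, c("r", "z")])
  run <- function(times, maxit, max_halve) {
    ctrl <- list(newton_tol = 1e-9, newton_maxit = maxit,
                 max_set_iter = 40, max_halve = max_halve,
                 store_states = FALSE)
    frpefit:::cpp_simulate(nodes, mesh$elements, mat$elem_mat, mat$dirs, mat$w,
                           times, rbind(c(0, 0), c(1, 0.04)),
                           as.integer(bc$fixed_u), as.integer(bc$driven_uz),
                           as.integer(bc$p_fixed), as.integer(bc$p_surface),
                           as.integer(bc$contact_nodes),
                           0.175, 0.13, FALSE, ctrl, numeric(0))
  }
  coarse <- run(c(0, 1), maxit = 12, max_halve = 6)
  expect_equal(coarse$status, 0)
  # find the explicit substep count that succeeds without internal halving
  matched <- FALSE
  for (k in 0:6) {
    fine <- run(seq(0, 1, length.out = 2^k + 1), maxit = 12, max_halve = 0)
    if (fine$status == 0) {
      expect_equal(as.numeric(fine$U), as.numeric(coarse$U), tolerance = 1e-7)
      matched <- TRUE
      break
    }
  }
  expect_true(matched)
})

test_that("confined drained equilibrium matches the uniaxial-strain closed form", {
  # high permeability + long hold drains the sample; the equilibrium platen
  # stress is the neo-Hookean uniaxial-strain response (fibrils slack)
  p <- cartilage_params(k_0 = 0.05, M = 0)
  strain <- 0.05
  res <- run_confined_compression(p, strain = strain, thickness = 0.5,
                                  radius = 0.3, t_end = 4000,
                                  config = quick_config(nz = 4))
  lam <- 1 - strain
  m <- derived_moduli(p$E_nf, p$nu_nf)
  Fm <- diag(c(1, lam, 1))
  s_zz <- oracle_neo_hookean(Fm, m$K_nf, m$G_nf)[2, 2]
  F_eq <- utils::tail(res$force_N, 1)
  expect_equal(F_eq, -s_zz * attr(res, "area"), tolerance = 0.01)
  # pressure decays to zero at drained equilibrium
  expect_lt(abs(utils::tail(res$p_base_MPa, 1)), 1e-6)
})

test_that("no contact force when the indenter does not touch", {
  mesh <- make_specimen_mesh(1.5, 0.13, 4, 3, "uniform")
  nd <- 3 * nrow(mesh$nodes)
  st <- backward_euler_step(rep(0, nd), mesh, ref_params(), dt = 0.5,
                            mode = "indent", delta = 0)
  expect_equal(st$force, 0)
})

test_that("contact complementarity: no residual penetration after a step", {
  p <- ref_params()
  mesh <- make_specimen_mesh(1.5, 0.13, 8, 5, "contact")
  nd <- 3 * nrow(mesh$nodes)
  delta <- 0.01
  st <- backward_euler_step(rep(0, nd), mesh, p, dt = 0.25, mode = "indent",
                            delta = delta)
  expect_gt(st$force, 0)
  # gap of every surface node against the analytic sphere
  Rs <- 0.175
  zc <- 0.13 + Rs - delta
  surf <- mesh$sets$surface
  r <- mesh$nodes$r[surf] + st$state[dof_u_r(surf)]
  z <- mesh$nodes$z[surf] + st$state[dof_u_z(surf)]
  inside <- r < 0.95 * Rs
  gap <- (zc - sqrt(Rs^2 - r[inside]^2)) - z[inside]
  expect_gt(min(gap), -1e-8)   # nodes never penetrate beyond tolerance
})

test_that("shallow drained indentation approaches the Hertzian contact force", {
  E <- 0.83; nu <- 0.42
  p <- cartilage_params(E_f = 1e-9, E_nf = E, nu_nf = nu)
  prot <- indentation_protocol(ramp_amplitude = 0.04, sample_thickness = 2,
                               sample_radius = 2, indenter_radius = 0.5)
  cfg <- solver_config("default", nr = 24, nz = 16)
  cv <- run_stress_relaxation(p, prot, cfg, drained = TRUE)
  F_hertz <- 4 / 3 * (E / (1 - nu^2)) * sqrt(0.5) * 0.04^1.5
  expect_equal(max(cv$force_N), F_hertz, tolerance = 0.10)
})

test_that("indenter force balances the base reaction", {
  p <- ref_params()
  cv <- run_stress_relaxation(p, indentation_protocol(), quick_config())
  d <- attr(cv, "diagnostics")
  sel <- cv$force_N > 0
  expect_lt(max(abs(d$force_base[sel] - cv$force_N[sel])) / max(cv$force_N),
            1e-5)
})

test_that("fluid efflux balances the volume change over a full relaxation", {
  cv <- run_stress_relaxation(ref_params(), indentation_protocol(),
                              quick_config())
  d <- attr(cv, "diagnostics")
  dV <- utils::tail(d$vol_change, 1)
  Q <- utils::tail(d$efflux_cum, 1)
  expect_equal(Q, -dV, tolerance = 0.01)
})

test_that("equilibrium indentation force does not depend on permeability", {
  prot <- indentation_protocol(relaxation_time = 2000)
  cfg <- quick_config(dt_max = 200)
  f_eq <- sapply(k0_from_si(c(0.5, 3.3, 6.5)), function(k0) {
    cv <- run_stress_relaxation(cartilage_params(k_0 = k0), prot, cfg)
    utils::tail(cv$force_N, 1)
  })
  expect_lt(diff(range(f_eq)) / mean(f_eq), 0.005)
})

test_that("mesh convergence study reports refinement differences", {
  p <- ref_params()
  prot <- indentation_protocol()
  cfg <- quick_config()
  # identical meshes at two levels -> zero difference
  rep0 <- mesh_convergence_study(p, prot, c(1, 1), cfg)
  expect_equal(rep0$rel_diff_peak[2], 0, tolerance = 1e-12)
  expect_true(rep0$meets_5pct[2])
  expect_error(mesh_convergence_study(p, prot, 1), "two refinement levels")
})
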