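#' Spherical-indentation stress-relaxation protocol
#'
#' The ramp-and-hold indentation protocol: after contact is established (an
#' automatic 0.01 N contact criterion in the physical experiment), the rigid
#' impermeable frictionless spherical indenter is driven in by
#' `ramp_amplitude` at `ramp_velocity` and held for `relaxation_time` while
#' the reaction force relaxes through fluid exudation.
#'
#' @param contact_criterion_force Contact-detection force threshold, N.
#' @param contact_velocity Contact-approach velocity, mm/s.
#' @param ramp_amplitude Indentation depth, mm (~30% of cartilage thickness).
#' @param ramp_velocity Compression velocity, mm/s.
#' @param relaxation_time Hold time after the ramp, s.
#' @param sample_thickness Cartilage thickness, mm.
#' @param sample_radius Specimen (cylinder) radius, mm.
#' @param indenter_radius Spherical indenter radius, mm.
#' @return A list of class `indentation_protocol`.
#' @export
indentation_protocol <- function(contact_criterion_force = 0.01,
                                 contact_velocity = 0.1,
                                 ramp_amplitude = 0.04,
                                 ramp_velocity = 0.04,
                                 relaxation_time = 400,
                                 sample_thickness = 0.13,
                                 sample_radius = 1.5,
                                 indenter_radius = 0.175) {
  vals <- c(contact_criterion_force, contact_velocity, ramp_velocity,
            relaxation_time, sample_thickness, sample_radius, indenter_radius)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all protocol quantities must be positive", call. = FALSE)
  if (ramp_amplitude < 0) stop("ramp_amplitude must be >= 0", call. = FALSE)
  if (ramp_amplitude >= sample_thickness)
    stop("ramp_amplitude must be smaller than the sample thickness", call. = FALSE)
  structure(list(contact_criterion_force = contact_criterion_force,
                 contact_velocity = contact_velocity,
                 ramp_amplitude = ramp_amplitude,
                 ramp_velocity = ramp_velocity,
                 relaxation_time = relaxation_time,
                 sample_thickness = sample_thickness,
                 sample_radius = sample_radius,
                 indenter_radius = indenter_radius),
            class = "indentation_protocol")
}

new_force_curve <- function(time_s, force_N, provenance, ...) {
  out <- tibble::tibble(time_s = time_s, force_N = force_N)
  attr(out, "provenance") <- provenance
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("force_curve", class(out))
  out
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve: %s> %d samples, t = [%g, %g] s, peak %0.4g N\n",
              attr(x, "provenance") %||% "?", nrow(x),
              min(x$time_s), max(x$time_s), max(x$force_N)))
  NextMethod()
}

#' Simulate an indentation stress-relaxation test
#'
#' Runs the axisymmetric finite-element model of a cylindrical cartilage
#' specimen under the ramp-and-hold spherical indentation protocol and returns
#' the indenter reaction force over time. The indenter starts at geometric
#' touch (zero force); the base is fixed and impermeable, the outer wall and
#' the non-contacting surface drain freely, and surface nodes are sealed while
#' in contact.
#'
#' @param params An [frpe_params()] object.
#' @param protocol An [indentation_protocol()].
#' @param config A [solver_config()].
#' @param drained Run the drained (elastic) limit: pore pressure prescribed
#'   zero everywhere, giving the equilibrium elastic response (used e.g. for
#'   comparison against the Hertzian contact solution).
#' @return A `force_curve` tibble (`time_s`, `force_N`) on the solver time
#'   grid, with the protocol, parameters and solver diagnostics attached as
#'   attributes.
#' @export
run_stress_relaxation <- function(params, protocol = indentation_protocol(),
                                  config = solver_config(), drained = FALSE) {
  amp <- protocol$ramp_amplitude
  ramp_time <- amp / protocol$ramp_velocity
  total <- ramp_time + protocol$relaxation_time
  mesh <- make_specimen_mesh(protocol$sample_radius, protocol$sample_thickness,
                             config$nr, config$nz, config$grading)
  if (amp <= 0) {
    times <- time_grid(1, total, config)
    return(new_force_curve(times, rep(0, length(times)),
                           provenance = "simulated", protocol = protocol,
                           params = params))
  }
  times <- time_grid(ramp_time, total, config)
  sched <- rbind(c(0, 0), c(ramp_time, amp), c(total, amp))
  out <- run_fe(params, mesh, times, sched, "indent", config,
                sphere_r = protocol$indenter_radius, drained = drained)
  new_force_curve(out$time, out$force_contact,
                  provenance = if (drained) "simulated-drained" else "simulated",
                  protocol = protocol,
                  params = params,
                  diagnostics = list(newton_iters = out$newton_iters,
                                     checkerboard = max(out$checkerboard),
                                     max_abs_p = out$max_abs_p,
                                     efflux_cum = out$efflux_cum,
                                     vol_change = out$vol_change,
                                     force_base = out$force_base),
                  state = out$U, fe_mesh = mesh)
}

#' Resample a force curve onto a compact acquisition grid
#'
#' Uniform sampling at `ramp_hz` during the ramp, then logarithmic sampling
#' (`pts_per_decade` points per decade) during relaxation; linear
#' interpolation in time.
#'
#' @param curve A `force_curve`.
#' @param ramp_time Ramp duration, s (taken from the attached protocol when
#'   available).
#' @param ramp_hz Sampling rate over the ramp, Hz.
#' @param pts_per_decade Log-spaced samples per decade of relaxation time.
#' @return A resampled `force_curve`.
#' @export
resample_force_curve <- function(curve, ramp_time = NULL, ramp_hz = 10,
                                 pts_per_decade = 30) {
  prot <- attr(curve, "protocol")
  if (is.null(ramp_time)) {
    if (is.null(prot)) stop("ramp_time required when no protocol is attached",
                            call. = FALSE)
    ramp_time <- prot$ramp_amplitude / prot$ramp_velocity
  }
  t_end <- max(curve$time_s)
  t_ramp <- seq(0, ramp_time, by = 1 / ramp_hz)
  n_dec <- log10(t_end / ramp_time)
  t_rel <- ramp_time * 10^(seq(0, n_dec, length.out = max(2, ceiling(n_dec * pts_per_decade))))
  tt <- sort(unique(pmin(c(t_ramp, t_rel), t_end)))
  ff <- approx(curve$time_s, curve$force_N, xout = tt, rule = 2)$y
  out <- new_force_curve(tt, ff, provenance = attr(curve, "provenance") %||% "resampled")
  for (a in c("protocol", "params", "truth"))
    if (!is.null(attr(curve, a))) attr(out, a) <- attr(curve, a)
  out
}

#' Indenter displacement at the contact-criterion force
#'
#' Returns the indenter displacement at which the simulated force first
#' reaches the contact-criterion threshold, used to align simulated curves
#' with measurements that zero their displacement at a force criterion rather
#' than at geometric touch.
#'
#' @param curve A `force_curve` from an indentation simulation (the
#'   displacement history is reconstructed from the attached protocol), or a
#'   data frame with columns `displacement_mm` and `force_N`.
#' @param criterion Force threshold, N (> 0).
#' @return Displacement offset, mm.
#' @export
apply_contact_criterion <- function(curve, criterion = 0.01) {
  if (criterion <= 0) stop("criterion must be > 0", call. = FALSE)
  if (!is.null(curve[["displacement_mm"]])) {
    d <- curve[["displacement_mm"]]
    f <- curve$force_N
  } else {
    prot <- attr(curve, "protocol")
    if (is.null(prot))
      stop("curve carries no displacement information", call. = FALSE)
    d <- pmin(curve$time_s * prot$ramp_velocity, prot$ramp_amplitude)
    f <- curve$force_N
  }
  if (f[1] >= criterion) return(0)
  idx <- which(f >= criterion)[1]
  if (is.na(idx)) stop("contact criterion force never reached", call. = FALSE)
  approx(f[(idx - 1):idx], d[(idx - 1):idx], xout = criterion)$y
}

#' Unconfined compression to drained equilibrium
#'
#' Compresses the specimen between frictionless impermeable rigid platens to
#' the given nominal axial strain, lets the pore pressure equilibrate through
#' the free-draining lateral surface, and evaluates the apparent (tissue
#' level) Poisson's ratio as minus the lateral-to-axial strain ratio from the
#' outer-edge radial displacement. Tensed fibrils restrain lateral expansion,
#' so the apparent ratio of cartilage is far below the Poisson's ratio of the
#' non-fibrillar matrix.
#'
#' @param params An [frpe_params()] object.
#' @param strain Nominal axial compressive strain, in (0, 0.3).
#' @param radius,thickness Specimen dimensions, mm.
#' @param config A [solver_config()].
#' @param t_end Simulated hold time, s; must be long enough that the maximum
#'   residual pore pressure falls below `p_tol` times its peak.
#' @param ramp_time Compression ramp duration, s.
#' @param p_tol Relative pore-pressure threshold defining equilibrium.
#' @return A list with `apparent_poisson`, `equilibrated`, `p_ratio` (residual
#'   over peak pressure), the force history tibble `curve`, and the axial and
#'   lateral strains.
#' @export
run_unconfined_compression <- function(params, strain = 0.10, radius = 1.5,
                                       thickness = 0.13,
                                       config = solver_config(),
                                       t_end = 2e4, ramp_time = NULL,
                                       p_tol = 1e-4) {
  if (strain <= 0 || strain >= 0.3)
    stop("strain must lie in (0, 0.3)", call. = FALSE)
  delta <- strain * thickness
  if (is.null(ramp_time)) ramp_time <- delta / 0.04
  mesh <- make_specimen_mesh(radius, thickness, config$nr, config$nz, "uniform")
  cfg <- config
  cfg$dt_max <- max(cfg$dt_max, t_end / 12)   # let steps grow to reach equilibrium
  times <- time_grid(ramp_time, t_end, cfg)
  sched <- rbind(c(0, 0), c(ramp_time, delta), c(t_end, delta))
  out <- run_fe(params, mesh, times, sched, "unconfined", cfg)
  peak_p <- max(out$max_abs_p)
  end_p <- out$max_abs_p[length(out$max_abs_p)]
  p_ratio <- if (peak_p > 0) end_p / peak_p else 0
  # lateral strain from outer-edge radial displacement
  U <- out$U
  outer <- mesh$sets$outer
  ur_outer <- U[dof_u_r(outer)]
  lateral <- mean(ur_outer) / radius
  axial <- -delta / thickness
  list(apparent_poisson = -lateral / axial,
       equilibrated = p_ratio < p_tol,
       p_ratio = p_ratio,
       axial_strain = axial, lateral_strain = lateral,
       curve = new_force_curve(out$time, out$force_top,
                               provenance = "simulated"),
       mesh = mesh, state = U)
}

#' Confined compression (1-D consolidation benchmark)
#'
#' Ramp-and-hold compression in a rigid impermeable confining ring with a
#' porous (free-draining) rigid top platen and impermeable base: fluid can
#' only escape upward, so the response is one-dimensional consolidation.
#' Returns the platen reaction force and the pore pressure at the sealed base
#' over time.
#'
#' @param params An [frpe_params()] object.
#' @param strain Nominal axial compressive strain (keep small, e.g. 1e-3, for
#'   comparison with the linear analytic series).
#' @param thickness Specimen height, mm.
#' @param radius Specimen radius, mm (results are radius-independent).
#' @param ramp_time Ramp duration, s.
#' @param t_end Total simulated time, s.
#' @param config A [solver_config()].
#' @return A tibble with `time_s`, `force_N`, `p_base_MPa`, plus the protocol
#'   constants as attributes.
#' @export
run_confined_compression <- function(params, strain = 1e-3, thickness = 1,
                                     radius = 0.3, ramp_time = NULL,
                                     t_end = NULL, config = solver_config()) {
  if (strain <= 0 || strain > 0.1)
    stop("strain must lie in (0, 0.1]", call. = FALSE)
  m <- derived_moduli(params$E_nf, params$nu_nf)
  HA <- m$K_nf + 4 / 3 * m$G_nf
  cv <- params$k_0 * HA
  tau <- thickness^2 / cv
  if (is.null(ramp_time)) ramp_time <- 0.02 * tau
  if (is.null(t_end)) t_end <- 1.5 * tau
  delta <- strain * thickness
  mesh <- make_specimen_mesh(radius, thickness, max(2, config$nr %/% 4),
                             config$nz, "uniform")
  cfg <- config
  cfg$dt_max <- max(cfg$dt_max, t_end / 15)
  times <- time_grid(ramp_time, t_end, cfg)
  sched <- rbind(c(0, 0), c(ramp_time, delta), c(t_end, delta))
  out <- run_fe(params, mesh, times, sched, "confined", cfg)
  res <- tibble::tibble(time_s = out$time, force_N = out$force_top,
                        p_base_MPa = out$p_base)
  attr(res, "HA") <- HA
  attr(res, "c_v") <- cv
  attr(res, "ramp_time") <- ramp_time
  attr(res, "delta") <- delta
  attr(res, "thickness") <- thickness
  attr(res, "area") <- pi * radius^2
  res
}

#' Analytic base pressure for ramp-driven 1-D consolidation
#'
#' Classical series solution of linear 1-D consolidation (confined
#' compression) driven by a displacement ramp of rate `V = delta / t0` applied
#' at the draining top surface, with a sealed base. The displacement field
#' obeys a diffusion equation with coefficient `c_v = k * H_A`; the base
#' (sealed-boundary) pore pressure follows from the strain series.
#'
#' @param t Times, s.
#' @param H Layer thickness, mm.
#' @param c_v Consolidation coefficient `k * H_A`, mm^2/s.
#' @param HA Aggregate (confined) modulus `K + 4G/3`, MPa.
#' @param delta Total ramp displacement, mm.
#' @param t0 Ramp duration, s.
#' @param n_terms Series terms.
#' @return Base pore pressure at each `t`, MPa (positive in compression).
#' @export
consolidation_base_pressure <- function(t, H, c_v, HA, delta, t0,
                                        n_terms = 200) {
  V <- delta / t0
  n <- seq_len(n_terms)
  omega <- c_v * (n * pi / H)^2
  bn <- 2 * (-1)^(n + 1) / (n * pi)
  sapply(t, function(ti) {
    wn <- if (ti <= t0) {
      V * bn / omega * (1 - exp(-omega * ti))
    } else {
      V * bn / omega * (1 - exp(-omega * t0)) * exp(-omega * (ti - t0))
    }
    # e(z) = -delta(t)/H + sum wn (n pi / H) cos(n pi z / H); base z = 0,
    # draining surface z = H; p(base) = HA * (e(0) - e(H))
    HA * sum(wn * (n * pi / H) * (1 - (-1)^n))
  })
}

#' Mesh-convergence study for the indentation protocol
#'
#' Re-runs the stress-relaxation simulation on successively refined meshes and
#' reports the peak and end-of-hold (equilibrium) reaction forces, their
#' relative change between levels, and which levels meet the 5%
#' peak-force-change convergence criterion.
#'
#' @param params An [frpe_params()] object.
#' @param protocol An [indentation_protocol()].
#' @param levels Integer refinement multipliers applied to `nr` and `nz`
#'   (e.g. `c(1, 2)` for the base mesh and a 2x-refined mesh).
#' @param config Base [solver_config()].
#' @return A tibble with one row per level: mesh size, peak/equilibrium force,
#'   relative difference to the previous level, and a `meets_5pct` flag.
#'   Levels whose simulation fails are kept with `NA` forces and flagged.
#' @export
mesh_convergence_study <- function(params, protocol = indentation_protocol(),
                                   levels = c(1, 2),
                                   config = solver_config()) {
  if (length(levels) < 2) stop("need at least two refinement levels", call. = FALSE)
  rows <- purrr::map(levels, function(lv) {
    cfg <- config
    cfg$nr <- config$nr * lv
    cfg$nz <- config$nz * lv
    res <- tryCatch(run_stress_relaxation(params, protocol, cfg),
                    error = function(e) NULL)
    if (is.null(res))
      return(tibble::tibble(level = lv, nr = cfg$nr, nz = cfg$nz,
                            n_elements = cfg$nr * cfg$nz,
                            peak_force = NA_real_, eq_force = NA_real_,
                            converged = FALSE))
    tibble::tibble(level = lv, nr = cfg$nr, nz = cfg$nz,
                   n_elements = cfg$nr * cfg$nz,
                   peak_force = max(res$force_N),
                   eq_force = res$force_N[nrow(res)],
                   converged = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  out$rel_diff_peak <- c(NA, abs(diff(out$peak_force)) / head(out$peak_force, -1))
  out$rel_diff_eq <- c(NA, abs(diff(out$eq_force)) / head(out$eq_force, -1))
  out$meets_5pct <- !is.na(out$rel_diff_peak) & out$rel_diff_peak < 0.05
  out
}
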