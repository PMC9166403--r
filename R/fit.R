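#' Normalized mean squared error between force curves
#'
#' The fitting objective: the simulated curve is linearly interpolated onto
#' the measured time grid and the mean squared force difference is normalized
#' by the mean squared measured force, making the objective scale-free.
#' Optionally normalize by the squared peak measured force instead
#' (`normalization = "peak"`).
#'
#' @param simulated,measured `force_curve` objects (or tibbles with `time_s`,
#'   `force_N`).
#' @param normalization `"mean"` (default) or `"peak"`.
#' @return Dimensionless NMSE, >= 0; 0 iff the curves agree on the measured
#'   grid.
#' @export
nmse <- function(simulated, measured, normalization = c("mean", "peak")) {
  normalization <- match.arg(normalization)
  f_sim <- approx(simulated$time_s, simulated$force_N,
                  xout = measured$time_s, rule = 2)$y
  denom <- switch(normalization,
                  mean = mean(measured$force_N^2),
                  peak = max(measured$force_N)^2)
  if (!is.finite(denom) || denom <= 0)
    stop("measured curve has no signal to normalize by", call. = FALSE)
  mean((f_sim - measured$force_N)^2) / denom
}

#' Coefficient of determination between force curves
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the residual sum of squares between
#' simulated and measured forces on the measured time grid, and the total sum
#' of squares about the measured mean.
#'
#' @inheritParams nmse
#' @return R-squared (<= 1; can be negative for a poor fit).
#' @export
r_squared <- function(simulated, measured) {
  f_sim <- approx(simulated$time_s, simulated$force_N,
                  xout = measured$time_s, rule = 2)$y
  ss_tot <- sum((measured$force_N - mean(measured$force_N))^2)
  if (ss_tot <= 0) stop("measured curve has zero variance", call. = FALSE)
  1 - sum((f_sim - measured$force_N)^2) / ss_tot
}

#' Configuration of the inverse parameter identification
#'
#' The four FRPE parameters `E_f`, `E_nf`, `k_0` and `M` are identified by
#' derivative-free simplex (Nelder-Mead) minimization of the [nmse()]
#' objective; `nu_nf` is held fixed (default 0.42) and `C` at its reference
#' value. `k_0` is optimized on a log10 scale (it spans decades); box bounds
#' are enforced by reflection. Several optimizations from Latin-hypercube
#' starting points are run, and the global minimum is accepted when all
#' successful starts agree within `agreement_tol` (relative, per parameter).
#'
#' @param lower,upper Named bounds for `E_f`, `E_nf` (MPa), `k_0`
#'   (mm^4 N^-1 s^-1) and `M`.
#' @param nu_nf Fixed Poisson's ratio of the non-fibrillar matrix.
#' @param n_starts Number of multi-start optimizations (>= 2).
#' @param seed Seed for the Latin-hypercube starting points.
#' @param maxit Maximum objective evaluations per Nelder-Mead run.
#' @param n_restarts Simplex restarts per start (restarting from the incumbent
#'   until no further improvement tightens convergence).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param polish Refine each simplex endpoint with damped Gauss-Newton
#'   (Levenberg-Marquardt) iterations on the force residuals (default TRUE).
#'   The simplex handles the global search; the least-squares polish descends
#'   the narrow curved valley of the objective (the fibril modulus and the
#'   permeability exponent are strongly correlated there) far faster than the
#'   simplex alone.
#' @param polish_maxit Maximum Levenberg-Marquardt iterations of the polish.
#' @param agreement_tol Relative tolerance for the multi-start global-minimum
#'   acceptance rule.
#' @param normalization NMSE normalization, see [nmse()].
#' @param config [solver_config()] used for the forward model during fitting
#'   (default the coarsened `"fit"` fidelity).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(E_f = 0.2, E_nf = 0.05, k_0 = 1e-4, M = 0.01),
                       upper = c(E_f = 15, E_nf = 3, k_0 = 5e-2, M = 5),
                       nu_nf = 0.42, n_starts = 5, seed = 1,
                       maxit = 150, n_restarts = 1, reltol = 1e-9,
                       polish = TRUE, polish_maxit = 25,
                       agreement_tol = 0.01,
                       normalization = "mean",
                       config = solver_config("fit")) {
  nm <- c("E_f", "E_nf", "k_0", "M")
  if (!all(nm %in% names(lower)) || !all(nm %in% names(upper)))
    stop("lower and upper must name E_f, E_nf, k_0, M", call. = FALSE)
  if (any(lower[nm] <= 0)) stop("bounds must be positive", call. = FALSE)
  if (any(upper[nm] <= lower[nm])) stop("upper must exceed lower", call. = FALSE)
  if (n_starts < 2) stop("need at least two starts for the global-minimum rule",
                         call. = FALSE)
  structure(list(lower = lower[nm], upper = upper[nm], nu_nf = nu_nf,
                 n_starts = n_starts, seed = seed, maxit = maxit,
                 n_restarts = n_restarts, reltol = reltol,
                 polish = polish, polish_maxit = polish_maxit,
                 agreement_tol = agreement_tol,
                 normalization = normalization, config = config),
            class = "fit_config")
}

# parameter transforms: k_0 on log10 scale (internal)
theta_from_params <- function(p) {
  c(p[["E_f"]], p[["E_nf"]], log10(p[["k_0"]]), p[["M"]])
}
params_from_theta <- function(theta) {
  c(E_f = theta[1], E_nf = theta[2], k_0 = 10^theta[3], M = theta[4])
}

# reflect transformed parameters into the transformed box (internal)
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Fit FRPE parameters to a measured force-relaxation curve
#'
#' Multi-start Nelder-Mead minimization of the normalized mean squared error
#' between the measured indentation force-relaxation curve and the
#' finite-element prediction, over (`E_f`, `E_nf`, `k_0`, `M`) with `nu_nf`
#' fixed. Forward-model failures at a trial point are penalized (not fatal).
#' The global minimum is accepted when all successful starts land on the same
#' parameters within the configured tolerance.
#'
#' @param measured A `force_curve` (e.g. from [read_force_curve()] or
#'   [generate_curve()]).
#' @param protocol The [indentation_protocol()] under which the measurement
#'   was taken (thickness, amplitude, timings).
#' @param config A [fit_config()].
#' @return An object of class `frpe_fit`: list with `params` (fitted
#'   [frpe_params()]), `estimate` (named vector), `nmse`, `r_squared`,
#'   `accepted`, per-start results `starts`, the fitted curve, and counters.
#' @export
fit_frpe <- function(measured, protocol = indentation_protocol(),
                     config = fit_config()) {
  stopifnot(nrow(measured) >= 2)
  lo_t <- theta_from_params(as.list(config$lower))
  hi_t <- theta_from_params(as.list(config$upper))
  n_fail <- 0L
  n_eval <- 0L
  forward <- function(est) {
    p <- frpe_params(E_f = est[["E_f"]], E_nf = est[["E_nf"]],
                     nu_nf = config$nu_nf, k_0 = est[["k_0"]], M = est[["M"]])
    run_stress_relaxation(p, protocol, config$config)
  }
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    theta <- reflect_into(theta, lo_t, hi_t)
    est <- params_from_theta(theta)
    sim <- tryCatch(forward(est), error = function(e) NULL)
    if (is.null(sim)) { n_fail <<- n_fail + 1L; return(1e6) }
    nmse(sim, measured, config$normalization)
  }
  # Latin-hypercube starts in the transformed box
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  lh <- lhs::randomLHS(config$n_starts, 4)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  starts <- t(apply(lh, 1, function(u) lo_t + u * (hi_t - lo_t)))

  # scaled force residual vector: sum of squares equals the NMSE
  denom <- switch(config$normalization, mean = mean(measured$force_N^2),
                  peak = max(measured$force_N)^2)
  n_meas <- nrow(measured)
  residual_vec <- function(theta) {
    n_eval <<- n_eval + 1L
    theta <- reflect_into(theta, lo_t, hi_t)
    est <- params_from_theta(theta)
    sim <- tryCatch(forward(est), error = function(e) NULL)
    if (is.null(sim)) { n_fail <<- n_fail + 1L; return(rep(1e3, n_meas)) }
    f_sim <- approx(sim$time_s, sim$force_N, xout = measured$time_s, rule = 2)$y
    (f_sim - measured$force_N) / sqrt(n_meas * denom)
  }
  run_start <- function(theta0) {
    opt <- optim(theta0, objective, method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = config$reltol))
    for (r in seq_len(config$n_restarts)) {
      prev <- opt$value
      opt2 <- optim(opt$par, objective, method = "Nelder-Mead",
                    control = list(maxit = config$maxit, reltol = config$reltol))
      if (opt2$value < opt$value) opt <- opt2
      if (prev - opt$value < 1e-12) break
    }
    if (config$polish) {
      lm <- tryCatch(
        suppressWarnings(
        minpack.lm::nls.lm(par = reflect_into(opt$par, lo_t, hi_t),
                           lower = lo_t, upper = hi_t, fn = residual_vec,
                           control = minpack.lm::nls.lm.control(
                             maxiter = config$polish_maxit, ptol = 1e-12,
                             ftol = 1e-14))),
        error = function(e) NULL)
      if (!is.null(lm)) {
        val <- sum(residuals(lm)^2)
        if (is.finite(val) && val < opt$value)
          opt <- list(par = lm$par, value = val)
      }
    }
    opt
  }
  results <- vector("list", config$n_starts)
  for (i in seq_len(config$n_starts)) {
    res <- tryCatch(run_start(starts[i, ]), error = function(e) NULL)
    results[[i]] <- res
  }
  ok <- !vapply(results, is.null, logical(1)) &
    vapply(results, function(r) is.finite(r$value) && r$value < 1e5, logical(1))
  if (!any(ok)) stop("all optimization starts failed", call. = FALSE)
  vals <- vapply(results, function(r) if (is.null(r)) Inf else r$value, numeric(1))
  ibest <- which.min(vals)
  theta_best <- reflect_into(results[[ibest]]$par, lo_t, hi_t)
  est <- params_from_theta(theta_best)

  start_tbl <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (is.null(r)) return(tibble::tibble(start = i, ok = FALSE))
    e <- params_from_theta(reflect_into(r$par, lo_t, hi_t))
    tibble::tibble(start = i, ok = ok[i], nmse = r$value,
                   E_f = e[["E_f"]], E_nf = e[["E_nf"]],
                   k_0 = e[["k_0"]], M = e[["M"]])
  }))
  # global-minimum acceptance: all successful starts agree within tolerance
  agree <- vapply(which(ok), function(i) {
    e <- unlist(start_tbl[start_tbl$start == i, c("E_f", "E_nf", "k_0", "M")])
    all(abs(e - est) / pmax(abs(est), 1e-12) <= config$agreement_tol)
  }, logical(1))
  accepted <- all(agree)

  fitted_params <- frpe_params(E_f = est[["E_f"]], E_nf = est[["E_nf"]],
                               nu_nf = config$nu_nf, k_0 = est[["k_0"]],
                               M = est[["M"]])
  fitted_curve <- forward(est)
  structure(list(params = fitted_params, estimate = est,
                 nmse = nmse(fitted_curve, measured, config$normalization),
                 r_squared = r_squared(fitted_curve, measured),
                 accepted = accepted, starts = start_tbl,
                 n_eval = n_eval, n_forward_failures = n_fail,
                 fitted_curve = fitted_curve, measured = measured,
                 protocol = protocol, config = config),
            class = "frpe_fit")
}

#' @export
print.frpe_fit <- function(x, ...) {
  cat("<frpe_fit>\n")
  cat(sprintf("  E_f = %.4g MPa, E_nf = %.4g MPa, k_0 = %.4g mm^4/(N s), M = %.4g\n",
              x$estimate[["E_f"]], x$estimate[["E_nf"]],
              x$estimate[["k_0"]], x$estimate[["M"]]))
  cat(sprintf("  NMSE = %.3g, R^2 = %.4f, global minimum %s (%d/%d starts agree)\n",
              x$nmse, x$r_squared,
              if (x$accepted) "accepted" else "NOT accepted",
              sum(x$starts$ok), nrow(x$starts)))
  invisible(x)
}

#' @rdname fit_frpe
#' @param x An `frpe_fit` object.
#' @param ... Unused.
#' @export
tidy.frpe_fit <- function(x, ...) {
  nm <- c("E_f", "E_nf", "k_0", "M")
  ok <- x$starts[x$starts$ok, , drop = FALSE]
  tibble::tibble(
    term = nm,
    estimate = unname(x$estimate[nm]),
    unit = c("MPa", "MPa", "mm^4/(N s)", "-"),
    start_sd = vapply(nm, function(n) stats::sd(ok[[n]]), numeric(1)))
}

#' @rdname fit_frpe
#' @export
glance.frpe_fit <- function(x, ...) {
  tibble::tibble(nmse = x$nmse, r_squared = x$r_squared,
                 accepted = x$accepted,
                 n_starts = nrow(x$starts), n_starts_ok = sum(x$starts$ok),
                 n_eval = x$n_eval,
                 n_forward_failures = x$n_forward_failures)
}

#' One-at-a-time parametric sweep of the FRPE parameters
#'
#' Varies each parameter over its grid while holding the others at the
#' reference values, re-running the indentation stress-relaxation simulation,
#' and reports the peak force, end-of-hold (equilibrium) force and the
#' time-to-50%-relaxation (time after the peak at which the force has decayed
#' halfway from peak to its end-of-hold value).
#'
#' @param base Reference [frpe_params()].
#' @param protocol An [indentation_protocol()].
#' @param grids Named list of parameter grids; default [table2_grids()]
#'   (`E_f`, `E_nf`, `k_0`, `nu_nf`).
#' @param config A [solver_config()].
#' @return A tibble with one row per run (the reference first): `param`,
#'   `value`, `is_reference`, `peak_force`, `eq_force`, `t50`, `converged`.
#' @export
sweep_parameters <- function(base = cartilage_params(),
                             protocol = indentation_protocol(),
                             grids = table2_grids(),
                             config = solver_config()) {
  if (length(grids) == 0) stop("empty sweep grids", call. = FALSE)
  run_one <- function(p) {
    res <- tryCatch(run_stress_relaxation(p, protocol, config),
                    error = function(e) NULL)
    if (is.null(res))
      return(list(peak = NA_real_, eq = NA_real_, t50 = NA_real_, ok = FALSE))
    ipk <- which.max(res$force_N)
    peak <- res$force_N[ipk]
    eq <- res$force_N[nrow(res)]
    half <- eq + 0.5 * (peak - eq)
    post <- res[ipk:nrow(res), ]
    # first crossing of the halfway level after the peak
    i2 <- which(post$force_N <= half)[1]
    t50 <- if (is.na(i2) || i2 == 1) NA_real_ else {
      f1 <- post$force_N[i2 - 1]; f2 <- post$force_N[i2]
      t1 <- post$time_s[i2 - 1]; t2 <- post$time_s[i2]
      t1 + (half - f1) / (f2 - f1) * (t2 - t1) - res$time_s[ipk]
    }
    list(peak = peak, eq = eq, t50 = t50, ok = TRUE)
  }
  ref <- run_one(base)
  rows <- list(tibble::tibble(param = "reference", value = NA_real_,
                              is_reference = TRUE, peak_force = ref$peak,
                              eq_force = ref$eq, t50 = ref$t50,
                              converged = ref$ok))
  for (nm in names(grids)) {
    for (v in grids[[nm]]) {
      if (isTRUE(all.equal(v, base[[nm]]))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          param = nm, value = v, is_reference = TRUE,
          peak_force = ref$peak, eq_force = ref$eq, t50 = ref$t50,
          converged = ref$ok)
        next
      }
      p <- base
      p[[nm]] <- v
      class(p) <- "frpe_params"
      r <- run_one(p)
      rows[[length(rows) + 1]] <- tibble::tibble(
        param = nm, value = v, is_reference = FALSE,
        peak_force = r$peak, eq_force = r$eq, t50 = r$t50, converged = r$ok)
    }
  }
  dplyr::bind_rows(rows)
}

#' Parametric-analysis grids
#'
#' The one-at-a-time variation grids of the parametric analysis:
#' `E_f` 1, 3.13, 5 MPa; `E_nf` 0.4, 0.83, 1.2 MPa; `k_0` 0.1, 3.3, 6.5 in
#' 1e-15 m^4 N^-1 s^-1 (converted to package units); `nu_nf` 0.15, 0.3, 0.42.
#' The bold reference values are those of [cartilage_params()].
#'
#' @return Named list of numeric grids.
#' @export
table2_grids <- function() {
  list(E_f = c(1, 3.13, 5),
       E_nf = c(0.4, 0.83, 1.2),
       k_0 = k0_from_si(c(0.1, 3.3, 6.5)),
       nu_nf = c(0.15, 0.3, 0.42))
}
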