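#' Generate a synthetic force-relaxation measurement
#'
#' Forward-simulates the indentation stress-relaxation protocol for known
#' ground-truth parameters, resamples the curve onto a compact acquisition
#' grid (10 Hz over the ramp, 30 log-spaced points per decade of relaxation)
#' and adds i.i.d. Gaussian measurement noise. The default noise standard
#' deviation, 3.5 mN, is the axial force resolution of the load cell used in
#' the physical indentation experiments this generator emulates.
#'
#' @param true_params Ground-truth [frpe_params()].
#' @param protocol An [indentation_protocol()].
#' @param noise_sd Gaussian noise standard deviation, N (>= 0).
#' @param seed Integer seed; the generator is deterministic given the seed
#'   (the caller's RNG state is left untouched).
#' @param config [solver_config()] for the forward simulation.
#' @return A `force_curve` with provenance `"synthetic"`, the truth stored in
#'   attribute `truth`, and the noise-free curve in attribute `clean`.
#' @export
generate_curve <- function(true_params, protocol = indentation_protocol(),
                           noise_sd = 3.5e-3, seed = NULL,
                           config = solver_config("fit")) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  sim <- run_stress_relaxation(true_params, protocol, config)
  clean <- resample_force_curve(sim)
  noise <- if (noise_sd == 0) {
    rep(0, nrow(clean))
  } else {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    if (!is.null(seed)) set.seed(seed)
    eps <- rnorm(nrow(clean), 0, noise_sd)
    if (!is.null(seed) && !is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv())
    eps
  }
  out <- new_force_curve(clean$time_s, clean$force_N + noise,
                         provenance = "synthetic",
                         protocol = protocol, truth = true_params,
                         clean = clean, noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n` samples (default 6, the cohort size of the indentation study the
#' generator emulates) with per-sample FRPE parameters from independent
#' truncated normal distributions centred on the reference fitted means with
#' the reported between-animal standard deviations
#' (`E_f` 3.13 +/- 2.56 MPa, `E_nf` 0.83 +/- 0.21 MPa,
#' `k_0` 3.30 +/- 3.00 e-15 m^4 N^-1 s^-1, `M` 1.67 +/- 0.62), per-sample
#' cartilage thickness around 0.13 mm, and simulates a noisy force curve for
#' each sample.
#'
#' Truncation keeps every draw inside the identification bounds of
#' [fit_config()], so all generated samples satisfy the parameter invariants
#' and are recoverable in principle.
#'
#' @param n Number of samples (>= 1).
#' @param seed Integer seed (fully determines the cohort).
#' @param means,sds Named means / SDs for `E_f`, `E_nf`, `k_0`, `M` (package
#'   units). Zero SD gives exactly the mean.
#' @param thickness_mean,thickness_sd Thickness distribution, mm (truncated to
#'   `[0.11, 0.18]`).
#' @param noise_sd Force noise SD, N.
#' @param protocol Protocol template; the per-sample thickness replaces
#'   `sample_thickness`.
#' @param config [solver_config()] for the forward simulations.
#' @return A tibble of class `synthetic_sample_set`: one row per sample with
#'   the true parameters, thickness, per-sample seed and the generated curve
#'   in the list-column `curve`.
#' @export
generate_sample_set <- function(n = 6, seed = 1,
                                means = c(E_f = 3.13, E_nf = 0.83,
                                          k_0 = 3.3e-3, M = 1.67),
                                sds = c(E_f = 2.56, E_nf = 0.21,
                                        k_0 = 3.0e-3, M = 0.62),
                                thickness_mean = 0.13, thickness_sd = 0.015,
                                noise_sd = 3.5e-3,
                                protocol = indentation_protocol(),
                                config = solver_config("fit")) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  nm <- c("E_f", "E_nf", "k_0", "M")
  if (!all(nm %in% names(means)) || !all(nm %in% names(sds)))
    stop("means and sds must name E_f, E_nf, k_0, M", call. = FALSE)
  if (any(sds < 0) || thickness_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  fb <- fit_config()
  lo <- fb$lower; hi <- fb$upper
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  draw_trunc <- function(mean, sd, lo, hi) {
    if (sd == 0) {
      if (mean < lo || mean > hi) stop("degenerate distribution outside bounds",
                                       call. = FALSE)
      return(mean)
    }
    for (i in 1:10000) {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) return(x)
    }
    stop("truncated-normal rejection sampling failed (degenerate distribution)",
         call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- vapply(nm, function(k) draw_trunc(means[[k]], sds[[k]], lo[[k]], hi[[k]]),
                numeric(1))
    th <- draw_trunc(thickness_mean, thickness_sd, 0.11, 0.18)
    sample_seed <- sample.int(.Machine$integer.max %/% 2, 1)
    rows[[i]] <- tibble::tibble(sample = i, thickness = th,
                                E_f = p[["E_f"]], E_nf = p[["E_nf"]],
                                k_0 = p[["k_0"]], M = p[["M"]],
                                seed = sample_seed)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  out <- dplyr::bind_rows(rows)
  out$curve <- purrr::pmap(out, function(sample, thickness, E_f, E_nf, k_0, M, seed, ...) {
    prot <- protocol
    prot$sample_thickness <- thickness
    truth <- frpe_params(E_f = E_f, E_nf = E_nf, nu_nf = 0.42, k_0 = k_0, M = M)
    generate_curve(truth, prot, noise_sd = noise_sd, seed = seed,
                   config = config)
  })
  attr(out, "seed") <- seed
  attr(out, "noise_sd") <- noise_sd
  attr(out, "protocol") <- protocol
  attr(out, "solver_config") <- config
  class(out) <- c("synthetic_sample_set", class(out))
  out
}

#' End-to-end parameter-recovery study
#'
#' Fits every sample of a synthetic cohort with [fit_frpe()] and reports, per
#' sample, the fitted parameters, their relative errors against the known
#' truth, the fit quality (NMSE, R-squared) and the multi-start acceptance
#' flag. Per-sample fit failures are flagged and the study continues.
#'
#' @param sample_set A [generate_sample_set()] cohort.
#' @param config A [fit_config()].
#' @return A tibble with one row per sample: truth (`*_true`), estimates
#'   (`*_fit`), relative errors (`*_relerr`), `r_squared`, `nmse`, `accepted`,
#'   `ok`.
#' @export
recovery_study <- function(sample_set, config = fit_config()) {
  protocol <- attr(sample_set, "protocol") %||% indentation_protocol()
  nm <- c("E_f", "E_nf", "k_0", "M")
  rows <- purrr::map(seq_len(nrow(sample_set)), function(i) {
    row <- sample_set[i, ]
    prot <- protocol
    prot$sample_thickness <- row$thickness
    fit <- tryCatch(fit_frpe(row$curve[[1]], prot, config),
                    error = function(e) NULL)
    base <- tibble::tibble(sample = row$sample, thickness = row$thickness)
    for (k in nm) base[[paste0(k, "_true")]] <- row[[k]]
    if (is.null(fit)) {
      for (k in nm) {
        base[[paste0(k, "_fit")]] <- NA_real_
        base[[paste0(k, "_relerr")]] <- NA_real_
      }
      base$r_squared <- NA_real_; base$nmse <- NA_real_
      base$accepted <- NA; base$ok <- FALSE
      return(base)
    }
    for (k in nm) {
      base[[paste0(k, "_fit")]] <- fit$estimate[[k]]
      base[[paste0(k, "_relerr")]] <- abs(fit$estimate[[k]] - row[[k]]) / row[[k]]
    }
    base$r_squared <- fit$r_squared
    base$nmse <- fit$nmse
    base$accepted <- fit$accepted
    base$ok <- TRUE
    base
  })
  dplyr::bind_rows(rows)
}
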