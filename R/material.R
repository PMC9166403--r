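#' Depth-dependent collagen fibril architecture
#'
#' Builds the set of reference-configuration fibril direction unit vectors at a
#' normalized depth `h`. Primary fibrils form the classical arcade: parallel to
#' the articular surface in the superficial zone, rotating continuously across
#' the middle zone, and parallel to the surface normal in the deep zone.
#' Secondary fibrils are a fixed quasi-uniform set of 13 directions (3
#' coordinate axes, 6 face diagonals, 4 body diagonals of the unit cube),
#' identical at all depths.
#'
#' Directions are expressed in local `(r, z, theta)` components with `z` the
#' surface normal. The set is symmetric under reflections in `r` and `theta`,
#' as required for use in an axisymmetric model.
#'
#' @param h Normalized depth in `[0, 1]` (0 = surface, 1 = bottom).
#' @param config Architecture configuration from [architecture_config()].
#' @return A list of class `fibril_architecture` with matrices `primary`
#'   (`n_primary` x 3) and `secondary` (`n_secondary` x 3) of unit row vectors,
#'   and the depth `h`.
#' @export
#' @examples
#' arch <- build_cartilage_architecture(0)    # surface: all primary in-plane
#' arch$primary
build_cartilage_architecture <- function(h, config = architecture_config()) {
  if (!is.finite(h) || h < 0 || h > 1) stop("h must lie in [0, 1]", call. = FALSE)
  z1 <- config$zone_superficial
  z2 <- config$zone_middle
  # arcade angle from the surface plane: 0 in the superficial zone, pi/2 deep
  alpha <- if (h <= z1) 0
           else if (h >= z2) pi / 2
           else (h - z1) / (z2 - z1) * pi / 2
  ca <- cos(alpha); sa <- sin(alpha)
  primary <- rbind(c( ca, sa, 0),
                   c(-ca, sa, 0),
                   c(0, sa,  ca),
                   c(0, sa, -ca))
  if (config$n_primary != 4)
    primary <- primary[rep_len(seq_len(4), config$n_primary), , drop = FALSE]
  primary <- primary / sqrt(rowSums(primary^2))
  structure(list(primary = primary,
                 secondary = secondary_directions(config$n_secondary),
                 h = h),
            class = "fibril_architecture")
}

#' @rdname build_cartilage_architecture
#' @param zone_superficial,zone_middle Depth fractions bounding the superficial
#'   (surface-parallel) and middle (rotating) zones; defaults 0.10 and 0.40.
#' @param n_primary Number of primary fibril directions (default 4).
#' @param n_secondary Number of secondary fibril directions (default 13).
#' @export
architecture_config <- function(zone_superficial = 0.10, zone_middle = 0.40,
                                n_primary = 4, n_secondary = 13) {
  if (!(zone_superficial >= 0 && zone_superficial < zone_middle && zone_middle <= 1))
    stop("zone boundaries must satisfy 0 <= superficial < middle <= 1",
         call. = FALSE)
  if (n_primary < 1 || n_secondary < 1)
    stop("fibril counts must be >= 1", call. = FALSE)
  list(zone_superficial = zone_superficial, zone_middle = zone_middle,
       n_primary = n_primary, n_secondary = n_secondary)
}

#' @rdname build_cartilage_architecture
#' @param n Number of secondary directions (only the default 13-direction cube
#'   set is predefined; other counts take the first `n` of that set recycled).
#' @export
secondary_directions <- function(n = 13) {
  s2 <- 1 / sqrt(2); s3 <- 1 / sqrt(3)
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(s2, s2, 0), c(s2, -s2, 0), c(s2, 0, s2), c(s2, 0, -s2),
    c(0, s2, s2), c(0, s2, -s2),
    c(s3, s3, s3), c(s3, s3, -s3), c(s3, -s3, s3), c(s3, -s3, -s3))
  dirs[rep_len(seq_len(13), n), , drop = FALSE]
}

# stack primary+secondary dirs and their density weights (internal)
arch_dirs_weights <- function(arch, params, h = arch$h) {
  rz <- rho_z_at(params, h)
  dirs <- rbind(arch$primary, arch$secondary)
  w <- c(rep(rz * params$C, nrow(arch$primary)),
         rep(rz, nrow(arch$secondary)))
  list(dirs = dirs, w = w)
}

check_F <- function(F) {
  if (!is.matrix(F) || any(dim(F) != c(3, 3)) || any(!is.finite(F)))
    stop("F must be a finite 3x3 matrix", call. = FALSE)
  J <- det(F)
  if (J <= 0) stop("inverted state: det(F) must be > 0", call. = FALSE)
  J
}

#' Neo-Hookean stress of the non-fibrillar matrix
#'
#' Cauchy stress of the hyperelastic non-fibrillar (proteoglycan) matrix:
#' `sigma_nf = 1/2 K_nf (J - 1/J) I + (G_nf / J) (F F' - J^(2/3) I)`.
#' Zero at the undeformed state.
#'
#' @param F Deformation gradient, 3x3 matrix with `det(F) > 0`.
#' @param moduli A list with `K_nf` and `G_nf` (MPa), e.g. from
#'   [derived_moduli()].
#' @return Symmetric 3x3 Cauchy stress tensor, MPa.
#' @export
#' @examples
#' m <- derived_moduli(0.83, 0.42)
#' nonfibrillar_stress(diag(3), m)            # zero
#' nonfibrillar_stress(diag(c(1.05, 1, 1)), m)
nonfibrillar_stress <- function(F, moduli) {
  check_F(F)
  out <- cpp_point_stress(F, 0, moduli$K_nf, moduli$G_nf, 0,
                          matrix(numeric(0), 0, 3), numeric(0))
  out$sigma_nf
}

#' Nominal fibril strain along a convected direction
#'
#' The strain of a fibril with reference unit direction `e0` under deformation
#' gradient `F`, measured as the nominal stretch change `|F e0| - 1`.
#'
#' @param F Deformation gradient, 3x3.
#' @param e0 Reference fibril direction (unit 3-vector).
#' @return Nominal strain, dimensionless (positive in tension).
#' @export
#' @examples
#' fibril_strain(diag(c(1.1, 1, 1)), c(1, 0, 0))  # 0.1
fibril_strain <- function(F, e0) {
  check_F(F)
  if (abs(sqrt(sum(e0^2)) - 1) > 1e-8)
    stop("e0 must be a unit vector", call. = FALSE)
  sqrt(sum((F %*% e0)^2)) - 1
}

#' Tension-only fibril network stress
#'
#' Sums the Cauchy-stress contributions of all fibrils at a material point.
#' Each fibril carries the linear tension-only stress
#' `sigma_f = E_f * eps_f` for `eps_f > 0` (zero otherwise), scaled by
#' `rho_z * C` for primary and `rho_z` for secondary fibrils, and contributes
#' along its deformed unit direction via the outer product.
#'
#' @param F Deformation gradient, 3x3.
#' @param arch A `fibril_architecture` from [build_cartilage_architecture()].
#' @param params An [frpe_params()] object.
#' @return Symmetric positive-semidefinite 3x3 Cauchy stress tensor, MPa.
#' @export
fibril_network_stress <- function(F, arch, params) {
  check_F(F)
  dw <- arch_dirs_weights(arch, params)
  out <- cpp_point_stress(F, 0, 1, 0, params$E_f, dw$dirs, dw$w)
  out$sigma_f
}

#' Total stress at a material point
#'
#' The total Cauchy stress of the saturated mixture,
#' `sigma_tot = sigma_f + sigma_nf - p I`: fibril network plus non-fibrillar
#' effective stress minus the pore-pressure contribution.
#'
#' @inheritParams fibril_network_stress
#' @param p Pore (hydrostatic fluid) pressure, MPa.
#' @return A list of class `stress_state` with `sigma_tot`, `sigma_nf`,
#'   `sigma_f` (the network tensor), `p`, `J`, and `fibrils`: a tibble with
#'   one row per fibril (type, reference direction, strain `eps_f`, bare
#'   tension-only stress `sigma_f` and its density-scaled value).
#' @export
total_stress <- function(F, p, arch, params) {
  check_F(F)
  m <- derived_moduli(params$E_nf, params$nu_nf)
  dw <- arch_dirs_weights(arch, params)
  out <- cpp_point_stress(F, p, m$K_nf, m$G_nf, params$E_f, dw$dirs, dw$w)
  eps <- apply(dw$dirs, 1, function(e0) fibril_strain(F, e0))
  sig <- params$E_f * pmax(eps, 0)
  fibrils <- tibble::tibble(
    fibril = seq_along(eps),
    type = rep(c("primary", "secondary"),
               c(nrow(arch$primary), nrow(arch$secondary))),
    eps_f = eps,
    sigma_f = sig,
    sigma_scaled = dw$w * sig)
  structure(list(sigma_tot = out$sigma_tot, sigma_nf = out$sigma_nf,
                 sigma_f = out$sigma_f, p = p, J = out$J, fibrils = fibrils),
            class = "stress_state")
}

#' @export
print.stress_state <- function(x, ...) {
  cat("<stress_state>  J =", format(x$J), " p =", format(x$p), "MPa\n")
  cat("sigma_tot (MPa):\n")
  print(signif(x$sigma_tot, 5))
  invisible(x)
}
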