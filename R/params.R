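#' FRPE material parameter set
#'
#' Container for the fibril-reinforced poroelastic material parameters: the
#' tension-only collagen fibril network modulus, the neo-Hookean non-fibrillar
#' (proteoglycan) matrix, the strain-dependent hydraulic permeability, the
#' primary-to-secondary fibril density ratio, and the depth profiles of the
#' relative collagen density and the fluid volume fraction.
#'
#' @param E_f Fibril network modulus, MPa. Must be >= 0 (0 disables fibrils).
#' @param E_nf Young's modulus of the non-fibrillar matrix, MPa (> 0).
#' @param nu_nf Poisson's ratio of the non-fibrillar matrix, in `[0, 0.5)`.
#' @param k_0 Initial hydraulic permeability, mm^4 N^-1 s^-1 (> 0).
#'   Note the unit: a literature value of `x` in 1e-15 m^4 N^-1 s^-1 is
#'   `x * 1e-3` here (see [k0_from_si()]).
#' @param M Exponent of the strain-dependent permeability `k = k_0 * J^M`
#'   (>= 0; 0 gives strain-independent permeability).
#' @param C Density ratio of primary to secondary collagen fibrils (> 0).
#' @param rho_z Relative collagen density: a single number or a function of
#'   normalized depth `h` in `[0, 1]` (surface = 0, bottom = 1). Default 1.
#' @param n_fl_surface,n_fl_slope Fluid volume fraction profile
#'   `n_fl(h) = n_fl_surface - n_fl_slope * h`; both dimensionless, and the
#'   profile must stay inside (0, 1) on `[0, 1]`.
#'
#' @return An object of class `frpe_params` (a named list).
#' @seealso [cartilage_params()], [meniscus_params()], [fluid_fraction_profile()]
#' @export
#' @examples
#' p <- frpe_params(E_f = 3.13, E_nf = 0.83, nu_nf = 0.42,
#'                  k_0 = 3.3e-3, M = 1.67, C = 12.16)
#' p$E_f
frpe_params <- function(E_f = 3.13, E_nf = 0.83, nu_nf = 0.42,
                        k_0 = 3.3e-3, M = 1.67, C = 12.16,
                        rho_z = 1, n_fl_surface = 0.8, n_fl_slope = 0.15) {
  stopifnot(is.numeric(E_f), length(E_f) == 1, is.finite(E_f))
  if (E_f < 0) stop("E_f must be >= 0", call. = FALSE)
  if (!is.finite(E_nf) || E_nf <= 0) stop("E_nf must be > 0", call. = FALSE)
  if (!is.finite(nu_nf) || nu_nf < 0 || nu_nf >= 0.5)
    stop("nu_nf must lie in [0, 0.5)", call. = FALSE)
  if (!is.finite(k_0) || k_0 <= 0) stop("k_0 must be > 0", call. = FALSE)
  if (!is.finite(M) || M < 0) stop("M must be >= 0", call. = FALSE)
  if (!is.finite(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  if (!is.function(rho_z) && (!is.numeric(rho_z) || rho_z < 0))
    stop("rho_z must be a non-negative number or a function of depth",
         call. = FALSE)
  nfl_ends <- n_fl_surface - n_fl_slope * c(0, 1)
  if (any(nfl_ends <= 0) || any(nfl_ends >= 1))
    stop("fluid fraction profile must stay inside (0, 1) over depth",
         call. = FALSE)
  structure(
    list(E_f = E_f, E_nf = E_nf, nu_nf = nu_nf, k_0 = k_0, M = M, C = C,
         rho_z = rho_z, n_fl_surface = n_fl_surface, n_fl_slope = n_fl_slope),
    class = "frpe_params")
}

#' @export
print.frpe_params <- function(x, ...) {
  cat("<frpe_params>\n")
  cat(sprintf("  E_f   = %g MPa   (fibril network modulus)\n", x$E_f))
  cat(sprintf("  E_nf  = %g MPa   (non-fibrillar matrix modulus)\n", x$E_nf))
  cat(sprintf("  nu_nf = %g       (matrix Poisson ratio)\n", x$nu_nf))
  cat(sprintf("  k_0   = %g mm^4/(N s), M = %g (k = k_0 J^M)\n", x$k_0, x$M))
  cat(sprintf("  C     = %g       (primary:secondary fibril density)\n", x$C))
  rz <- if (is.function(x$rho_z)) "profile(h)" else format(x$rho_z)
  cat(sprintf("  rho_z = %s, n_fl(h) = %g - %g h\n",
              rz, x$n_fl_surface, x$n_fl_slope))
  invisible(x)
}

#' Reference cartilage and meniscus parameter sets
#'
#' `cartilage_params()` returns the mean fibril-reinforced poroelastic
#' parameters identified for healthy rat tibial cartilage
#' (E_f = 3.13 MPa, E_nf = 0.83 MPa, nu_nf = 0.42,
#' k_0 = 3.30e-15 m^4 N^-1 s^-1, M = 1.67, C = 12.16,
#' n_fl = 0.8 - 0.15 h). `meniscus_params()` returns the meniscus set, with
#' the fibril network modulus derived from the circumferential Young's modulus
#' via [meniscus_fibril_modulus()] and a homogeneous fluid fraction of 0.72.
#'
#' @param ... Overrides passed on to [frpe_params()].
#' @return An `frpe_params` object.
#' @export
cartilage_params <- function(...) {
  args <- list(...)
  do.call(frpe_params, modifyList(list(), args))
}

#' @rdname cartilage_params
#' @param E_theta Circumferential Young's modulus of the meniscus, MPa.
#' @param n_fp Number of primary fibrils.
#' @export
meniscus_params <- function(E_theta = 184, n_fp = 4, ...) {
  base <- list(E_f = meniscus_fibril_modulus(E_theta, 12.16, n_fp),
               E_nf = 0.08, nu_nf = 0.3, k_0 = 0.08e-3, M = 12.1, C = 12.16,
               n_fl_surface = 0.72, n_fl_slope = 0)
  p <- do.call(frpe_params, modifyList(base, list(...)))
  p$E_theta <- E_theta
  p
}

#' Convert permeability from SI to package units
#'
#' Literature permeabilities are commonly given in 1e-15 m^4 N^-1 s^-1; the
#' package works in mm^4 N^-1 s^-1 (1 m^4 = 1e12 mm^4, so
#' 1e-15 m^4 N^-1 s^-1 = 1e-3 mm^4 N^-1 s^-1).
#'
#' @param x Permeability in units of 1e-15 m^4 N^-1 s^-1.
#' @return Permeability in mm^4 N^-1 s^-1.
#' @export
#' @examples
#' k0_from_si(3.30)  # 3.3e-3 mm^4/(N s)
k0_from_si <- function(x) x * 1e-3

#' Bulk and shear moduli of the non-fibrillar matrix
#'
#' Converts the Young's modulus and Poisson's ratio of the isotropic
#' non-fibrillar matrix to its bulk and shear moduli:
#' `K_nf = E_nf / (3 (1 - 2 nu_nf))`, `G_nf = E_nf / (2 (1 + nu_nf))`.
#'
#' @param E_nf Young's modulus, MPa (> 0).
#' @param nu_nf Poisson's ratio, in `[0, 0.5)`.
#' @return A named list with `K_nf` and `G_nf` (MPa).
#' @export
#' @examples
#' derived_moduli(0.83, 0.42)
derived_moduli <- function(E_nf, nu_nf) {
  if (!is.finite(E_nf) || E_nf <= 0) stop("E_nf must be > 0", call. = FALSE)
  if (!is.finite(nu_nf) || nu_nf < 0)
    stop("nu_nf must be non-negative", call. = FALSE)
  if (nu_nf >= 0.5)
    stop("nu_nf >= 0.5: incompressible limit, bulk modulus undefined",
         call. = FALSE)
  list(K_nf = E_nf / (3 * (1 - 2 * nu_nf)),
       G_nf = E_nf / (2 * (1 + nu_nf)))
}

#' Depth-wise fluid volume fraction
#'
#' Linear fluid-fraction profile `n_fl(h) = surface - slope * h` over the
#' normalized depth `h` (0 = articular surface, 1 = bone interface). The
#' default profile, 0.8 - 0.15 h, runs from 0.8 at the surface to 0.65 at the
#' bottom.
#'
#' @param h Normalized depth(s) in `[0, 1]`.
#' @param surface,slope Profile coefficients.
#' @return Fluid volume fraction(s), dimensionless.
#' @export
#' @examples
#' fluid_fraction_profile(c(0, 0.5, 1))
fluid_fraction_profile <- function(h, surface = 0.8, slope = 0.15) {
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1))
    stop("depth h must lie in [0, 1]", call. = FALSE)
  surface - slope * h
}

#' Void ratio from the fluid volume fraction
#'
#' The void ratio is the fluid-to-solid volume fraction ratio
#' `e = n_fl / (1 - n_fl)` of the saturated mixture.
#'
#' @param n_fl Fluid volume fraction(s) in (0, 1).
#' @return Void ratio(s), dimensionless.
#' @export
#' @examples
#' void_ratio(0.8)   # 4
#' void_ratio(0.72)  # ~2.571
void_ratio <- function(n_fl) {
  if (any(!is.finite(n_fl)) || any(n_fl <= 0) || any(n_fl >= 1))
    stop("n_fl must lie strictly inside (0, 1)", call. = FALSE)
  n_fl / (1 - n_fl)
}

#' Strain-dependent hydraulic permeability
#'
#' `k = k_0 * ((e + 1) / (1 + e_0))^M`, where the void-ratio factor equals the
#' volume ratio `J` of the deformation under affine pore-volume kinematics, so
#' the law is evaluated directly as `k = k_0 * J^M`.
#'
#' @param J Determinant of the deformation gradient (> 0).
#' @param k_0 Initial permeability, mm^4 N^-1 s^-1.
#' @param M Permeability exponent (>= 0).
#' @param e_0 Initial void ratio (optional, documentation of the underlying
#'   void-ratio form; not needed for the evaluation).
#' @return Current permeability, mm^4 N^-1 s^-1.
#' @export
#' @examples
#' permeability(1, 3.3e-3, 1.67)    # k_0 at the reference state
#' permeability(0.8, 3.3e-3, 1.67)
permeability <- function(J, k_0, M, e_0 = NULL) {
  if (any(!is.finite(J)) || any(J <= 0))
    stop("J must be > 0 (volume ratio)", call. = FALSE)
  k_0 * J^M
}

#' Meniscus fibril network modulus from the circumferential modulus
#'
#' The fibril network modulus assigned to meniscus tissue is derived from its
#' circumferential Young's modulus: `E_f = E_theta / (C * n_fp)`, spreading
#' the circumferential stiffness over the `n_fp` primary fibril directions
#' weighted by the primary-to-secondary density ratio `C`.
#'
#' @param E_theta Circumferential Young's modulus, MPa.
#' @param C Primary-to-secondary fibril density ratio.
#' @param n_fp Number of primary fibrils.
#' @return Fibril network modulus, MPa.
#' @export
#' @examples
#' meniscus_fibril_modulus(184, 12.16, 4)  # 3.79 MPa (2 dp)
meniscus_fibril_modulus <- function(E_theta, C, n_fp) {
  if (any(!is.finite(c(E_theta, C, n_fp))) || E_theta <= 0 || C <= 0 || n_fp <= 0)
    stop("all inputs must be positive", call. = FALSE)
  E_theta / (C * n_fp)
}

# evaluate rho_z at depth h (internal)
rho_z_at <- function(params, h) {
  if (is.function(params$rho_z)) params$rho_z(h) else rep(params$rho_z, length(h))
}
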