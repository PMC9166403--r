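#' Structured axisymmetric specimen mesh
#'
#' Builds a structured quadrilateral mesh of a cylindrical cartilage specimen
#' in the (r, z) half-plane: `nr` x `nz` four-node elements of the
#' displacement/pore-pressure class, with node sets for the fixed impermeable
#' base (z = 0), the symmetry axis (r = 0), the free-draining outer wall
#' (r = radius) and the articular surface (z = thickness).
#'
#' With `grading = "contact"` the radial node spacing is refined towards the
#' axis (where the indenter contacts) and, vertically, towards the surface;
#' `"uniform"` gives equal spacing.
#'
#' @param radius Specimen radius, mm.
#' @param thickness Specimen (cartilage) thickness, mm.
#' @param nr,nz Number of elements radially and through the thickness (>= 2).
#' @param grading `"contact"` (default) or `"uniform"`.
#' @param r_fine Radius of the refined contact zone, mm (contact grading only).
#' @return An object of class `frpe_mesh`: list with `nodes` (tibble of
#'   `node`, `r`, `z`), `elements` (integer matrix, counter-clockwise), node
#'   `sets`, per-element normalized depth `elem_h`, and the build parameters.
#' @export
#' @examples
#' m <- make_specimen_mesh(1.5, 0.13, 4, 3)
#' nrow(m$nodes)          # (4+1)*(3+1) = 20
#' nrow(m$elements)       # 12
make_specimen_mesh <- function(radius, thickness, nr, nz,
                               grading = c("contact", "uniform"),
                               r_fine = NULL) {
  grading <- match.arg(grading)
  if (!all(is.finite(c(radius, thickness))) || radius <= 0 || thickness <= 0)
    stop("radius and thickness must be positive", call. = FALSE)
  if (nr < 2 || nz < 2) stop("nr and nz must be >= 2", call. = FALSE)

  if (grading == "uniform") {
    rc <- seq(0, radius, length.out = nr + 1)
    zc <- seq(0, thickness, length.out = nz + 1)
  } else {
    if (is.null(r_fine)) r_fine <- min(radius / 3, 0.30)
    n_in <- max(2, ceiling(0.6 * nr))
    n_out <- nr - n_in
    if (n_out < 1) { n_in <- nr - 1; n_out <- 1 }
    rin <- seq(0, r_fine, length.out = n_in + 1)
    # geometric spacing outward
    g <- seq(0, 1, length.out = n_out + 1)[-1]
    rout <- r_fine + (radius - r_fine) * (exp(2 * g) - 1) / (exp(2) - 1)
    rc <- c(rin, rout)
    # mild vertical refinement towards the surface
    gz <- seq(0, 1, length.out = nz + 1)
    zc <- thickness * (1 - (exp(1.0 * (1 - gz)) - 1) / (exp(1.0) - 1))
    zc <- sort(zc)
    zc[1] <- 0; zc[nz + 1] <- thickness
  }

  nnr <- nr + 1; nnz <- nz + 1
  nodes <- tibble::tibble(
    node = seq_len(nnr * nnz),
    r = rep(rc, times = nnz),
    z = rep(zc, each = nnr))
  nid <- function(i, j) (j - 1) * nnr + i   # i radial, j vertical (1-based)
  elements <- matrix(0L, nrow = nr * nz, ncol = 4)
  elem_h <- numeric(nr * nz)
  e <- 0L
  for (j in seq_len(nz)) {
    for (i in seq_len(nr)) {
      e <- e + 1L
      elements[e, ] <- as.integer(c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1)))
      zc_mid <- (zc[j] + zc[j + 1]) / 2
      elem_h[e] <- (thickness - zc_mid) / thickness
    }
  }
  sets <- list(
    base = which(nodes$z <= 0 + 1e-12),
    axis = which(nodes$r <= 0 + 1e-12),
    outer = which(abs(nodes$r - radius) <= 1e-12),
    surface = which(abs(nodes$z - thickness) <= 1e-12))
  structure(list(nodes = nodes, elements = elements, sets = sets,
                 elem_h = elem_h, radius = radius, thickness = thickness,
                 nr = nr, nz = nz, grading = grading),
            class = "frpe_mesh")
}

#' @export
print.frpe_mesh <- function(x, ...) {
  cat(sprintf("<frpe_mesh> %d x %d = %d elements, %d nodes, radius %g mm, thickness %g mm (%s grading)\n",
              x$nr, x$nz, nrow(x$elements), nrow(x$nodes), x$radius,
              x$thickness, x$grading))
  invisible(x)
}

#' Total meshed area in the (r, z) plane
#'
#' Sum of element areas (shoelace formula); equals `radius * thickness` for a
#' valid mesh of the rectangular section.
#'
#' @param mesh An `frpe_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  r <- mesh$nodes$r; z <- mesh$nodes$z
  a <- 0
  for (e in seq_len(nrow(mesh$elements))) {
    id <- mesh$elements[e, ]
    x <- r[id]; y <- z[id]
    a <- a + 0.5 * abs(sum(x * y[c(2, 3, 4, 1)] - x[c(2, 3, 4, 1)] * y))
  }
  a
}
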