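#' Read and write force-relaxation curves as CSV
#'
#' The on-disk format is a two-column CSV with header exactly
#' `time_s,force_N`, one row per sample, written at full double precision so a
#' write-read round trip is lossless. Reading enforces strictly increasing
#' time and finite values, reporting the first offending line.
#'
#' @param path File path.
#' @param curve A `force_curve` (or tibble with `time_s`, `force_N`).
#' @param metadata Optionally write a JSON sidecar (`<path>.json`) with
#'   provenance and protocol.
#' @return `read_force_curve()` returns a `force_curve` tibble;
#'   `write_force_curve()` returns `path` invisibly.
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty force-curve file: ", path, call. = FALSE)
  if (trimws(lines[1]) != "time_s,force_N")
    stop("line 1: expected header 'time_s,force_N'", call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2)
    stop("force curve needs at least 2 samples", call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    stop(sprintf("line %d: expected 2 comma-separated values", bad[1] + 1),
         call. = FALSE)
  tt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  ff <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  bad <- which(!is.finite(tt) | !is.finite(ff))
  if (length(bad) > 0)
    stop(sprintf("line %d: non-numeric value", bad[1] + 1), call. = FALSE)
  nd <- which(diff(tt) <= 0)
  if (length(nd) > 0)
    stop(sprintf("line %d: time not strictly increasing", nd[1] + 2),
         call. = FALSE)
  prov <- "measured"
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- tryCatch(jsonlite::read_json(meta_path), error = function(e) NULL)
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  new_force_curve(tt, ff, provenance = prov, source = path)
}

#' @rdname read_force_curve
#' @export
write_force_curve <- function(curve, path, metadata = FALSE) {
  stopifnot(all(c("time_s", "force_N") %in% names(curve)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,force_N", con)
  writeLines(sprintf("%.17g,%.17g", curve$time_s, curve$force_N), con)
  if (metadata) {
    meta <- list(provenance = attr(curve, "provenance") %||% "unknown",
                 n_samples = nrow(curve))
    prot <- attr(curve, "protocol")
    if (!is.null(prot)) meta$protocol <- unclass(prot)
    truth <- attr(curve, "truth")
    if (!is.null(truth))
      meta$truth <- unclass(truth)[c("E_f", "E_nf", "nu_nf", "k_0", "M", "C")]
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

config_schema <- function() {
  list(
    command = c("simulate", "fit", "synthesize", "recover", "sweep",
                "benchmark", "mesh-study"),
    protocol = names(indentation_protocol()),
    material = c("E_f", "E_nf", "nu_nf", "k_0", "M", "C", "rho_z",
                 "n_fl_surface", "n_fl_slope"),
    solver = setdiff(names(solver_config()), "fidelity"),
    fit = c("n_starts", "seed", "maxit", "n_restarts", "reltol",
            "agreement_tol", "normalization", "lower", "upper", "nu_nf"),
    scalar = c("output_dir", "seed"))
}

#' Load and validate a run configuration
#'
#' Run configurations are JSON with blocks `protocol`, `material`, `solver`,
#' `fit` and scalars `command`, `output_dir`, `seed`. Unknown keys are
#' rejected by name; missing keys take the package defaults (the reference
#' cartilage material, the standard indentation protocol, the default solver
#' and fit settings). All units are the package units (mm, N, s, MPa,
#' mm^4 N^-1 s^-1).
#'
#' @param path JSON file path.
#' @return A list of class `frpe_config` with fully populated blocks:
#'   `command`, `protocol` ([indentation_protocol()]), `material`
#'   ([frpe_params()]), `solver` ([solver_config()]), `fit` ([fit_config()]),
#'   `output_dir`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- config_schema()
  known_top <- c("command", "protocol", "material", "solver", "fit",
                 "output_dir", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0)
    stop("unknown config key: ", unknown[1], call. = FALSE)
  check_block <- function(block, allowed, label) {
    if (is.null(block)) return(list())
    extra <- setdiff(names(block), allowed)
    if (length(extra) > 0)
      stop(sprintf("unknown key '%s' in block '%s'", extra[1], label),
           call. = FALSE)
    as.list(block)
  }
  prot_args <- check_block(raw$protocol, schema$protocol, "protocol")
  mat_args <- check_block(raw$material, schema$material, "material")
  sol_args <- check_block(raw$solver, schema$solver, "solver")
  fit_args <- check_block(raw$fit, schema$fit, "fit")
  if (!is.null(raw$command) && !(raw$command %in% schema$command))
    stop("unknown command: ", raw$command, call. = FALSE)
  if (!is.null(fit_args$lower)) fit_args$lower <- unlist(fit_args$lower)
  if (!is.null(fit_args$upper)) fit_args$upper <- unlist(fit_args$upper)
  structure(list(
    command = raw$command %||% "simulate",
    protocol = do.call(indentation_protocol, prot_args),
    material = do.call(frpe_params, mat_args),
    solver = do.call(solver_config, sol_args),
    fit = do.call(fit_config, fit_args),
    output_dir = raw$output_dir %||% ".",
    seed = as.integer(raw$seed %||% 1L)), class = "frpe_config")
}

#' @rdname load_config
#' @param config An `frpe_config` (or the argument list used to build one).
#' @export
write_config <- function(config, path) {
  fit_keep <- c("n_starts", "seed", "maxit", "n_restarts", "reltol",
                "agreement_tol", "normalization", "lower", "upper", "nu_nf")
  out <- list(command = config$command,
              protocol = unclass(config$protocol),
              material = unclass(config$material)[config_schema()$material],
              solver = unclass(config$solver)[config_schema()$solver],
              fit = unclass(config$fit)[fit_keep],
              output_dir = config$output_dir,
              seed = config$seed)
  out$fit$lower <- as.list(out$fit$lower)
  out$fit$upper <- as.list(out$fit$upper)
  out$material$rho_z <- if (is.function(out$material$rho_z)) 1 else out$material$rho_z
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export finite-element fields as legacy ASCII VTK
#'
#' Writes one legacy VTK unstructured-grid file per stored state, with nodal
#' displacement (3-component, zero hoop) and pore pressure as point data, and
#' per-cell volume ratio `J`, current permeability and maximum principal
#' effective (solid) stress as cell data. Files are named
#' `<prefix>_0000.vtk`, `<prefix>_0001.vtk`, ...
#'
#' @param sim A simulation result holding `states` (run with
#'   `store_states = TRUE`), or a single state vector.
#' @param mesh The `frpe_mesh` used for the simulation.
#' @param params The [frpe_params()] used (for permeability/stress fields).
#' @param prefix Output file prefix (directories are created).
#' @return Character vector of the written file paths, invisibly.
#' @export
export_fields <- function(sim, mesh, params, prefix) {
  states <- if (is.matrix(sim)) sim
            else if (is.list(sim) && !is.null(sim$states)) sim$states
            else matrix(sim, ncol = 1)
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  mat <- build_fe_material(params, mesh)
  nodes <- as.matrix(mesh$nodes[, c("r", "z")])
  nn <- nrow(nodes); ne <- nrow(mesh$elements)
  paths <- character(ncol(states))
  for (s in seq_len(ncol(states))) {
    U <- states[, s]
    fields <- cpp_cell_fields(nodes, mesh$elements, mat$elem_mat, mat$dirs,
                              mat$w, U)
    path <- sprintf("%s_%04d.vtk", prefix, s - 1)
    con <- file(path, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 "frpefit axisymmetric u-p state", "ASCII",
                 "DATASET UNSTRUCTURED_GRID",
                 sprintf("POINTS %d double", nn)), con)
    writeLines(sprintf("%.9g %.9g 0", nodes[, 1], nodes[, 2]), con)
    writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
    writeLines(sprintf("4 %d %d %d %d",
                       mesh$elements[, 1] - 1, mesh$elements[, 2] - 1,
                       mesh$elements[, 3] - 1, mesh$elements[, 4] - 1), con)
    writeLines(sprintf("CELL_TYPES %d", ne), con)
    writeLines(rep("9", ne), con)  # VTK_QUAD
    ur <- U[dof_u_r(seq_len(nn))]; uz <- U[dof_u_z(seq_len(nn))]
    pp <- U[dof_p(seq_len(nn))]
    writeLines(sprintf("POINT_DATA %d", nn), con)
    writeLines("VECTORS displacement double", con)
    writeLines(sprintf("%.9g %.9g 0", ur, uz), con)
    writeLines(c("SCALARS pore_pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", pp), con)
    writeLines(sprintf("CELL_DATA %d", ne), con)
    writeLines(c("SCALARS J double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", fields[, 1]), con)
    writeLines(c("SCALARS permeability double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", fields[, 2]), con)
    writeLines(c("SCALARS max_principal_stress double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", fields[, 4]), con)
    close(con)
    paths[s] <- path
  }
  invisible(paths)
}

#' Write a reproducibility manifest
#'
#' Records the command, seed, configuration hash and package version needed to
#' reproduce a run's outputs.
#'
#' @param path Output JSON path.
#' @param config The `frpe_config` (or any list) describing the run.
#' @param seed The seed in effect.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = config$seed %||% NA) {
  manifest <- list(
    package = "frpefit",
    version = as.character(utils::packageVersion("frpefit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = rlang::hash(config))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read a mesh as CSV node/element tables
#'
#' Two plain CSV files: `<prefix>_nodes.csv` (`node,r,z`) and
#' `<prefix>_elements.csv` (`element,n1,n2,n3,n4`, counter-clockwise
#' connectivity). Reading rebuilds the node sets from the coordinates.
#'
#' @param mesh An `frpe_mesh`.
#' @param prefix Path prefix for the two files.
#' @return `write_mesh()` returns the two paths invisibly; `read_mesh()`
#'   returns an `frpe_mesh`.
#' @export
write_mesh <- function(mesh, prefix) {
  np <- paste0(prefix, "_nodes.csv")
  ep <- paste0(prefix, "_elements.csv")
  utils::write.csv(mesh$nodes, np, row.names = FALSE)
  el <- data.frame(element = seq_len(nrow(mesh$elements)),
                   n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                   n3 = mesh$elements[, 3], n4 = mesh$elements[, 4])
  utils::write.csv(el, ep, row.names = FALSE)
  invisible(c(np, ep))
}

#' @rdname write_mesh
#' @export
read_mesh <- function(prefix) {
  np <- paste0(prefix, "_nodes.csv")
  ep <- paste0(prefix, "_elements.csv")
  if (!file.exists(np) || !file.exists(ep))
    stop("mesh files not found for prefix: ", prefix, call. = FALSE)
  nodes <- utils::read.csv(np)
  el <- utils::read.csv(ep)
  elements <- as.matrix(el[, c("n1", "n2", "n3", "n4")])
  dimnames(elements) <- NULL
  radius <- max(nodes$r)
  thickness <- max(nodes$z)
  zc <- sort(unique(nodes$z))
  elem_z <- (nodes$z[elements[, 1]] + nodes$z[elements[, 4]]) / 2
  sets <- list(base = which(nodes$z <= 1e-12),
               axis = which(nodes$r <= 1e-12),
               outer = which(abs(nodes$r - radius) <= 1e-12),
               surface = which(abs(nodes$z - thickness) <= 1e-12))
  structure(list(nodes = tibble::as_tibble(nodes), elements = elements,
                 sets = sets, elem_h = (thickness - elem_z) / thickness,
                 radius = radius, thickness = thickness,
                 nr = length(unique(nodes$r)) - 1, nz = length(zc) - 1,
                 grading = "unknown"),
            class = "frpe_mesh")
}
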