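# Plain-text parameter-file interface: a tree of documented key-value
# entries grouped in bracketed subsections, with template generation at
# three verbosity levels, strict parsing, and per-volume subsections.
#
# Grammar: `[Section name]` headers, `key = value` lines, `#` comments,
# blank lines ignored.  Keys absent from a file retain their defaults.

# level: 1 = minimal, 2 = default, 3 = full verbosity
.par_entry <- function(default, doc, level = 2L) {
  list(value = default, default = default, doc = doc, level = level)
}

# catalogue of sections; volume sections are added per label
.param_catalogue <- function(volume_labels = NULL) {
  tree <- list(
    "Mesh and space discretization" = list(
      "Mesh file" = .par_entry("", "Path to a gmsh MSH or VTU mesh; empty uses the built-in slab generator", 1L),
      "Element type" = .par_entry("Hex", "Hex | Tet (built-in slab generator only)", 1L),
      "FE space degree" = .par_entry("1", "Polynomial degree p (1 or 2)", 2L),
      "Scaling factor" = .par_entry("1", "Coordinate scale applied at import (1e-3 for millimetre meshes)", 1L),
      "Number of refinements" = .par_entry("0", "Uniform refinements of the built-in hexahedral slab (halves the element size each time)", 3L),
      "Slab extents (m)" = .par_entry("0.003 0.007 0.02", "Edge lengths of the built-in slab", 2L),
      "Slab element size (m)" = .par_entry("0.0005", "Edge of the built-in slab's cubic cells", 1L)),
    "Time discretization" = list(
      "BDF order" = .par_entry("2", "Order of the backward differentiation formula (1-3)", 2L),
      "Time step (s)" = .par_entry("5e-05", "Time step", 1L),
      "Final time (s)" = .par_entry("0.05", "End of the simulation", 1L)),
    "Fiber generation" = list(
      "Geometry type" = .par_entry("Slab", "Slab | Import from file", 2L),
      "Endocardium angle (deg)" = .par_entry("0", "Fiber angle at the endocardial face (Slab rule)", 2L),
      "Epicardium angle (deg)" = .par_entry("0", "Fiber angle at the epicardial face (Slab rule)", 2L),
      "Fiber file" = .par_entry("", "VTU file with fiber point-data arrays (Import from file)", 2L),
      "Fiber scaling factor" = .par_entry("1", "Coordinate scale of the fiber file", 3L),
      "Fiber array names" = .par_entry("fibers sheets sheet_normals", "Names of the f0/s0/n0 point-data arrays", 3L)),
    "Applied current" = list(
      "Type" = .par_entry("Cubic", "Cubic | Spherical | Planar | Gaussian | None", 1L),
      "Center (m)" = .par_entry("0.00075 0.00075 0.00075", "Centre of the stimulated region", 1L),
      "Half width (m)" = .par_entry("0.00075", "Half edge of the cubic impulse", 2L),
      "Radius (m)" = .par_entry("0.0025", "Radius of the spherical impulse", 2L),
      "Normal" = .par_entry("0 0 1", "Normal of the planar impulse", 3L),
      "Plane offset (m)" = .par_entry("0", "Signed distance of the plane from the origin", 3L),
      "Thickness (m)" = .par_entry("0.001", "Thickness of the planar impulse", 3L),
      "Gaussian width (m)" = .par_entry("0.002", "Standard deviation of the Gaussian impulse", 3L),
      "Amplitude (V/s)" = .par_entry("35.714", "Stimulus amplitude", 1L),
      "Duration (s)" = .par_entry("0.002", "Pulse duration", 1L),
      "Impulse initial times (s)" = .par_entry("0", "Start times of the pulses (space-separated list)", 2L)),
    "Linear solver" = list(
      "Method" = .par_entry("Cholesky", "Cholesky | CG", 3L),
      "Tolerance" = .par_entry("1e-10", "Relative residual for CG", 3L),
      "Max iterations" = .par_entry("10000", "Iteration cap for CG", 3L)),
    "Electrophysiology/Output" = list(
      "Enable CSV" = .par_entry("false", "Write min/max/pointwise CSV traces", 2L),
      "CSV filename" = .par_entry("monodomain_trace.csv", "Trace file", 2L),
      "Enable VTU" = .par_entry("false", "Write VTU snapshots (plus a PVD collection)", 2L),
      "VTU basename" = .par_entry("monodomain", "Snapshot file prefix", 2L),
      "Output every n steps" = .par_entry("20", "Snapshot/trace cadence in steps", 2L)),
    "Electrophysiology/Activation time" = list(
      "Enable" = .par_entry("true", "Track per-DOF activation times", 3L),
      "Threshold (V/s)" = .par_entry("10", "Minimum du/dt counting as activation", 3L)))
  if (is.null(volume_labels)) volume_labels <- character(0)
  vol_section <- function(lab, first_id) list(
    "Material IDs" = .par_entry(as.character(first_id), "Element labels owned by this volume (space-separated)", 1L),
    "Ionic model" = .par_entry("TTP06", "AlievPanfilov | BuenoOrovio | TTP06 | CRN", 1L),
    "Cell type" = .par_entry("Epicardium", "Cell-type variant where the model has one", 2L),
    "Longitudinal conductivity (m^2/s)" = .par_entry(.fmt_num(.benchmark_sigma()[1]), "sigma_l", 1L),
    "Transversal conductivity (m^2/s)" = .par_entry(.fmt_num(.benchmark_sigma()[2]), "sigma_t", 1L),
    "Normal conductivity (m^2/s)" = .par_entry(.fmt_num(.benchmark_sigma()[3]), "sigma_n", 1L),
    "Disable conduction" = .par_entry("false", "true excludes the volume from the conduction solve (scar)", 2L),
    "Parameter overrides" = .par_entry("", "Ionic overrides, e.g. 'GNa=10; GCaL=2e-5'", 3L))
  if (length(volume_labels)) {
    for (i in seq_along(volume_labels)) {
      tree[[paste0("Volumetric: ", volume_labels[i])]] <-
        vol_section(volume_labels[i], i - 1L)
    }
  } else {
    tree[["Volumetric"]] <- vol_section("Volumetric", 0L)
  }
  attr(tree, "volume_labels") <- volume_labels
  class(tree) <- "parameter_tree"
  tree
}

# Monodomain conductivities of the N-version slab benchmark: harmonic means
# of the intra/extracellular values (0.17/0.62 S/m longitudinal, 0.019/0.24
# transversal) divided by chi_m * C_m = 140 mm^-1 * 0.01 uF/mm^2.
.benchmark_sigma <- function() {
  chi_cm <- 1.4e5 * 0.01                   # F / m^3
  sl <- (0.17 * 0.62 / (0.17 + 0.62)) / chi_cm
  st <- (0.019 * 0.24 / (0.019 + 0.24)) / chi_cm
  c(sl, st, st)
}

#' Write a template parameter file
#'
#' Emits the full catalogue of parameters with their defaults and one-line
#' documentation, at one of three verbosity levels.  Passing volume labels
#' creates one `Volumetric: <label>` subsection per label (multi-volume
#' simulations); without labels a single global `Volumetric` section is
#' generated.
#'
#' @param path output file.
#' @param volume_labels optional character vector of subdomain labels.
#' @param verbosity `"minimal"`, `"default"` or `"full"`.
#' @return `path`, invisibly.
#' @export
generate_parameter_file <- function(path, volume_labels = NULL,
                                    verbosity = c("default", "minimal", "full")) {
  verbosity <- match.arg(verbosity)
  write_parameter_file(.param_catalogue(volume_labels), path, verbosity)
}

#' Write a parameter tree back to a file
#'
#' Emits the current values of a `parameter_tree` in the same documented
#' `key = value` format used by [generate_parameter_file()]; writing and
#' re-parsing a tree is idempotent.
#'
#' @param tree a `parameter_tree`.
#' @param path output file.
#' @param verbosity `"minimal"`, `"default"` or `"full"`.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(tree, path,
                                 verbosity = c("default", "minimal", "full")) {
  stopifnot(inherits(tree, "parameter_tree"))
  verbosity <- match.arg(verbosity)
  lvl <- c(minimal = 1L, default = 2L, full = 3L)[[verbosity]]
  volume_labels <- attr(tree, "volume_labels")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# monodomain simulation parameters", con)
  writeLines(sprintf("# volume labels: %s",
                     if (length(volume_labels)) paste(volume_labels, collapse = " ")
                     else "(single volume)"), con)
  for (sec in names(tree)) {
    keys <- tree[[sec]]
    keep <- vapply(keys, function(e) e$level <= lvl, TRUE)
    if (!any(keep)) next
    writeLines(c("", sprintf("[%s]", sec)), con)
    for (k in names(keys)[keep]) {
      writeLines(sprintf("  # %s", keys[[k]]$doc), con)
      writeLines(sprintf("  %s = %s", k, keys[[k]]$value), con)
    }
  }
  invisible(path)
}

#' Parse a parameter file
#'
#' Reads a `key = value` file with bracketed section headers into the full
#' parameter tree; keys missing from the file keep their defaults.  Unknown
#' sections or keys, malformed lines, and a volume-label set differing from
#' the one used to generate the file are rejected.
#'
#' @param path parameter file (may be empty: pure defaults).
#' @param volume_labels the volume labels the file was generated with.
#' @return a `parameter_tree`.
#' @export
parse_parameter_file <- function(path, volume_labels = NULL) {
  tree <- .param_catalogue(volume_labels)
  lines <- if (file.exists(path)) readLines(path) else
    stop(sprintf("parameter file not found: %s", path))
  sec <- NULL
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    txt <- trimws(raw)
    if (!nzchar(txt)) next
    if (grepl("^\\[.*\\]$", txt)) {
      sec <- sub("^\\[(.*)\\]$", "\\1", txt)
      if (!sec %in% names(tree)) {
        if (grepl("^Volumetric", sec)) {
          stop(sprintf(
            "line %d: volume section '[%s]' does not match the labels used for generating the parameter file",
            ln, sec))
        }
        stop(sprintf("line %d: unknown section '[%s]'", ln, sec))
      }
      next
    }
    if (!grepl("=", txt, fixed = TRUE)) {
      stop(sprintf("line %d: malformed line (expected 'key = value'): %s",
                   ln, lines[ln]))
    }
    if (is.null(sec)) {
      stop(sprintf("line %d: key outside any [section]", ln))
    }
    key <- trimws(sub("=.*$", "", txt))
    val <- trimws(sub("^[^=]*=", "", txt))
    if (!key %in% names(tree[[sec]])) {
      stop(sprintf("line %d: unknown key '%s' in section '[%s]'", ln, key, sec))
    }
    tree[[sec]][[key]]$value <- val
  }
  tree
}

# typed accessors
par_get <- function(tree, sec, key) tree[[sec]][[key]]$value
par_num <- function(tree, sec, key) {
  v <- scan(text = par_get(tree, sec, key), quiet = TRUE)
  if (!length(v)) stop(sprintf("parameter '%s / %s' is empty", sec, key))
  v
}
par_bool <- function(tree, sec, key) {
  tolower(par_get(tree, sec, key)) %in% c("true", "yes", "1")
}

#' Build and run a simulation from a parameter tree
#'
#' Realises the full pipeline described by a parsed parameter file: mesh
#' construction or import, fiber generation or import, subdomain setup,
#' stimulation protocol, solver execution, and output writing.
#'
#' @param tree a `parameter_tree` from [parse_parameter_file()].
#' @param output_dir directory for configured outputs.
#' @return the [run_simulation()] result, invisibly.
#' @export
run_from_parameters <- function(tree, output_dir = ".") {
  stopifnot(inherits(tree, "parameter_tree"))
  msec <- "Mesh and space discretization"
  mesh_file <- par_get(tree, msec, "Mesh file")
  if (nzchar(mesh_file)) {
    mesh <- import_mesh(mesh_file, par_num(tree, msec, "Scaling factor"))
  } else {
    ext <- par_num(tree, msec, "Slab extents (m)")
    dx <- par_num(tree, msec, "Slab element size (m)")
    nref <- par_num(tree, msec, "Number of refinements")
    dx <- dx / 2^nref
    mesh <- build_slab_mesh(ext, dx)
    if (toupper(par_get(tree, msec, "Element type")) == "TET") {
      mesh <- hex_to_tet(mesh)
    }
  }
  degree <- as.integer(par_num(tree, msec, "FE space degree"))
  space <- fe_space(mesh, degree)

  vol_secs <- grep("^Volumetric", names(tree), value = TRUE)
  specs <- list()
  models <- list()
  for (vs in vol_secs) {
    lab <- sub("^Volumetric: ?", "", vs)
    if (lab == "Volumetric") lab <- "Volumetric"
    ov_txt <- par_get(tree, vs, "Parameter overrides")
    ov <- list()
    if (nzchar(ov_txt)) {
      for (tok in strsplit(ov_txt, ";")[[1]]) {
        kv <- strsplit(trimws(tok), "=")[[1]]
        if (length(kv) != 2) stop(sprintf("bad override '%s' in [%s]", tok, vs))
        ov[[trimws(kv[1])]] <- as.numeric(kv[2])
      }
    }
    specs[[lab]] <- subdomain_spec(
      label = lab,
      material_ids = as.integer(par_num(tree, vs, "Material IDs")),
      sigma_l = par_num(tree, vs, "Longitudinal conductivity (m^2/s)"),
      sigma_t = par_num(tree, vs, "Transversal conductivity (m^2/s)"),
      sigma_n = par_num(tree, vs, "Normal conductivity (m^2/s)"),
      ionic_model = par_get(tree, vs, "Ionic model"),
      overrides = ov,
      conductive = !par_bool(tree, vs, "Disable conduction"))
    if (!par_bool(tree, vs, "Disable conduction")) {
      mname <- par_get(tree, vs, "Ionic model")
      ct <- par_get(tree, vs, "Cell type")
      ct_ok <- !is.null(.model_registry[[mname]]$cell_types) &&
        ct %in% .model_registry[[mname]]$cell_types
      models[[lab]] <- ionic_model(mname,
                                   cell_type = if (ct_ok) ct else NULL,
                                   overrides = ov)
    }
  }
  part <- build_subdomains(mesh, unname(specs), space)

  fsec <- "Fiber generation"
  gtype <- par_get(tree, fsec, "Geometry type")
  if (gtype == "Slab") {
    ly <- diff(range(mesh$nodes[, 2]))
    phi_nodes <- mesh$nodes[, 2] / ly
    frame <- slab_fiber_rule(mesh, phi_nodes,
                             par_num(tree, fsec, "Endocardium angle (deg)"),
                             par_num(tree, fsec, "Epicardium angle (deg)"))
  } else if (gtype == "Import from file") {
    nms <- strsplit(par_get(tree, fsec, "Fiber array names"), "[ ]+")[[1]]
    frame <- import_fibers(par_get(tree, fsec, "Fiber file"), mesh,
                           par_num(tree, fsec, "Fiber scaling factor"), nms)
  } else {
    stop(sprintf(
      "Geometry type '%s' is not available (only 'Slab' and 'Import from file'; ventricular and atrial rule-based methods are out of scope)",
      gtype))
  }

  asec <- "Applied current"
  stype <- par_get(tree, asec, "Type")
  protocol <- if (toupper(stype) == "NONE") stimulus_protocol(list()) else {
    common <- list(amplitude = par_num(tree, asec, "Amplitude (V/s)"),
                   duration = par_num(tree, asec, "Duration (s)"),
                   initial_times = par_num(tree, asec, "Impulse initial times (s)"))
    st <- switch(toupper(stype),
      CUBIC = do.call(stimulus, c(list(shape = "cube",
        center = par_num(tree, asec, "Center (m)"),
        half_width = par_num(tree, asec, "Half width (m)")), common)),
      SPHERICAL = do.call(stimulus, c(list(shape = "sphere",
        center = par_num(tree, asec, "Center (m)"),
        radius = par_num(tree, asec, "Radius (m)")), common)),
      PLANAR = do.call(stimulus, c(list(shape = "plane",
        normal = par_num(tree, asec, "Normal"),
        offset = par_num(tree, asec, "Plane offset (m)"),
        thickness = par_num(tree, asec, "Thickness (m)")), common)),
      GAUSSIAN = do.call(stimulus, c(list(shape = "gaussian",
        center = par_num(tree, asec, "Center (m)"),
        width = par_num(tree, asec, "Gaussian width (m)")), common)),
      stop(sprintf("unknown applied current type '%s'", stype)))
    stimulus_protocol(st)
  }

  tsec <- "Time discretization"
  osec <- "Electrophysiology/Output"
  every <- if (par_bool(tree, osec, "Enable CSV") ||
               par_bool(tree, osec, "Enable VTU")) {
    as.integer(par_num(tree, osec, "Output every n steps"))
  } else 0L
  prob <- monodomain_problem(
    part, frame, protocol, models,
    dt = par_num(tree, tsec, "Time step (s)"),
    t_end = par_num(tree, tsec, "Final time (s)"),
    scheme_order = as.integer(par_num(tree, tsec, "BDF order")),
    solver = list(method = tolower(par_get(tree, "Linear solver", "Method")),
                  tol = par_num(tree, "Linear solver", "Tolerance"),
                  maxit = as.integer(par_num(tree, "Linear solver",
                                             "Max iterations"))),
    activation_threshold = par_num(tree, "Electrophysiology/Activation time",
                                   "Threshold (V/s)"),
    output = list(every = every, points = NULL))
  result <- run_simulation(prob)
  if (par_bool(tree, osec, "Enable CSV") || par_bool(tree, osec, "Enable VTU")) {
    write_outputs(result,
                  dir = output_dir,
                  basename = par_get(tree, osec, "VTU basename"),
                  csv = par_bool(tree, osec, "Enable CSV"),
                  csv_file = par_get(tree, osec, "CSV filename"),
                  vtu = par_bool(tree, osec, "Enable VTU"))
  }
  invisible(result)
}
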