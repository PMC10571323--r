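# The N-version slab benchmark harness: a (3 x 7 x 20) mm slab, fibers
# along the long axis, TTP06 (epicardial), a (1.5 mm)^3 corner stimulus of
# 35.714 V/s for 2 ms, BDF2, and activation-time sampling along the P1-P8
# diagonal and at the named probe points
#   P1 = (0, 0, 0)        stimulated corner
#   P8 = (3, 7, 20) mm    opposite corner
#   P9 = (1.5, 3.5, 10) mm  domain centroid.

.bench_extents <- c(3, 7, 20) * 1e-3

#' Split a hexahedral mesh into tetrahedra
#'
#' Kuhn subdivision: each hexahedron becomes 6 tetrahedra following the
#' monotone vertex paths from corner (0,0,0) to (1,1,1), which is conforming
#' across identically oriented cells (as produced by [build_slab_mesh()]).
#'
#' @param mesh a hexahedral [mono_mesh()].
#' @return a tetrahedral [mono_mesh()] with 6x the elements.
#' @export
hex_to_tet <- function(mesh) {
  stopifnot(inherits(mesh, "mono_mesh"))
  if (mesh$element_kind != "hexahedron") stop("mesh is not hexahedral")
  # VTK local id of the corner with binary offsets (i, j, k)
  bid <- function(i, j, k) {
    c(`000` = 1L, `100` = 2L, `110` = 3L, `010` = 4L,
      `001` = 5L, `101` = 6L, `111` = 7L, `011` = 8L)[[paste0(i, j, k)]]
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tets_local <- lapply(perms, function(p) {
    b <- c(0L, 0L, 0L)
    ids <- integer(4)
    ids[1] <- bid(b[1], b[2], b[3])
    for (s in 1:3) {
      b[p[s]] <- 1L
      ids[s + 1] <- bid(b[1], b[2], b[3])
    }
    ids
  })
  E <- nrow(mesh$elements)
  conn <- matrix(0L, 6L * E, 4L)
  for (s in seq_along(tets_local)) {
    conn[seq.int(s, by = 6L, length.out = E), ] <-
      mesh$elements[, tets_local[[s]], drop = FALSE]
  }
  mat <- rep(mesh$material_id, each = 6L)
  # enforce positive orientation
  v1 <- mesh$nodes[conn[, 1], , drop = FALSE]
  a <- mesh$nodes[conn[, 2], , drop = FALSE] - v1
  b <- mesh$nodes[conn[, 3], , drop = FALSE] - v1
  cc <- mesh$nodes[conn[, 4], , drop = FALSE] - v1
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  flip <- det3 < 0
  if (any(flip)) conn[flip, 3:4] <- conn[flip, 4:3]
  mono_mesh(mesh$nodes, conn, "tetrahedron", mat)
}

#' Benchmark conductivities (m^2/s)
#'
#' Longitudinal / transversal / normal monodomain conductivities of the
#' N-version slab benchmark: harmonic means of the intra- and extracellular
#' conductivities divided by \eqn{\chi_m C_m} (transversely isotropic,
#' \eqn{\sigma_n = \sigma_t}).
#'
#' @return named numeric length-3 vector.
#' @export
benchmark_conductivities <- function() {
  s <- .benchmark_sigma()
  c(sigma_l = s[1], sigma_t = s[2], sigma_n = s[3])
}

#' Run the N-version slab benchmark
#'
#' Builds the (3 x 7 x 20) mm slab at the requested resolution, aligns the
#' fibers with the long axis, applies the (1.5 mm)^3 corner stimulus
#' (35.714 V/s for 2 ms), runs the TTP06 epicardial monodomain to
#' `t_end`, and samples the activation map along the P1-P8 diagonal and at
#' P1, P8, P9.
#'
#' @param dx element size (m); must divide all slab extents.
#' @param dt time step (s).
#' @param element_kind `"hexahedron"` or `"tetrahedron"` (Kuhn-split).
#' @param degree FE degree (1 or 2).
#' @param scheme_order BDF order (paper setting: 2).
#' @param t_end final time (s).
#' @param n_diagonal number of equispaced sample points on the diagonal.
#' @param solver solver settings passed to [monodomain_problem()].
#' @param progress progress cadence in steps (0 silent).
#' @return object of class `benchmark_result`: probe activation times in
#'   ms (`P1`, `P8`, `P9`), `latest` (max over active DOFs, ms),
#'   `diagonal` (data.frame with arc-length fraction and activation),
#'   `complete` (all active DOFs activated), `meta`, and the full
#'   simulation `result`.
#' @export
run_niederer_benchmark <- function(dx, dt, element_kind = "hexahedron",
                                   degree = 1L, scheme_order = 2L,
                                   t_end = 0.05, n_diagonal = 50L,
                                   solver = list(method = "cholesky"),
                                   progress = 0L) {
  element_kind <- match.arg(element_kind, c("hexahedron", "tetrahedron"))
  mesh <- build_slab_mesh(.bench_extents, dx)
  if (element_kind == "tetrahedron") mesh <- hex_to_tet(mesh)
  space <- fe_space(mesh, degree)
  sg <- benchmark_conductivities()
  spec <- subdomain_spec("Tissue", 0L, sg[1], sg[2], sg[3],
                         ionic_model = "TTP06")
  part <- build_subdomains(mesh, spec, space)
  frame <- axis_fiber_frame(mesh, f0 = c(0, 0, 1))  # fibers along long axis
  stim <- stimulus(shape = "cube", center = rep(0.75e-3, 3),
                   half_width = 0.75e-3, amplitude = 35.714,
                   duration = 2e-3, initial_times = 0)
  prob <- monodomain_problem(
    part, frame, stimulus_protocol(stim),
    models = list(Tissue = ionic_model("TTP06", cell_type = "Epicardium")),
    dt = dt, t_end = t_end, scheme_order = scheme_order, solver = solver)
  result <- run_simulation(prob, progress = progress)
  summarize_benchmark(result, n_diagonal = n_diagonal,
                      meta = list(dx = dx, dt = dt,
                                  element_kind = element_kind, degree = degree,
                                  scheme_order = scheme_order, t_end = t_end))
}

#' Summarise a slab run into benchmark quantities
#'
#' @param result a [run_simulation()] result on the benchmark slab.
#' @param n_diagonal number of diagonal sample points.
#' @param meta run metadata stored in the output.
#' @return a `benchmark_result` (see [run_niederer_benchmark()]).
#' @export
summarize_benchmark <- function(result, n_diagonal = 50L, meta = list()) {
  prob <- result$problem
  space <- prob$partition$space
  act <- result$activation$time * 1000          # ms
  active <- result$activation$active_dofs
  complete <- all(!is.na(act[active]))
  if (!complete) {
    warning(sprintf("benchmark incomplete: %d active DOF(s) never activated",
                    sum(is.na(act[active]))))
  }
  P1 <- c(0, 0, 0); P8 <- .bench_extents; P9 <- .bench_extents / 2
  sfrac <- seq(0, 1, length.out = n_diagonal)
  diag_pts <- outer(sfrac, P8 - P1) + matrix(P1, n_diagonal, 3, byrow = TRUE)
  act_full <- act
  act_full[is.na(act_full)] <- Inf  # sentinel survives interpolation visibly
  diag_act <- fe_interpolate(space, act_full, diag_pts)
  probes <- fe_interpolate(space, act_full, rbind(P1, P8, P9))
  structure(
    list(P1 = probes[1], P8 = probes[2], P9 = probes[3],
         latest = if (all(is.na(act[active]))) NA_real_
                  else max(act[active], na.rm = TRUE),
         diagonal = data.frame(s = sfrac,
                               x = diag_pts[, 1], y = diag_pts[, 2],
                               z = diag_pts[, 3], activation_ms = diag_act),
         complete = complete, meta = meta, result = result),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  if (length(x$meta)) {
    cat(sprintf("  dx = %g m, dt = %g s, %s, p = %d, BDF%d\n",
                x$meta$dx, x$meta$dt, x$meta$element_kind, x$meta$degree,
                x$meta$scheme_order))
  }
  cat(sprintf("  activation [ms]: P1 = %.3f, P9 = %.3f, P8 = %.3f, latest = %.3f%s\n",
              x$P1, x$P9, x$P8, x$latest,
              if (x$complete) "" else "  (INCOMPLETE)"))
  invisible(x)
}

#' Plane-wave conduction velocity on a thin bar
#'
#' Builds a thin bar along z, stimulates one end with a planar pulse, and
#' measures the wavefront speed from activation times at two probe planes
#' in the central portion of the bar (away from ends).  Used to verify the
#' monodomain scaling law CV proportional to the square root of the
#' conductivity.
#'
#' @param sigma conductivity along the bar (m^2/s); the transverse
#'   conductivities are set equal to `sigma` (the wave is planar, so they
#'   do not matter).
#' @param length_m,width_m bar dimensions (m).
#' @param dx,dt discretization (m, s).
#' @param t_end final time (s).
#' @param model an [ionic_model()] (default TTP06 epicardial).
#' @param probe_frac positions of the two probe planes as fractions of the
#'   bar length.
#' @param stim_thickness half-thickness (m) of the stimulated end slab;
#'   kept at a fixed physical size so initiation does not fall below the
#'   liminal volume at fine resolutions.
#' @return conduction velocity in m/s.
#' @export
bar_conduction_velocity <- function(sigma, length_m = 0.02, width_m = 8e-4,
                                    dx = 2e-4, dt = 5e-5, t_end = 0.06,
                                    model = ionic_model("TTP06", "Epicardium"),
                                    probe_frac = c(0.4, 0.8),
                                    stim_thickness = 1e-3) {
  mesh <- build_slab_mesh(c(width_m, width_m, length_m), dx)
  space <- fe_space(mesh, 1L)
  spec <- subdomain_spec("Bar", 0L, sigma, sigma, sigma, model$name)
  part <- build_subdomains(mesh, spec, space)
  frame <- axis_fiber_frame(mesh, f0 = c(0, 0, 1))
  # fixed physical stimulus thickness: a 2-cell sliver falls below the
  # liminal size at fine resolutions and fails to initiate a wave
  stim <- stimulus(shape = "plane", normal = c(0, 0, 1), offset = 0,
                   thickness = max(2 * stim_thickness, 2 * dx + 1e-9),
                   amplitude = 35.714, duration = 2e-3)
  prob <- monodomain_problem(part, frame, stimulus_protocol(stim),
                             models = list(Bar = model),
                             dt = dt, t_end = t_end, scheme_order = 2L)
  res <- run_simulation(prob)
  act <- res$activation$time
  z1 <- probe_frac[1] * length_m
  z2 <- probe_frac[2] * length_m
  mid <- width_m / 2
  t12 <- fe_interpolate(space, act, rbind(c(mid, mid, z1), c(mid, mid, z2)))
  if (anyNA(t12)) stop("wavefront did not reach both probe planes")
  (z2 - z1) / (t12[2] - t12[1])
}
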