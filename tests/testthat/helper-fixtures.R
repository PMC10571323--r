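# Shared fixtures, built in code at test time.

# tiny two-tetrahedron mesh with two material labels, coordinates in mm
two_tet_mesh_mm <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  elements <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  mono_mesh(nodes, elements, "tetrahedron", material_id = c(1L, 2L))
}

# write the two-tet mesh as a gmsh MSH v2.2 ASCII file
write_two_tet_msh22 <- function(path) {
  m <- two_tet_mesh_mm()
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(m$nodes))), con)
  for (i in seq_len(nrow(m$nodes))) {
    writeLines(sprintf("%d %.17g %.17g %.17g", i, m$nodes[i, 1],
                       m$nodes[i, 2], m$nodes[i, 3]), con)
  }
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(m$elements))), con)
  for (e in seq_len(nrow(m$elements))) {
    writeLines(sprintf("%d 4 2 %d %d %s", e, m$material_id[e],
                       m$material_id[e],
                       paste(m$elements[e, ], collapse = " ")), con)
  }
  writeLines("$EndElements", con)
  path
}

# write the two-tet mesh as a gmsh MSH v4.1 ASCII file (one block per
# material, entity tag = physical tag via $Entities)
write_two_tet_msh41 <- function(path) {
  m <- two_tet_mesh_mm()
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat"), con)
  writeLines(c("$Entities", "0 0 0 2",
               "1 0 0 0 1 1 1 1 1 0",
               "2 0 0 0 1 1 1 1 2 0",
               "$EndEntities"), con)
  writeLines(c("$Nodes", "1 5 1 5", "3 1 0 5"), con)
  writeLines(as.character(1:5), con)
  for (i in 1:5) {
    writeLines(sprintf("%.17g %.17g %.17g", m$nodes[i, 1], m$nodes[i, 2],
                       m$nodes[i, 3]), con)
  }
  writeLines(c("$EndNodes", "$Elements", "2 2 1 2"), con)
  writeLines("3 1 4 1", con)
  writeLines(paste(c(1L, m$elements[1, ]), collapse = " "), con)
  writeLines("3 2 4 1", con)
  writeLines(paste(c(2L, m$elements[2, ]), collapse = " "), con)
  writeLines("$EndElements", con)
  path
}

# random orthonormal frame at n nodes (seeded by the caller)
random_frame <- function(n) {
  f <- matrix(rnorm(3 * n), n, 3)
  s <- matrix(rnorm(3 * n), n, 3)
  nr <- matrix(rnorm(3 * n), n, 3)
  fiber_frame(f, s, nr)
}

# quick single-region slab problem used by several solver tests
tiny_problem <- function(model_name = "TTP06", sigma = c(0, 0, 0),
                         dx = 0.5e-3, extents = c(1, 1, 1) * 1e-3,
                         dt = 5e-5, t_end = 5e-3, scheme_order = 2L,
                         amplitude = 0, duration = 2e-3,
                         solver = list(method = "cholesky")) {
  mesh <- build_slab_mesh(extents, dx)
  space <- fe_space(mesh, 1L)
  spec <- subdomain_spec("A", 0L, sigma[1], sigma[2], sigma[3], model_name)
  part <- build_subdomains(mesh, spec, space)
  frame <- axis_fiber_frame(mesh)
  protocol <- if (amplitude > 0) {
    stimulus_protocol(stimulus(shape = "cube", center = extents / 2,
                               half_width = max(extents), amplitude = amplitude,
                               duration = duration))
  } else stimulus_protocol(list())
  monodomain_problem(part, frame, protocol,
                     models = stats::setNames(list(ionic_model(model_name)), "A"),
                     dt = dt, t_end = t_end, scheme_order = scheme_order,
                     solver = solver)
}
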