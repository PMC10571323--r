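# Mesh construction, import/export, scaling and subdomain bookkeeping.

test_that("slab generator produces the structured lattice", {
  cases <- list(
    list(extents = c(3, 7, 20) * 1e-3, dx = 0.5e-3,
         elements = 6L * 14L * 40L, nodes = 7L * 15L * 41L),
    list(extents = c(1, 1, 1), dx = 1,
         elements = 1L, nodes = 8L),
    list(extents = c(3, 7, 20) * 1e-3, dx = 0.1e-3,
         elements = 30L * 70L * 200L, nodes = 31L * 71L * 201L))
  for (cs in cases) {
    m <- build_slab_mesh(cs$extents, cs$dx)
    expect_identical(nrow(m$elements), cs$elements)
    expect_identical(nrow(m$nodes), cs$nodes)
    expect_true(all(m$material_id == 0L))
  }
})

test_that("slab generator rejects bad discretizations", {
  expect_error(build_slab_mesh(c(1, 1, 1) * 1e-3, -1e-4), "positive")
  expect_error(build_slab_mesh(c(1, 1, 1) * 1e-3, 3e-4), "integer multiple")
})

test_that("slab mesh volume equals the product of the extents", {
  ext <- c(3, 7, 20) * 1e-3
  m <- build_slab_mesh(ext, 0.5e-3)
  expect_lt(abs(sum(element_volumes(m)) - prod(ext)) / prod(ext), 1e-12)
  mt <- hex_to_tet(m)
  expect_lt(abs(sum(element_volumes(mt)) - prod(ext)) / prod(ext), 1e-12)
  expect_identical(nrow(mt$elements), 6L * nrow(m$elements))
})

test_that("MSH import rescales mm fixtures to metres and keeps labels", {
  for (writer in list(write_two_tet_msh22, write_two_tet_msh41)) {
    path <- withr::local_tempfile(fileext = ".msh")
    writer(path)
    m <- import_mesh(path, scaling_factor = 1e-3)
    ref <- two_tet_mesh_mm()
    expect_equal(m$nodes, ref$nodes * 1e-3, tolerance = 0)
    expect_identical(sort(unique(m$material_id)), c(1L, 2L))
    expect_identical(m$element_kind, "tetrahedron")
  }
})

test_that("VTU export/import round trip is bit-identical at factor 1", {
  m <- two_tet_mesh_mm()
  path <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m, path)
  m2 <- import_mesh(path, scaling_factor = 1)
  expect_identical(m2$nodes, m$nodes)
  expect_identical(m2$elements, m$elements)
  expect_identical(m2$material_id, m$material_id)
})

test_that("slab export/import agrees with the generator", {
  m <- build_slab_mesh(c(1, 2, 2) * 1e-3, 0.5e-3)
  # author the file in millimetres, reimport with the 1e-3 factor
  m_mm <- scale_mesh(m, 1e3)
  path <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m_mm, path)
  m2 <- import_mesh(path, scaling_factor = 1e-3)
  expect_lt(max(abs(m2$nodes - m$nodes)), 1e-12)
})

test_that("import rejects mixed meshes and warns on missing labels", {
  # hand-written minimal VTU without any cell label array
  unlabelled <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid"><UnstructuredGrid>',
    '<Piece NumberOfPoints="5" NumberOfCells="2">',
    '<Points><DataArray NumberOfComponents="3">',
    "0 0 0 1 0 0 0 1 0 0 0 1 1 1 1",
    "</DataArray></Points><Cells>",
    '<DataArray Name="connectivity">0 1 2 3 1 2 3 4</DataArray>',
    '<DataArray Name="offsets">4 8</DataArray>',
    '<DataArray Name="types">10 10</DataArray>',
    "</Cells></Piece></UnstructuredGrid></VTKFile>")
  path <- withr::local_tempfile(fileext = ".vtu")
  writeLines(unlabelled, path)
  expect_warning(m2 <- import_mesh(path, 1), "label")
  expect_true(all(m2$material_id == 0L))
  # a file mixing tetrahedra and hexahedra is rejected
  mixed <- sub('"types">10 10', '"types">10 12', unlabelled)
  mixed <- sub('"offsets">4 8', '"offsets">4 12', mixed)
  mixed <- sub('"connectivity">0 1 2 3 1 2 3 4',
               '"connectivity">0 1 2 3 0 1 2 3 4 4 4 4', mixed)
  writeLines(mixed, path)
  expect_error(suppressWarnings(import_mesh(path, 1)), "mixed")
})

test_that("subdomain partition covers, separates, and rejects misuse", {
  m <- two_tet_mesh_mm()
  s1 <- subdomain_spec("A", 1L, 1e-4, 1e-5, 1e-5)
  s2 <- subdomain_spec("B", 2L, 1e-4, 1e-5, 1e-5)
  p <- build_subdomains(m, list(s1, s2))
  expect_identical(sort(unlist(p$elem_sets)), 1:2)
  expect_identical(p$active_dofs, 1:5)
  # single spec covering everything
  s12 <- subdomain_spec("All", c(1L, 2L), 1e-4, 1e-5, 1e-5)
  p1 <- build_subdomains(m, s12)
  expect_identical(p1$active_dofs, 1:5)
  # overlap and orphan labels
  expect_error(build_subdomains(m, list(s1, subdomain_spec("C", 1:2, 1, 1, 1))),
               "more than one")
  expect_error(build_subdomains(m, s1), "not covered")
  expect_error(build_subdomains(m, list(s1, subdomain_spec("A", 2L, 1, 1, 1))),
               "unique")
})

test_that("non-conductive subdomains release interior DOFs, keep interfaces", {
  # 2 x 1 x 1 cells: elements [0, dx] and [dx, 2 dx] in x
  m <- build_slab_mesh(c(2, 1, 1) * 1e-3, 1e-3)
  m$material_id <- c(0L, 1L)
  sA <- subdomain_spec("A", 0L, 1e-4, 1e-5, 1e-5)
  sB <- subdomain_spec("B", 1L, 0, 0, 0, conductive = FALSE)
  p <- build_subdomains(m, list(sA, sB))
  # conductive element owns 8 DOFs, 4 of them shared on the interface plane
  expect_identical(length(p$active_dofs), 8L)
  shared <- intersect(p$dof_sets[[1]], p$dof_sets[[2]])
  expect_identical(length(shared), 4L)
  expect_true(all(shared %in% p$active_dofs))
  inactive <- setdiff(seq_len(nrow(m$nodes)), p$active_dofs)
  expect_identical(length(inactive), 4L)  # x = 2 dx face only
  # element counts partition the mesh
  expect_identical(sort(unlist(p$elem_sets)), seq_len(nrow(m$elements)))
})
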