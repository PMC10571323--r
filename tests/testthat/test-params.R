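# Parameter-file interface: templates, parsing, defaults, volume labels,
# and the full parameter-driven pipeline.

test_that("an empty file yields the pure-default tree", {
  path <- withr::local_tempfile(fileext = ".prm")
  writeLines(character(0), path)
  tree <- parse_parameter_file(path)
  ref <- monodomain:::.param_catalogue(NULL)
  expect_identical(tree, ref)
  expect_identical(monodomain:::par_get(tree, "Applied current",
                                        "Amplitude (V/s)"), "35.714")
})

test_that("defaults freeze the slab benchmark configuration", {
  tree <- monodomain:::.param_catalogue(NULL)
  g <- function(sec, key) monodomain:::par_get(tree, sec, key)
  n <- function(sec, key) monodomain:::par_num(tree, sec, key)
  expect_equal(n("Mesh and space discretization", "Slab extents (m)"),
               c(3, 7, 20) * 1e-3)
  expect_equal(n("Mesh and space discretization", "Slab element size (m)"),
               0.5e-3)
  expect_identical(g("Mesh and space discretization", "Element type"), "Hex")
  expect_equal(n("Mesh and space discretization", "FE space degree"), 1)
  expect_equal(n("Time discretization", "BDF order"), 2)
  expect_equal(n("Time discretization", "Time step (s)"), 5e-5)
  expect_identical(g("Applied current", "Type"), "Cubic")
  expect_equal(n("Applied current", "Center (m)"), rep(0.75e-3, 3))
  expect_equal(n("Applied current", "Half width (m)"), 0.75e-3)
  expect_equal(n("Applied current", "Amplitude (V/s)"), 35.714)
  expect_equal(n("Applied current", "Duration (s)"), 2e-3)
  expect_identical(g("Volumetric", "Ionic model"), "TTP06")
  expect_identical(g("Volumetric", "Cell type"), "Epicardium")
  sg <- benchmark_conductivities()
  expect_equal(n("Volumetric", "Longitudinal conductivity (m^2/s)"),
               unname(sg[1]), tolerance = 1e-12)
  expect_equal(n("Volumetric", "Transversal conductivity (m^2/s)"),
               unname(sg[2]), tolerance = 1e-12)
  expect_equal(n("Volumetric", "Normal conductivity (m^2/s)"),
               unname(sg[3]), tolerance = 1e-12)
})

test_that("volume labels create one subsection each and must match", {
  path <- withr::local_tempfile(fileext = ".prm")
  labs <- c("Healthy", "Fibrosis", "Scar")
  generate_parameter_file(path, volume_labels = labs)
  tree <- parse_parameter_file(path, volume_labels = labs)
  expect_true(all(paste0("Volumetric: ", labs) %in% names(tree)))
  # parsing with different labels is rejected
  expect_error(parse_parameter_file(path, volume_labels = c("Healthy")),
               "labels used for generating")
})

test_that("malformed lines and unknown keys report the line number", {
  path <- withr::local_tempfile(fileext = ".prm")
  writeLines(c("[Time discretization]", "BDF order 2"), path)
  expect_error(parse_parameter_file(path), "line 2")
  writeLines(c("[Time discretization]", "No such key = 1"), path)
  expect_error(parse_parameter_file(path), "unknown key")
  writeLines(c("[No such section]", "x = 1"), path)
  expect_error(parse_parameter_file(path), "unknown section")
})

test_that("template emission and parsing reach a fixed point", {
  for (verbosity in c("minimal", "default", "full")) {
    p1 <- withr::local_tempfile(fileext = ".prm")
    p2 <- withr::local_tempfile(fileext = ".prm")
    generate_parameter_file(p1, verbosity = verbosity)
    t1 <- parse_parameter_file(p1)
    write_parameter_file(t1, p2, verbosity = verbosity)
    expect_identical(readLines(p2), readLines(p1))
    expect_identical(parse_parameter_file(p2), t1)
  }
  # minimal shows fewer keys than full
  pmin_ <- withr::local_tempfile(fileext = ".prm")
  pfull <- withr::local_tempfile(fileext = ".prm")
  generate_parameter_file(pmin_, verbosity = "minimal")
  generate_parameter_file(pfull, verbosity = "full")
  expect_lt(length(readLines(pmin_)), length(readLines(pfull)))
})

test_that("a parameter file drives a complete simulation", {
  path <- withr::local_tempfile(fileext = ".prm")
  outdir <- withr::local_tempdir()
  writeLines(c(
    "[Mesh and space discretization]",
    "Slab extents (m) = 0.001 0.001 0.002",
    "Slab element size (m) = 0.0005",
    "[Time discretization]",
    "Time step (s) = 1e-4",
    "Final time (s) = 0.004",
    "[Applied current]",
    "Half width (m) = 0.00051",
    "Center (m) = 0.00025 0.00025 0.00025",
    "[Electrophysiology/Output]",
    "Enable CSV = true",
    "Enable VTU = true",
    "Output every n steps = 10"), path)
  res <- run_from_parameters(parse_parameter_file(path), output_dir = outdir)
  expect_s3_class(res, "monodomain_result")
  expect_true(file.exists(file.path(outdir, "monodomain.pvd")))
  expect_true(file.exists(file.path(outdir, "monodomain_trace.csv")))
  # imported-mesh path: author the same slab in mm with a scaling factor
  mesh_mm <- scale_mesh(build_slab_mesh(c(1, 1, 2) * 1e-3, 0.5e-3), 1e3)
  mesh_file <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(mesh_mm, mesh_file)
  writeLines(c(
    "[Mesh and space discretization]",
    sprintf("Mesh file = %s", mesh_file),
    "Scaling factor = 1e-3",
    "[Time discretization]",
    "Time step (s) = 1e-4",
    "Final time (s) = 0.0005"), path)
  res2 <- run_from_parameters(parse_parameter_file(path), output_dir = outdir)
  expect_lt(max(abs(res2$problem$partition$mesh$nodes -
                    build_slab_mesh(c(1, 1, 2) * 1e-3, 0.5e-3)$nodes)), 1e-12)
})

test_that("unavailable fiber rule-based geometry types are refused", {
  path <- withr::local_tempfile(fileext = ".prm")
  writeLines(c("[Fiber generation]", "Geometry type = Left atrium"), path)
  expect_error(run_from_parameters(parse_parameter_file(path)),
               "out of scope")
})
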