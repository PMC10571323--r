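# Tissue solver: ICI vector, 0D-oracle equivalence, conservation and
# symmetry properties, activation mapping, checkpoint/restart, partition
# invisibility.

test_that("ICI vector collapses correctly for single and trivial cases", {
  m <- build_slab_mesh(c(2, 1, 1) * 1e-3, 0.5e-3)
  m$material_id <- as.integer(m$nodes[m$elements[, 1], 1] > 0.9e-3)
  sp <- fe_space(m, 1)
  M <- assemble_mass(sp)
  M1 <- assemble_mass(sp, which(m$material_id == 0L))
  M2 <- assemble_mass(sp, which(m$material_id == 1L))
  Ione <- rep(1, sp$n_dofs)
  # N = 1 collapse: s = M I
  expect_equal(ici_ionic_vector(list(Ione), list(M)),
               as.vector(M %*% Ione), tolerance = 0)
  # zero current gives the zero vector
  expect_identical(ici_ionic_vector(list(numeric(sp$n_dofs)), list(M)),
                   numeric(sp$n_dofs))
  # I = 1 everywhere: total equals the conductive volume
  s <- ici_ionic_vector(list(Ione, Ione), list(M1, M2))
  expect_equal(sum(s), prod(c(2, 1, 1) * 1e-3), tolerance = 1e-15)
  expect_error(ici_ionic_vector(list(Ione), list(M1, M2)), "length")
})

test_that("with zero conductivity every DOF reproduces the 0D integrator", {
  for (nm in ionic_model_names()) {
    mod <- ionic_model(nm)
    amp <- if (mod$unit_scale == 1) 150 else 60
    prob <- tiny_problem(nm, sigma = c(0, 0, 0), dt = 5e-5, t_end = 0.015,
                         scheme_order = 2L, amplitude = amp)
    res <- run_simulation(prob)
    oracle <- single_cell_run(mod, period = 0.015, n_cycles = 1, dt = 5e-5,
                              stim_amplitude = amp, stim_duration = 2e-3,
                              scheme = bdf_scheme(2))
    expect_lt(max(abs(res$u / mod$unit_scale - oracle$u)), 1e-10)
    # and the ionic state matches too
    expect_lt(max(abs(t(res$state$w_hist[[1]][[1]]) - oracle$w)), 1e-10)
  }
})

test_that("rest state is preserved and uniform data stays uniform", {
  # exact equilibria (phenomenological models): u_n = u_0 to 1e-9
  prob <- tiny_problem("BuenoOrovio", sigma = c(2e-4, 1e-4, 1e-4),
                       dt = 1e-4, t_end = 0.02)
  res <- run_simulation(prob)
  expect_lt(max(abs(res$u)), 1e-9)
  # published TTP06 state is a near-equilibrium: drift stays at its
  # intrinsic rate (about 1e-3 mV/ms), orders below any activation signal
  probt <- tiny_problem("TTP06", sigma = benchmark_conductivities(),
                        dt = 1e-4, t_end = 0.02)
  rest <- run_simulation(probt)
  expect_lt(max(abs(rest$u - ionic_model("TTP06")$u0 * 1e-3)), 1e-4)
  # spatially uniform stimulus keeps the state spatially uniform
  prob2 <- tiny_problem("TTP06", sigma = benchmark_conductivities(),
                        dt = 5e-5, t_end = 0.01, amplitude = 60)
  res2 <- run_simulation(prob2)
  expect_lt(diff(range(res2$u)), 1e-9)
})

test_that("uniform states remain exact trajectories stepwise", {
  prob <- tiny_problem("BuenoOrovio", sigma = c(2e-4, 1e-4, 1e-4),
                       dt = 1e-4, t_end = 5e-3, amplitude = 200)
  ops <- NULL; state <- NULL
  for (k in 1:30) {
    out <- monodomain_step(prob, ops, state)
    ops <- out$ops; state <- out$state
    expect_lt(diff(range(state$u_hist[[1]])), 1e-9)
  }
})

test_that("activation map finds the inflection of a known trace", {
  tstar <- 0.02; tau <- 2e-3
  times <- seq(0, 0.05, by = 5e-4)
  u <- tanh((times - tstar) / tau)
  am <- activation_map(times, u, threshold = 10)
  expect_lt(abs(am$time[1] - tstar), 5e-4 + 1e-12)
  # constant trace: never activated
  am0 <- activation_map(times, rep(-0.08, length(times)))
  expect_true(is.na(am0$time[1]))
  expect_error(activation_map(0, 1), "two time levels")
})

test_that("stimulated-corner DOFs activate first in a conducting slab", {
  mesh <- build_slab_mesh(c(1, 1, 3) * 1e-3, 0.5e-3)
  sp <- fe_space(mesh, 1)
  sg <- benchmark_conductivities()
  part <- build_subdomains(mesh, subdomain_spec("A", 0L, sg[1], sg[2], sg[3],
                                                "TTP06"), sp)
  stim <- stimulus(shape = "cube", center = rep(0.25e-3, 3),
                   half_width = 0.51e-3, amplitude = 35.714, duration = 2e-3)
  prob <- monodomain_problem(part, axis_fiber_frame(mesh),
                             stimulus_protocol(stim),
                             models = list(A = ionic_model("TTP06")),
                             dt = 5e-5, t_end = 0.02)
  res <- run_simulation(prob)
  act <- res$activation$time
  expect_true(all(is.finite(act)))
  inside <- which(stimulus_support(stim, mesh$nodes) > 0)
  expect_identical(which.min(act) %in% inside, TRUE)
  expect_lt(min(act[inside]), min(act[-inside]))
})

test_that("checkpoint/restart resumes bit-identically", {
  prob <- tiny_problem("TTP06", sigma = benchmark_conductivities(),
                       dt = 1e-4, t_end = 0.01, amplitude = 60)
  full <- run_simulation(prob)
  # run half, checkpoint, restore, run the rest
  prob_half <- prob; prob_half$t_end <- 0.005
  half <- run_simulation(prob_half)
  path <- withr::local_tempfile(fileext = ".rds")
  checkpoint(half$state, prob, path)
  st <- restore(path, prob)
  expect_identical(st, half$state)
  resumed <- run_simulation(prob, state = st)
  expect_identical(resumed$u, full$u)
  expect_identical(resumed$state$w_hist, full$state$w_hist)
  # guards: different mesh and different settings are rejected
  prob2 <- tiny_problem("TTP06", sigma = benchmark_conductivities(),
                        dx = 0.25e-3, dt = 1e-4, t_end = 0.01)
  expect_error(restore(path, prob2), "different mesh")
  prob3 <- prob; prob3$dt <- 2e-4
  expect_error(restore(path, prob3), "settings")
})

test_that("an invisible partition does not change the solution", {
  mesh <- build_slab_mesh(c(1, 1, 3) * 1e-3, 0.5e-3)
  sp <- fe_space(mesh, 1)
  sg <- benchmark_conductivities()
  stim <- stimulus(shape = "cube", center = rep(0.25e-3, 3),
                   half_width = 0.51e-3, amplitude = 35.714, duration = 2e-3)
  run_with_materials <- function(mat, specs, models) {
    m <- mesh; m$material_id <- mat
    part <- build_subdomains(m, specs, fe_space(m, 1))
    prob <- monodomain_problem(part, axis_fiber_frame(m),
                               stimulus_protocol(stim), models = models,
                               dt = 1e-4, t_end = 0.008)
    run_simulation(prob)
  }
  sgl <- run_with_materials(
    rep(0L, nrow(mesh$elements)),
    subdomain_spec("All", 0L, sg[1], sg[2], sg[3], "TTP06"),
    list(All = ionic_model("TTP06")))
  # three z-layers with identical properties
  zc <- mesh$nodes[mesh$elements[, 1], 3]
  mat3 <- as.integer(cut(zc, c(-1, 0.9e-3, 1.9e-3, 4e-3))) - 1L
  tri <- run_with_materials(
    mat3,
    list(subdomain_spec("L1", 0L, sg[1], sg[2], sg[3], "TTP06"),
         subdomain_spec("L2", 1L, sg[1], sg[2], sg[3], "TTP06"),
         subdomain_spec("L3", 2L, sg[1], sg[2], sg[3], "TTP06")),
    list(L1 = ionic_model("TTP06"), L2 = ionic_model("TTP06"),
         L3 = ionic_model("TTP06")))
  expect_identical(tri$u, sgl$u)
})

test_that("CG with Jacobi preconditioning matches the direct solver", {
  sg <- benchmark_conductivities()
  direct <- tiny_problem("TTP06", sigma = sg, dx = 0.25e-3, dt = 1e-4,
                         t_end = 5e-3, amplitude = 60)
  cg <- tiny_problem("TTP06", sigma = sg, dx = 0.25e-3, dt = 1e-4,
                     t_end = 5e-3, amplitude = 60,
                     solver = list(method = "cg", tol = 1e-12))
  rd <- run_simulation(direct)
  rc <- run_simulation(cg)
  expect_lt(max(abs(rd$u - rc$u)), 1e-10)
})

test_that("non-finite states abort with a step report", {
  # an absurd time step with a violent sustained stimulus overflows
  prob <- tiny_problem("AlievPanfilov", sigma = c(0, 0, 0), dt = 0.5,
                       t_end = 10, amplitude = 1e6, duration = 9)
  expect_error(run_simulation(prob), "step|diverg|finite")
})

test_that("three-layer ventricular-slab cell types partition the elements", {
  mesh <- build_slab_mesh(c(1, 3, 1) * 1e-3, 0.5e-3)
  yc <- mesh$nodes[mesh$elements[, 1], 2]
  mesh$material_id <- as.integer(cut(yc, c(-1, 0.9e-3, 1.9e-3, 4e-3))) - 1L
  sg <- benchmark_conductivities()
  specs <- list(
    subdomain_spec("Sub Endocardium", 0L, sg[1], sg[2], sg[3], "TTP06"),
    subdomain_spec("Myocardium", 1L, sg[1], sg[2], sg[3], "TTP06"),
    subdomain_spec("Sub Epicardium", 2L, sg[1], sg[2], sg[3], "TTP06"))
  part <- build_subdomains(mesh, specs)
  expect_identical(length(part$elem_sets), 3L)
  expect_identical(sort(unlist(part$elem_sets)), seq_len(nrow(mesh$elements)))
  expect_identical(sum(vapply(part$elem_sets, length, 0L)),
                   nrow(mesh$elements))
  models <- list(
    "Sub Endocardium" = ionic_model("TTP06", "Endocardium"),
    "Myocardium" = ionic_model("TTP06", "Myocardium"),
    "Sub Epicardium" = ionic_model("TTP06", "Epicardium"))
  prob <- monodomain_problem(part, axis_fiber_frame(mesh),
                             stimulus_protocol(list()), models,
                             dt = 1e-4, t_end = 1e-3)
  res <- run_simulation(prob)
  expect_lt(max(abs(res$u - ionic_model("TTP06")$u0 * 1e-3)), 1e-5)
})

test_that("the solver runs on tetrahedral meshes and activates fully", {
  mesh <- hex_to_tet(build_slab_mesh(c(1, 1, 3) * 1e-3, 0.5e-3))
  sp <- fe_space(mesh, 1)
  sg <- benchmark_conductivities()
  part <- build_subdomains(mesh, subdomain_spec("A", 0L, sg[1], sg[2], sg[3],
                                                "TTP06"), sp)
  stim <- stimulus(shape = "cube", center = rep(0.25e-3, 3),
                   half_width = 0.51e-3, amplitude = 35.714, duration = 2e-3)
  prob <- monodomain_problem(part, axis_fiber_frame(mesh),
                             stimulus_protocol(stim),
                             models = list(A = ionic_model("TTP06")),
                             dt = 5e-5, t_end = 0.02)
  res <- run_simulation(prob)
  expect_true(all(is.finite(res$activation$time)))
  # far-end activation happens later than near the stimulus
  far <- which(mesh$nodes[, 3] > 2.9e-3)
  near <- which(mesh$nodes[, 3] < 0.1e-3)
  expect_gt(min(res$activation$time[far]), max(res$activation$time[near]))
})
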