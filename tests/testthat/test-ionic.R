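# Cellular layer: published rest states, the closed-form IMEX gate update,
# potential rescaling, membrane normalisation, and 0D pacing behaviour.

test_that("phenomenological models are at rest at their resting state", {
  apf <- ionic_model("AlievPanfilov")
  r <- evaluate_rhs(apf, 0, 0)
  expect_identical(r$Iion, 0)
  expect_identical(as.vector(r$H), 0)
  bo <- ionic_model("BuenoOrovio")
  r <- evaluate_rhs(bo, 0, c(1, 1, 0))
  # all three currents vanish below every threshold
  expect_identical(r$Iion, 0)
})

test_that("physiological models start near equilibrium", {
  for (nm in c("TTP06", "CRN")) {
    mod <- ionic_model(nm)
    r <- evaluate_rhs(mod, mod$u0, mod$w0)
    expect_lt(abs(r$Iion), 1e-2)  # mV/ms, numerically V/s
  }
})

test_that("every model holds its rest state for one second unstimulated", {
  for (nm in ionic_model_names()) {
    mod <- ionic_model(nm)
    out <- single_cell_run(mod, period = 1, n_cycles = 1, dt = 1e-5,
                           stim_amplitude = 0)
    drift_tol <- if (mod$unit_scale == 1) 0.01 else 1  # model units / mV
    expect_lt(abs(out$u - mod$u0), drift_tol)
  }
})

test_that("implicit gate update inverts the BDF1 relation in closed form", {
  # scalar gate dw/dt = (winf - w)/tau under BuenoOrovio's s gate at fixed u
  bo <- ionic_model("BuenoOrovio")
  u <- 0.4
  p <- bo$params
  winf <- (1 + tanh(p[["k_s"]] * (u - p[["u_s"]]))) / 2
  tau <- p[["tau_s2"]]  # u = 0.4 > theta_w
  w0 <- c(0, 0.2, 0.5)
  dt <- 3
  w1 <- ionic_step(bo, u, matrix(w0, 1), dt, bdf_scheme(1))
  expect_equal(w1[1, "s"], (w0[3] + dt * winf / tau) / (1 + dt / tau),
               tolerance = 1e-14, ignore_attr = TRUE)
  # dt -> 0 limit: w unchanged, any model
  for (nm in ionic_model_names()) {
    mod <- ionic_model(nm)
    w <- matrix(mod$w0, 1)
    w1 <- ionic_step(mod, mod$u0, w, 1e-12, bdf_scheme(1))
    expect_equal(as.vector(w1), mod$w0, tolerance = 1e-8)
  }
  # explicit variable reduces to the forward update with BDF1
  apf <- ionic_model("AlievPanfilov")
  u <- 0.3; v0 <- 0.7; dt <- 0.5
  H <- evaluate_rhs(apf, u, v0)$H[1, 1]
  v1 <- ionic_step(apf, u, matrix(v0, 1), dt, bdf_scheme(1))
  expect_equal(v1[1, 1], v0 + dt * H, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("implicit gates are unconditionally stable for any step size", {
  bo <- ionic_model("BuenoOrovio")
  for (dt in c(1e-3, 1, 1e3, 1e6)) {
    w <- matrix(c(1, 1, 0), 1)
    for (k in 1:20) w <- ionic_step(bo, 0.5, w, dt, bdf_scheme(1))
    expect_true(all(is.finite(w)) && all(w >= 0 & w <= 1))
  }
})

test_that("overriding a parameter and restoring it reproduces the trajectory", {
  base <- ionic_model("TTP06")
  tweaked <- ionic_model("TTP06", overrides = list(GNa = 10))
  restored <- ionic_model("TTP06", overrides = list(GNa = 14.838))
  run <- function(mod) single_cell_run(mod, period = 0.05, n_cycles = 1,
                                       dt = 1e-4, stim_amplitude = 60,
                                       stim_duration = 2e-3)
  expect_identical(run(base)$u, run(restored)$u)
  expect_false(identical(run(base)$u, run(tweaked)$u))
  expect_error(ionic_model("TTP06", overrides = list(nonsense = 1)),
               "valid names")
})

test_that("potential rescaling matches the published formulas", {
  apf <- ionic_model("AlievPanfilov")
  expect_equal(rescale_potential(apf, 0), -80)
  expect_equal(rescale_potential(apf, 1), 20)
  bo <- ionic_model("BuenoOrovio")
  expect_equal(rescale_potential(bo, 0), -84)
  ttp <- ionic_model("TTP06")
  expect_identical(rescale_potential(ttp, -85.23), -85.23)
})

test_that("membrane normalisation rescales the capacitance form", {
  sc <- membrane_scaling(C_m = 1, chi_m = 1)
  out <- normalize_formulation(2, 3, 4, sc)
  expect_identical(out, list(I_ion = 2, I_app = 3, D = 4))
  sc2 <- membrane_scaling(C_m = 0.01, chi_m = 1.4e5)
  out1 <- normalize_formulation(0, 0, 1, sc2)
  out2 <- normalize_formulation(0, 0, 2, sc2)
  expect_equal(out2$D, 2 * out1$D)
  # the slab benchmark convention: 5e4 A/m^3 over chi*Cm gives 35.714 V/s
  expect_equal(normalize_formulation(0, 35.714 * 0.01, 0, sc2)$I_app,
               35.714, tolerance = 1e-12)
  expect_error(membrane_scaling(-1, 1), "positive")
})

test_that("paced single cells fire and settle towards a limit cycle", {
  apf <- ionic_model("AlievPanfilov")
  out <- single_cell_run(apf, period = 0.5, n_cycles = 4, dt = 5e-5,
                         stim_amplitude = 150, stim_duration = 2e-3,
                         trace_every = 10)
  expect_gt(max(out$trace$u), 0.9)          # an action potential occurred
  expect_true(all(out$trace$u >= -1e-6 & out$trace$u <= 1 + 1e-2))
  # cycle-to-cycle distance shrinks towards the periodic steady state
  expect_lt(utils::tail(out$cycle_deltas, 1), out$cycle_deltas[1])
  # zero stimulus preserves equilibrium exactly at rest
  o0 <- single_cell_run(apf, period = 0.1, n_cycles = 1, dt = 1e-4,
                        stim_amplitude = 0)
  expect_lt(abs(o0$u - apf$u0), 1e-8)
  expect_lt(max(abs(o0$w - apf$w0)), 1e-8)
})

test_that("single-cell runs write a usable CSV trace", {
  ttp <- ionic_model("TTP06")
  path <- withr::local_tempfile(fileext = ".csv")
  out <- single_cell_run(ttp, period = 0.02, n_cycles = 1, dt = 1e-4,
                         stim_amplitude = 60, stim_duration = 2e-3,
                         trace_every = 5, trace_file = path)
  tr <- utils::read.csv(path)
  expect_identical(names(tr), c("time", "u", ttp$var_names))
  expect_equal(tr$u[nrow(tr)], out$u, tolerance = 1e-12)
})
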