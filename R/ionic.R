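# The cellular layer: model registry (parameters, initial states, units),
# right-hand-side evaluation, the IMEX ionic update, single-cell pacing, and
# potential rescaling.
#
# Every model runs in its native units -- millivolts (TTP06, CRN) or a
# dimensionless potential (Aliev-Panfilov, Bueno-Orovio) -- with time in
# milliseconds.  `unit_scale` converts one model potential unit to tissue
# volts; ionic rates convert to SI with I_SI = I_model * unit_scale * 1000.

# Bueno-Orovio parameter sets (epicardial / endocardial / mid-myocardial)
.bo_param_names <- c(
  "u_o", "u_u", "theta_v", "theta_w", "theta_vminus", "theta_o",
  "tau_v1minus", "tau_v2minus", "tau_vplus", "tau_w1minus", "tau_w2minus",
  "k_wminus", "u_wminus", "tau_wplus", "tau_fi", "tau_o1", "tau_o2",
  "tau_so1", "tau_so2", "k_so", "u_so", "tau_s1", "tau_s2", "k_s", "u_s",
  "tau_si", "tau_winf", "w_infstar")
.bo_sets <- list(
  Epicardium = c(0, 1.55, 0.3, 0.13, 0.006, 0.006, 60, 1150, 1.4506, 60, 15,
                 65, 0.03, 200, 0.11, 400, 6, 30.0181, 0.9957, 2.0458, 0.65,
                 2.7342, 16, 2.0994, 0.9087, 1.8875, 0.07, 0.94),
  Endocardium = c(0, 1.56, 0.3, 0.13, 0.2, 0.006, 75, 10, 1.4506, 6, 140,
                  200, 0.016, 280, 0.1, 470, 6, 40, 1.2, 2, 0.65,
                  2.7342, 2, 2.0994, 0.9087, 2.9013, 0.0273, 0.78),
  Myocardium = c(0, 1.61, 0.3, 0.13, 0.1, 0.005, 80, 1.4506, 1.4506, 70, 8,
                 200, 0.016, 280, 0.078, 410, 7, 91, 0.8, 2.1, 0.6,
                 2.7342, 4, 2.0994, 0.9087, 3.3849, 0.01, 0.5))

.model_registry <- local({
  reg <- list()

  reg$AlievPanfilov <- list(
    id = 1L, M = 1L, var_names = "v",
    params = c(k = 8, a = 0.15, eps0 = 0.002, mu1 = 0.2, mu2 = 0.3,
               time_scale_ms = 12.9),
    u0 = 0, w0 = 0,
    unit_scale = 1,            # dimensionless potential at the tissue level
    rescale = c(a = 100, b = -80),  # u_mV = 100 u - 80
    cell_types = NULL)

  reg$BuenoOrovio <- list(
    id = 2L, M = 3L, var_names = c("v", "w", "s"),
    params = stats::setNames(.bo_sets$Epicardium, .bo_param_names),
    u0 = 0, w0 = c(1, 1, 0),
    unit_scale = 1,
    rescale = c(a = 85.7, b = -84),
    cell_types = names(.bo_sets))

  reg$TTP06 <- list(
    id = 3L, M = 18L,
    var_names = c("Cai", "CaSR", "Cass", "Nai", "Ki", "m", "h", "j",
                  "xr1", "xr2", "xs", "r", "s", "d", "f", "f2", "fCass",
                  "Rbar"),
    params = c(GNa = 14.838, GCaL = 3.98e-5, Gto = 0.294, Gkr = 0.153,
               Gks = 0.392, GK1 = 5.405, GpCa = 0.1238, GpK = 0.0146,
               GbNa = 0.00029, GbCa = 0.000592, knak = 2.724,
               knaca = 1000, Ko = 5.4, Nao = 140, Cao = 2,
               Vmaxup = 0.006375, Vrel = 0.102, Vleak = 0.00036,
               Vxfer = 0.0038, k1prime = 0.15, k2prime = 0.045, k3 = 0.06,
               k4 = 0.005, cell_code = 0),
    u0 = -85.23,
    w0 = c(0.000126, 3.64, 0.00036, 8.604, 136.89,
           0.00172, 0.7444, 0.7045, 0.00621, 0.4712, 0.0095,
           2.42e-8, 0.999998, 3.373e-5, 0.7888, 0.9755, 0.9953, 0.9073),
    unit_scale = 1e-3,         # model mV -> tissue V
    rescale = c(a = 1, b = 0), # already millivolts
    cell_types = c("Epicardium", "Endocardium", "Myocardium"))

  reg$CRN <- list(
    id = 4L, M = 20L,
    var_names = c("Nai", "Ki", "Cai", "Caup", "Carel", "m", "h", "j",
                  "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fca",
                  "u", "v", "w"),
    params = c(gNa = 7.8, gK1 = 0.09, gto = 0.1652, gKur_fix = 0.005,
               gKur_var = 0.05, gKr = 0.0294, gKs = 0.129, gCaL = 0.1238,
               INaK_max = 0.59933874, INaCa_max = 1600, IpCa_max = 0.275,
               gbNa = 0.0006744375, gbCa = 0.001131, krel = 30),
    u0 = -81.18,
    w0 = c(11.17, 139.0, 1.013e-4, 1.488, 1.488,
           2.908e-3, 0.9649, 0.9775, 3.043e-2, 0.9992, 4.966e-3, 0.9986,
           3.296e-5, 1.869e-2, 1.367e-4, 0.9996, 0.7755, 0, 1, 0.9992),
    unit_scale = 1e-3,
    rescale = c(a = 1, b = 0),
    cell_types = NULL)

  reg
})

#' Available ionic models
#' @return character vector of model names.
#' @export
ionic_model_names <- function() names(.model_registry)

#' Construct an ionic model specification
#'
#' Resolves a named model, a cell-type variant where the model has one
#' (TTP06: Epicardium / Endocardium / Myocardium, changing the transient
#' outward and slow-delayed-rectifier conductances and the s-gate kinetics;
#' Bueno-Orovio: the three published parameter sets), and per-region
#' parameter overrides.  Unknown override names are rejected with the list
#' of valid names.
#'
#' @param name one of [ionic_model_names()].
#' @param cell_type optional variant name.
#' @param overrides named list/vector of parameter values replacing the
#'   published defaults.
#' @return object of class `ionic_model`: fields `name`, `M` (number of
#'   ionic variables), `var_names`, `params`, `u0`/`w0` (initial state,
#'   model units), `unit_scale`, `rescale`.
#' @export
ionic_model <- function(name, cell_type = NULL, overrides = list()) {
  if (!name %in% names(.model_registry)) {
    stop(sprintf("unknown ionic model '%s' (available: %s)", name,
                 paste(names(.model_registry), collapse = ", ")))
  }
  base <- .model_registry[[name]]
  params <- base$params
  if (!is.null(cell_type)) {
    if (is.null(base$cell_types) || !cell_type %in% base$cell_types) {
      stop(sprintf("model %s has no cell type '%s'", name, cell_type))
    }
    if (name == "TTP06") {
      params["cell_code"] <- match(cell_type, base$cell_types) - 1
      if (cell_type == "Endocardium") params["Gto"] <- 0.073
      if (cell_type == "Myocardium") params["Gks"] <- 0.098
    } else if (name == "BuenoOrovio") {
      params <- stats::setNames(.bo_sets[[cell_type]], .bo_param_names)
    }
  } else if (!is.null(base$cell_types)) {
    cell_type <- base$cell_types[1]
  }
  overrides <- unlist(overrides)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad)) {
      stop(sprintf("unknown parameter override(s) %s for model %s; valid names: %s",
                   paste(bad, collapse = ", "), name,
                   paste(names(params), collapse = ", ")))
    }
    params[names(overrides)] <- overrides
  }
  structure(
    list(name = name, id = base$id, M = base$M, var_names = base$var_names,
         cell_type = cell_type, params = params,
         u0 = base$u0, w0 = base$w0, unit_scale = base$unit_scale,
         rescale = base$rescale),
    class = "ionic_model")
}

#' @export
print.ionic_model <- function(x, ...) {
  cat(sprintf("<ionic_model> %s%s, %d ionic variables, u0 = %g\n", x$name,
              if (is.null(x$cell_type)) "" else paste0(" (", x$cell_type, ")"),
              x$M, x$u0))
  invisible(x)
}

#' Evaluate the ionic right-hand sides
#'
#' Returns \eqn{I_{ion}(u, w)} and \eqn{H(u, w)} of the cellular ODE system
#' \eqn{du/dt + I_{ion} = I_{app}}, \eqn{dw/dt = H}, in model units (per
#' millisecond; for the millivolt-based models mV/ms coincides numerically
#' with V/s).
#'
#' @param model an [ionic_model()].
#' @param u potential, model units (scalar or length-n).
#' @param w ionic state: length-M vector or n x M matrix.
#' @return list with `Iion` (length n) and `H` (n x M).
#' @export
evaluate_rhs <- function(model, u, w) {
  stopifnot(inherits(model, "ionic_model"))
  w <- .as_state_matrix(w, length(u), model$M)
  if (!all(is.finite(u)) || !all(is.finite(w))) stop("state must be finite")
  out <- ionic_rhs_cpp(model$id, as.numeric(u), w, unname(model$params))
  colnames(out$H) <- model$var_names
  out
}

.as_state_matrix <- function(w, n, M) {
  if (is.matrix(w)) {
    if (ncol(w) != M) stop(sprintf("w must have %d columns", M))
    w
  } else {
    if (length(w) != M) stop(sprintf("w must have length %d", M))
    matrix(w, n, M, byrow = TRUE)
  }
}

#' One IMEX update of the ionic variables
#'
#' Solves the time-discrete ionic equations
#' \eqn{(\alpha w_{n+1} - w_{BDF,n})/\Delta t = H(u_{EXT}, w_{EXT}, w_{n+1})}
#' by direct inversion: Hodgkin-Huxley-type gating variables (dynamics
#' affine in the gate at frozen drivers) are advanced with the closed-form
#' implicit formula; all other variables explicitly from the extrapolated
#' state.  No iterative nonlinear solve is involved.  Gates are clamped to
#' `[0, 1]` (clamp count returned as attribute `"clamped"`).
#'
#' @param model an [ionic_model()].
#' @param u_ext extrapolated potential (model units), length n.
#' @param w_history list of past states (n x M matrices), most recent first;
#'   depth must be at least the scheme order.
#' @param dt time step in milliseconds.
#' @param scheme a [bdf_scheme()].
#' @return n x M matrix \eqn{w_{n+1}}.
#' @export
ionic_step <- function(model, u_ext, w_history, dt, scheme = bdf_scheme(1)) {
  stopifnot(inherits(model, "ionic_model"), inherits(scheme, "bdf_scheme"))
  if (dt <= 0) stop("dt must be positive")
  if (!is.list(w_history)) w_history <- list(w_history)
  if (length(w_history) < scheme$order) {
    stop("history depth must be at least the scheme order")
  }
  n <- length(u_ext)
  w_history <- lapply(w_history, .as_state_matrix, n = n, M = model$M)
  w_bdf <- bdf_combine(scheme$bdf_weights, w_history)
  w_ext <- bdf_combine(scheme$ext_weights, w_history)
  out <- ionic_step_cpp(model$id, as.numeric(u_ext), w_bdf, w_ext,
                        dt, scheme$alpha, unname(model$params))
  colnames(out) <- model$var_names
  out
}

#' Rescale a model potential to millivolts
#'
#' Phenomenological models evolve a dimensionless potential; for output the
#' physiological millivolt scale is recovered as \eqn{u_{mV} = a u + b}
#' (Aliev-Panfilov: \eqn{100u - 80}; Bueno-Orovio: \eqn{85.7u - 84}).  The
#' millivolt-based models pass through unchanged.
#'
#' @param model an [ionic_model()].
#' @param u potential in model units.
#' @return potential in millivolts.
#' @export
rescale_potential <- function(model, u) {
  stopifnot(inherits(model, "ionic_model"))
  model$rescale[["a"]] * u + model$rescale[["b"]]
}

#' Membrane scaling constants
#'
#' @param C_m membrane capacitance per unit area (F/m^2), positive.
#' @param chi_m membrane surface-to-volume ratio (1/m), positive.
#' @return object of class `membrane_scaling`.
#' @export
membrane_scaling <- function(C_m, chi_m) {
  if (!is.finite(C_m) || C_m <= 0 || !is.finite(chi_m) || chi_m <= 0) {
    stop("C_m and chi_m must be positive")
  }
  structure(list(C_m = C_m, chi_m = chi_m), class = "membrane_scaling")
}

#' Rescale the capacitance-form monodomain data
#'
#' The monodomain equation is often written with explicit \eqn{\chi_m} and
#' \eqn{C_m}; this converts its data to the normalised form used here:
#' \eqn{I_{ion} = \hat I_{ion} / C_m}, \eqn{I_{app} = \hat I_{app} / C_m},
#' \eqn{D = \hat D / (\chi_m C_m)}.
#'
#' @param I_ion_hat,I_app_hat currents in the capacitance form.
#' @param D_hat conductivity (tensor entries or scalars) in the capacitance
#'   form.
#' @param scaling a [membrane_scaling()].
#' @return list with rescaled `I_ion`, `I_app`, `D`.
#' @export
normalize_formulation <- function(I_ion_hat, I_app_hat, D_hat, scaling) {
  stopifnot(inherits(scaling, "membrane_scaling"))
  list(I_ion = I_ion_hat / scaling$C_m,
       I_app = I_app_hat / scaling$C_m,
       D = D_hat / (scaling$chi_m * scaling$C_m))
}

#' Single-cell pacing run
#'
#' Integrates the ionic model in 0D with a periodic square stimulus, using
#' the same IMEX BDF update as the tissue solver.  Used to bring a model to
#' its periodic steady state before a tissue simulation (the final state
#' becomes the tissue initial condition).
#'
#' @param model an [ionic_model()].
#' @param period pacing cycle length in seconds.
#' @param n_cycles number of cycles.
#' @param dt time step in seconds.
#' @param stim_amplitude stimulus amplitude in tissue units per second
#'   (V/s for millivolt models); applied from the start of each cycle.
#' @param stim_duration stimulus duration in seconds.
#' @param scheme a [bdf_scheme()] (default order 1).
#' @param trace_every record every k-th step in the returned trace
#'   (0 disables the trace).
#' @param trace_file optional CSV path for the trace (columns time, u,
#'   ionic variables; SI seconds, model potential units).
#' @return list with `u` (final potential, model units), `w` (final ionic
#'   state), `trace` (data.frame or NULL), `cycle_deltas` (L2 distance
#'   between consecutive end-of-cycle states).
#' @export
single_cell_run <- function(model, period, n_cycles, dt,
                            stim_amplitude = 0, stim_duration = 0.001,
                            scheme = bdf_scheme(1), trace_every = 0L,
                            trace_file = NULL) {
  stopifnot(inherits(model, "ionic_model"))
  if (!(period > stim_duration && stim_duration > 0) && stim_amplitude != 0) {
    stop("need period > stimulus duration > 0")
  }
  if (dt <= 0 || dt > period) stop("need 0 < dt <= period")
  dt_ms <- dt * 1000
  # stimulus in model units per ms
  amp_model <- stim_amplitude / model$unit_scale / 1000
  steps_per_cycle <- round(period / dt)
  if (abs(steps_per_cycle * dt - period) > 1e-9 * period) {
    steps_per_cycle <- ceiling(period / dt)
  }
  u <- model$u0
  w <- matrix(model$w0, 1L, model$M)
  depth <- scheme$order
  u_hist <- rep(list(u), depth)
  w_hist <- rep(list(w), depth)
  trace <- NULL
  if (trace_every > 0L) {
    nrec <- floor(steps_per_cycle * n_cycles / trace_every) + 1L
    trace <- matrix(NA_real_, nrec, 2L + model$M)
    trace[1L, ] <- c(0, u, w)
    irec <- 1L
  }
  end_states <- list()
  step_idx <- 0L
  for (cyc in seq_len(n_cycles)) {
    for (sstep in seq_len(steps_per_cycle)) {
      step_idx <- step_idx + 1L
      # bootstrap: effective order grows with available history
      eff <- bdf_scheme(min(scheme$order, step_idx))
      uh <- u_hist[seq_len(eff$order)]
      wh <- w_hist[seq_len(eff$order)]
      u_ext <- bdf_combine(eff$ext_weights, uh)
      w_new <- ionic_step(model, u_ext, wh, dt_ms, eff)
      Iion <- ionic_current_cpp(model$id, u_ext, w_new,
                                unname(model$params))
      t_new <- step_idx * dt
      # applied current evaluated at t_{n+1} (as in the tissue loop), with
      # the half-open gate [0, duration) relative to the cycle start
      tins <- sstep * dt
      Iapp <- if (tins < stim_duration) amp_model else 0
      u_bdf <- bdf_combine(eff$bdf_weights, uh)
      u_new <- (u_bdf + dt_ms * (Iapp - Iion)) / eff$alpha
      if (!is.finite(u_new) || !all(is.finite(w_new))) {
        stop(sprintf("single-cell state diverged in cycle %d (t = %g s)",
                     cyc, t_new))
      }
      u_hist <- c(list(u_new), utils::head(u_hist, depth - 1L))
      w_hist <- c(list(w_new), utils::head(w_hist, depth - 1L))
      u <- u_new; w <- w_new
      if (trace_every > 0L && step_idx %% trace_every == 0L) {
        irec <- irec + 1L
        trace[irec, ] <- c(t_new, u, w)
      }
    }
    end_states[[cyc]] <- c(u, w)
  }
  cycle_deltas <- if (n_cycles >= 2) {
    vapply(2:n_cycles, function(c_) {
      sqrt(sum((end_states[[c_]] - end_states[[c_ - 1]])^2))
    }, 0)
  } else numeric(0)
  if (!is.null(trace)) {
    trace <- as.data.frame(trace[seq_len(irec), , drop = FALSE])
    names(trace) <- c("time", "u", model$var_names)
    if (!is.null(trace_file)) {
      utils::write.csv(trace, trace_file, row.names = FALSE)
    }
  }
  list(u = u, w = drop(w), trace = trace, cycle_deltas = cycle_deltas)
}
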