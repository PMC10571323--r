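# The tissue solver: monodomain problem assembly, the IMEX BDF time loop
# with ionic current interpolation (ICI), online activation mapping, and
# checkpoint/restore.
#
# Tissue units are SI: potential in volts for millivolt-based ionic models
# (u_tissue = 1e-3 * u_model), dimensionless for the phenomenological
# models; time in seconds.  All models in one problem must share the same
# potential unit.

#' Ionic current interpolation vector
#'
#' \eqn{s_{n+1} = \sum_i M^i I^i_{ion,n+1}}: per-subdomain mass matrices
#' applied to the nodal ionic current evaluations (ICI: currents evaluated
#' at DOF support points, interpolated onto quadrature nodes by the mass
#' matrix).
#'
#' @param I_list list of full-length nodal ionic current vectors, one per
#'   subdomain (zero outside the subdomain's DOF set).
#' @param M_list list of matching per-subdomain mass matrices.
#' @return the assembled right-hand-side vector `s`.
#' @export
ici_ionic_vector <- function(I_list, M_list) {
  if (length(I_list) != length(M_list)) {
    stop("I_list and M_list must have the same length")
  }
  n <- nrow(M_list[[1]])
  s <- numeric(n)
  for (i in seq_along(I_list)) {
    if (length(I_list[[i]]) != n) stop("dimension mismatch in ICI vectors")
    s <- s + as.vector(M_list[[i]] %*% I_list[[i]])
  }
  s
}

#' Define a monodomain problem
#'
#' Binds together the discrete domain (partition with per-subdomain ionic
#' models and conductivities), the fiber frame, the stimulation protocol,
#' and the numerical settings of the IMEX BDF solver.
#'
#' @param partition a [build_subdomains()] partition.
#' @param frame a [fiber_frame()] on the mesh nodes.
#' @param protocol a [stimulus_protocol()].
#' @param models named list mapping subdomain labels to [ionic_model()]
#'   objects; labels may be omitted for non-conductive subdomains.
#' @param dt time step (s).
#' @param t_end final time (s), `dt <= t_end`.
#' @param scheme_order BDF order (1-3); startup bootstraps from order 1.
#' @param initial optional named list mapping labels to `list(u, w)` initial
#'   states in model units (e.g. from [single_cell_run()]); defaults to each
#'   model's published initial state.
#' @param solver list: `method` ("cholesky" or "cg"), `tol` (relative
#'   residual for CG), `maxit`.
#' @param activation_threshold minimum du/dt (tissue units per second) for a
#'   DOF to count as activated (default 10).
#' @param output list: `every` (steps between recorded snapshots; 0 none),
#'   `points` (m x 3 probe coordinates for pointwise traces).
#' @return object of class `monodomain_problem`.
#' @export
monodomain_problem <- function(partition, frame, protocol, models,
                               dt, t_end, scheme_order = 2L,
                               initial = NULL,
                               solver = list(method = "cholesky",
                                             tol = 1e-10, maxit = 10000L),
                               activation_threshold = 10,
                               output = list(every = 0L, points = NULL)) {
  stopifnot(inherits(partition, "subdomain_partition"),
            inherits(frame, "fiber_frame"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.finite(dt) || dt <= 0 || dt > t_end) stop("need 0 < dt <= t_end")
  cond <- which(partition$conductive)
  mods <- vector("list", length(partition$specs))
  for (i in cond) {
    lab <- partition$labels[i]
    m <- models[[lab]]
    if (is.null(m)) {
      # fall back to the model named in the subdomain_spec
      nm <- partition$specs[[i]]$ionic_model
      if (is.null(nm) || is.na(nm)) {
        stop(sprintf("conductive subdomain '%s' has no ionic model", lab))
      }
      m <- ionic_model(nm, overrides = partition$specs[[i]]$overrides)
    }
    stopifnot(inherits(m, "ionic_model"))
    mods[[i]] <- m
  }
  scales <- unique(vapply(mods[cond], `[[`, 0, "unit_scale"))
  if (length(scales) != 1L) {
    stop("all ionic models in one problem must share the same potential unit")
  }
  solver <- utils::modifyList(list(method = "cholesky", tol = 1e-10,
                                   maxit = 10000L), solver)
  output <- utils::modifyList(list(every = 0L, points = NULL), output)
  structure(
    list(partition = partition, frame = frame, protocol = protocol,
         models = mods, dt = dt, t_end = t_end,
         scheme_order = as.integer(scheme_order),
         initial = initial, solver = solver,
         activation_threshold = activation_threshold,
         unit_scale = scales, output = output),
    class = "monodomain_problem")
}

# Assemble the operators of a problem once: the mass over the conductive
# domain, the stiffness, the stacked per-element ICI operator, and caches
# for the system matrices/factorisations per effective BDF order (startup
# uses lower orders).  Pre-applies the mass matrix to each stimulus support
# vector.
#
# The ICI vector s = sum_i M^i I^i is evaluated element by element: the
# stacked operator P holds every element's local mass block (columns
# indexed by (element, local node)), and the stacked current vector takes
# each element's nodal currents from the ionic state of the subdomain that
# owns the element.  This is algebraically identical to applying the
# per-subdomain mass matrices, and its floating-point result is independent
# of how the conductive elements are partitioned into subdomains.
assemble_operators <- function(prob) {
  part <- prob$partition
  space <- part$space
  cond <- which(part$conductive)
  cond_elems <- sort(unlist(part$elem_sets[cond]))
  Mc <- assemble_mass(space, cond_elems)
  K <- assemble_stiffness(space, prob$frame, part)
  blocks <- .element_matrices(space, cond_elems, "mass")
  nb <- blocks$nb
  Ec <- length(cond_elems)
  ia <- as.vector(blocks$dofs[, rep(seq_len(nb), times = nb), drop = FALSE])
  pair_b <- rep(seq_len(nb), each = nb)        # b of each (a, b) pair
  ja <- rep((seq_len(Ec) - 1L) * nb, times = nb * nb) +
    rep(pair_b, each = Ec)
  P <- Matrix::sparseMatrix(i = ia, j = ja, x = as.vector(blocks$Ke),
                            dims = c(space$n_dofs, Ec * nb))
  # per-subdomain scatter maps into the stacked current vector
  stack <- vector("list", length(part$specs))
  for (i in cond) {
    loc <- match(part$elem_sets[[i]], cond_elems)
    ne <- length(loc)
    scol <- rep((loc - 1L) * nb, times = nb) + rep(seq_len(nb), each = ne)
    dofv <- as.vector(space$elem_dofs[part$elem_sets[[i]], , drop = FALSE])
    stack[[i]] <- list(col = scol, pos = match(dofv, part$dof_sets[[i]]))
  }
  act <- part$active_dofs
  stim_vec <- lapply(prob$protocol$stimuli, function(s) {
    gx <- stimulus_support(s, space$support_points)
    as.vector(Mc %*% gx)
  })
  list(Mc = Mc, K = K, P = P, stack = stack, n_stack = Ec * nb,
       active = act, stim_vec = stim_vec, A = list(), factor = list(),
       space = space)
}

# system matrix/solver for one effective order, cached
.get_factor <- function(ops, prob, order) {
  key <- as.character(order)
  if (!is.null(ops$factor[[key]])) return(ops)
  sch <- bdf_scheme(order)
  A <- build_system_matrix(sch, prob$dt, ops$Mc, ops$K)
  Aact <- A[ops$active, ops$active, drop = FALSE]
  ops$A[[key]] <- Aact
  if (prob$solver$method == "cholesky") {
    ops$factor[[key]] <- Matrix::Cholesky(Matrix::forceSymmetric(Aact),
                                          LDL = FALSE, super = TRUE)
  } else {
    ops$factor[[key]] <- "cg"
  }
  ops
}

# Jacobi-preconditioned conjugate gradients (A SPD)
.cg_solve <- function(A, b, x0, tol, maxit) {
  d <- Matrix::diag(A)
  x <- x0
  r <- b - as.vector(A %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(length(b)), iters = 0L))
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bnorm) {
      return(list(x = x, iters = it))
    }
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf(
    "CG did not converge in %d iterations (relative residual %.3e)",
    maxit, sqrt(sum(r^2)) / bnorm))
}

# initial state of the time loop
init_state <- function(prob) {
  part <- prob$partition
  space <- part$space
  n <- space$n_dofs
  cond <- which(part$conductive)
  u <- numeric(n)
  w <- vector("list", length(part$specs))
  for (i in cond) {
    mod <- prob$models[[i]]
    dofs <- part$dof_sets[[i]]
    ini <- prob$initial[[part$labels[i]]]
    u0 <- if (!is.null(ini)) ini$u else mod$u0
    w0 <- if (!is.null(ini)) ini$w else mod$w0
    u[dofs] <- u0 * mod$unit_scale
    w[[i]] <- matrix(w0, length(dofs), mod$M, byrow = TRUE)
  }
  depth <- prob$scheme_order
  list(step = 0L, t = 0,
       u_hist = rep(list(u), depth),
       w_hist = lapply(w, function(wi) if (is.null(wi)) NULL
                       else rep(list(wi), depth)),
       act_best = rep(-Inf, n), act_time = rep(NA_real_, n),
       clamped = 0L)
}

#' Advance a monodomain state by one time step
#'
#' One IMEX step: (i) ionic variables updated per subdomain at every DOF
#' with the extrapolated potential; (ii) ionic current evaluated at
#' `(u_EXT, w_{n+1})` and assembled by ICI; (iii) right-hand side
#' \eqn{(1/\Delta t) M u_{BDF,n} - s_{n+1} + f_{n+1}}; (iv) one SPD solve
#' with the cached system matrix.  Histories rotate; the online activation
#' tracker records the time of the running-maximum du/dt.
#'
#' @param prob a [monodomain_problem()].
#' @param ops operators from `assemble_operators` (rebuilt if `NULL`).
#' @param state loop state from `init_state` (created if `NULL`).
#' @return list `(state, ops)` with the advanced state.
#' @export
monodomain_step <- function(prob, ops = NULL, state = NULL) {
  if (is.null(ops)) ops <- assemble_operators(prob)
  if (is.null(state)) state <- init_state(prob)
  part <- prob$partition
  cond <- which(part$conductive)
  dt <- prob$dt
  dt_ms <- dt * 1000
  us <- prob$unit_scale
  eff_order <- min(prob$scheme_order, state$step + 1L)
  sch <- bdf_scheme(eff_order)
  ops <- .get_factor(ops, prob, eff_order)

  uh <- state$u_hist[seq_len(eff_order)]
  u_ext <- bdf_combine(sch$ext_weights, uh)
  u_bdf <- bdf_combine(sch$bdf_weights, uh)

  n <- length(u_ext)
  cstack <- numeric(ops$n_stack)
  for (i in cond) {
    mod <- prob$models[[i]]
    dofs <- part$dof_sets[[i]]
    wh <- state$w_hist[[i]][seq_len(eff_order)]
    u_ext_model <- u_ext[dofs] / us
    w_new <- ionic_step(mod, u_ext_model, wh, dt_ms, sch)
    state$clamped <- state$clamped + attr(w_new, "clamped")
    Iion <- ionic_current_cpp(mod$id, u_ext_model, w_new,
                              unname(mod$params)) * us * 1000  # SI
    cstack[ops$stack[[i]]$col] <- Iion[ops$stack[[i]]$pos]
    state$w_hist[[i]] <- c(list(w_new),
                           state$w_hist[[i]][seq_len(prob$scheme_order - 1L)])
  }
  s_vec <- as.vector(ops$P %*% cstack)
  t_new <- (state$step + 1L) * dt
  f_vec <- numeric(n)
  for (k in seq_along(prob$protocol$stimuli)) {
    g <- .time_gate(prob$protocol$stimuli[[k]], t_new)
    if (g > 0) {
      f_vec <- f_vec + prob$protocol$stimuli[[k]]$amplitude * g *
        ops$stim_vec[[k]]
    }
  }
  rhs <- (1 / dt) * as.vector(ops$Mc %*% u_bdf) - s_vec + f_vec
  u_new <- state$u_hist[[1]]
  actd <- ops$active
  key <- as.character(eff_order)
  if (prob$solver$method == "cholesky") {
    u_new[actd] <- as.vector(Matrix::solve(ops$factor[[key]], rhs[actd],
                                           system = "A"))
  } else {
    sol <- .cg_solve(ops$A[[key]], rhs[actd], state$u_hist[[1]][actd],
                     prob$solver$tol, prob$solver$maxit)
    u_new[actd] <- sol$x
  }
  if (!all(is.finite(u_new[actd]))) {
    stop(sprintf("non-finite potential at step %d (t = %g s)",
                 state$step + 1L, t_new))
  }
  # online activation: running max of backward-difference du/dt
  dudt <- (u_new - state$u_hist[[1]]) / dt
  better <- dudt > state$act_best & dudt > prob$activation_threshold
  state$act_time[better] <- t_new
  state$act_best <- pmax(state$act_best, dudt)
  state$u_hist <- c(list(u_new),
                    state$u_hist[seq_len(prob$scheme_order - 1L)])
  state$step <- state$step + 1L
  state$t <- t_new
  list(state = state, ops = ops)
}

#' Run a monodomain simulation
#'
#' Executes `round(t_end/dt)` IMEX steps, recording the configured outputs,
#' and returns the final state together with the activation map and traces.
#'
#' @param prob a [monodomain_problem()].
#' @param state optional state to resume from (see [checkpoint()] /
#'   [restore()]).
#' @param progress print a progress line every this many steps (0 silent).
#' @return object of class `monodomain_result`: `u` (final tissue
#'   potential), `state`, `activation` (an `activation_map`), `trace`
#'   (data.frame time/min/max and probe columns), `snapshots` (list of
#'   recorded potential vectors), `times` (snapshot times), `problem`.
#' @export
run_simulation <- function(prob, state = NULL, progress = 0L) {
  stopifnot(inherits(prob, "monodomain_problem"))
  ops <- assemble_operators(prob)
  if (is.null(state)) state <- init_state(prob)
  n_steps <- round(prob$t_end / prob$dt)
  every <- prob$output$every
  probes <- prob$output$points
  probe_idx <- NULL
  if (!is.null(probes)) {
    probes <- matrix(probes, ncol = 3)
  }
  trace_rows <- list()
  snapshots <- list()
  snap_times <- numeric(0)
  record <- function(state) {
    u <- state$u_hist[[1]]
    row <- c(time = state$t, min = min(u[ops$active]),
             max = max(u[ops$active]))
    if (!is.null(probes)) {
      pv <- fe_interpolate(prob$partition$space, u, probes)
      names(pv) <- paste0("p", seq_len(nrow(probes)))
      row <- c(row, pv)
    }
    trace_rows[[length(trace_rows) + 1L]] <<- row
    snapshots[[length(snapshots) + 1L]] <<- u
    snap_times[length(snap_times) + 1L] <<- state$t
  }
  if (every > 0L && state$step == 0L) record(state)
  while (state$step < n_steps) {
    res <- monodomain_step(prob, ops, state)
    state <- res$state
    ops <- res$ops
    if (every > 0L && state$step %% every == 0L) record(state)
    if (progress > 0L && state$step %% progress == 0L) {
      message(sprintf("step %d / %d (t = %.4f s)", state$step, n_steps,
                      state$t))
    }
  }
  act <- structure(
    list(time = state$act_time, peak_dudt = state$act_best,
         threshold = prob$activation_threshold,
         active_dofs = ops$active),
    class = "activation_map")
  trace <- if (length(trace_rows)) {
    as.data.frame(do.call(rbind, trace_rows))
  } else NULL
  if (state$clamped > 0L) {
    message(sprintf("gate clamping triggered %d time(s) during the run",
                    state$clamped))
  }
  structure(
    list(u = state$u_hist[[1]], state = state, activation = act,
         trace = trace, snapshots = snapshots, times = snap_times,
         problem = prob),
    class = "monodomain_result")
}

#' @export
print.monodomain_result <- function(x, ...) {
  act <- x$activation$time[x$activation$active_dofs]
  cat(sprintf("<monodomain_result> %d steps, t = %g s\n", x$state$step,
              x$state$t))
  cat(sprintf("  activated DOFs: %d / %d; latest activation: %s\n",
              sum(!is.na(act)), length(act),
              if (all(is.na(act))) "none" else
                sprintf("%.4g ms", max(act, na.rm = TRUE) * 1000)))
  invisible(x)
}

#' Activation map from a recorded potential time series
#'
#' Per DOF, the time at which the discrete derivative du/dt attains its
#' maximum (first occurrence on ties), provided the maximum exceeds the
#' activation threshold; otherwise the DOF is marked never activated
#' (`NA`).
#'
#' @param times snapshot times (s), strictly increasing, length >= 2.
#' @param U n x length(times) matrix of potentials (or a vector time series
#'   for a single DOF).
#' @param threshold minimum du/dt (units of U per second).
#' @return an `activation_map` (fields `time`, `peak_dudt`).
#' @export
activation_map <- function(times, U, threshold = 10) {
  if (is.vector(U)) U <- matrix(U, nrow = 1)
  if (length(times) < 2L) stop("need at least two time levels")
  dU <- (U[, -1, drop = FALSE] - U[, -ncol(U), drop = FALSE]) /
    rep(diff(times), each = nrow(U))
  best <- apply(dU, 1, max)
  idx <- apply(dU, 1, which.max)
  act <- times[-1][idx]
  act[best <= threshold] <- NA_real_
  structure(list(time = act, peak_dudt = best, threshold = threshold,
                 active_dofs = seq_len(nrow(U))),
            class = "activation_map")
}

# ---- checkpointing ----------------------------------------------------------

.checkpoint_version <- 1L

#' Serialize the solver state
#'
#' Writes the complete time-loop state (all histories, activation tracker,
#' step counter) with metadata (scheme order, dt, mesh fingerprint) so a
#' run can be paused and resumed bit-identically.
#'
#' @param state a solver state (e.g. `result$state`).
#' @param prob the owning [monodomain_problem()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
checkpoint <- function(state, prob, path) {
  payload <- list(version = .checkpoint_version,
                  meta = list(scheme_order = prob$scheme_order,
                              dt = prob$dt,
                              fingerprint = mesh_fingerprint(prob$partition$mesh)),
                  state = state)
  saveRDS(payload, path)
  invisible(path)
}

#' Restore a serialized solver state
#'
#' @param path checkpoint file from [checkpoint()].
#' @param prob the [monodomain_problem()] to resume; its scheme order, time
#'   step, and mesh fingerprint must match the checkpoint metadata.
#' @return the restored state.
#' @export
restore <- function(path, prob) {
  payload <- readRDS(path)
  if (!identical(payload$version, .checkpoint_version)) {
    stop("checkpoint version mismatch")
  }
  meta <- payload$meta
  if (!identical(meta$scheme_order, prob$scheme_order) ||
      !identical(meta$dt, prob$dt)) {
    stop("checkpoint was written with different solver settings")
  }
  fp <- mesh_fingerprint(prob$partition$mesh)
  if (!isTRUE(all.equal(meta$fingerprint, fp, tolerance = 0))) {
    stop("checkpoint belongs to a different mesh")
  }
  payload$state
}
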