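# Applied current: I_app(x, t) = sum_i g_t^i(t) g_x^i(x), with indicator
# space shapes (cube, sphere, plane slab) or a peak-1 Gaussian, and
# half-open time gates [t0, t0 + duration) supporting pulse trains.

#' Define one stimulus
#'
#' @param shape `"cube"`, `"sphere"`, `"plane"` or `"gaussian"`.
#' @param center length-3 centre (m) for cube/sphere/gaussian.
#' @param half_width half edge length (m) of the cube.
#' @param radius sphere radius (m).
#' @param normal,offset,thickness plane-slab geometry: points with
#'   `|dot(x, normal) - offset| <= thickness/2` are stimulated.
#' @param width Gaussian standard deviation (m); the spatial profile is
#'   `exp(-|x - center|^2 / (2 width^2))` with peak 1 at the centre, so the
#'   amplitude is read directly in V/s.
#' @param amplitude stimulus amplitude (V/s), non-negative.
#' @param duration pulse duration (s), positive.
#' @param initial_times start times of the pulses (s); alternatively use
#'   `period` and `count` as a shorthand for an evenly spaced train.
#' @param period,count optional train shorthand: `count` pulses starting at
#'   `initial_times[1]` (default 0) spaced by `period` seconds.
#' @return object of class `stimulus`.
#' @export
stimulus <- function(shape = c("cube", "sphere", "plane", "gaussian"),
                     center = c(0, 0, 0), half_width = NULL, radius = NULL,
                     normal = NULL, offset = 0, thickness = NULL,
                     width = NULL, amplitude = 0, duration = 1e-3,
                     initial_times = 0, period = NULL, count = NULL) {
  shape <- match.arg(shape)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(period) && !is.null(count)) {
    t0 <- if (length(initial_times)) initial_times[1] else 0
    initial_times <- t0 + period * (seq_len(count) - 1L)
  }
  initial_times <- sort(as.numeric(initial_times))
  geom <- switch(shape,
    cube = {
      if (is.null(half_width)) stop("cube stimulus needs half_width")
      list(center = center, half_width = half_width)
    },
    sphere = {
      if (is.null(radius)) stop("sphere stimulus needs radius")
      list(center = center, radius = radius)
    },
    plane = {
      if (is.null(normal) || is.null(thickness)) {
        stop("plane stimulus needs normal and thickness")
      }
      list(normal = normal / sqrt(sum(normal^2)), offset = offset,
           thickness = thickness)
    },
    gaussian = {
      if (is.null(width)) stop("gaussian stimulus needs width")
      list(center = center, width = width)
    })
  structure(c(list(shape = shape, amplitude = amplitude,
                   duration = duration, initial_times = initial_times),
              geom),
            class = "stimulus")
}

#' Stimulation protocol
#'
#' @param ... [stimulus()] objects (or one list of them).  An empty protocol
#'   yields identically zero applied current.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(...) {
  stims <- list(...)
  if (length(stims) == 1L && is.list(stims[[1]]) &&
      !inherits(stims[[1]], "stimulus")) {
    stims <- stims[[1]]
  }
  if (!all(vapply(stims, inherits, TRUE, "stimulus"))) {
    stop("all arguments must be stimulus objects")
  }
  structure(list(stimuli = stims), class = "stimulus_protocol")
}

#' Spatial support of a stimulus
#'
#' The indicator value (cube/sphere/plane) or Gaussian profile (peak 1 at
#' the centre) at the given points.
#'
#' @param stim a [stimulus()].
#' @param x points: length-3 vector or n x 3 matrix (m).
#' @return numeric vector of `g_x(x) >= 0`.
#' @export
stimulus_support <- function(stim, x) {
  stopifnot(inherits(stim, "stimulus"))
  x <- matrix(x, ncol = 3)
  switch(stim$shape,
    cube = {
      d <- abs(sweep(x, 2, stim$center))
      as.numeric(apply(d <= stim$half_width, 1, all))
    },
    sphere = {
      d2 <- rowSums(sweep(x, 2, stim$center)^2)
      as.numeric(d2 <= stim$radius^2)
    },
    plane = {
      d <- abs(as.vector(x %*% stim$normal) - stim$offset)
      as.numeric(d <= stim$thickness / 2)
    },
    gaussian = {
      d2 <- rowSums(sweep(x, 2, stim$center)^2)
      exp(-d2 / (2 * stim$width^2))
    })
}

# time gate: 1 on [t0, t0 + duration) for any of the pulse start times
.time_gate <- function(stim, t) {
  out <- numeric(length(t))
  for (t0 in stim$initial_times) {
    out <- pmax(out, as.numeric(t >= t0 & t < t0 + stim$duration))
  }
  out
}

#' Applied current of a protocol
#'
#' \eqn{I_{app}(x, t) = \sum_i A_i \, g^t_i(t) \, g^x_i(x)} with the time
#' gate equal to 1 on the half-open interval `[t0, t0 + duration)` of each
#' pulse.
#'
#' @param protocol a [stimulus_protocol()].
#' @param x points (length-3 vector or n x 3 matrix, m).
#' @param t time (s, scalar).
#' @return applied current (V/s) at each point.
#' @export
applied_current <- function(protocol, x, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  x <- matrix(x, ncol = 3)
  out <- numeric(nrow(x))
  for (stim in protocol$stimuli) {
    g_t <- .time_gate(stim, t)
    if (g_t > 0) {
      out <- out + stim$amplitude * g_t * stimulus_support(stim, x)
    }
  }
  out
}

# earliest/latest activity window of a protocol (used to size runs)
.protocol_window <- function(protocol) {
  if (!length(protocol$stimuli)) return(c(0, 0))
  lo <- min(vapply(protocol$stimuli, function(s) min(s$initial_times), 0))
  hi <- max(vapply(protocol$stimuli, function(s)
    max(s$initial_times) + s$duration, 0))
  c(lo, hi)
}
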