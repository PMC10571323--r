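# Myocardial fiber architecture: the orthonormal frame (f0, s0, n0) at mesh
# nodes, the transmural Laplace coordinate, the slab fiber rule, VTU
# import/export of fiber fields, and the anisotropic diffusion tensor.

# Gram-Schmidt on row triplets, fiber direction first.
.orthonormalise_rows <- function(f, s, n) {
  nf <- sqrt(rowSums(f^2))
  if (any(nf < 1e-12)) stop("zero-length fiber vector during orthonormalisation")
  f <- f / nf
  s <- s - f * rowSums(s * f)
  ns <- sqrt(rowSums(s^2))
  if (any(ns < 1e-12)) stop("fiber and sheet directions are parallel")
  s <- s / ns
  # n = f x s guarantees a right-handed orthonormal triplet; the sign is
  # matched to the supplied n where possible
  cr <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
              f[, 3] * s[, 1] - f[, 1] * s[, 3],
              f[, 1] * s[, 2] - f[, 2] * s[, 1])
  flip <- rowSums(cr * n) < 0
  cr[flip, ] <- -cr[flip, , drop = FALSE]
  list(f0 = f, s0 = s, n0 = cr)
}

#' Per-node orthonormal fiber frame
#'
#' Stores the fiber (`f0`), sheetlet (`s0`) and sheet-normal (`n0`) unit
#' directions at every mesh node.  The constructor re-orthonormalises the
#' triplet (Gram-Schmidt with `f0` priority) and validates unit norms and
#' pairwise orthogonality to 1e-6.
#'
#' @param f0,s0,n0 n x 3 matrices of direction vectors.
#' @return object of class `fiber_frame`.
#' @export
fiber_frame <- function(f0, s0, n0) {
  f0 <- as.matrix(f0); s0 <- as.matrix(s0); n0 <- as.matrix(n0)
  if (!all(dim(f0) == dim(s0)) || !all(dim(f0) == dim(n0)) || ncol(f0) != 3L) {
    stop("f0, s0, n0 must be matching n x 3 matrices")
  }
  nrm <- sqrt(rowSums(f0^2))
  bad <- which(nrm < 1e-8)
  if (length(bad)) {
    stop(sprintf("near-zero fiber vector at node %d", bad[1]))
  }
  o <- .orthonormalise_rows(f0, s0, n0)
  stopifnot(max(abs(rowSums(o$f0^2) - 1)) < 1e-6,
            max(abs(rowSums(o$f0 * o$s0))) < 1e-6,
            max(abs(rowSums(o$f0 * o$n0))) < 1e-6,
            max(abs(rowSums(o$s0 * o$n0))) < 1e-6)
  structure(o, class = "fiber_frame")
}

#' @export
print.fiber_frame <- function(x, ...) {
  cat(sprintf("<fiber_frame> %d nodes\n", nrow(x$f0)))
  invisible(x)
}

#' Uniform axis-aligned fiber frame
#'
#' Convenience frame with `f0`, `s0`, `n0` equal to the given constant
#' directions at every node (default: the coordinate axes with the fiber
#' along z, the slab long axis of the N-version benchmark).
#'
#' @param mesh a [mono_mesh()] (or an [fe_space()], whose support points set
#'   the node count).
#' @param f0,s0,n0 length-3 direction vectors.
#' @return a [fiber_frame()].
#' @export
axis_fiber_frame <- function(mesh, f0 = c(0, 0, 1), s0 = c(1, 0, 0),
                             n0 = c(0, 1, 0)) {
  n <- if (inherits(mesh, "fe_space")) nrow(mesh$support_points)
       else nrow(mesh$nodes)
  fiber_frame(matrix(f0, n, 3, byrow = TRUE),
              matrix(s0, n, 3, byrow = TRUE),
              matrix(n0, n, 3, byrow = TRUE))
}

#' Transmural Laplace coordinate
#'
#' Solves the Laplace equation on the mesh with Dirichlet values 0 on the
#' endocardial node set and 1 on the epicardial node set (natural boundary
#' conditions elsewhere).  The harmonic solution \eqn{\phi \in [0, 1]} is the
#' transmural coordinate driving rule-based fiber generation.
#'
#' @param mesh a [mono_mesh()].
#' @param endo_selector,epi_selector either logical/integer node index
#'   vectors, or predicate functions of the n x 3 node coordinate matrix.
#' @param degree FE degree for the solve (default 1).
#' @return numeric vector of \eqn{\phi} at the FE support points.
#' @export
transmural_laplace <- function(mesh, endo_selector, epi_selector, degree = 1L) {
  space <- fe_space(mesh, degree)
  pts <- space$support_points
  sel <- function(s) {
    idx <- if (is.function(s)) which(s(pts)) else
      if (is.logical(s)) which(s) else as.integer(s)
    idx
  }
  endo <- sel(endo_selector)
  epi <- sel(epi_selector)
  if (!length(endo) || !length(epi)) {
    stop("both Dirichlet face sets must be non-empty")
  }
  if (length(intersect(endo, epi))) {
    stop("endocardial and epicardial face sets must be disjoint")
  }
  frame <- axis_fiber_frame(space)
  K <- assemble_stiffness(space, frame, sigma = c(1, 1, 1))
  phi <- numeric(space$n_dofs)
  phi[epi] <- 1
  fixed <- c(endo, epi)
  free <- setdiff(seq_len(space$n_dofs), fixed)
  rhs <- -K[free, fixed, drop = FALSE] %*% phi[fixed]
  phi[free] <- as.vector(Matrix::solve(K[free, free], rhs))
  # clip harmless round-off outside [0, 1]
  pmin(pmax(phi, 0), 1)
}

#' Rule-based slab fiber frame
#'
#' Linear transmural rotation of the fiber direction in the sheet plane of a
#' slab: the in-plane fiber angle is
#' \eqn{\alpha(\phi) = \alpha_{endo} + \phi(\alpha_{epi} - \alpha_{endo})}
#' measured from the slab long axis, with the sheet-normal direction `n0`
#' transmural (along the \eqn{\nabla\phi} axis).
#'
#' @param mesh a [mono_mesh()].
#' @param phi transmural coordinate in `[0, 1]` at the nodes.
#' @param endo_angle,epi_angle fiber angles in degrees at \eqn{\phi = 0}
#'   and \eqn{\phi = 1}.
#' @param long_axis,transmural_axis unit vectors spanning the slab: the long
#'   axis (angle 0 reference) and the transmural direction (defaults: z and
#'   y, the layout of [build_slab_mesh()]).
#' @return a [fiber_frame()].
#' @export
slab_fiber_rule <- function(mesh, phi, endo_angle = 60, epi_angle = -60,
                            long_axis = c(0, 0, 1),
                            transmural_axis = c(0, 1, 0)) {
  if (any(phi < -1e-9 | phi > 1 + 1e-9)) stop("phi must lie in [0, 1]")
  n <- length(phi)
  ez <- long_axis / sqrt(sum(long_axis^2))
  ey <- transmural_axis / sqrt(sum(transmural_axis^2))
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],   # in-plane axis completing the triad
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])
  alpha <- (endo_angle + phi * (epi_angle - endo_angle)) * pi / 180
  f0 <- outer(cos(alpha), ez) + outer(sin(alpha), ex)
  s0 <- outer(-sin(alpha), ez) + outer(cos(alpha), ex)
  n0 <- matrix(ey, n, 3, byrow = TRUE)
  fiber_frame(f0, s0, n0)
}

#' Anisotropic diffusion tensor field
#'
#' \eqn{D = \sigma_l f_0 \otimes f_0 + \sigma_t s_0 \otimes s_0 +
#' \sigma_n n_0 \otimes n_0} at every node of the frame.
#'
#' @param frame a [fiber_frame()].
#' @param sigma_l,sigma_t,sigma_n non-negative conductivities (m^2/s).
#' @return object of class `diffusion_field`: an n x 6 matrix of the unique
#'   tensor entries with columns `xx, yy, zz, xy, xz, yz`.
#' @export
diffusion_tensor_field <- function(frame, sigma_l, sigma_t, sigma_n) {
  stopifnot(inherits(frame, "fiber_frame"))
  if (any(c(sigma_l, sigma_t, sigma_n) < 0)) {
    stop("conductivities must be non-negative")
  }
  d <- .tensor6(frame$f0, frame$s0, frame$n0, sigma_l, sigma_t, sigma_n)
  out <- cbind(xx = d$xx, yy = d$yy, zz = d$zz,
               xy = d$xy, xz = d$xz, yz = d$yz)
  class(out) <- c("diffusion_field", class(out))
  out
}

# expand row i of a diffusion_field into a 3x3 matrix
diffusion_tensor_at <- function(field, i) {
  matrix(c(field[i, "xx"], field[i, "xy"], field[i, "xz"],
           field[i, "xy"], field[i, "yy"], field[i, "yz"],
           field[i, "xz"], field[i, "yz"], field[i, "zz"]), 3, 3)
}

#' Import a fiber frame from a VTU file
#'
#' Reads the three point-data vector arrays (default names `fibers`,
#' `sheets`, `sheet_normals`), checks the point count against the mesh,
#' re-normalises the vectors, and rejects near-zero vectors.
#'
#' @param path VTU file.
#' @param mesh the target [mono_mesh()] (node counts must match after
#'   scaling).
#' @param scaling_factor factor applied to the file's coordinates before
#'   comparing with the mesh (e.g. 1e-3 for a millimetre file).
#' @param array_names character length-3: the f0/s0/n0 array names.
#' @return a [fiber_frame()].
#' @export
import_fibers <- function(path, mesh, scaling_factor = 1,
                          array_names = c("fibers", "sheets", "sheet_normals")) {
  vt <- read_vtu(path)
  if (nrow(vt$points) != nrow(mesh$nodes)) {
    stop(sprintf("fiber file has %d points but the mesh has %d nodes",
                 nrow(vt$points), nrow(mesh$nodes)))
  }
  pts <- vt$points * scaling_factor
  if (max(abs(pts - mesh$nodes)) > 1e-9 * max(1, max(abs(mesh$nodes)))) {
    warning("fiber file point coordinates differ from the mesh nodes")
  }
  arrs <- lapply(array_names, function(nm) {
    a <- vt$point_data[[nm]]
    if (is.null(a)) stop(sprintf("point-data array '%s' missing from %s", nm, path))
    a <- matrix(a, ncol = 3)
    nrm <- sqrt(rowSums(a^2))
    bad <- which(nrm < 1e-8)
    if (length(bad)) {
      stop(sprintf("array '%s' has a near-zero vector at node %d", nm, bad[1]))
    }
    a / nrm
  })
  fiber_frame(arrs[[1]], arrs[[2]], arrs[[3]])
}

#' Export a fiber frame as VTU point data
#'
#' @param frame a [fiber_frame()].
#' @param mesh the owning [mono_mesh()].
#' @param path output VTU file.
#' @param array_names names for the f0/s0/n0 arrays.
#' @return `path`, invisibly.
#' @export
export_fibers <- function(frame, mesh, path,
                          array_names = c("fibers", "sheets", "sheet_normals")) {
  pd <- list(frame$f0, frame$s0, frame$n0)
  names(pd) <- array_names
  write_vtu(mesh, path, point_data = pd)
  invisible(path)
}
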