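# FE reference elements, quadrature, DOF numbering and operator assembly.
#
# Reference cells: unit tetrahedron (vertices 0, e1, e2, e3) and unit cube
# [0,1]^3.  Geometry is always the linear (tet4) / trilinear (hex8) map from
# the element vertices; quadratic FE spaces are subparametric (extra DOFs on
# edges/faces/centres of the straight-sided cell).

# ---- 1D Gauss-Legendre (Golub-Welsch) on [0, 1] -----------------------------
gauss_legendre_01 <- function(n) {
  if (n == 1L) return(list(x = 0.5, w = 1))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(k, k + 1L)] <- b
  Jm[cbind(k + 1L, k)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  x <- rev(e$values)
  w <- rev(2 * e$vectors[1, ]^2)
  list(x = (x + 1) / 2, w = w / 2)
}

# ---- symmetric simplex rules ------------------------------------------------
# Published Gauss-type rules on the unit tetrahedron (volume 1/6), weights
# already scaled to the reference volume.  Exactness is asserted by the test
# suite through monomial integration.

# expand a barycentric orbit (all distinct permutations) into cartesian rows
.tet_orbit <- function(bary) {
  perms <- matrix(c(1,2,3,4, 1,2,4,3, 1,3,2,4, 1,3,4,2, 1,4,2,3, 1,4,3,2,
                    2,1,3,4, 2,1,4,3, 2,3,1,4, 2,3,4,1, 2,4,1,3, 2,4,3,1,
                    3,1,2,4, 3,1,4,2, 3,2,1,4, 3,2,4,1, 3,4,1,2, 3,4,2,1,
                    4,1,2,3, 4,1,3,2, 4,2,1,3, 4,2,3,1, 4,3,1,2, 4,3,2,1),
                  ncol = 4, byrow = TRUE)
  pts <- unique(t(apply(perms, 1, function(p) bary[p])))
  pts[, 2:4, drop = FALSE]  # cartesian = barycentric components 2..4
}

# degree-2 four-point rule
.tet_rule_deg2 <- function() {
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  x <- .tet_orbit(c(a, b, b, b))
  list(x = x, w = rep(1 / 24, 4))
}

# degree-4 eleven-point rule (Keast): centroid + (11/14,1/14,1/14,1/14)
# orbit + (a,a,b,b) orbit with a,b = (1 +/- sqrt(5/14))/4
.tet_rule_deg4 <- function() {
  x1 <- matrix(0.25, 1, 3)
  x2 <- .tet_orbit(c(11 / 14, 1 / 14, 1 / 14, 1 / 14))
  ab <- sqrt(5 / 14)
  a <- (1 + ab) / 4
  b <- (1 - ab) / 4
  x3 <- .tet_orbit(c(a, a, b, b))
  list(x = rbind(x1, x2, x3),
       w = c(-74 / 5625, rep(343 / 45000, nrow(x2)), rep(28 / 1125, nrow(x3))))
}

#' Quadrature rule on the reference element
#'
#' Hexahedra use the tensor Gauss-Legendre rule with `degree + 1` points per
#' axis (the minimum that integrates the mass matrix of a degree-`degree`
#' space exactly on parallelepiped elements).  Tetrahedra use a
#' Grundmann-Moller rule exact at least to polynomial degree `2 * degree`.
#'
#' @param kind `"tetrahedron"` or `"hexahedron"`.
#' @param degree FE polynomial degree the rule must serve (1 or 2).
#' @return list with `x` (q x 3 reference points) and `w` (weights summing to
#'   the reference volume).
#' @export
quadrature_rule <- function(kind, degree) {
  kind <- match.arg(kind, c("tetrahedron", "hexahedron"))
  degree <- as.integer(degree)
  if (kind == "hexahedron") {
    g <- gauss_legendre_01(degree + 1L)
    n <- length(g$x)
    x <- cbind(rep(g$x, times = n * n),
               rep(rep(g$x, each = n), times = n),
               rep(g$x, each = n * n))
    w <- rep(g$w, times = n * n) * rep(rep(g$w, each = n), times = n) *
      rep(g$w, each = n * n)
    list(x = x, w = w)
  } else {
    # exact to degree 2p
    if (degree == 1L) .tet_rule_deg2() else .tet_rule_deg4()
  }
}

# ---- reference shape functions ----------------------------------------------

# 1D Lagrange bases on nodes {0,1} (p=1) and {0,1,1/2} (p=2), VTK node order.
.lag1d <- function(p, t) {
  if (p == 1L) {
    list(N = cbind(1 - t, t), dN = cbind(rep(-1, length(t)), rep(1, length(t))))
  } else {
    list(N = cbind(2 * t^2 - 3 * t + 1, 2 * t^2 - t, 4 * t - 4 * t^2),
         dN = cbind(4 * t - 3, 4 * t - 1, 4 - 8 * t))
  }
}

# VTK local node -> per-axis 1D node index (1=coord 0, 2=coord 1, 3=coord 1/2)
.hex_node_table <- function(p) {
  if (p == 1L) {
    cbind(c(1, 2, 2, 1, 1, 2, 2, 1),
          c(1, 1, 2, 2, 1, 1, 2, 2),
          c(1, 1, 1, 1, 2, 2, 2, 2))
  } else {
    rbind(
      # 8 vertices
      c(1, 1, 1), c(2, 1, 1), c(2, 2, 1), c(1, 2, 1),
      c(1, 1, 2), c(2, 1, 2), c(2, 2, 2), c(1, 2, 2),
      # 12 edges: bottom, top, vertical (VTK_TRIQUADRATIC_HEXAHEDRON)
      c(3, 1, 1), c(2, 3, 1), c(3, 2, 1), c(1, 3, 1),
      c(3, 1, 2), c(2, 3, 2), c(3, 2, 2), c(1, 3, 2),
      c(1, 1, 3), c(2, 1, 3), c(2, 2, 3), c(1, 2, 3),
      # 6 faces: x=0, x=1, y=0, y=1, z=0, z=1
      c(1, 3, 3), c(2, 3, 3), c(3, 1, 3), c(3, 2, 3), c(3, 3, 1), c(3, 3, 2),
      # centre
      c(3, 3, 3))
  }
}

# tet10 edge list in VTK order (pairs of 1-based vertex ids)
.tet_edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
# hex edge list in VTK hex27 order
.hex_edges <- rbind(
  c(1, 2), c(2, 3), c(3, 4), c(4, 1),
  c(5, 6), c(6, 7), c(7, 8), c(8, 5),
  c(1, 5), c(2, 6), c(3, 7), c(4, 8))
# hex face list (vertex quads) in the x0,x1,y0,y1,z0,z1 order used above
.hex_faces <- rbind(
  c(1, 4, 8, 5), c(2, 3, 7, 6),
  c(1, 2, 6, 5), c(4, 3, 7, 8),
  c(1, 2, 3, 4), c(5, 6, 7, 8))

#' Reference element basis evaluation
#'
#' Evaluates the Lagrange basis of degree `degree` and its reference
#' gradients at a set of reference points (defaults to the quadrature rule
#' of [quadrature_rule()]).
#'
#' @param kind element kind.
#' @param degree 1 or 2.
#' @param points optional q x 3 matrix of reference coordinates.
#' @return list with `N` (q x nb), `grad` (q x nb x 3 array), `nb`, and
#'   `nodes` (nb x 3 reference support points).
#' @export
reference_element <- function(kind, degree, points = NULL) {
  kind <- match.arg(kind, c("tetrahedron", "hexahedron"))
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  if (is.null(points)) points <- quadrature_rule(kind, degree)$x
  points <- matrix(points, ncol = 3)
  q <- nrow(points)
  if (kind == "hexahedron") {
    tab <- .hex_node_table(degree)
    nb <- nrow(tab)
    bx <- .lag1d(degree, points[, 1])
    by <- .lag1d(degree, points[, 2])
    bz <- .lag1d(degree, points[, 3])
    N <- matrix(0, q, nb)
    grad <- array(0, c(q, nb, 3))
    for (a in seq_len(nb)) {
      i <- tab[a, 1]; j <- tab[a, 2]; k <- tab[a, 3]
      N[, a] <- bx$N[, i] * by$N[, j] * bz$N[, k]
      grad[, a, 1] <- bx$dN[, i] * by$N[, j] * bz$N[, k]
      grad[, a, 2] <- bx$N[, i] * by$dN[, j] * bz$N[, k]
      grad[, a, 3] <- bx$N[, i] * by$N[, j] * bz$dN[, k]
    }
    node1d <- if (degree == 1L) c(0, 1) else c(0, 1, 0.5)
    nodes <- cbind(node1d[tab[, 1]], node1d[tab[, 2]], node1d[tab[, 3]])
  } else {
    x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
    L <- cbind(1 - x - y - z, x, y, z)
    dL <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    if (degree == 1L) {
      N <- L
      grad <- array(0, c(q, 4, 3))
      for (a in 1:4) for (i in 1:3) grad[, a, i] <- dL[a, i]
      nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    } else {
      nb <- 10L
      N <- matrix(0, q, nb)
      grad <- array(0, c(q, nb, 3))
      for (a in 1:4) {
        N[, a] <- L[, a] * (2 * L[, a] - 1)
        for (i in 1:3) grad[, a, i] <- (4 * L[, a] - 1) * dL[a, i]
      }
      for (e in 1:6) {
        a <- .tet_edges[e, 1]; b <- .tet_edges[e, 2]
        N[, 4L + e] <- 4 * L[, a] * L[, b]
        for (i in 1:3) {
          grad[, 4L + e, i] <- 4 * (dL[a, i] * L[, b] + L[, a] * dL[b, i])
        }
      }
      verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
      nodes <- rbind(verts, (verts[.tet_edges[, 1], ] + verts[.tet_edges[, 2], ]) / 2)
    }
  }
  list(N = N, grad = grad, nb = ncol(N), nodes = nodes)
}

# ---- FE space ---------------------------------------------------------------

#' Scalar Lagrange finite-element space
#'
#' Builds the global DOF numbering for continuous piecewise polynomials of
#' degree `p` on the mesh: degree 1 DOFs coincide with mesh nodes; degree 2
#' adds edge midpoints (tet and hex), and on hexahedra also face centres and
#' cell centres.  Degrees 1 and 2 are supported on both element kinds.
#'
#' @param mesh a [mono_mesh()].
#' @param degree polynomial degree (1 or 2).
#' @return object of class `fe_space` with `n_dofs`, `support_points`
#'   (n_dofs x 3, metres), and `elem_dofs` (E x nb global DOF indices in the
#'   local ordering of [reference_element()]).
#' @export
fe_space <- function(mesh, degree = 1L) {
  stopifnot(inherits(mesh, "mono_mesh"))
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  el <- mesh$elements
  E <- nrow(el)
  if (degree == 1L) {
    space <- list(mesh = mesh, degree = 1L, n_dofs = nrow(mesh$nodes),
                  support_points = mesh$nodes, elem_dofs = el)
  } else {
    nn <- nrow(mesh$nodes)
    edges <- if (mesh$element_kind == "tetrahedron") .tet_edges else .hex_edges
    ea <- el[, edges[, 1], drop = FALSE]  # E x ne
    eb <- el[, edges[, 2], drop = FALSE]
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    key <- paste(lo, hi)
    uk <- unique(key)
    edge_id <- match(key, uk)              # E*ne vector (column-major)
    ne <- nrow(edges)
    first <- match(uk, key)
    edge_pts <- (mesh$nodes[lo[first], , drop = FALSE] +
                 mesh$nodes[hi[first], , drop = FALSE]) / 2
    edof <- matrix(nn + edge_id, E, ne)
    extra <- nn + length(uk)
    if (mesh$element_kind == "tetrahedron") {
      elem_dofs <- cbind(el, edof)
      support <- rbind(mesh$nodes, edge_pts)
    } else {
      # faces
      fa <- .hex_faces
      fkey <- vapply(seq_len(nrow(fa)), function(f) {
        v <- el[, fa[f, ], drop = FALSE]
        vs <- apply(v, 1, function(r) paste(sort(r), collapse = " "))
        vs
      }, character(E))
      fkey <- as.vector(fkey)
      ufk <- unique(fkey)
      face_id <- match(fkey, ufk)
      firstf <- match(ufk, fkey)
      # face centre = mean of its 4 vertices (flat faces assumed)
      fcol <- ((firstf - 1L) %/% E) + 1L
      frow <- ((firstf - 1L) %% E) + 1L
      face_pts <- t(vapply(seq_along(ufk), function(s) {
        colMeans(mesh$nodes[el[frow[s], fa[fcol[s], ]], , drop = FALSE])
      }, numeric(3)))
      fdof <- matrix(extra + face_id, E, nrow(fa))
      extra2 <- extra + length(ufk)
      cell_pts <- t(vapply(seq_len(E), function(e) {
        colMeans(mesh$nodes[el[e, ], , drop = FALSE])
      }, numeric(3)))
      cdof <- matrix(extra2 + seq_len(E), E, 1)
      elem_dofs <- cbind(el, edof, fdof, cdof)
      support <- rbind(mesh$nodes, edge_pts, face_pts, cell_pts)
    }
    space <- list(mesh = mesh, degree = 2L, n_dofs = nrow(support),
                  support_points = support, elem_dofs = elem_dofs)
  }
  class(space) <- "fe_space"
  space
}

#' @export
print.fe_space <- function(x, ...) {
  cat(sprintf("<fe_space> degree %d, %d DOFs on %d %s elements\n",
              x$degree, x$n_dofs, nrow(x$elem_dofs), x$mesh$element_kind))
  invisible(x)
}

# ---- BDF / extrapolation coefficients ---------------------------------------

#' Backward differentiation formula coefficients
#'
#' Returns the implicit coefficient \eqn{\alpha_{BDF}}, the history weights
#' that build \eqn{f_{BDF,n}} from \eqn{(f_n, f_{n-1}, \dots)}, and the
#' extrapolation weights that build \eqn{f_{EXT,n+1}} from the same history,
#' for orders 1-3.  Both weight sets reproduce polynomials of degree
#' `order - 1` exactly.
#'
#' @param order 1, 2 or 3.
#' @return object of class `bdf_scheme` with fields `order`, `alpha`,
#'   `bdf_weights`, `ext_weights`.
#' @export
bdf_scheme <- function(order) {
  order <- as.integer(order)
  if (!order %in% 1:3) stop("BDF order must be 1, 2 or 3")
  co <- switch(order,
    list(alpha = 1,      bdf = 1,                  ext = 1),
    list(alpha = 3 / 2,  bdf = c(2, -1 / 2),       ext = c(2, -1)),
    list(alpha = 11 / 6, bdf = c(3, -3 / 2, 1 / 3), ext = c(3, -3, 1)))
  structure(list(order = order, alpha = co$alpha,
                 bdf_weights = co$bdf, ext_weights = co$ext),
            class = "bdf_scheme")
}

# linear combination of history columns (most recent first)
bdf_combine <- function(weights, history) {
  out <- history[[1]] * weights[1]
  if (length(weights) > 1L) {
    for (k in 2:length(weights)) out <- out + history[[k]] * weights[k]
  }
  out
}

# ---- assembly ---------------------------------------------------------------

# Per-element matrices.  integrand = "mass" or "stiffness".  For stiffness,
# Dfun(q, elems) must return the 6 unique tensor entries (xx, yy, zz, xy,
# xz, yz) at quadrature point q for the given elements.  Returns the dense
# E x nb x nb block array and the element DOF map.
.element_matrices <- function(space, elems, integrand, Dfun = NULL) {
  mesh <- space$mesh
  qr_ <- quadrature_rule(mesh$element_kind, space$degree)
  ref <- reference_element(mesh$element_kind, space$degree, qr_$x)
  geo <- reference_element(mesh$element_kind, 1L, qr_$x)  # geometry is linear
  sub <- mesh
  sub$elements <- mesh$elements[elems, , drop = FALSE]
  E <- length(elems)
  nb <- ref$nb
  Ke <- array(0, c(E, nb, nb))
  tet <- mesh$element_kind == "tetrahedron"
  Jfix <- if (tet) .element_jacobians(sub, geo$grad[1, , ]) else NULL
  for (q in seq_along(qr_$w)) {
    J <- if (tet) Jfix else .element_jacobians(sub, geo$grad[q, , ])
    wdet <- qr_$w[q] * J$det
    if (integrand == "mass") {
      Nq <- ref$N[q, ]
      for (a in seq_len(nb)) for (b in a:nb) {
        v <- wdet * (Nq[a] * Nq[b])
        Ke[, a, b] <- Ke[, a, b] + v
        if (b > a) Ke[, b, a] <- Ke[, b, a] + v
      }
    } else {
      D6 <- Dfun(q, elems)
      # physical gradients of each basis function at q: list of E-vectors
      gx <- gy <- gz <- vector("list", nb)
      for (a in seq_len(nb)) {
        r <- ref$grad[q, a, ]
        gx[[a]] <- r[1] * J$inv[["11"]] + r[2] * J$inv[["21"]] + r[3] * J$inv[["31"]]
        gy[[a]] <- r[1] * J$inv[["12"]] + r[2] * J$inv[["22"]] + r[3] * J$inv[["32"]]
        gz[[a]] <- r[1] * J$inv[["13"]] + r[2] * J$inv[["23"]] + r[3] * J$inv[["33"]]
      }
      for (a in seq_len(nb)) {
        Dgx <- D6$xx * gx[[a]] + D6$xy * gy[[a]] + D6$xz * gz[[a]]
        Dgy <- D6$xy * gx[[a]] + D6$yy * gy[[a]] + D6$yz * gz[[a]]
        Dgz <- D6$xz * gx[[a]] + D6$yz * gy[[a]] + D6$zz * gz[[a]]
        for (b in a:nb) {
          v <- wdet * (Dgx * gx[[b]] + Dgy * gy[[b]] + Dgz * gz[[b]])
          Ke[, a, b] <- Ke[, a, b] + v
          if (b > a) Ke[, b, a] <- Ke[, b, a] + v
        }
      }
    }
  }
  dofs <- space$elem_dofs[elems, , drop = FALSE]
  list(Ke = Ke, dofs = dofs, elems = elems, nb = nb)
}

# triplets of a block set, laid out pair-major with the element index
# fastest (the canonical order used for deterministic global assembly)
.block_triplets <- function(blocks) {
  nb <- blocks$nb
  ia <- blocks$dofs[, rep(seq_len(nb), times = nb), drop = FALSE]
  ja <- blocks$dofs[, rep(seq_len(nb), each = nb), drop = FALSE]
  list(i = as.vector(ia), j = as.vector(ja), x = as.vector(blocks$Ke),
       elem = rep(blocks$elems, nb * nb),
       pair = rep(seq_len(nb * nb), each = length(blocks$elems)))
}

.assemble <- function(space, elems, integrand, Dfun = NULL) {
  tr <- .block_triplets(.element_matrices(space, elems, integrand, Dfun))
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(space$n_dofs, space$n_dofs))
}

#' Assemble the consistent mass matrix
#'
#' \eqn{M_{jk} = \int \varphi_k \varphi_j \, dx} over the whole mesh or an
#' element subset (per-subdomain masses \eqn{M^i}).  No lumping; the
#' quadrature integrates the products exactly on affine elements.
#'
#' @param space an [fe_space()].
#' @param elems optional element index subset (default: all).
#' @return sparse symmetric `n_dofs x n_dofs` matrix.
#' @export
assemble_mass <- function(space, elems = NULL) {
  stopifnot(inherits(space, "fe_space"))
  if (is.null(elems)) elems <- seq_len(nrow(space$elem_dofs))
  .assemble(space, elems, "mass")
}

#' Assemble the anisotropic stiffness matrix
#'
#' \eqn{K_{jk} = \sum_i \int_{\Omega_i} D^i \nabla\varphi_k \cdot
#' \nabla\varphi_j \, dx}, with \eqn{D^i} built from the fiber frame and the
#' subdomain conductivities.  The frame is interpolated from nodes to each
#' quadrature point with the FE basis and re-orthonormalised there
#' (Gram-Schmidt, fiber direction first).  Non-conductive subdomains
#' contribute nothing.
#'
#' @param space an [fe_space()].
#' @param frame a [fiber_frame()] on the mesh nodes.
#' @param partition a [build_subdomains()] partition carrying per-subdomain
#'   conductivities; alternatively `sigma = c(l, t, n)` for a single region.
#' @param sigma optional length-3 conductivities used when `partition` is
#'   `NULL`.
#' @return sparse symmetric positive semidefinite matrix.
#' @export
assemble_stiffness <- function(space, frame, partition = NULL, sigma = NULL) {
  stopifnot(inherits(space, "fe_space"))
  mesh <- space$mesh
  qr_ <- quadrature_rule(mesh$element_kind, space$degree)
  geo <- reference_element(mesh$element_kind, 1L, qr_$x)
  if (is.null(partition)) {
    if (is.null(sigma) || length(sigma) != 3L) {
      stop("either a partition or sigma = c(l, t, n) must be given")
    }
    sets <- list(seq_len(nrow(mesh$elements)))
    sigmas <- list(sigma)
  } else {
    keep <- which(partition$conductive)
    sets <- partition$elem_sets[keep]
    sigmas <- lapply(partition$specs[keep], function(sp) {
      c(sp$sigma_l, sp$sigma_t, sp$sigma_n)
    })
  }
  # per-subdomain triplets, then one deterministic global assembly in the
  # canonical (pair-major, element-fastest) order: the assembled operator is
  # bit-identical however the conductive elements are partitioned
  trips <- list()
  for (s in seq_along(sets)) {
    elems <- sets[[s]]
    if (!length(elems)) next
    sg <- sigmas[[s]]
    if (any(sg < 0)) stop("conductivities must be non-negative")
    el <- mesh$elements[elems, , drop = FALSE]
    Dfun <- function(q, elems_in) {
      # interpolate the nodal frame to quadrature point q, re-orthonormalise
      Nq <- geo$N[q, ]
      f <- s0 <- n0 <- matrix(0, length(elems_in), 3)
      for (a in seq_len(ncol(el))) {
        f <- f + Nq[a] * frame$f0[el[, a], , drop = FALSE]
        s0 <- s0 + Nq[a] * frame$s0[el[, a], , drop = FALSE]
        n0 <- n0 + Nq[a] * frame$n0[el[, a], , drop = FALSE]
      }
      o <- .orthonormalise_rows(f, s0, n0)
      .tensor6(o$f0, o$s0, o$n0, sg[1], sg[2], sg[3])
    }
    trips[[length(trips) + 1L]] <-
      .block_triplets(.element_matrices(space, elems, "stiffness", Dfun))
  }
  if (!length(trips)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0),
                                dims = c(space$n_dofs, space$n_dofs)))
  }
  i <- unlist(lapply(trips, `[[`, "i"))
  j <- unlist(lapply(trips, `[[`, "j"))
  x <- unlist(lapply(trips, `[[`, "x"))
  elem <- unlist(lapply(trips, `[[`, "elem"))
  pair <- unlist(lapply(trips, `[[`, "pair"))
  ord <- order(pair, elem)
  Matrix::sparseMatrix(i = i[ord], j = j[ord], x = x[ord],
                       dims = c(space$n_dofs, space$n_dofs))
}

# D = sl f f' + st s s' + sn n n' -> unique entries as E-vectors
.tensor6 <- function(f, s, n, sl, st, sn) {
  list(
    xx = sl * f[, 1]^2 + st * s[, 1]^2 + sn * n[, 1]^2,
    yy = sl * f[, 2]^2 + st * s[, 2]^2 + sn * n[, 2]^2,
    zz = sl * f[, 3]^2 + st * s[, 3]^2 + sn * n[, 3]^2,
    xy = sl * f[, 1] * f[, 2] + st * s[, 1] * s[, 2] + sn * n[, 1] * n[, 2],
    xz = sl * f[, 1] * f[, 3] + st * s[, 1] * s[, 3] + sn * n[, 1] * n[, 3],
    yz = sl * f[, 2] * f[, 3] + st * s[, 2] * s[, 3] + sn * n[, 2] * n[, 3])
}

#' System matrix of the implicit monodomain step
#'
#' \eqn{A = (\alpha_{BDF}/\Delta t) M + K}.  Assembled once per run and
#' reused at every time step (the factorisation is cached alongside).
#'
#' @param scheme a [bdf_scheme()].
#' @param dt time step in seconds.
#' @param M,K assembled mass and stiffness matrices.
#' @return sparse symmetric positive definite matrix (on active DOFs).
#' @export
build_system_matrix <- function(scheme, dt, M, K) {
  stopifnot(inherits(scheme, "bdf_scheme"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  (scheme$alpha / dt) * M + K
}

# ---- point evaluation -------------------------------------------------------

# Map physical points into elements and evaluate a DOF vector there.
# Brute-force bounding-box candidate search; meant for a handful of probes.
fe_interpolate <- function(space, values, points) {
  mesh <- space$mesh
  points <- matrix(points, ncol = 3)
  out <- rep(NA_real_, nrow(points))
  el <- mesh$elements
  lo <- hi <- NULL
  for (d in 1:3) {
    cm <- matrix(mesh$nodes[el, d], nrow(el), ncol(el))
    lo <- cbind(lo, apply(cm, 1, min))
    hi <- cbind(hi, apply(cm, 1, max))
  }
  tol <- 1e-9 * max(hi - lo)
  for (p in seq_len(nrow(points))) {
    x <- points[p, ]
    cand <- which(lo[, 1] <= x[1] + tol & hi[, 1] >= x[1] - tol &
                  lo[, 2] <= x[2] + tol & hi[, 2] >= x[2] - tol &
                  lo[, 3] <= x[3] + tol & hi[, 3] >= x[3] - tol)
    for (e in cand) {
      xi <- .invert_map(mesh, e, x)
      if (is.null(xi)) next
      ref <- reference_element(mesh$element_kind, space$degree,
                               matrix(xi, 1, 3))
      out[p] <- sum(ref$N[1, ] * values[space$elem_dofs[e, ]])
      break
    }
  }
  out
}

# reference coordinates of physical point x in element e, or NULL if outside
.invert_map <- function(mesh, e, x, tol = 1e-10) {
  v <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
  if (mesh$element_kind == "tetrahedron") {
    A <- t(v[2:4, ]) - v[1, ]
    xi <- tryCatch(solve(A, x - v[1, ]), error = function(e) NULL)
    if (is.null(xi)) return(NULL)
    if (all(xi > -1e-9) && sum(xi) < 1 + 1e-9) return(xi)
    return(NULL)
  }
  xi <- c(0.5, 0.5, 0.5)
  for (it in 1:50) {
    ref <- reference_element("hexahedron", 1L, matrix(xi, 1, 3))
    r <- as.vector(t(v) %*% ref$N[1, ]) - x
    if (sqrt(sum(r^2)) < tol * (1 + sqrt(sum(x^2)))) break
    J <- matrix(0, 3, 3)
    for (a in 1:8) J <- J + outer(v[a, ], ref$grad[1, a, ])
    xi <- xi - solve(J, r)
  }
  if (all(xi > -1e-7 & xi < 1 + 1e-7)) pmin(pmax(xi, 0), 1) else NULL
}
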