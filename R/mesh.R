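#' @useDynLib monodomain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Matrix
#' @importFrom methods as is new
#' @importFrom utils read.csv write.csv
NULL

# Nodes per element by kind and geometric order (linear geometry only:
# tet4 / hex8; quadratic FE spaces add DOFs on top of linear geometry).
.kind_nv <- c(tetrahedron = 4L, hexahedron = 8L)

#' Volumetric mesh container
#'
#' A `mono_mesh` stores node coordinates in metres, element connectivity
#' (1-based node indices, VTK vertex ordering), the element kind
#' (all-tetrahedral or all-hexahedral), and one integer material label per
#' element.  Vertex ordering follows the VTK conventions:
#' \describe{
#'   \item{tetrahedron}{vertices 1-4 with positive orientation,
#'     \eqn{\det[v_2-v_1, v_3-v_1, v_4-v_1] > 0}.}
#'   \item{hexahedron}{vertices 1-4 the bottom quad counter-clockwise
#'     (seen from above), 5-8 the matching top quad
#'     (VTK_HEXAHEDRON).}
#' }
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in metres.
#' @param elements integer matrix, one row per element, 4 (tet) or 8 (hex)
#'   1-based node indices in VTK order.
#' @param element_kind `"tetrahedron"` or `"hexahedron"`.
#' @param material_id integer vector, one label per element (default all 0).
#' @return an object of class `mono_mesh`.
#' @export
mono_mesh <- function(nodes, elements, element_kind, material_id = NULL) {
  element_kind <- match.arg(element_kind, c("tetrahedron", "hexahedron"))
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns (x, y, z)")
  if (!all(is.finite(nodes))) stop("node coordinates must be finite")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  nv <- .kind_nv[[element_kind]]
  if (ncol(elements) != nv) {
    stop(sprintf("%s elements need %d nodes per row, got %d",
                 element_kind, nv, ncol(elements)))
  }
  if (nrow(elements) == 0L) stop("mesh has no elements")
  if (min(elements) < 1L || max(elements) > nrow(nodes)) {
    stop("element connectivity references node indices out of range")
  }
  if (is.null(material_id)) material_id <- integer(nrow(elements))
  material_id <- as.integer(material_id)
  if (length(material_id) != nrow(elements)) {
    stop("material_id must have one entry per element")
  }
  structure(
    list(nodes = nodes, elements = elements,
         element_kind = element_kind, material_id = material_id),
    class = "mono_mesh")
}

#' @export
print.mono_mesh <- function(x, ...) {
  cat(sprintf("<mono_mesh> %d nodes, %d %s elements, materials {%s}\n",
              nrow(x$nodes), nrow(x$elements), x$element_kind,
              paste(sort(unique(x$material_id)), collapse = ", ")))
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("  bounding box [%g, %g] x [%g, %g] x [%g, %g] m\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Structured hexahedral slab mesh
#'
#' Builds the regular hexahedral lattice covering the box
#' `[0, Lx] x [0, Ly] x [0, Lz]` with cubic cells of edge `dx`.  Every
#' extent must be an integer multiple of `dx` (to within a relative
#' rounding tolerance of 1e-8).  All elements get material label 0.
#'
#' @param extents numeric length-3, box edge lengths in metres.
#' @param dx cell edge in metres.
#' @return a `mono_mesh` with `prod(extents/dx)` hexahedra.
#' @examples
#' m <- build_slab_mesh(c(3, 7, 20) * 1e-3, 0.5e-3)
#' nrow(m$elements)  # 6 * 14 * 40 = 3360
#' @export
build_slab_mesh <- function(extents, dx) {
  if (length(extents) != 3L || any(!is.finite(extents)) || any(extents <= 0)) {
    stop("extents must be 3 positive lengths (m)")
  }
  if (!is.finite(dx) || dx <= 0) stop("dx must be a positive length (m)")
  ncell <- round(extents / dx)
  if (any(ncell < 1) || any(abs(ncell * dx - extents) > 1e-8 * pmax(extents, dx))) {
    stop(sprintf(
      "each extent must be an integer multiple of dx = %g m (got %s m)",
      dx, paste(extents, collapse = ", ")))
  }
  ncell <- as.integer(ncell)
  nx <- ncell[1]; ny <- ncell[2]; nz <- ncell[3]
  xs <- seq(0, by = dx, length.out = nx + 1L)
  ys <- seq(0, by = dx, length.out = ny + 1L)
  zs <- seq(0, by = dx, length.out = nz + 1L)
  # node (i,j,k) -> index i + (nx+1)(j + (ny+1) k) + 1, i fastest
  nodes <- cbind(
    rep(xs, times = (ny + 1L) * (nz + 1L)),
    rep(rep(ys, each = nx + 1L), times = nz + 1L),
    rep(zs, each = (nx + 1L) * (ny + 1L)))
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  i <- rep(0:(nx - 1L), times = ny * nz)
  j <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  k <- rep(0:(nz - 1L), each = nx * ny)
  elements <- cbind(
    nid(i,      j,      k),
    nid(i + 1L, j,      k),
    nid(i + 1L, j + 1L, k),
    nid(i,      j + 1L, k),
    nid(i,      j,      k + 1L),
    nid(i + 1L, j,      k + 1L),
    nid(i + 1L, j + 1L, k + 1L),
    nid(i,      j + 1L, k + 1L))
  mono_mesh(nodes, elements, "hexahedron")
}

#' Per-element volumes
#'
#' Tetrahedra use the determinant formula; hexahedra are integrated with the
#' trilinear-map Jacobian at a 2x2x2 Gauss rule (exact for trilinear maps).
#'
#' @param mesh a `mono_mesh`.
#' @return numeric vector of element volumes in cubic metres.
#' @export
element_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "mono_mesh"))
  if (mesh$element_kind == "tetrahedron") {
    v1 <- mesh$nodes[mesh$elements[, 1], , drop = FALSE]
    a <- mesh$nodes[mesh$elements[, 2], , drop = FALSE] - v1
    b <- mesh$nodes[mesh$elements[, 3], , drop = FALSE] - v1
    c_ <- mesh$nodes[mesh$elements[, 4], , drop = FALSE] - v1
    det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    abs(det3) / 6
  } else {
    qr_ <- quadrature_rule("hexahedron", 1L)
    ref <- reference_element("hexahedron", 1L, qr_$x)
    vol <- numeric(nrow(mesh$elements))
    for (q in seq_along(qr_$w)) {
      J <- .element_jacobians(mesh, ref$grad[q, , ])
      vol <- vol + qr_$w[q] * J$det
    }
    vol
  }
}

# Jacobian of the (tri)linear geometry map at one reference point.
# grad_q: nv x 3 reference gradients at that point. Returns list of the 9
# entries (vectors over elements), the determinant, and the inverse entries.
.element_jacobians <- function(mesh, grad_q) {
  el <- mesh$elements
  J <- vector("list", 9L)
  idx <- 1L
  for (i in 1:3) for (j in 1:3) {      # J[i,j] = d x_i / d xi_j
    acc <- 0
    for (a in seq_len(ncol(el))) {
      acc <- acc + mesh$nodes[el[, a], i] * grad_q[a, j]
    }
    J[[idx]] <- acc
    idx <- idx + 1L
  }
  names(J) <- c("11", "12", "13", "21", "22", "23", "31", "32", "33")
  det <- J[["11"]] * (J[["22"]] * J[["33"]] - J[["23"]] * J[["32"]]) -
    J[["12"]] * (J[["21"]] * J[["33"]] - J[["23"]] * J[["31"]]) +
    J[["13"]] * (J[["21"]] * J[["32"]] - J[["22"]] * J[["31"]])
  if (any(det <= 0)) {
    stop(sprintf("degenerate element (non-positive Jacobian), e.g. element %d",
                 which(det <= 0)[1]))
  }
  inv <- vector("list", 9L)
  # inverse via adjugate / det
  inv[[1]] <- (J[["22"]] * J[["33"]] - J[["23"]] * J[["32"]]) / det
  inv[[2]] <- (J[["13"]] * J[["32"]] - J[["12"]] * J[["33"]]) / det
  inv[[3]] <- (J[["12"]] * J[["23"]] - J[["13"]] * J[["22"]]) / det
  inv[[4]] <- (J[["23"]] * J[["31"]] - J[["21"]] * J[["33"]]) / det
  inv[[5]] <- (J[["11"]] * J[["33"]] - J[["13"]] * J[["31"]]) / det
  inv[[6]] <- (J[["13"]] * J[["21"]] - J[["11"]] * J[["23"]]) / det
  inv[[7]] <- (J[["21"]] * J[["32"]] - J[["22"]] * J[["31"]]) / det
  inv[[8]] <- (J[["12"]] * J[["31"]] - J[["11"]] * J[["32"]]) / det
  inv[[9]] <- (J[["11"]] * J[["22"]] - J[["12"]] * J[["21"]]) / det
  names(inv) <- c("11", "12", "13", "21", "22", "23", "31", "32", "33")
  list(J = J, det = det, inv = inv)
}

#' Rescale mesh coordinates
#'
#' Multiplies all node coordinates by `scaling_factor`, e.g. `1e-3` to turn a
#' mesh authored in millimetres into the internal SI metres.
#'
#' @param mesh a `mono_mesh`.
#' @param scaling_factor positive dimensionless factor.
#' @return the rescaled `mono_mesh`.
#' @export
scale_mesh <- function(mesh, scaling_factor) {
  stopifnot(inherits(mesh, "mono_mesh"))
  if (!is.finite(scaling_factor) || scaling_factor <= 0) {
    stop("scaling_factor must be positive")
  }
  mesh$nodes <- mesh$nodes * scaling_factor
  mesh
}

#' Subdomain specification
#'
#' Describes one labelled region \eqn{\Omega_i}: which element material IDs
#' it owns, its conductivities along the fiber / sheet / sheet-normal
#' directions (m^2/s, already divided by \eqn{\chi_m C_m}), the ionic model
#' run there, optional per-region ionic parameter overrides, and whether the
#' region conducts at all (scar tissue sets `conductive = FALSE` and is
#' excluded from the solve).
#'
#' @param label unique region name.
#' @param material_ids integer element labels owned by this region.
#' @param sigma_l,sigma_t,sigma_n conductivities (m^2/s), non-negative.
#' @param ionic_model model name (see [ionic_model()]); may be `NA` for
#'   non-conductive regions.
#' @param overrides named list of ionic parameter overrides.
#' @param conductive logical; `FALSE` excludes the region from conduction.
#' @return an object of class `subdomain_spec`.
#' @export
subdomain_spec <- function(label, material_ids, sigma_l, sigma_t, sigma_n,
                           ionic_model = "TTP06", overrides = list(),
                           conductive = TRUE) {
  if (!nzchar(label)) stop("label must be a non-empty string")
  if (any(c(sigma_l, sigma_t, sigma_n) < 0)) {
    stop("conductivities must be non-negative")
  }
  structure(
    list(label = label, material_ids = as.integer(material_ids),
         sigma_l = sigma_l, sigma_t = sigma_t, sigma_n = sigma_n,
         ionic_model = ionic_model, overrides = overrides,
         conductive = isTRUE(conductive)),
    class = "subdomain_spec")
}

#' Partition a mesh into labelled subdomains
#'
#' Maps every element to exactly one [subdomain_spec()] through its material
#' label and computes, for the FE space of degree `degree`, which DOFs take
#' part in the conduction solve.  A DOF supported only on non-conductive
#' elements is inactive; DOFs on the interface between a conductive and a
#' non-conductive region are retained (they belong to conductive elements).
#'
#' @param mesh a `mono_mesh`.
#' @param specs list of [subdomain_spec()]; their `material_ids` must cover
#'   all element labels and be pairwise disjoint.
#' @param space optional [fe_space()] over `mesh`; defaults to degree 1.
#' @return an object of class `subdomain_partition` with per-subdomain
#'   element index sets, per-subdomain DOF sets, and the global active DOF
#'   index vector.
#' @export
build_subdomains <- function(mesh, specs, space = NULL) {
  stopifnot(inherits(mesh, "mono_mesh"))
  if (inherits(specs, "subdomain_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("at least one subdomain_spec is required")
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("subdomain labels must be unique")
  all_ids <- unlist(lapply(specs, `[[`, "material_ids"))
  if (anyDuplicated(all_ids)) {
    dup <- unique(all_ids[duplicated(all_ids)])
    stop(sprintf("material ID(s) %s claimed by more than one subdomain",
                 paste(dup, collapse = ", ")))
  }
  present <- sort(unique(mesh$material_id))
  orphan <- setdiff(present, all_ids)
  if (length(orphan)) {
    stop(sprintf("mesh material ID(s) not covered by any subdomain: %s",
                 paste(orphan, collapse = ", ")))
  }
  if (is.null(space)) space <- fe_space(mesh, degree = 1L)
  elem_sets <- lapply(specs, function(sp) {
    which(mesh$material_id %in% sp$material_ids)
  })
  dof_sets <- lapply(elem_sets, function(ix) {
    sort(unique(as.vector(space$elem_dofs[ix, , drop = FALSE])))
  })
  conductive <- vapply(specs, `[[`, TRUE, "conductive")
  active <- sort(unique(unlist(dof_sets[conductive])))
  structure(
    list(mesh = mesh, space = space, specs = specs, labels = labels,
         elem_sets = elem_sets, dof_sets = dof_sets,
         conductive = conductive, active_dofs = active),
    class = "subdomain_partition")
}

#' @export
print.subdomain_partition <- function(x, ...) {
  cat(sprintf("<subdomain_partition> %d subdomain(s), %d/%d active DOFs\n",
              length(x$specs), length(x$active_dofs), x$space$n_dofs))
  for (i in seq_along(x$specs)) {
    cat(sprintf("  %-12s: %d elements, %d DOFs%s\n", x$labels[i],
                length(x$elem_sets[[i]]), length(x$dof_sets[[i]]),
                if (x$conductive[i]) "" else " (non-conductive)"))
  }
  invisible(x)
}

# Structural fingerprint used by checkpoint/restore guards.
mesh_fingerprint <- function(mesh) {
  c(n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$elements),
    kind = unname(.kind_nv[[mesh$element_kind]]),
    coord_sum = sum(mesh$nodes), coord_sq = sum(mesh$nodes^2),
    conn_sum = sum(as.double(mesh$elements)),
    mat_sum = sum(as.double(mesh$material_id)))
}
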