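# Mesh and field I/O: ASCII VTU (XML unstructured grid) read/write and gmsh
# MSH (v2.2 / v4.1 ASCII) readers.  All files are plain text; coordinates are
# rescaled to SI metres at import time via the scaling factor.

.vtk_cell_types <- c(tetrahedron = 10L, hexahedron = 12L)

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a mesh (with optional fields) to an ASCII VTU file
#'
#' @param mesh a [mono_mesh()].
#' @param path output file.
#' @param point_data named list of per-node scalars (length n) or vectors
#'   (n x 3 matrices).
#' @param cell_data named list of per-element scalars.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "mono_mesh"))
  n <- nrow(mesh$nodes); E <- nrow(mesh$elements)
  nv <- ncol(mesh$elements)
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, E)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(.fmt_num(mesh$nodes[, 1]), .fmt_num(mesh$nodes[, 2]),
                   .fmt_num(mesh$nodes[, 3])), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elements - 1L, 1, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(E) * nv), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(.vtk_cell_types[[mesh$element_kind]], E)), con)
  w('        </DataArray>')
  w('      </Cells>')
  write_arrays <- function(data, rows) {
    for (nm in names(data)) {
      a <- data[[nm]]
      nc <- if (is.matrix(a)) ncol(a) else 1L
      a <- matrix(a, nrow = rows)
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, nc)
      txt <- do.call(paste, lapply(seq_len(nc), function(j) .fmt_num(a[, j])))
      writeLines(txt, con)
      w('        </DataArray>')
    }
  }
  w('      <PointData>')
  write_arrays(point_data, n)
  w('      </PointData>')
  w('      <CellData>')
  write_arrays(c(list(material_id = as.numeric(mesh$material_id)), cell_data), E)
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read an ASCII VTU file
#'
#' Returns the raw contents (points, connectivity, cell types, named point
#' and cell data arrays); use [import_mesh()] to get a [mono_mesh()].
#'
#' @param path VTU file.
#' @return list with `points`, `connectivity` (list of 1-based index
#'   vectors), `types`, `point_data`, `cell_data`.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("no <Piece> in VTU file")
  num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  pts <- matrix(num(pts_node), ncol = 3, byrow = TRUE)
  get_cell_array <- function(name) {
    node <- xml2::xml_find_first(
      piece, sprintf("./Cells/DataArray[@Name='%s']", name))
    num(node)
  }
  connect <- get_cell_array("connectivity")
  offsets <- get_cell_array("offsets")
  types <- as.integer(get_cell_array("types"))
  starts <- c(1, utils::head(offsets, -1) + 1)
  connectivity <- lapply(seq_along(offsets), function(e) {
    as.integer(connect[starts[e]:offsets[e]]) + 1L
  })
  read_data <- function(which) {
    nodes <- xml2::xml_find_all(piece, sprintf("./%s/DataArray", which))
    out <- list()
    for (nd in nodes) {
      nm <- xml2::xml_attr(nd, "Name")
      nc <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
      if (is.na(nc)) nc <- 1L
      v <- num(nd)
      out[[nm]] <- if (nc > 1L) matrix(v, ncol = nc, byrow = TRUE) else v
    }
    out
  }
  list(points = pts, connectivity = connectivity, types = types,
       point_data = read_data("PointData"), cell_data = read_data("CellData"))
}

# ---- gmsh MSH readers -------------------------------------------------------

.read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- scan(text = sec("MeshFormat")[1], quiet = TRUE)
  version <- fmt[1]
  if (version >= 4) .read_msh41(sec) else .read_msh22(sec)
}

.read_msh22 <- function(sec) {
  nl <- sec("Nodes")
  nn <- as.integer(nl[1])
  ndat <- matrix(scan(text = nl[2:(nn + 1)], quiet = TRUE), ncol = 4, byrow = TRUE)
  tag_map <- ndat[, 1]
  points <- ndat[, 2:4, drop = FALSE]
  elines <- sec("Elements")
  ne <- as.integer(elines[1])
  conn <- list(); types <- integer(0); mats <- integer(0)
  for (i in 2:(ne + 1)) {
    v <- scan(text = elines[i], quiet = TRUE)
    etype <- v[2]; ntags <- v[3]
    if (!etype %in% c(4, 5)) next  # volumetric linear cells only
    nodes <- v[(4 + ntags):length(v)]
    conn[[length(conn) + 1L]] <- match(nodes, tag_map)
    types <- c(types, if (etype == 4) 10L else 12L)
    mats <- c(mats, if (ntags >= 1) as.integer(v[4]) else NA_integer_)
  }
  list(points = points, connectivity = conn, types = types, material = mats)
}

.read_msh41 <- function(sec) {
  # physical tag of each 3D entity, when the $Entities section is present
  ent_phys <- list()
  el <- sec("Entities")
  if (!is.null(el)) {
    counts <- scan(text = el[1], quiet = TRUE)  # nPoints nCurves nSurfaces nVolumes
    row <- 2 + sum(counts[1:3])
    if (counts[4] > 0) {
      for (i in seq_len(counts[4])) {
        v <- scan(text = el[row + i - 1], quiet = TRUE)
        # tag, 6 bbox values, numPhysicalTags, tags..., numBounding...
        npt <- v[8]
        ent_phys[[as.character(as.integer(v[1]))]] <-
          if (npt >= 1) as.integer(v[9]) else NA_integer_
      }
    }
  }
  nl <- sec("Nodes")
  hdr <- scan(text = nl[1], quiet = TRUE)
  nblocks <- hdr[1]; nn <- hdr[2]
  tag_map <- integer(nn); points <- matrix(0, nn, 3)
  row <- 2L; filled <- 0L
  for (b in seq_len(nblocks)) {
    bh <- scan(text = nl[row], quiet = TRUE)  # dim tag parametric count
    cnt <- bh[4]; row <- row + 1L
    if (cnt > 0) {
      tags <- as.integer(scan(text = nl[row:(row + cnt - 1)], quiet = TRUE))
      row <- row + cnt
      xyz <- matrix(scan(text = nl[row:(row + cnt - 1)], quiet = TRUE),
                    ncol = 3, byrow = TRUE)
      row <- row + cnt
      tag_map[filled + seq_len(cnt)] <- tags
      points[filled + seq_len(cnt), ] <- xyz
      filled <- filled + cnt
    }
  }
  el2 <- sec("Elements")
  hdr <- scan(text = el2[1], quiet = TRUE)
  nblocks <- hdr[1]
  conn <- list(); types <- integer(0); mats <- integer(0)
  row <- 2L
  for (b in seq_len(nblocks)) {
    bh <- scan(text = el2[row], quiet = TRUE)  # entityDim entityTag elemType count
    dim <- bh[1]; etag <- bh[2]; etype <- bh[3]; cnt <- bh[4]
    row <- row + 1L
    if (cnt == 0) next
    block <- el2[row:(row + cnt - 1)]
    row <- row + cnt
    if (dim != 3 || !etype %in% c(4, 5)) next
    mat <- ent_phys[[as.character(as.integer(etag))]]
    if (is.null(mat) || is.na(mat)) mat <- as.integer(etag)
    for (ln in block) {
      v <- scan(text = ln, quiet = TRUE)
      conn[[length(conn) + 1L]] <- match(v[-1], tag_map)
      types <- c(types, if (etype == 4) 10L else 12L)
      mats <- c(mats, mat)
    }
  }
  list(points = points, connectivity = conn, types = types, material = mats)
}

#' Import a mesh from a gmsh MSH or VTU file
#'
#' Reads the file (format chosen by extension: `.msh` or `.vtu`), keeps the
#' volumetric cells, and multiplies coordinates by `scaling_factor` so the
#' internal units are SI metres (`1e-3` for millimetre files).  Meshes mixing
#' tetrahedra and hexahedra are rejected.  Elements without a material label
#' get label 0 with a warning.
#'
#' @param path mesh file.
#' @param scaling_factor positive coordinate scale (default 1).
#' @return a [mono_mesh()].
#' @export
import_mesh <- function(path, scaling_factor = 1) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "msh") {
    .read_msh(path)
  } else if (ext == "vtu") {
    vt <- read_vtu(path)
    mat <- vt$cell_data[["material_id"]]
    if (is.null(mat)) mat <- vt$cell_data[["gmsh:physical"]]
    list(points = vt$points, connectivity = vt$connectivity,
         types = vt$types,
         material = if (is.null(mat)) rep(NA_integer_, length(vt$types))
                    else as.integer(round(mat)))
  } else {
    stop(sprintf("unsupported mesh format '.%s' (use .msh or .vtu)", ext))
  }
  vol <- raw$types %in% c(10L, 12L)
  if (!any(vol)) stop("no volumetric (tet/hex) cells in file")
  types <- unique(raw$types[vol])
  if (length(types) > 1L) {
    stop("mixed tetrahedral/hexahedral meshes are not supported")
  }
  kind <- if (types == 10L) "tetrahedron" else "hexahedron"
  conn <- do.call(rbind, raw$connectivity[vol])
  mats <- raw$material[vol]
  if (anyNA(mats)) {
    warning("cells without material label assigned label 0")
    mats[is.na(mats)] <- 0L
  }
  used <- sort(unique(as.vector(conn)))
  if (length(used) < nrow(raw$points)) {
    # drop nodes only referenced by lower-dimensional cells
    remap <- integer(nrow(raw$points))
    remap[used] <- seq_along(used)
    conn <- matrix(remap[conn], nrow(conn), ncol(conn))
    pts <- raw$points[used, , drop = FALSE]
  } else {
    pts <- raw$points
  }
  scale_mesh(mono_mesh(pts, conn, kind, mats), scaling_factor)
}
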