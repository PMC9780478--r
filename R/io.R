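#' File input/output
#'
#' Plain-text mesh formats (STL, PLY, legacy VTK polydata, VTU unstructured
#' grids), NIfTI label volumes, and Abaqus-INP finite element decks.
#'
#' @name io
NULL

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Write a surface or hex mesh to a file by extension
#'
#' Supported: `.stl`, `.ply`, `.vtk` (legacy polydata) for surfaces;
#' `.vtu` (XML unstructured grid, ASCII) for surfaces and hex meshes.
#'
#' @param mesh a [tri_surface()] or `hex_mesh`.
#' @param path output path; the extension selects the format.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(mesh, "hex_mesh") || (!is.null(mesh$hexes))) {
    if (ext != "vtu") stop("hex meshes can only be written to .vtu")
    return(write_vtu_hex(mesh, path))
  }
  switch(ext,
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         vtk = write_vtk_poly(mesh, path),
         vtu = write_vtu_tri(mesh, path),
         stop("unknown mesh extension: .", ext))
}

#' Read a surface or hex mesh from a file by extension
#'
#' STL input (a triangle soup) is welded into a connected surface with a
#' documented vertex-merge tolerance of 1e-6 mm.
#'
#' @param path input path (`.stl`, `.ply`, `.vtk`, `.vtu`).
#' @return a [tri_surface()], or a `hex_mesh` for `.vtu` files containing
#'   hexahedral cells.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         vtk = read_vtk_poly(path),
         vtu = read_vtu(path),
         stop("unknown mesh extension: .", ext))
}

write_stl <- function(surface, path) {
  V <- surface$vertices; F <- surface$triangles
  n <- triangle_normals(surface)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid hexcart", con)
  for (r in seq_len(nrow(F))) {
    writeLines(c(
      paste(" facet normal", paste(fmt_num(n[r, ]), collapse = " ")),
      "  outer loop",
      paste("   vertex", paste(fmt_num(V[F[r, 1], ]), collapse = " ")),
      paste("   vertex", paste(fmt_num(V[F[r, 2], ]), collapse = " ")),
      paste("   vertex", paste(fmt_num(V[F[r, 3], ]), collapse = " ")),
      "  endloop", " endfacet"), con)
  }
  writeLines("endsolid hexcart", con)
  invisible(path)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  nt <- nrow(nums) / 3
  soup <- tri_surface(nums, matrix(seq_len(3 * nt), nt, 3, byrow = TRUE))
  weld_vertices(soup, tol = 1e-6)
}

write_ply <- function(surface, path) {
  V <- surface$vertices; F <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(V, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(apply(F - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines, value = TRUE)))
  hdr <- which(lines == "end_header")
  V <- do.call(rbind, lapply(strsplit(trimws(lines[hdr + seq_len(nv)]),
                                      "\\s+"), function(p) as.numeric(p[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(lines[hdr + nv + seq_len(nf)]),
                                      "\\s+"), function(p)
    as.integer(p[2:4]) + 1L))
  tri_surface(V, F)
}

write_vtk_poly <- function(surface, path) {
  V <- surface$vertices; F <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hexcart surface", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nrow(V), "double")), con)
  writeLines(apply(V, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(paste("POLYGONS", nrow(F), 4 * nrow(F)), con)
  writeLines(apply(F - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

read_vtk_poly <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pl <- grep("^POINTS", lines)
  nv <- as.integer(strsplit(lines[pl], "\\s+")[[1]][2])
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(pl + 1):(pl + ceiling(nv))]), "\\s+")))
  V <- matrix(vals[seq_len(3 * nv)], nv, 3, byrow = TRUE)
  gl <- grep("^POLYGONS", lines)
  nf <- as.integer(strsplit(lines[gl], "\\s+")[[1]][2])
  F <- do.call(rbind, lapply(strsplit(trimws(lines[gl + seq_len(nf)]),
                                      "\\s+"), function(p)
    as.integer(p[2:4]) + 1L))
  tri_surface(V, F)
}

vtu_skeleton <- function(points, connectivity, offsets, types) {
  c('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(points), length(offsets)),
    "<Points>",
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    apply(points, 1, function(r) paste(fmt_num(r), collapse = " ")),
    "</DataArray>", "</Points>", "<Cells>",
    '<DataArray type="Int64" Name="connectivity" format="ascii">',
    paste(connectivity, collapse = " "),
    "</DataArray>",
    '<DataArray type="Int64" Name="offsets" format="ascii">',
    paste(offsets, collapse = " "),
    "</DataArray>",
    '<DataArray type="UInt8" Name="types" format="ascii">',
    paste(types, collapse = " "),
    "</DataArray>", "</Cells>", "</Piece>", "</UnstructuredGrid>",
    "</VTKFile>")
}

write_vtu_hex <- function(mesh, path) {
  h <- mesh$hexes
  conn <- as.vector(t(h)) - 1L
  offs <- seq_len(nrow(h)) * 8L
  writeLines(vtu_skeleton(mesh$nodes, conn, offs, rep(12L, nrow(h))), path)
  invisible(path)
}

write_vtu_tri <- function(surface, path) {
  F <- surface$triangles
  conn <- as.vector(t(F)) - 1L
  offs <- seq_len(nrow(F)) * 3L
  writeLines(vtu_skeleton(surface$vertices, conn, offs, rep(5L, nrow(F))),
             path)
  invisible(path)
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  arr <- function(xp) as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(piece, xp))), "\\s+")[[1]])
  pts <- arr(".//Points/DataArray")
  V <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- as.integer(arr(".//DataArray[@Name='connectivity']")) + 1L
  types <- as.integer(arr(".//DataArray[@Name='types']"))
  if (all(types == 12L)) {
    h <- matrix(conn, ncol = 8, byrow = TRUE)
    structure(list(nodes = V, hexes = h, layer_count = NA_integer_,
                   provenance = list(fallbacks = character(0))),
              class = "hex_mesh")
  } else if (all(types == 5L)) {
    tri_surface(V, matrix(conn, ncol = 3, byrow = TRUE))
  } else stop("unsupported VTU cell types: ", paste(unique(types),
                                                    collapse = ", "))
}

#' Write a label volume to NIfTI
#' @param volume a [label_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_label_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$codes)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#' @param path input `.nii` / `.nii.gz` path.
#' @param tissue_map named code mapping (default [default_tissue_map()]).
#' @export
read_label_volume <- function(path, tissue_map = default_tissue_map()) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  label_volume(array(as.integer(img), dim(img)), sp[1:3],
               origin = c(0, 0, 0), tissue_map = tissue_map)
}

# ---------------------------------------------------------------------------
# Abaqus INP export
# ---------------------------------------------------------------------------

#' Export meshes and attachment sites as an Abaqus-INP deck
#'
#' Cartilage hex meshes become 8-node linear continuum (C3D8) element sets,
#' bone surfaces become 3-node rigid shell (R3D3) element sets, and every
#' attachment site or joint-axis landmark becomes a named node set. The deck
#' round-trips through [read_fe_deck()] with exact counts and coordinates to
#' at least nine significant digits.
#'
#' @param meshes named list of `hex_mesh` (cartilage) and/or
#'   [tri_surface()] (bone) objects.
#' @param attachment_sites optional data.frame from
#'   [map_attachment_sites()]; node ids must refer to the mesh named by the
#'   `tissue` column.
#' @param path output `.inp` path.
#' @export
export_fe_deck <- function(meshes, attachment_sites = NULL, path) {
  lines <- c("*HEADING", "hexcart export")
  offset <- 0L
  el_offset <- 0L
  node_offsets <- integer(0)
  for (nm in names(meshes)) {
    mesh <- meshes[[nm]]
    is_hex <- !is.null(mesh$hexes)
    if (is_hex) {
      cc <- check_conformity(mesh)
      if (!cc$conforming)
        stop("refusing to export non-conforming hex mesh '", nm, "'")
    }
    nodes <- if (is_hex) mesh$nodes else mesh$vertices
    elems <- if (is_hex) mesh$hexes else mesh$triangles
    node_offsets[nm] <- offset
    lines <- c(lines, sprintf("*NODE, NSET=N_%s", toupper(nm)),
               sprintf("%d, %s, %s, %s", seq_len(nrow(nodes)) + offset,
                       fmt_num(nodes[, 1]), fmt_num(nodes[, 2]),
                       fmt_num(nodes[, 3])))
    eltype <- if (is_hex) "C3D8" else "R3D3"
    lines <- c(lines, sprintf("*ELEMENT, TYPE=%s, ELSET=E_%s", eltype,
                              toupper(nm)),
               apply(cbind(seq_len(nrow(elems)) + el_offset,
                           elems + offset), 1, paste, collapse = ", "))
    offset <- offset + nrow(nodes)
    el_offset <- el_offset + nrow(elems)
  }
  if (!is.null(attachment_sites)) {
    for (r in seq_len(nrow(attachment_sites))) {
      tis <- attachment_sites$tissue[r]
      off <- if (tis %in% names(node_offsets)) node_offsets[[tis]] else
        node_offsets[[1]]
      lines <- c(lines,
                 sprintf("*NSET, NSET=SITE_%s",
                         toupper(attachment_sites$name[r])),
                 sprintf("%d", attachment_sites$node_id[r] + off))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back an Abaqus-INP deck written by [export_fe_deck()]
#'
#' @param path `.inp` path.
#' @return list with `nodes` (matrix, rows in file node-id order),
#'   `elements` (list per ELSET: matrix of node ids + `type`), `nsets`
#'   (named list of node-id vectors for the site sets).
#' @export
read_fe_deck <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nodes <- list(); elements <- list(); nsets <- list()
  i <- 1
  while (i <= length(lines)) {
    l <- lines[i]
    if (grepl("^\\*NODE", l)) {
      j <- i + 1
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1
      p <- strsplit(lines[(i + 1):(j - 1)], ",\\s*")
      ids <- as.integer(vapply(p, `[[`, character(1), 1))
      xyz <- t(vapply(p, function(r) as.numeric(r[2:4]), numeric(3)))
      nodes[[length(nodes) + 1]] <- cbind(ids, xyz)
      i <- j
    } else if (grepl("^\\*ELEMENT", l)) {
      type <- sub(".*TYPE=([A-Z0-9]+).*", "\\1", l)
      elset <- sub(".*ELSET=([A-Za-z0-9_]+).*", "\\1", l)
      j <- i + 1
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1
      p <- strsplit(lines[(i + 1):(j - 1)], ",\\s*")
      conn <- t(vapply(p, function(r) as.integer(r[-1]),
                       integer(length(p[[1]]) - 1)))
      elements[[elset]] <- list(type = type, connectivity = conn)
      i <- j
    } else if (grepl("^\\*NSET", l)) {
      nset <- sub(".*NSET=([A-Za-z0-9_]+).*", "\\1", l)
      j <- i + 1
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1
      nsets[[nset]] <- as.integer(unlist(strsplit(lines[(i + 1):(j - 1)],
                                                  ",\\s*")))
      i <- j
    } else i <- i + 1
  }
  nodemat <- do.call(rbind, nodes)
  nodemat <- nodemat[order(nodemat[, 1]), , drop = FALSE]
  list(nodes = nodemat[, 2:4, drop = FALSE], elements = elements,
       nsets = nsets)
}
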