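#' Surface reconstruction from tissue label masks
#'
#' Turns per-tissue binary label masks into clean, consistently oriented
#' triangular surfaces: iso-surface extraction on an antialiased indicator
#' field, artifact-component removal, quadric decimation, Laplacian
#' smoothing, and orientation/topology repair.
#'
#' @name reconstruct
NULL

# 3x3x3 box mean of a numeric array (edge-replicated): antialiases the
# binary indicator so the iso 0.5 surface is smooth rather than a staircase
box_smooth3 <- function(a) {
  d <- dim(a)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    acc <- acc + shift_array_num(a, di, dj, dk, 0)
    cnt <- cnt + shift_array_num(array(1, d), di, dj, dk, 0)
  }
  acc / cnt
}

shift_array_num <- function(a, di, dj, dk, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) max(1, 1 - s):min(n, n - s)
  i <- src(d[1], di); j <- src(d[2], dj); k <- src(d[3], dk)
  out[i + di, j + dj, k + dk] <- a[i, j, k]
  out
}

shift_na_to_zero <- function(a) { a[is.na(a)] <- 0; a }

#' Extract the iso-surface of one tissue code
#'
#' The binary mask is zero-padded (so surfaces touching the volume boundary
#' are capped closed), antialiased with a small box filter, and triangulated
#' at the 0.5 iso-level by marching tetrahedra on a consistent 6-tet cube
#' split. The output is a closed surface in world (mm) coordinates with
#' outward-facing normals.
#'
#' @param volume a [label_volume()].
#' @param code integer tissue code or tissue name present in the volume.
#' @return a [tri_surface()].
#' @export
extract_surface <- function(volume, code) {
  code <- tissue_code(volume, code)
  mask <- volume$codes == code
  if (!any(mask)) stop("code ", code, " absent from volume")
  pad <- 2L
  d <- dim(mask) + 2L * pad
  field <- array(0, d)
  field[pad + seq_len(dim(mask)[1]), pad + seq_len(dim(mask)[2]),
        pad + seq_len(dim(mask)[3])] <- as.numeric(mask)
  field <- box_smooth3(field)
  origin <- volume$origin - pad * volume$spacing
  s <- cpp_marching_tets(as.numeric(field), d, volume$spacing, origin, 0.5)
  if (nrow(s$triangles) == 0)
    stop("iso-surface is empty: mask for code ", code,
         " is below the resolvable size")
  surf <- tri_surface(s$vertices, s$triangles)
  if (surface_volume(surf) < 0)
    surf <- tri_surface(surf$vertices, surf$triangles[, c(1, 3, 2)])
  surf
}

#' Keep only the component with the largest enclosed volume
#'
#' Disconnected pieces are treated as segmentation artifacts. Components are
#' ranked by absolute divergence-theorem signed volume; open components,
#' whose signed volume is not meaningful, are ranked by surface area instead
#' (scaled to compare against volumes only among themselves).
#'
#' @param surface a [tri_surface()], possibly multi-component.
#' @return a [tri_surface()] with a single connected component.
#' @export
keep_largest_component <- function(surface) {
  comp <- surface_components(surface)
  if (max(comp) == 1) return(surface)
  scores <- vapply(seq_len(max(comp)), function(ci) {
    sub <- tri_surface(surface$vertices,
                       surface$triangles[comp == ci, , drop = FALSE])
    if (is_watertight_sub(sub)) abs(surface_volume(sub))
    else -1 / surface_area(sub) # open artifacts rank below any closed piece
  }, numeric(1))
  if (all(scores < 0)) # all open: rank by area
    scores <- vapply(seq_len(max(comp)), function(ci)
      surface_area(tri_surface(surface$vertices,
                               surface$triangles[comp == ci, , drop = FALSE])),
      numeric(1))
  best <- which.max(scores)
  drop_unused_vertices(tri_surface(surface$vertices,
                                   surface$triangles[comp == best, ,
                                                     drop = FALSE]))
}

is_watertight_sub <- function(surface) {
  if (nrow(surface$triangles) == 0) return(FALSE)
  all(surface_edges(surface)$counts == 2)
}

drop_unused_vertices <- function(surface) {
  used <- sort(unique(as.vector(surface$triangles)))
  map <- integer(nrow(surface$vertices))
  map[used] <- seq_along(used)
  tri_surface(surface$vertices[used, , drop = FALSE],
              matrix(map[surface$triangles], ncol = 3))
}

#' Decimate and smooth a reconstructed surface
#'
#' Quadric-error-metric edge collapse reduces the triangle count by
#' `decimation_fraction` (0.8 removes 80% of the triangles), then uniform
#' Laplacian smoothing is applied for `smoothing_iterations` passes.
#'
#' @param surface a [tri_surface()] with at least 100 triangles (unless both
#'   parameters are zero, in which case the surface is returned unchanged).
#' @param decimation_fraction fraction of triangles to remove, in [0, 1).
#' @param smoothing_iterations Laplacian smoothing passes.
#' @param relaxation smoothing relaxation factor; the small default removes
#'   voxel-staircase noise without collapsing thin rims.
#' @return a [tri_surface()].
#' @export
simplify_smooth <- function(surface, decimation_fraction = 0.8,
                            smoothing_iterations = 9, relaxation = 0.1) {
  if (decimation_fraction == 0 && smoothing_iterations == 0) return(surface)
  if (nrow(surface$triangles) < 100)
    stop("surface has fewer than 100 triangles; refusing to decimate")
  if (decimation_fraction > 0) {
    target <- as.integer(round(nrow(surface$triangles) *
                                 (1 - decimation_fraction)))
    d <- cpp_qem_decimate(surface$vertices, surface$triangles, target)
    surface <- tri_surface(d$vertices, d$triangles)
  }
  laplacian_smooth(surface, smoothing_iterations, relaxation)
}

#' Repair a reconstructed surface
#'
#' Bone surfaces get a full repair: vertex welding, removal of degenerate
#' and duplicated triangles, retention of the largest component, consistent
#' re-orientation, and a watertightness check. Cartilage surfaces only have
#' inconsistent or inward-facing normals flipped, leaving boundary and hole
#' topology untouched (physiological holes must survive).
#'
#' @param surface a connected [tri_surface()].
#' @param mode `"bone_full"` or `"cartilage_normals_only"`.
#' @return a [tri_surface()].
#' @export
repair_surface <- function(surface,
                           mode = c("bone_full", "cartilage_normals_only")) {
  mode <- match.arg(mode)
  if (mode == "bone_full") {
    surface <- weld_vertices(surface, tol = 1e-9)
    surface <- remove_degenerate_triangles(surface)
    surface <- remove_duplicate_triangles(surface)
    surface <- keep_largest_component(surface)
    surface <- orient_consistently(surface)
    e <- surface_edges(surface)
    if (any(e$counts > 2))
      stop("unrecoverable non-manifold bone surface: ",
           sum(e$counts > 2), " edges shared by >2 triangles")
    surface
  } else {
    orient_consistently(surface)
  }
}

remove_degenerate_triangles <- function(surface) {
  n <- triangle_normals(surface)
  area2 <- sqrt(rowSums(n^2))
  tri_surface(surface$vertices,
              surface$triangles[area2 > 1e-12, , drop = FALSE])
}

remove_duplicate_triangles <- function(surface) {
  F <- surface$triangles
  key <- apply(F, 1, function(r) paste(sort(r), collapse = "-"))
  tri_surface(surface$vertices, F[!duplicated(key), , drop = FALSE])
}

# flood-fill consistent winding across shared edges, then flip globally if
# the enclosed signed volume is negative (closed components only)
orient_consistently <- function(surface) {
  F <- surface$triangles
  nf <- nrow(F)
  if (nf == 0) return(surface)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  keys <- ekey(e[, 1], e[, 2])
  face_of_edge <- split(rep(seq_len(nf), 3), keys)
  dir_of_edge <- split(e[, 1] < e[, 2], keys) # TRUE if stored low->high
  adj <- vector("list", nf)
  for (i in seq_along(face_of_edge)) {
    fs <- face_of_edge[[i]]
    if (length(fs) == 2) {
      adj[[fs[1]]] <- rbind(adj[[fs[1]]], c(fs[2], i))
      adj[[fs[2]]] <- rbind(adj[[fs[2]]], c(fs[1], i))
    }
  }
  flip <- rep(NA, nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      f <- queue[[1]]; queue <- queue[-1]
      nbrs <- adj[[f]]
      if (is.null(nbrs)) next
      for (r in seq_len(nrow(nbrs))) {
        g <- nbrs[r, 1]; ei <- nbrs[r, 2]
        if (!is.na(flip[g])) next
        dirs <- dir_of_edge[[ei]]
        fs <- face_of_edge[[ei]]
        df <- dirs[match(f, fs)]; dg <- dirs[match(g, fs)]
        # consistent orientation: the two faces traverse the edge oppositely
        same <- xor(df, dg)
        flip[g] <- if (same) flip[f] else !flip[f]
        queue <- c(queue, g)
      }
    }
  }
  Fo <- F
  Fo[flip, ] <- Fo[flip, c(1, 3, 2)]
  out <- tri_surface(surface$vertices, Fo)
  comp <- surface_components(out)
  for (ci in seq_len(max(comp))) {
    sel <- comp == ci
    sub <- tri_surface(out$vertices, out$triangles[sel, , drop = FALSE])
    if (is_watertight_sub(sub) && surface_volume(sub) < 0)
      out$triangles[sel, ] <- out$triangles[sel, c(1, 3, 2)]
  }
  out
}

#' Full reconstruction pipeline for one tissue
#'
#' Morphological closing, iso-surface extraction, largest-component filter,
#' decimation + smoothing, and repair, in order.
#'
#' @param volume a [label_volume()].
#' @param tissue tissue name or code.
#' @param tissue_class `"cartilage"` or `"bone"`; selects closing kernel
#'   (5 vs 3 voxels) and repair mode.
#' @param decimation_fraction,smoothing_iterations see [simplify_smooth()].
#' @return a [tri_surface()].
#' @export
reconstruct_tissue <- function(volume, tissue,
                               tissue_class = c("cartilage", "bone"),
                               decimation_fraction = 0.8,
                               smoothing_iterations = 9) {
  tissue_class <- match.arg(tissue_class)
  closed <- close_labels(volume, tissue, tissue_class)
  surf <- extract_surface(closed, 1L)
  surf <- keep_largest_component(surf)
  if (nrow(surf$triangles) >= 100)
    surf <- simplify_smooth(surf, decimation_fraction, smoothing_iterations)
  repair_surface(surf, if (tissue_class == "bone") "bone_full"
                 else "cartilage_normals_only")
}
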