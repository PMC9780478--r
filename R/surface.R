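#' Triangular surface mesh
#'
#' Lightweight container for an oriented triangle mesh in world (mm)
#' coordinates. Triangles index into the vertex table (1-based). Outward
#' orientation means a positive divergence-theorem signed volume for closed
#' surfaces.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param triangles integer M x 3 matrix of vertex indices (1-based).
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface: %d vertices, %d triangles%s>\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

#' Per-triangle areas and (unnormalized) normals
#' @keywords internal
triangle_normals <- function(surface) {
  V <- surface$vertices; F <- surface$triangles
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area (mm^2)
#' @param surface a [tri_surface()].
#' @export
surface_area <- function(surface) {
  n <- triangle_normals(surface)
  sum(sqrt(rowSums(n^2))) / 2
}

#' Signed enclosed volume (mm^3) by the divergence theorem
#'
#' Positive for closed surfaces with outward-facing normals.
#' @param surface a [tri_surface()].
#' @export
surface_volume <- function(surface) {
  V <- surface$vertices; F <- surface$triangles
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c2 <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c2[, 3] - b[, 3] * c2[, 2]) +
      a[, 2] * (b[, 3] * c2[, 1] - b[, 1] * c2[, 3]) +
      a[, 3] * (b[, 1] * c2[, 2] - b[, 2] * c2[, 1])) / 6
}

#' Undirected edge list with per-edge face counts
#' @keywords internal
surface_edges <- function(surface) {
  F <- surface$triangles
  e <- rbind(F[, c(1, 2), drop = FALSE],
             F[, c(2, 3), drop = FALSE],
             F[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  counts <- table(key)
  list(edges = e, key = key, counts = counts)
}

#' Number of boundary edges (edges used by exactly one triangle)
#' @param surface a [tri_surface()].
#' @export
boundary_edge_count <- function(surface) {
  sum(surface_edges(surface)$counts == 1)
}

#' Is every edge shared by exactly two triangles?
#' @param surface a [tri_surface()].
#' @export
is_watertight <- function(surface) {
  if (nrow(surface$triangles) == 0) return(FALSE)
  all(surface_edges(surface)$counts == 2)
}

#' Euler characteristic V - E + F
#' @param surface a [tri_surface()].
#' @export
euler_characteristic <- function(surface) {
  used <- sort(unique(as.vector(surface$triangles)))
  e <- surface_edges(surface)
  length(used) - length(e$counts) + nrow(surface$triangles)
}

#' Connected-component label per triangle (via shared vertices)
#' @keywords internal
surface_components <- function(surface) {
  F <- surface$triangles
  nv <- nrow(surface$vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(F))) {
    a <- find(F[r, 1]); b <- find(F[r, 2]); c2 <- find(F[r, 3])
    parent[b] <- a; parent[find(c2)] <- a
  }
  roots <- vapply(F[, 1], find, integer(1))
  match(roots, unique(roots))
}

#' Area-weighted vertex normals
#' @param surface a [tri_surface()].
#' @return N x 3 matrix of unit normals (zero rows for unused vertices).
#' @export
vertex_normals <- function(surface) {
  F <- surface$triangles
  fn <- triangle_normals(surface) # area-weighted already (length = 2*area)
  n <- matrix(0, nrow(surface$vertices), 3)
  for (c2 in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], F[, c2], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Apply a similarity transform to a surface
#' @param surface a [tri_surface()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @param scale positive scalar.
#' @export
transform_surface <- function(surface, rotation = diag(3),
                              translation = c(0, 0, 0), scale = 1) {
  v <- scale * surface$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  tri_surface(v, surface$triangles)
}

#' Uniform-umbrella Laplacian smoothing
#'
#' Each iteration moves every vertex toward the mean of its edge-connected
#' neighbours by the relaxation factor; boundary vertices are free. Small
#' relaxation factors remove voxel-staircase noise while limiting the
#' volumetric shrinkage inherent to Laplacian smoothing.
#' @param surface a [tri_surface()].
#' @param iterations number of smoothing passes.
#' @param relaxation step fraction toward the neighbourhood mean, in (0, 1].
#' @export
laplacian_smooth <- function(surface, iterations, relaxation = 1) {
  if (iterations <= 0) return(surface)
  F <- surface$triangles
  nv <- nrow(surface$vertices)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  i <- c(e[, 1], e[, 2]); j <- c(e[, 2], e[, 1])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  A@x[] <- 1 # collapse duplicate face contributions to unit edge weight
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  V <- surface$vertices
  for (it in seq_len(iterations))
    V <- (1 - relaxation) * V + relaxation * as.matrix(A %*% V) / deg
  tri_surface(V, F)
}

#' Closest points on a surface
#'
#' @param points N x 3 query points (mm).
#' @param surface a [tri_surface()].
#' @return list with `distance` (N), `point` (N x 3), `triangle` (N).
#' @export
closest_point_on_surface <- function(points, surface) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_closest_point(points, surface$vertices, surface$triangles)
}

#' Cast rays against a surface
#'
#' @param origins N x 3 ray origins (mm).
#' @param directions N x 3 ray directions (normalized internally).
#' @param surface a [tri_surface()].
#' @param tmin minimum accepted ray parameter.
#' @return list of numeric vectors of sorted hit distances, one per ray.
#' @export
cast_rays <- function(origins, directions, surface, tmin = 0) {
  origins <- matrix(as.numeric(origins), ncol = 3)
  directions <- matrix(as.numeric(directions), ncol = 3)
  len <- sqrt(rowSums(directions^2))
  directions <- directions / len
  cpp_ray_hits(origins, directions, surface$vertices, surface$triangles, tmin)
}

#' Merge coincident vertices
#' @param surface a [tri_surface()].
#' @param tol welding tolerance (mm).
#' @export
weld_vertices <- function(surface, tol = 1e-6) {
  V <- surface$vertices
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  Vn <- V[first, , drop = FALSE]
  Fn <- matrix(map[surface$triangles], ncol = 3)
  keep <- Fn[, 1] != Fn[, 2] & Fn[, 2] != Fn[, 3] & Fn[, 1] != Fn[, 3]
  tri_surface(Vn, Fn[keep, , drop = FALSE])
}

#' Symmetric Hausdorff distance between two surfaces (vertex sampled)
#' @param a,b [tri_surface()] objects.
#' @export
hausdorff_distance <- function(a, b) {
  d1 <- max(closest_point_on_surface(a$vertices, b)$distance)
  d2 <- max(closest_point_on_surface(b$vertices, a)$distance)
  max(d1, d2)
}
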