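#' Mesh quality and comparison metrics
#'
#' Scaled Jacobian element quality, feature angles between adjacent faces,
#' surface-to-surface deviation with nodal coverage, Dice overlap of label
#' masks, and min-max-normalized RMS differences between response series.
#'
#' @name metrics
NULL

# corner index pattern: bottom nodes 1:4 (counter-clockwise seen from the
# top node side), top nodes 5:8 aligned above. At bottom corner i the edges
# are (next - x, prev - x, up - x); at top corner (prev - x, next - x,
# down - x), which keeps all eight determinants +1 on the unit cube.
hex_corner_triplets <- function() {
  nxt <- c(2, 3, 4, 1); prv <- c(4, 1, 2, 3)
  rows <- vector("list", 8)
  for (i in 1:4) rows[[i]] <- c(i, nxt[i], prv[i], i + 4)
  for (i in 1:4) rows[[i + 4]] <- c(i + 4, prv[i] + 4, nxt[i] + 4, i)
  do.call(rbind, rows) # corner, a, b, c with edges a-corner, b-corner, c-corner
}

#' Scaled Jacobian of one hexahedral element
#'
#' Minimum over the eight corners of the determinant of the corner Jacobian
#' built from unit-normalized edge vectors. 1 is a perfect cube; values at
#' or below 0 indicate degenerate or inverted elements. Invariant under
#' rigid transforms and uniform scaling.
#'
#' @param hex_nodes 8 x 3 matrix of corner coordinates, ordered bottom face
#'   counter-clockwise (1-4) then top face (5-8) aligned above.
#' @return scalar in [-1, 1].
#' @export
scaled_jacobian <- function(hex_nodes) {
  hex_nodes <- matrix(as.numeric(hex_nodes), 8, 3)
  min(scaled_jacobian_all(hex_nodes, matrix(1:8, 1)))
}

#' Scaled Jacobian for every element of a hex mesh (vectorized)
#' @param nodes N x 3 node coordinates.
#' @param hexes E x 8 node indices.
#' @return numeric vector of length E.
#' @export
scaled_jacobian_all <- function(nodes, hexes) {
  hexes <- matrix(as.integer(hexes), ncol = 8)
  E <- nrow(hexes)
  trip <- hex_corner_triplets()
  sj <- rep(Inf, E)
  for (r in 1:8) {
    x0 <- nodes[hexes[, trip[r, 1]], , drop = FALSE]
    u <- nodes[hexes[, trip[r, 2]], , drop = FALSE] - x0
    v <- nodes[hexes[, trip[r, 3]], , drop = FALSE] - x0
    w <- nodes[hexes[, trip[r, 4]], , drop = FALSE] - x0
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2)); nw <- sqrt(rowSums(w^2))
    det3 <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
    denom <- nu * nv * nw
    val <- ifelse(denom > 0, det3 / denom, -1)
    sj <- pmin(sj, val)
  }
  pmax(-1, pmin(1, sj))
}

#' Feature angle across a shared edge
#'
#' The fold angle between the two faces meeting at an edge, measured as the
#' angle between their normals: 0 degrees for coplanar faces, 90 for
#' perpendicular ones. This deviation-from-flat convention is used for every
#' feature-angle threshold in the package (a 45-degree ramp meeting a plane
#' reads as 45 degrees).
#'
#' @param surface a [tri_surface()] or a list with `vertices` and `faces`
#'   (quad faces allowed, E x 4).
#' @param edge length-2 vector of vertex indices; the edge must be shared by
#'   exactly two faces.
#' @return angle in degrees.
#' @export
feature_angle <- function(surface, edge) {
  faces <- if (!is.null(surface$triangles)) surface$triangles else surface$faces
  V <- surface$vertices
  has <- rowSums(matrix(faces %in% edge, nrow(faces))) >= 2
  idx <- which(has)
  if (length(idx) != 2)
    stop("edge is shared by ", length(idx), " faces, need exactly 2")
  n1 <- face_normal(V, faces[idx[1], ])
  n2 <- face_normal(V, faces[idx[2], ])
  ang <- acos(pmax(-1, pmin(1, sum(n1 * n2))))
  ang * 180 / pi
}

face_normal <- function(V, f) {
  f <- f[!is.na(f)]
  a <- V[f[1], ]; b <- V[f[2], ]; c2 <- V[f[3], ]
  n <- c((b[2] - a[2]) * (c2[3] - a[3]) - (b[3] - a[3]) * (c2[2] - a[2]),
         (b[3] - a[3]) * (c2[1] - a[1]) - (b[1] - a[1]) * (c2[3] - a[3]),
         (b[1] - a[1]) * (c2[2] - a[2]) - (b[2] - a[2]) * (c2[1] - a[1]))
  if (length(f) == 4) { # average the two triangle normals of the quad
    n2 <- c((c2[2] - a[2]) * (V[f[4], 3] - a[3]) - (c2[3] - a[3]) * (V[f[4], 2] - a[2]),
            (c2[3] - a[3]) * (V[f[4], 1] - a[1]) - (c2[1] - a[1]) * (V[f[4], 3] - a[3]),
            (c2[1] - a[1]) * (V[f[4], 2] - a[2]) - (c2[2] - a[2]) * (V[f[4], 1] - a[1]))
    n <- n + n2
  }
  n / sqrt(sum(n^2))
}

#' Surface deviation with nodal coverage
#'
#' For every node of the predicted surface, the distance to the nearest
#' point on the reference surface is traced. Rays whose direction deviates
#' from the node normal by more than `max_normal_dev_deg` are excluded from
#' the statistics (they indicate mismatched, non-overlapping edges rather
#' than surface error); the percentage retained is the nodal coverage.
#'
#' @param predicted,reference oriented [tri_surface()] objects.
#' @param max_normal_dev_deg normal-deviation cutoff in degrees.
#' @return a `deviation_report`: per-node `distance` (mm), `included` flag,
#'   `coverage` (%), `summary` (median, quartiles, max over included nodes),
#'   and `kde` (Gaussian kernel density of included distances, Scott
#'   bandwidth).
#' @export
surface_deviation <- function(predicted, reference, max_normal_dev_deg = 20) {
  P <- predicted$vertices
  cp <- closest_point_on_surface(P, reference)
  d <- cp$distance
  nrm <- vertex_normals(predicted)
  ray <- cp$point - P
  raylen <- sqrt(rowSums(ray^2))
  cosang <- abs(rowSums(ray * nrm)) / pmax(raylen, 1e-12)
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  included <- raylen < 1e-9 | ang <= max_normal_dev_deg
  coverage <- 100 * mean(included)
  di <- d[included]
  summ <- if (length(di)) {
    q <- quantile(di, c(0.25, 0.5, 0.75), names = FALSE)
    c(q25 = q[1], median = q[2], q75 = q[3], max = max(di))
  } else c(q25 = NA_real_, median = NA_real_, q75 = NA_real_, max = NA_real_)
  kde <- if (length(di) >= 2 && sd(di) > 0)
    density(di, bw = "nrd") else NULL
  structure(list(distance = d, included = included, coverage = coverage,
                 summary = summ, kde = kde),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(
    "<deviation_report: %d nodes, coverage %.1f%%, median %.3f mm, max %.3f mm>\n",
    length(x$distance), x$coverage, x$summary["median"], x$summary["max"]))
  invisible(x)
}

#' Dice similarity coefficient of one label code in two volumes
#'
#' `2|A n B| / (|A| + |B|)` overlap of the binary masks for `code`.
#'
#' @param volume_a,volume_b [label_volume()] objects on the same grid.
#' @param code integer tissue code (or name resolvable in both volumes).
#' @return value in [0, 1] (1 if both masks are empty).
#' @export
dice_coefficient <- function(volume_a, volume_b, code = 1L) {
  if (!all(dim(volume_a$codes) == dim(volume_b$codes)))
    stop("volumes must share the same grid shape")
  a <- volume_a$codes == tissue_code(volume_a, code)
  b <- volume_b$codes == tissue_code(volume_b, code)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Root-mean-square difference with min-max normalization
#'
#' @param reference,comparison equal-length numeric series; the percentage is
#'   normalized by the min-max range of `reference`.
#' @return list with `rms` and `rms_percent_of_range`.
#' @export
minmax_rms <- function(reference, comparison) {
  stopifnot(length(reference) == length(comparison))
  rms <- sqrt(mean((reference - comparison)^2))
  rng <- max(reference) - min(reference)
  list(rms = rms,
       rms_percent_of_range = if (rng > 0) 100 * rms / rng else
         if (rms == 0) 0 else Inf)
}
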