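#' Template-based soft-tissue attachment site mapping
#'
#' Subject femoral surfaces are registered to a template atlas with an
#' iterative closest point (ICP) algorithm estimating a similarity
#' transform; attachment sites and joint-axis landmarks are then mapped by
#' nearest-neighbour search in the template frame and inverse-transformed
#' back to the subject's original scale and position.
#'
#' @name attach
NULL

#' Similarity transform (rotation, translation, scale)
#'
#' @param rotation 3 x 3 proper rotation matrix (det = +1).
#' @param translation length-3 vector (mm).
#' @param scale positive scalar.
#' @return an object of class `similarity_transform`. Maps a point `x` to
#'   `scale * rotation %*% x + translation`.
#' @export
similarity_transform <- function(rotation = diag(3),
                                 translation = c(0, 0, 0), scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  stopifnot(scale > 0)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rotation (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- acos(pmax(-1, pmin(1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf(
    "<similarity_transform: rotation %.1f deg, |t| = %.2f mm, scale %.4f>\n",
    ang, sqrt(sum(x$translation^2)), x$scale))
  invisible(x)
}

#' Apply a similarity transform to points
#' @param transform a [similarity_transform()].
#' @param points N x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(transform$scale * points %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Invert a similarity transform
#' @param transform a [similarity_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  s <- 1 / transform$scale
  similarity_transform(Rt, -s * as.vector(Rt %*% transform$translation), s)
}

# Umeyama closed-form similarity fit: finds (R, t, s) minimizing
# sum |s R x_i + t - y_i|^2
umeyama_fit <- function(X, Y, with_scale = TRUE) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- mean(rowSums(Xc^2))
  s <- if (with_scale) sum(sv$d * diag(D)) / varx else 1
  t <- my - s * as.vector(R %*% mx)
  similarity_transform(R, t, s)
}

#' Register a surface to a template by iterative closest points
#'
#' Point-to-nearest-surface-point correspondences between the moving
#' surface's vertices and the template surface, with a closed-form
#' similarity (or rigid) update each iteration. Initialized by centroid and
#' principal-axes pre-alignment.
#'
#' @param moving_femur [tri_surface()] to register (subject).
#' @param template_femur [tri_surface()] target (template).
#' @param with_scale estimate a uniform scale (7-dof similarity) if `TRUE`,
#'   otherwise rigid.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the RMS residual change (mm).
#' @param n_samples number of moving vertices used for correspondence.
#' @return a [similarity_transform()] with attributes `residual` (final RMS,
#'   mm), `iterations`, and `converged`.
#' @export
register_icp <- function(moving_femur, template_femur, with_scale = TRUE,
                         max_iter = 50, tol = 1e-6, n_samples = 500) {
  # pre-alignment: centroid + principal axes of the full vertex sets.
  # Principal-axis signs are ambiguous, so all four proper sign flips are
  # scored by closest-point RMS and the best one seeds the iteration.
  pm <- stats::prcomp(moving_femur$vertices)
  M <- moving_femur$vertices
  if (nrow(M) > n_samples) {
    idx <- round(seq(1, nrow(M), length.out = n_samples))
    M <- M[idx, , drop = FALSE]
  }
  pt <- stats::prcomp(template_femur$vertices)
  Rm <- pm$rotation; Rt <- pt$rotation
  if (det(Rm) < 0) Rm[, 3] <- -Rm[, 3]
  if (det(Rt) < 0) Rt[, 3] <- -Rt[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tr <- NULL
  best0 <- Inf
  for (fl in flips) {
    R0 <- Rt %*% diag(fl) %*% t(Rm)
    t0 <- pt$center - as.vector(R0 %*% pm$center)
    cand <- similarity_transform(R0, t0, 1)
    r0 <- sqrt(mean(closest_point_on_surface(
      apply_transform(cand, M), template_femur)$distance^2))
    if (r0 < best0) { best0 <- r0; tr <- cand }
  }

  prev <- Inf
  converged <- FALSE
  iterations <- 0L
  residuals <- numeric(0)
  for (it in seq_len(max_iter)) {
    iterations <- it
    Mt <- apply_transform(tr, M)
    cp <- closest_point_on_surface(Mt, template_femur)
    res <- sqrt(mean(cp$distance^2))
    if (!is.finite(res)) stop("ICP diverged: non-finite residual")
    residuals <- c(residuals, res)
    tr <- umeyama_fit(M, cp$point, with_scale = with_scale)
    if (abs(prev - res) < tol) { converged <- TRUE; break }
    prev <- res
  }
  Mt <- apply_transform(tr, M)
  res <- sqrt(mean(closest_point_on_surface(Mt, template_femur)$distance^2))
  attr(tr, "residual") <- res
  attr(tr, "residuals") <- c(residuals, res)
  attr(tr, "iterations") <- iterations
  attr(tr, "converged") <- converged
  tr
}

#' Map template attachment sites onto subject surfaces
#'
#' Each atlas site (and joint-axis point) is matched to the nearest subject
#' node in the template frame; the returned coordinates are the matched
#' subject nodes in the subject frame (the inverse transform of the
#' registration). Nearest-neighbour ties break to the lowest node id.
#'
#' @param transform the subject-to-template [similarity_transform()] from
#'   [register_icp()].
#' @param atlas a `template_atlas` (see [make_template_atlas()]).
#' @param subject_surfaces named list of subject [tri_surface()] objects;
#'   sites are matched against the surface named by their `tissue` field
#'   (falling back to the first surface).
#' @return data.frame: `name`, `tissue`, `node_id`, `x`, `y`, `z` (subject
#'   frame, mm), plus rows `axis_1`, `axis_2` for the joint axis points.
#' @export
map_attachment_sites <- function(transform, atlas, subject_surfaces) {
  if (inherits(subject_surfaces, "tri_surface"))
    subject_surfaces <- list(femur = subject_surfaces)
  if (any(vapply(subject_surfaces, function(s) nrow(s$vertices) == 0,
                 logical(1))))
    stop("empty subject surface")
  site_pts <- as.matrix(atlas$sites[, c("x", "y", "z")])
  all_pts <- rbind(site_pts, atlas$joint_axis_points)
  tissues <- c(atlas$sites$tissue, rep(atlas$sites$tissue[1], 2))
  names_out <- c(atlas$sites$name, "axis_1", "axis_2")
  out <- data.frame(name = names_out, tissue = tissues,
                    node_id = NA_integer_, x = NA_real_, y = NA_real_,
                    z = NA_real_, stringsAsFactors = FALSE)
  for (tis in unique(tissues)) {
    surf <- subject_surfaces[[tis]]
    if (is.null(surf)) surf <- subject_surfaces[[1]]
    Vt <- apply_transform(transform, surf$vertices) # subject -> template
    rows <- which(tissues == tis)
    for (r in rows) {
      d2 <- (Vt[, 1] - all_pts[r, 1])^2 + (Vt[, 2] - all_pts[r, 2])^2 +
        (Vt[, 3] - all_pts[r, 3])^2
      nd <- which.min(d2) # which.min returns the lowest index on ties
      out$node_id[r] <- nd
      out[r, c("x", "y", "z")] <- surf$vertices[nd, ]
    }
  }
  out
}
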