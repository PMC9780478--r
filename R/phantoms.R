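#' Synthetic joint phantoms
#'
#' Phantoms stand in for segmented knee imaging data: each carries a tissue
#' label volume, matching analytic surfaces, and a ground-truth record
#' (thickness, curvature, hole geometry) so reconstruction and meshing can be
#' verified against known answers. All phantoms are deterministic given their
#' parameters.
#'
#' @name phantoms
NULL

new_phantom <- function(label_volume, surfaces, ground_truth) {
  structure(list(label_volume = label_volume, surfaces = surfaces,
                 ground_truth = ground_truth), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %s; tissues: %s>\n",
              paste(dim(x$label_volume$codes), collapse = "x"),
              paste(names(x$surfaces), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Generic closed laminar shell: two parametric layers over a (u, v) grid with
# a cell validity mask. Emits top (joint), bottom (bone) and wall triangles;
# wall winding is fixed geometrically so normals face outward.
# ---------------------------------------------------------------------------
laminar_shell_surface <- function(bone_fun, joint_fun, u, v, cell_mask) {
  nu <- length(u); nv <- length(v)
  stopifnot(all(dim(cell_mask) == c(nu - 1, nv - 1)))
  uu <- matrix(u, nu, nv)
  vv <- matrix(v, nu, nv, byrow = TRUE)
  B <- bone_fun(as.vector(uu), as.vector(vv))   # (nu*nv) x 3
  J <- joint_fun(as.vector(uu), as.vector(vv))
  nid <- function(i, j) (j - 1L) * nu + i       # grid node id
  # node usage: any incident valid cell
  used <- matrix(FALSE, nu, nv)
  for (j in seq_len(nv - 1)) for (i in seq_len(nu - 1)) if (cell_mask[i, j])
    used[i:(i + 1), j:(j + 1)] <- TRUE
  V <- rbind(B, J)                               # bone layer then joint layer
  joff <- nu * nv
  tris <- list()
  up_ok <- NULL
  for (j in seq_len(nv - 1)) for (i in seq_len(nu - 1)) {
    if (!cell_mask[i, j]) next
    n00 <- nid(i, j); n10 <- nid(i + 1, j)
    n01 <- nid(i, j + 1); n11 <- nid(i + 1, j + 1)
    # joint (top): outward = bone->joint direction
    tris[[length(tris) + 1]] <- rbind(
      c(n00, n10, n11) + joff, c(n00, n11, n01) + joff,
      c(n00, n11, n10), c(n00, n01, n11))
    # walls where the neighbouring cell is invalid or off-grid
    nbrs <- list(c(i, j - 1, n00, n10), c(i + 1, j, n10, n11),
                 c(i, j + 1, n11, n01), c(i - 1, j, n01, n00))
    for (nb in nbrs) {
      ni <- nb[1]; nj <- nb[2]
      open <- ni < 1 || nj < 1 || ni > nu - 1 || nj > nv - 1 ||
        !cell_mask[ni, nj]
      if (!open) next
      e0 <- nb[3]; e1 <- nb[4]
      # wall quad bone(e0) bone(e1) joint(e1) joint(e0), winding fixed below
      cellc <- (V[n00 + joff, ] + V[n10 + joff, ] +
                V[n01 + joff, ] + V[n11 + joff, ]) / 4
      edgec <- (V[e0 + joff, ] + V[e1 + joff, ]) / 2
      outward <- edgec - cellc
      a <- V[e0, ]; b <- V[e1, ]; c2 <- V[e1 + joff, ]
      n <- c((b[2] - a[2]) * (c2[3] - a[3]) - (b[3] - a[3]) * (c2[2] - a[2]),
             (b[3] - a[3]) * (c2[1] - a[1]) - (b[1] - a[1]) * (c2[3] - a[3]),
             (b[1] - a[1]) * (c2[2] - a[2]) - (b[2] - a[2]) * (c2[1] - a[1]))
      if (sum(n * outward) >= 0)
        tris[[length(tris) + 1]] <- rbind(c(e0, e1, e1 + joff),
                                          c(e0, e1 + joff, e0 + joff))
      else
        tris[[length(tris) + 1]] <- rbind(c(e1, e0, e0 + joff),
                                          c(e1, e0 + joff, e1 + joff))
    }
  }
  F <- do.call(rbind, tris)
  # verify the top orientation: signed volume must be positive, else flip all
  s <- tri_surface(V, F)
  s <- weld_vertices(s, tol = 1e-9)
  if (surface_volume(s) < 0)
    s <- tri_surface(s$vertices, s$triangles[, c(1, 3, 2)])
  s
}

# holes: list of list(center = c(u, v), radius = r) in footprint coordinates
apply_hole_mask <- function(cell_mask, uc, vc, holes) {
  for (h in holes) {
    d <- sqrt(outer((uc - h$center[1])^2, (vc - h$center[2])^2, "+"))
    cell_mask[d <= h$radius] <- FALSE
  }
  cell_mask
}

#' Slab cartilage phantom
#'
#' A rectangular cartilage slab (optionally wrapped on a cylinder of given
#' radius, emulating a condylar surface) sitting on a bone block, with
#' optional cylindrical through-holes emulating focal cartilage loss. Hole
#' centres are given in footprint coordinates: x along the length (arc length
#' for curved slabs, centred on 0) and y along the width.
#'
#' @param length_mm slab length (chord/arc extent, mm).
#' @param width_mm slab width (mm).
#' @param thickness_mm cartilage thickness (mm); must be at least twice the
#'   voxel spacing to be resolvable.
#' @param curvature_radius_mm cylinder radius for a curved slab, or `NULL`
#'   for a flat slab.
#' @param hole_specs list of `list(center = c(x, y), radius = r)` holes.
#' @param voxel_spacing_mm isotropic voxel spacing of the label volume (mm).
#' @param bone_depth_mm thickness of the bone block under the cartilage.
#' @param bone_margin_mm lateral margin by which the bone block extends
#'   beyond the cartilage footprint (bone surfaces extend past cartilage in
#'   the joint, which the blending step relies on).
#' @return a `phantom` with tissues `bone` and `cartilage`.
#' @export
make_slab_phantom <- function(length_mm = 20, width_mm = 10, thickness_mm = 3,
                              curvature_radius_mm = NULL, hole_specs = list(),
                              voxel_spacing_mm = 0.5, bone_depth_mm = 4,
                              bone_margin_mm = 6) {
  if (thickness_mm < 2 * voxel_spacing_mm)
    stop("thickness ", thickness_mm, " mm is below the resolvable limit of ",
         "2 voxels (", 2 * voxel_spacing_mm, " mm)")
  t <- thickness_mm
  curved <- !is.null(curvature_radius_mm)
  if (curved && length_mm >= 2 * curvature_radius_mm)
    stop("chord length must be below the cylinder diameter")
  # for curved slabs length_mm is the chord; parameterize by arc length
  half_u <- if (curved)
    curvature_radius_mm * asin(length_mm / 2 / curvature_radius_mm)
  else length_mm / 2
  pitch <- min(voxel_spacing_mm, 0.5)
  nu <- max(8, ceiling(2 * half_u / pitch) + 1)
  nv <- max(8, ceiling(width_mm / pitch) + 1)
  u <- seq(-half_u, half_u, length.out = nu)  # arc length
  v <- seq(-width_mm / 2, width_mm / 2, length.out = nv)
  uc <- (u[-1] + u[-nu]) / 2
  vc <- (v[-1] + v[-nv]) / 2
  cell_mask <- apply_hole_mask(matrix(TRUE, nu - 1, nv - 1), uc, vc, hole_specs)

  if (curved) {
    R <- curvature_radius_mm
    surf_at <- function(radius) function(uu, vv) {
      th <- uu / R
      cbind(radius * sin(th), vv, radius * cos(th) - R)
    }
    bone_fun <- surf_at(R); joint_fun <- surf_at(R + t)
    bone_inner <- surf_at(R - bone_depth_mm)
  } else {
    bone_fun <- function(uu, vv) cbind(uu, vv, 0)
    joint_fun <- function(uu, vv) cbind(uu, vv, t)
    bone_inner <- function(uu, vv) cbind(uu, vv, -bone_depth_mm)
  }
  cart_surf <- laminar_shell_surface(bone_fun, joint_fun, u, v, cell_mask)
  mb <- bone_margin_mm
  nub <- max(8, ceiling((2 * half_u + 2 * mb) / pitch) + 1)
  nvb <- max(8, ceiling((width_mm + 2 * mb) / pitch) + 1)
  ub <- seq(-half_u - mb, half_u + mb, length.out = nub)
  vb <- seq(-width_mm / 2 - mb, width_mm / 2 + mb, length.out = nvb)
  bone_surf <- laminar_shell_surface(bone_inner, bone_fun, ub, vb,
                                     matrix(TRUE, nub - 1, nvb - 1))

  # analytic voxelization
  sp <- rep(voxel_spacing_mm, 3)
  allv <- rbind(cart_surf$vertices, bone_surf$vertices)
  lo <- apply(allv, 2, min) - 2 * sp + sp / 2
  hi <- apply(allv, 2, max) + 2 * sp
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  ax <- lo[1] + (seq_len(dims[1]) - 1) * sp[1]
  ay <- lo[2] + (seq_len(dims[2]) - 1) * sp[2]
  az <- lo[3] + (seq_len(dims[3]) - 1) * sp[3]
  X <- array(ax, dims)
  Y <- array(rep(ay, each = dims[1]), dims)
  Z <- array(rep(az, each = dims[1] * dims[2]), dims)
  if (curved) {
    R <- curvature_radius_mm
    rho <- sqrt(X^2 + (Z + R)^2)
    th <- atan2(X, Z + R)
    s_arc <- R * th
    in_fp <- abs(s_arc) <= half_u & abs(Y) <= width_mm / 2
    in_fpb <- abs(s_arc) <= half_u + mb & abs(Y) <= width_mm / 2 + mb
    cart <- in_fp & rho >= R & rho <= R + t
    bone <- in_fpb & rho >= R - bone_depth_mm & rho < R
    hx <- s_arc
  } else {
    in_fp <- abs(X) <= length_mm / 2 & abs(Y) <= width_mm / 2
    in_fpb <- abs(X) <= length_mm / 2 + mb & abs(Y) <= width_mm / 2 + mb
    cart <- in_fp & Z >= 0 & Z <= t
    bone <- in_fpb & Z >= -bone_depth_mm & Z < 0
    hx <- X
  }
  for (h in hole_specs) {
    d <- sqrt((hx - h$center[1])^2 + (Y - h$center[2])^2)
    cart[d <= h$radius] <- FALSE
  }
  codes <- array(0L, dims)
  tm <- c(bone = 1L, cartilage = 2L)
  codes[bone] <- 1L
  codes[cart] <- 2L
  vol <- label_volume(codes, sp, lo, tm)

  gt <- list(thickness_mm = t, length_mm = length_mm, width_mm = width_mm,
             curvature_radius_mm = curvature_radius_mm,
             holes = hole_specs, voxel_spacing_mm = voxel_spacing_mm,
             sagittal_height_mm = if (curved)
               curvature_radius_mm -
                 sqrt(curvature_radius_mm^2 - (length_mm / 2)^2) else 0)
  new_phantom(vol, list(bone = bone_surf, cartilage = cart_surf), gt)
}

#' Joint-style cartilage phantoms
#'
#' Shapes mimicking the meshed knee tissues: `femoral` is a cylindrical
#' condylar shell, `tibial` is a pair of flat plateau compartments (medial and
#' lateral, independent labels) on one bone block, and `patellar` is a single
#' elliptical flat patch.
#'
#' @param style one of `"femoral"`, `"tibial"`, `"patellar"`.
#' @param size named list overriding style defaults (`length_mm`, `width_mm`,
#'   `thickness_mm`, `radius_mm` for femoral).
#' @param hole_specs list of holes (`list(center = c(x, y), radius)`), applied
#'   to the cartilage footprint (for tibial: each compartment's local frame).
#' @param voxel_spacing_mm voxel spacing (mm).
#' @return a `phantom`; tibial style carries `cartilage_medial` and
#'   `cartilage_lateral` surfaces.
#' @export
make_joint_phantom <- function(style = c("femoral", "tibial", "patellar"),
                               size = list(), hole_specs = list(),
                               voxel_spacing_mm = 0.5) {
  style <- match.arg(style)
  if (style == "femoral") {
    p <- modifyList(list(length_mm = 40, width_mm = 30, thickness_mm = 2,
                         radius_mm = 30), size)
    ph <- make_slab_phantom(p$length_mm, p$width_mm, p$thickness_mm,
                            curvature_radius_mm = p$radius_mm,
                            hole_specs = hole_specs,
                            voxel_spacing_mm = voxel_spacing_mm)
    ph$ground_truth$style <- "femoral"
    return(ph)
  }
  if (style == "patellar") {
    p <- modifyList(list(length_mm = 24, width_mm = 20, thickness_mm = 2.5),
                    size)
    ph <- make_patch_phantom(p$length_mm, p$width_mm, p$thickness_mm,
                             footprint = "ellipse", hole_specs = hole_specs,
                             voxel_spacing_mm = voxel_spacing_mm)
    ph$ground_truth$style <- "patellar"
    return(ph)
  }
  # tibial: two rectangular plateau compartments, gap between them
  p <- modifyList(list(length_mm = 22, width_mm = 16, thickness_mm = 2.5,
                       gap_mm = 8), size)
  off <- p$width_mm / 2 + p$gap_mm / 2
  med <- make_patch_phantom(p$length_mm, p$width_mm, p$thickness_mm,
                            footprint = "rect", hole_specs = hole_specs,
                            voxel_spacing_mm = voxel_spacing_mm,
                            y_offset = -off, bone_span = 2 * off + p$width_mm)
  lat <- make_patch_phantom(p$length_mm, p$width_mm, p$thickness_mm,
                            footprint = "rect", hole_specs = list(),
                            voxel_spacing_mm = voxel_spacing_mm,
                            y_offset = off, bone_span = 2 * off + p$width_mm)
  # merge label volumes on the medial grid (same geometry by construction)
  codes <- med$label_volume$codes
  tm <- c(bone = 1L, cartilage_medial = 2L, cartilage_lateral = 3L)
  lat_cart <- lat$label_volume$codes == 2L
  codes[lat_cart] <- 3L
  vol <- label_volume(codes, med$label_volume$spacing,
                      med$label_volume$origin, tm)
  gt <- med$ground_truth
  gt$style <- "tibial"
  gt$compartment_offset_mm <- off
  new_phantom(vol, list(bone = med$surfaces$bone,
                        cartilage_medial = med$surfaces$cartilage,
                        cartilage_lateral = lat$surfaces$cartilage), gt)
}

# flat patch on a wide bone block; footprint rect or ellipse, offset along y
make_patch_phantom <- function(length_mm, width_mm, thickness_mm,
                               footprint = c("rect", "ellipse"),
                               hole_specs = list(), voxel_spacing_mm = 0.5,
                               y_offset = 0, bone_span = NULL,
                               bone_depth_mm = 4, bone_margin_mm = 6) {
  footprint <- match.arg(footprint)
  t <- thickness_mm
  pitch <- min(voxel_spacing_mm, 0.5)
  nu <- max(8, ceiling(length_mm / pitch) + 1)
  nv <- max(8, ceiling(width_mm / pitch) + 1)
  u <- seq(-length_mm / 2, length_mm / 2, length.out = nu)
  v <- seq(-width_mm / 2, width_mm / 2, length.out = nv) + y_offset
  uc <- (u[-1] + u[-nu]) / 2
  vc <- (v[-1] + v[-nv]) / 2 - y_offset
  cell_mask <- matrix(TRUE, nu - 1, nv - 1)
  if (footprint == "ellipse") {
    d <- outer((uc / (length_mm / 2))^2, (vc / (width_mm / 2))^2, "+")
    cell_mask[d > 1] <- FALSE
  }
  cell_mask <- apply_hole_mask(cell_mask, uc, vc, hole_specs)
  bone_fun <- function(uu, vv) cbind(uu, vv, 0)
  joint_fun <- function(uu, vv) cbind(uu, vv, t)
  cart_surf <- laminar_shell_surface(bone_fun, joint_fun, u, v, cell_mask)

  span <- (if (is.null(bone_span)) width_mm else bone_span) +
    2 * bone_margin_mm
  lenb <- length_mm + 2 * bone_margin_mm
  nub <- max(8, ceiling(lenb / pitch) + 1)
  nb <- max(8, ceiling(span / pitch) + 1)
  ub <- seq(-lenb / 2, lenb / 2, length.out = nub)
  vb <- seq(-span / 2, span / 2, length.out = nb)
  bone_surf <- laminar_shell_surface(
    function(uu, vv) cbind(uu, vv, -bone_depth_mm), bone_fun,
    ub, vb, matrix(TRUE, nub - 1, nb - 1))

  sp <- rep(voxel_spacing_mm, 3)
  allv <- rbind(cart_surf$vertices, bone_surf$vertices)
  lo <- apply(allv, 2, min) - 2 * sp + sp / 2
  hi <- apply(allv, 2, max) + 2 * sp
  hi[3] <- hi[3] + t  # headroom above both compartments
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  ax <- lo[1] + (seq_len(dims[1]) - 1) * sp[1]
  ay <- lo[2] + (seq_len(dims[2]) - 1) * sp[2]
  az <- lo[3] + (seq_len(dims[3]) - 1) * sp[3]
  X <- array(ax, dims)
  Y <- array(rep(ay, each = dims[1]), dims)
  Z <- array(rep(az, each = dims[1] * dims[2]), dims)
  Yl <- Y - y_offset
  in_fp <- if (footprint == "ellipse")
    (X / (length_mm / 2))^2 + (Yl / (width_mm / 2))^2 <= 1
  else abs(X) <= length_mm / 2 & abs(Yl) <= width_mm / 2
  cart <- in_fp & Z >= 0 & Z <= t
  for (h in hole_specs) {
    d <- sqrt((X - h$center[1])^2 + (Yl - h$center[2])^2)
    cart[d <= h$radius] <- FALSE
  }
  bone <- abs(X) <= lenb / 2 & abs(Y) <= span / 2 &
    Z >= -bone_depth_mm & Z <= 0
  codes <- array(0L, dims)
  codes[bone] <- 1L
  codes[cart] <- 2L
  vol <- label_volume(codes, sp, lo, c(bone = 1L, cartilage = 2L))
  gt <- list(thickness_mm = t, length_mm = length_mm, width_mm = width_mm,
             curvature_radius_mm = NULL, holes = hole_specs,
             voxel_spacing_mm = voxel_spacing_mm, footprint = footprint)
  new_phantom(vol, list(bone = bone_surf, cartilage = cart_surf), gt)
}

#' Synthetic template atlas with named attachment sites
#'
#' A femur-like ellipsoidal template surface carrying `n_sites` uniquely
#' named soft-tissue attachment sites at deterministic parametric locations
#' (golden-angle spiral), plus two points defining the joint axis.
#'
#' @param n_sites number of attachment sites (>= 1).
#' @param radii ellipsoid semi-axes (mm), femur-condyle-like by default.
#' @return list with `femur_surface` ([tri_surface()]), `sites`
#'   (data.frame: name, tissue, x, y, z), `joint_axis_points` (2 x 3 matrix);
#'   class `template_atlas`.
#' @export
make_template_atlas <- function(n_sites = 160, radii = c(35, 30, 25)) {
  stopifnot(n_sites >= 1)
  femur <- uv_ellipsoid(radii, n_theta = 48, n_phi = 24)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_sites)
  z <- 1 - (2 * k - 1) / n_sites
  phi <- acos(pmax(-1, pmin(1, z)))
  th <- (k - 1) * golden
  pts <- cbind(radii[1] * sin(phi) * cos(th),
               radii[2] * sin(phi) * sin(th),
               radii[3] * cos(phi))
  # snap to the nearest mesh vertex so sites coincide with atlas nodes
  V <- femur$vertices
  nd <- vapply(seq_len(n_sites), function(i)
    which.min((V[, 1] - pts[i, 1])^2 + (V[, 2] - pts[i, 2])^2 +
                (V[, 3] - pts[i, 3])^2), integer(1))
  sites <- data.frame(name = sprintf("site_%03d", k),
                      tissue = "femur",
                      x = V[nd, 1], y = V[nd, 2], z = V[nd, 3],
                      stringsAsFactors = FALSE)
  axis_pts <- rbind(c(-radii[1] * 0.8, 0, 0), c(radii[1] * 0.8, 0, 0))
  structure(list(femur_surface = femur, sites = sites,
                 joint_axis_points = axis_pts), class = "template_atlas")
}

#' Closed triangulated ellipsoid surface
#'
#' A UV-sphere triangulation (pole fans) scaled to the given semi-axes, with
#' an optional smooth asymmetric radial modulation that breaks the
#' ellipsoid's flip symmetries (useful for registration targets). With
#' `asymmetry = 0` and equal radii this is a plain sphere.
#'
#' @param radii semi-axes (mm), length 3.
#' @param n_theta,n_phi angular resolution.
#' @param asymmetry relative amplitude of the symmetry-breaking modulation.
#' @return a watertight [tri_surface()].
#' @export
make_ellipsoid_surface <- function(radii, n_theta = 64, n_phi = 32,
                                   asymmetry = 0) {
  uv_ellipsoid(radii, n_theta, n_phi, asymmetry)
}

# closed UV-triangulated ellipsoid with pole fans; a smooth asymmetric
# radial modulation breaks the ellipsoid's flip symmetries so registration
# has a unique optimum (real femora are strongly asymmetric)
uv_ellipsoid <- function(radii, n_theta = 32, n_phi = 16,
                         asymmetry = 0.1) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 1)[c(-1, -(n_phi + 1))]
  V <- rbind(c(0, 0, radii[3]))
  for (p in ph)
    V <- rbind(V, cbind(radii[1] * sin(p) * cos(th),
                        radii[2] * sin(p) * sin(th),
                        radii[3] * cos(p)))
  V <- rbind(V, c(0, 0, -radii[3]))
  if (asymmetry > 0) {
    xn <- V[, 1] / radii[1]; yn <- V[, 2] / radii[2]; zn <- V[, 3] / radii[3]
    f <- 1 + asymmetry * xn + 0.7 * asymmetry * yn * zn +
      0.5 * asymmetry * xn * zn
    V <- V * f
  }
  nid <- function(ring, i) 1L + (ring - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  tris <- list()
  for (i in seq_len(n_theta))
    tris[[length(tris) + 1]] <- c(1L, nid(1, i), nid(1, i + 1))
  for (ring in seq_len(length(ph) - 1))
    for (i in seq_len(n_theta)) {
      a <- nid(ring, i); b <- nid(ring, i + 1)
      c2 <- nid(ring + 1, i); d <- nid(ring + 1, i + 1)
      tris[[length(tris) + 1]] <- c(a, c2, b)
      tris[[length(tris) + 1]] <- c(b, c2, d)
    }
  south <- nrow(V)
  for (i in seq_len(n_theta))
    tris[[length(tris) + 1]] <- c(south, nid(length(ph), i + 1),
                                  nid(length(ph), i))
  s <- tri_surface(V, do.call(rbind, tris))
  if (surface_volume(s) < 0)
    s <- tri_surface(s$vertices, s$triangles[, c(1, 3, 2)])
  s
}

#' Voxelize a closed surface into a binary label volume
#'
#' Interior voxels (parity ray casting through voxel centres) are labelled 1.
#'
#' @param surface a closed [tri_surface()].
#' @param spacing_mm isotropic voxel spacing (mm).
#' @param pad voxels of background padding around the bounding box.
#' @return a [label_volume()] with codes 0/1.
#' @export
voxelize_surface <- function(surface, spacing_mm, pad = 2L) {
  if (!is_watertight(surface))
    stop("surface is not closed (boundary or non-manifold edges present); ",
         "cannot voxelize")
  sp <- rep(spacing_mm, 3)
  lo <- apply(surface$vertices, 2, min) - pad * sp + sp / 2
  hi <- apply(surface$vertices, 2, max) + pad * sp
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  inside <- cpp_voxelize(surface$vertices, surface$triangles, dims, sp, lo)
  codes <- array(as.integer(inside), dims)
  label_volume(codes, sp, lo, c(tissue = 1L))
}
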