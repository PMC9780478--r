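#' Swept-extrusion hexahedral cartilage meshing
#'
#' Cartilage is a laminar tissue: a thin solid bounded by a bone-side and a
#' joint-side surface. The mesher places a rectangular grid of ray origins,
#' traces each ray through the closed cartilage surface, and pairs the
#' bone-side and joint-side hits into one column of a structured hexahedral
#' sheet. Boundary cells with only six distinct nodes are classified into
#' degenerate configurations and repaired, element quality is optimized on
#' the scaled Jacobian, the sheet is subdivided in-plane and finally through
#' the depth.
#'
#' @name hexsweep
NULL

strategy_failure <- function(msg) {
  stop(structure(class = c("hexcart_strategy_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

optimize_failure <- function(msg, worst = NULL) {
  stop(structure(class = c("hexcart_optimize_failure", "error", "condition"),
                 list(message = msg, call = NULL, worst = worst)))
}

# principal axes of the vertex cloud, columns ordered by decreasing extent
principal_axes <- function(V) {
  p <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  list(center = p$center, axes = p$rotation, sdev = p$sdev)
}

# Kasa least-squares circle fit in 2-D; returns center and radius
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(cx = sol[1], cy = sol[2], r = sqrt(r2))
}

# joint-side ("up") direction: the least-extent principal axis, oriented
# toward world +z (ties toward +x). Convention: tissues are posed with the
# joint surface superior, as in the phantoms and typical knee imaging.
up_direction <- function(axes) {
  up <- axes[, 3]
  s <- up[3]
  if (abs(s) < 1e-9) s <- up[1]
  if (abs(s) < 1e-9) s <- up[2]
  if (s < 0) up <- -up
  up
}

#' Build a sweep grid of paired surface hits
#'
#' Femoral and patellar sites sweep ray origins along the medial-lateral
#' (cylinder) axis with a fan of radial rays from the fitted curvature
#' centre; flat patellar surfaces degrade gracefully to near-parallel rays
#' as the fitted radius grows. The tibial site uses a planar projection
#' (back faces discarded) with an interior rectilinear grid on a scaled
#' bounding box whose outermost ring is radially projected onto the
#' cartilage silhouette (`"sector"`), or a plain rectilinear grid on the
#' unscaled bounding box (`"rect"`, the fallback). Grid pitch is
#' `pitch_factor * target_edge_mm` so that the final in-plane edges after
#' subdivision come out near the target.
#'
#' @param cartilage_surface closed, repaired, outward-oriented
#'   [tri_surface()].
#' @param site `"femoral"`, `"tibial"`, or `"patellar"`.
#' @param target_edge_mm final in-plane element edge target (mm).
#' @param strategy grid strategy override: `"fan"`, `"sector"`, or
#'   `"rect"`; default picked by site.
#' @param pitch_factor grid pitch in units of `target_edge_mm`.
#' @param bbox_scale scale factor of the tibial interior-grid bounding box.
#' @return a `sweep_grid`.
#' @export
make_sweep_grid <- function(cartilage_surface,
                            site = c("femoral", "tibial", "patellar"),
                            target_edge_mm = 1.0, strategy = NULL,
                            pitch_factor = 2, bbox_scale = 0.9) {
  site <- match.arg(site)
  if (is.null(strategy))
    strategy <- switch(site, femoral = "fan", patellar = "fan",
                       tibial = "sector")
  pitch <- pitch_factor * target_edge_mm
  g <- switch(strategy,
              fan = sweep_grid_fan(cartilage_surface, pitch),
              sector = sweep_grid_planar(cartilage_surface, pitch,
                                         bbox_scale = bbox_scale,
                                         rim_project = TRUE),
              rect = sweep_grid_planar(cartilage_surface, pitch,
                                       bbox_scale = 1, rim_project = FALSE),
              stop("unknown strategy: ", strategy))
  g$site <- site
  g$strategy <- strategy
  g$pitch <- pitch
  g$surface <- cartilage_surface
  g <- cleanup_grid(g)
  class(g) <- "sweep_grid"
  g
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid %s/%s: %d x %d, %.0f%% valid>\n", x$site,
              x$strategy, x$shape[1], x$shape[2], 100 * mean(x$valid)))
  invisible(x)
}

# assign bone/joint roles to the first/last hits of each ray given whether
# the ray travels along (+1) or against (-1) the outward joint normal
assign_hits <- function(origins, dirs, hits, along_outward) {
  n <- nrow(origins)
  bone <- matrix(NA_real_, n, 3)
  joint <- matrix(NA_real_, n, 3)
  valid <- logical(n)
  for (r in seq_len(n)) {
    ts <- hits[[r]]
    if (length(ts) < 2) next
    p1 <- origins[r, ] + ts[1] * dirs[r, ]
    p2 <- origins[r, ] + ts[length(ts)] * dirs[r, ]
    if (along_outward > 0) { bone[r, ] <- p1; joint[r, ] <- p2 }
    else { bone[r, ] <- p2; joint[r, ] <- p1 }
    valid[r] <- TRUE
  }
  list(bone = bone, joint = joint, valid = valid)
}

sweep_grid_fan <- function(surface, pitch) {
  V <- surface$vertices
  pa <- principal_axes(V)
  axis <- pa$axes[, 2]  # sweep (medial-lateral) direction
  e1 <- pa$axes[, 1]; e3 <- pa$axes[, 3]
  s <- as.vector((V - matrix(pa$center, nrow(V), 3, byrow = TRUE)) %*% axis)
  px <- as.vector((V - matrix(pa$center, nrow(V), 3, byrow = TRUE)) %*% e1)
  pz <- as.vector((V - matrix(pa$center, nrow(V), 3, byrow = TRUE)) %*% e3)
  up <- up_direction(pa$axes)
  up2 <- c(sum(up * e1), sum(up * e3))
  up2 <- up2 / sqrt(sum(up2^2))
  centroid2 <- c(mean(px), mean(pz))
  fit <- fit_circle(px, pz)
  bad_fit <- is.null(fit) || fit$r > 1e4 ||
    sum((centroid2 - c(fit$cx, fit$cy)) * up2) <= 0
  if (bad_fit) {
    # essentially flat (or centre on the joint side): far centre on the
    # bone side so the fan degrades to near-parallel rays
    fit <- list(cx = centroid2[1] - 1e4 * up2[1],
                cy = centroid2[2] - 1e4 * up2[2], r = 1e4)
  }
  # the curvature centre sits on the bone side, so rays travelling outward
  # from it cross the bone-side surface first
  along_outward <- 1
  phi <- atan2(px - fit$cx, pz - fit$cy)
  phi0 <- atan2(centroid2[1] - fit$cx, centroid2[2] - fit$cy)
  dphi <- (phi - phi0 + pi) %% (2 * pi) - pi   # unwrap about the centroid
  rmean <- mean(sqrt((px - fit$cx)^2 + (pz - fit$cy)^2))
  dphi_step <- pitch / rmean
  nphi <- max(3, round((max(dphi) - min(dphi)) / dphi_step) + 1)
  phis <- phi0 + seq(min(dphi), max(dphi), length.out = nphi)
  ns_ <- max(3, round((max(s) - min(s)) / pitch) + 1)
  ss <- seq(min(s), max(s), length.out = ns_)
  m <- length(ss); n <- length(phis)
  if (m < 3 || n < 3)
    strategy_failure("fan grid degenerate: surface smaller than grid pitch")
  centre_w <- pa$center + fit$cx * e1 + fit$cy * e3
  origins <- matrix(0, m * n, 3)
  dirs <- matrix(0, m * n, 3)
  idx <- 1
  for (j in seq_len(n)) for (i in seq_len(m)) {
    origins[idx, ] <- centre_w + ss[i] * axis
    dirs[idx, ] <- sin(phis[j]) * e1 + cos(phis[j]) * e3
    idx <- idx + 1
  }
  hits <- cast_rays(origins, dirs, surface, tmin = 1e-9)
  a <- assign_hits(origins, dirs, hits, along_outward)
  list(shape = c(m, n),
       origins = array(origins, c(m, n, 3)),
       directions = array(dirs, c(m, n, 3)),
       bone_hits = array(a$bone, c(m, n, 3)),
       joint_hits = array(a$joint, c(m, n, 3)),
       valid = matrix(a$valid, m, n))
}

sweep_grid_planar <- function(surface, pitch, bbox_scale = 0.9,
                              rim_project = TRUE) {
  V <- surface$vertices
  pa <- principal_axes(V)
  e1 <- pa$axes[, 1]; e2 <- pa$axes[, 2]
  up <- up_direction(pa$axes)
  # discard back faces during the planar projection: keep vertices of faces
  # whose outward normal has a positive component along `up`
  tn <- triangle_normals(surface)
  front <- as.vector(tn %*% up) > 0
  fv <- unique(as.vector(surface$triangles[front, ]))
  Vc <- V - matrix(pa$center, nrow(V), 3, byrow = TRUE)
  u <- as.vector(Vc %*% e1); v <- as.vector(Vc %*% e2)
  h <- as.vector(Vc %*% up)
  # rotate the in-plane axes to the minimum-area bounding box of the
  # footprint so the grid aligns with the cartilage outline
  best <- list(area = Inf, ang = 0)
  for (ang in seq(0, 89, by = 1) * pi / 180) {
    ur2 <- u[fv] * cos(ang) - v[fv] * sin(ang)
    vr2 <- u[fv] * sin(ang) + v[fv] * cos(ang)
    a <- diff(range(ur2)) * diff(range(vr2))
    if (a < best$area) best <- list(area = a, ang = ang)
  }
  if (best$ang != 0) {
    ca <- cos(best$ang); sa <- sin(best$ang)
    e1n <- ca * e1 - sa * e2
    e2n <- sa * e1 + ca * e2
    e1 <- e1n; e2 <- e2n
    u <- as.vector(Vc %*% e1); v <- as.vector(Vc %*% e2)
  }
  ur <- range(u[fv]); vr <- range(v[fv])
  cen <- c(mean(ur), mean(vr))
  half <- c(diff(ur), diff(vr)) / 2 * bbox_scale
  eps <- pitch * 0.01
  nu <- max(3, round((2 * half[1] - 2 * eps) / pitch) + 1)
  nv <- max(3, round((2 * half[2] - 2 * eps) / pitch) + 1)
  us <- seq(cen[1] - half[1] + eps, cen[1] + half[1] - eps, length.out = nu)
  vs <- seq(cen[2] - half[2] + eps, cen[2] + half[2] - eps, length.out = nv)
  m <- length(us); n <- length(vs)
  if (m < 3 || n < 3)
    strategy_failure("planar grid degenerate: footprint smaller than pitch")
  htop <- max(h) + 5
  mk_origin <- function(uu, vv)
    pa$center + uu * e1 + vv * e2 + htop * up
  origins <- matrix(0, m * n, 3)
  idx <- 1
  for (j in seq_len(n)) for (i in seq_len(m)) {
    origins[idx, ] <- mk_origin(us[i], vs[j])
    idx <- idx + 1
  }
  dirs <- matrix(rep(-up, each = m * n), m * n, 3)
  hits <- cast_rays(origins, dirs, surface, tmin = 1e-9)
  a <- assign_hits(origins, dirs, hits, along_outward = -1)
  g <- list(shape = c(m, n),
            origins = array(origins, c(m, n, 3)),
            directions = array(dirs, c(m, n, 3)),
            bone_hits = array(a$bone, c(m, n, 3)),
            joint_hits = array(a$joint, c(m, n, 3)),
            valid = matrix(a$valid, m, n))
  if (!rim_project) return(g)

  # sector-style interior grid: all border nodes must be interior to the
  # footprint, and no hole may touch the interior-grid edge, otherwise the
  # radial rim projection is ill-defined
  valid <- g$valid
  border <- matrix(FALSE, m, n)
  border[c(1, m), ] <- TRUE; border[, c(1, n)] <- TRUE
  if (!all(valid[border]))
    strategy_failure("interior grid edge leaves the cartilage footprint")
  near_border <- matrix(FALSE, m, n)
  near_border[c(2, m - 1), 2:(n - 1)] <- TRUE
  near_border[2:(m - 1), c(2, n - 1)] <- TRUE
  if (any(!valid[near_border]))
    strategy_failure("cartilage hole lies on the edge of the interior grid")
  # radially project the border ring outward to the silhouette
  step <- pitch / 3
  for (idx in which(border)) {
    i <- (idx - 1) %% m + 1; j <- (idx - 1) %/% m + 1
    pos <- c(us[i], vs[j])
    rad <- pos - cen
    rl <- sqrt(sum(rad^2))
    if (rl < 1e-9) next
    rad <- rad / rl
    best <- NULL
    for (k in seq_len(60)) {
      p2 <- pos + k * step * rad
      o <- mk_origin(p2[1], p2[2])
      ts <- cast_rays(rbind(o), rbind(-up), surface, tmin = 1e-9)[[1]]
      if (length(ts) < 2) break
      best <- list(bone = o - up * ts[length(ts)], joint = o - up * ts[1])
    }
    if (!is.null(best)) {
      g$bone_hits[i, j, ] <- best$bone
      g$joint_hits[i, j, ] <- best$joint
    }
  }
  g
}

# fill isolated invalid nodes, keep the largest valid component, and check
# the interior hit fraction
cleanup_grid <- function(g) {
  m <- g$shape[1]; n <- g$shape[2]
  valid <- g$valid
  # isolated invalid nodes (all 4 neighbours valid): interpolate
  for (j in 2:(n - 1)) for (i in 2:(m - 1)) {
    if (valid[i, j]) next
    if (valid[i - 1, j] && valid[i + 1, j] && valid[i, j - 1] && valid[i, j + 1]) {
      for (d in 1:3) {
        g$bone_hits[i, j, d] <- mean(c(g$bone_hits[i - 1, j, d],
                                       g$bone_hits[i + 1, j, d],
                                       g$bone_hits[i, j - 1, d],
                                       g$bone_hits[i, j + 1, d]))
        g$joint_hits[i, j, d] <- mean(c(g$joint_hits[i - 1, j, d],
                                        g$joint_hits[i + 1, j, d],
                                        g$joint_hits[i, j - 1, d],
                                        g$joint_hits[i, j + 1, d]))
      }
      bp <- closest_point_on_surface(rbind(g$bone_hits[i, j, ]), g$surface)
      jp <- closest_point_on_surface(rbind(g$joint_hits[i, j, ]), g$surface)
      g$bone_hits[i, j, ] <- bp$point
      g$joint_hits[i, j, ] <- jp$point
      valid[i, j] <- TRUE
    }
  }
  comp <- mask_components(valid)
  if (max(comp, na.rm = TRUE) >= 1) {
    sizes <- tabulate(comp[!is.na(comp)])
    keep <- which.max(sizes)
    valid[!is.na(comp) & comp != keep] <- FALSE
  }
  g$valid <- valid
  if (mean(valid) < 0.6)
    strategy_failure(sprintf(
      "only %.0f%% of rays hit both cartilage sides", 100 * mean(valid)))
  g
}

# 4-connected components of a logical mask; NA where FALSE
mask_components <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  comp <- matrix(NA_integer_, m, n)
  cid <- 0L
  for (j0 in seq_len(n)) for (i0 in seq_len(m)) {
    if (!mask[i0, j0] || !is.na(comp[i0, j0])) next
    cid <- cid + 1L
    stack <- matrix(c(i0, j0), 1)
    while (nrow(stack)) {
      i <- stack[1, 1]; j <- stack[1, 2]
      stack <- stack[-1, , drop = FALSE]
      if (i < 1 || j < 1 || i > m || j > n) next
      if (!mask[i, j] || !is.na(comp[i, j])) next
      comp[i, j] <- cid
      stack <- rbind(stack, c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    }
  }
  comp
}

# ---------------------------------------------------------------------------
# HexSheet: a single-layer structured hex sheet backed by its sweep grid.
# ---------------------------------------------------------------------------

#' Connect a sweep grid into a single-layer hexahedral sheet
#'
#' Every 2x2 patch of valid grid nodes becomes one hexahedral element
#' connecting the bone-side hits to the joint-side hits. Patches with
#' exactly three valid corners become degenerate six-node wedges (the
#' missing corner's node indices are collapsed onto an adjacent valid
#' corner); these are repaired by [repair_degenerates()].
#'
#' @param grid a `sweep_grid` from [make_sweep_grid()].
#' @return a `hex_sheet`.
#' @export
build_hex_sheet <- function(grid) {
  comp <- mask_components(grid$valid)
  if (max(comp, na.rm = TRUE) > 1)
    stop("valid mask has multiple components after cleanup")
  sheet <- list(grid = grid,
                cell_active = matrix(TRUE, grid$shape[1] - 1,
                                     grid$shape[2] - 1),
                created = matrix(FALSE, grid$shape[1], grid$shape[2]),
                allow_degenerate = TRUE,
                provenance = list(fallbacks = character(0)))
  class(sheet) <- "hex_sheet"
  sheet_rebuild(sheet)
}

#' @export
print.hex_sheet <- function(x, ...) {
  cat(sprintf("<hex_sheet: %d nodes, %d hexes (%d degenerate)>\n",
              nrow(x$nodes), nrow(x$hexes), sum(x$degenerate)))
  invisible(x)
}

# materialize nodes / elements / quads from the grid state
sheet_rebuild <- function(sheet) {
  g <- sheet$grid
  m <- g$shape[1]; n <- g$shape[2]
  valid <- g$valid
  nid <- matrix(NA_integer_, m, n)
  nid[valid] <- seq_len(sum(valid))
  nvalid <- sum(valid)
  bone_pts <- cbind(g$bone_hits[, , 1][valid], g$bone_hits[, , 2][valid],
                    g$bone_hits[, , 3][valid])
  joint_pts <- cbind(g$joint_hits[, , 1][valid], g$joint_hits[, , 2][valid],
                     g$joint_hits[, , 3][valid])
  nodes <- rbind(bone_pts, joint_pts)
  hexes <- list(); cells <- list(); degen <- logical(0)
  for (j in seq_len(n - 1)) for (i in seq_len(m - 1)) {
    if (!sheet$cell_active[i, j]) next
    cs <- rbind(c(i, j), c(i + 1, j), c(i + 1, j + 1), c(i, j + 1)) # 00 10 11 01
    cv <- valid[cs]
    nv <- sum(cv)
    if (nv < 3) next
    if (nv == 3 && !sheet$allow_degenerate) next
    corner <- integer(4)
    for (cidx in 1:4) {
      if (cv[cidx]) corner[cidx] <- nid[cs[cidx, 1], cs[cidx, 2]]
      else {
        # collapse the missing corner onto an adjacent valid corner of the
        # quad cycle; prefer the u-direction neighbour, then v (lowest id)
        nb <- switch(cidx, c(2, 4), c(1, 3), c(4, 2), c(3, 1))
        pick <- if (cv[nb[1]]) nb[1] else nb[2]
        corner[cidx] <- nid[cs[pick, 1], cs[pick, 2]]
      }
    }
    hexes[[length(hexes) + 1]] <- c(corner, corner + nvalid)
    cells[[length(cells) + 1]] <- c(i, j)
    degen <- c(degen, nv == 3)
  }
  hexes <- do.call(rbind, hexes)
  cells <- do.call(rbind, cells)
  # ensure positive orientation: test a clean element
  full <- which(!degen)
  if (length(full)) {
    sj <- scaled_jacobian_all(nodes, hexes[full[1], , drop = FALSE])
    if (sj < 0) {
      hexes <- hexes[, c(1, 4, 3, 2, 5, 8, 7, 6), drop = FALSE]
      sheet$flipped <- TRUE
    }
  }
  sheet$nodes <- nodes
  sheet$hexes <- hexes
  sheet$cell_index <- cells
  sheet$degenerate <- degen
  sheet$node_grid <- nid
  sheet$n_surface_nodes <- nvalid
  sheet$bone_quads <- hexes[, 1:4, drop = FALSE]
  sheet$joint_quads <- hexes[, 5:8, drop = FALSE]
  sheet$edge_node_flags <- sheet_edge_nodes(sheet)
  sheet
}

# nodes on the boundary of the meshed region: grid nodes incident to fewer
# than 4 realized cells (flag covers both bone and joint copies)
sheet_edge_nodes <- function(sheet) {
  g <- sheet$grid
  m <- g$shape[1]; n <- g$shape[2]
  cellcount <- matrix(0L, m, n)
  if (!is.null(sheet$cell_index))
    for (r in seq_len(nrow(sheet$cell_index))) {
      i <- sheet$cell_index[r, 1]; j <- sheet$cell_index[r, 2]
      cellcount[i:(i + 1), j:(j + 1)] <- cellcount[i:(i + 1), j:(j + 1)] + 1L
    }
  onedge <- g$valid & cellcount < 4
  flags <- logical(2 * sheet$n_surface_nodes)
  ids <- sheet$node_grid[onedge]
  ids <- ids[!is.na(ids)]
  flags[ids] <- TRUE
  flags[ids + sheet$n_surface_nodes] <- TRUE
  flags
}

# ---------------------------------------------------------------------------
# Degenerate classification and repair
# ---------------------------------------------------------------------------

#' Classify degenerate six-node elements
#'
#' Each degenerate element has exactly one invalid grid corner; elements are
#' grouped by that corner's topological index and classified by the local
#' configuration: `peak` (one element, corner on the exterior boundary),
#' `corner` (one element, corner on an interior hole), `step` (two
#' edge-adjacent elements collapsing at the same topological index),
#' `mirror` (two diagonal elements), `stair` (three elements). Any other
#' configuration is an error naming the element ids.
#'
#' @param sheet a `hex_sheet` from [build_hex_sheet()].
#' @return list of records: `element_ids`, `klass`,
#'   `shared_topological_indices`.
#' @export
classify_degenerates <- function(sheet) {
  if (!any(sheet$degenerate)) return(list())
  g <- sheet$grid
  m <- g$shape[1]; n <- g$shape[2]
  valid <- g$valid
  # invalid-region components and whether they touch the grid border
  invcomp <- mask_components(!valid)
  touches <- rep(FALSE, max(invcomp, na.rm = TRUE))
  bord <- c(invcomp[c(1, m), ], invcomp[, c(1, n)])
  touches[unique(bord[!is.na(bord)])] <- TRUE

  degel <- which(sheet$degenerate)
  inv_of <- matrix(NA_integer_, length(degel), 2)
  for (k in seq_along(degel)) {
    e <- degel[k]
    i <- sheet$cell_index[e, 1]; j <- sheet$cell_index[e, 2]
    cs <- rbind(c(i, j), c(i + 1, j), c(i + 1, j + 1), c(i, j + 1))
    bad <- which(!valid[cs])
    inv_of[k, ] <- cs[bad, ]
  }
  key <- paste(inv_of[, 1], inv_of[, 2])
  groups <- split(seq_along(degel), key)
  records <- list()
  for (grp in groups) {
    els <- degel[grp]
    v <- inv_of[grp[1], ]
    k <- length(els)
    klass <- if (k == 1) {
      ci <- invcomp[v[1], v[2]]
      if (!is.na(ci) && !touches[ci]) "corner" else "peak"
    } else if (k == 2) {
      ci <- sheet$cell_index[els, , drop = FALSE]
      d <- abs(ci[1, ] - ci[2, ])
      if (sum(d) == 1) "step" else "mirror"
    } else if (k == 3) "stair"
    else NA_character_
    if (is.na(klass))
      stop("unclassifiable degenerate configuration at grid node (",
           v[1], ",", v[2], "): elements ", paste(els, collapse = ", "))
    records[[length(records) + 1]] <-
      list(element_ids = els, klass = klass,
           shared_topological_indices = v)
  }
  records
}

#' Repair degenerate elements
#'
#' Class-specific repair: `peak` elements (a lone protruding corner) are
#' deleted; for every other class the missing grid node is created by
#' extrapolating the neighbouring bone-side and joint-side hits and
#' projecting them back onto the cartilage surface, turning all member
#' elements into full eight-node hexahedra. Idempotent.
#'
#' @param sheet a `hex_sheet`.
#' @param records output of [classify_degenerates()].
#' @return a repaired `hex_sheet` (no degenerate elements remain).
#' @export
repair_degenerates <- function(sheet, records) {
  if (length(records) == 0 && !any(sheet$degenerate)) {
    sheet$allow_degenerate <- FALSE
    return(sheet_rebuild(sheet))
  }
  g <- sheet$grid
  m <- g$shape[1]; n <- g$shape[2]
  for (rec in records) {
    v <- rec$shared_topological_indices
    if (rec$klass == "peak") {
      for (e in rec$element_ids) {
        ci <- sheet$cell_index[e, ]
        sheet$cell_active[ci[1], ci[2]] <- FALSE
      }
    } else {
      # create the missing node by parallelogram completion of each member
      # cell (adjacent corners' sum minus the diagonal corner), averaged;
      # kept unprojected -- snapping onto the nearest surface (often a hole
      # wall) would collapse the column
      i <- v[1]; j <- v[2]
      at <- function(arr, ij) arr[ij[1], ij[2], ]
      bp <- matrix(0, 0, 3); jp <- matrix(0, 0, 3)
      for (e in rec$element_ids) {
        ci <- sheet$cell_index[e, ]
        cs <- rbind(c(ci[1], ci[2]), c(ci[1] + 1, ci[2]),
                    c(ci[1] + 1, ci[2] + 1), c(ci[1], ci[2] + 1))
        miss <- which(cs[, 1] == i & cs[, 2] == j)
        adj <- switch(miss, c(2, 4), c(1, 3), c(4, 2), c(3, 1))
        diag_c <- setdiff(1:4, c(miss, adj))
        bp <- rbind(bp, at(g$bone_hits, cs[adj[1], ]) +
                      at(g$bone_hits, cs[adj[2], ]) -
                      at(g$bone_hits, cs[diag_c, ]))
        jp <- rbind(jp, at(g$joint_hits, cs[adj[1], ]) +
                      at(g$joint_hits, cs[adj[2], ]) -
                      at(g$joint_hits, cs[diag_c, ]))
      }
      g$bone_hits[i, j, ] <- colMeans(bp)
      g$joint_hits[i, j, ] <- colMeans(jp)
      g$valid[i, j] <- TRUE
      sheet$created[i, j] <- TRUE
    }
  }
  sheet$grid <- g
  sheet$allow_degenerate <- FALSE
  sheet_rebuild(sheet)
}

# ---------------------------------------------------------------------------
# Quality optimization
# ---------------------------------------------------------------------------

#' Optimize element quality to a scaled-Jacobian floor
#'
#' Alternating constrained Laplacian smoothing of the nodes of
#' below-threshold elements with re-projection onto the cartilage surface.
#' An iteration is only accepted if it does not increase the number of
#' elements below the target (monotone acceptance); the step is halved
#' otherwise. Terminates with an error -- never an unbounded loop -- after
#' `max_iterations`.
#'
#' @param sheet a repaired `hex_sheet`.
#' @param sj_target scaled-Jacobian floor (0 for untangling, 0.5 for the
#'   final quality stage).
#' @param max_iterations iteration guard.
#' @param project re-project moved nodes onto the source surface.
#' @return the optimized `hex_sheet`.
#' @export
optimize_quality <- function(sheet, sj_target, max_iterations = 200,
                             project = TRUE) {
  if (any(sheet$degenerate))
    stop("optimize_quality requires a repaired sheet")
  nodes <- sheet$nodes
  hexes <- sheet$hexes
  ns <- sheet$n_surface_nodes
  sj <- scaled_jacobian_all(nodes, hexes)
  n_bad <- sum(sj < sj_target)
  if (n_bad == 0) return(sheet)
  # node -> grid neighbours (same layer) adjacency from the grid
  nid <- sheet$node_grid
  m <- nrow(nid); n <- ncol(nid)
  nbr <- vector("list", ns)
  for (j in seq_len(n)) for (i in seq_len(m)) {
    id <- nid[i, j]
    if (is.na(id)) next
    nb <- c()
    if (i > 1 && !is.na(nid[i - 1, j])) nb <- c(nb, nid[i - 1, j])
    if (i < m && !is.na(nid[i + 1, j])) nb <- c(nb, nid[i + 1, j])
    if (j > 1 && !is.na(nid[i, j - 1])) nb <- c(nb, nid[i, j - 1])
    if (j < n && !is.na(nid[i, j + 1])) nb <- c(nb, nid[i, j + 1])
    nbr[[id]] <- nb
  }
  for (iter in seq_len(max_iterations)) {
    bad_el <- which(sj < sj_target)
    if (length(bad_el) == 0) break
    bad_nodes <- unique(as.vector(hexes[bad_el, , drop = FALSE]))
    step <- 1
    repeat {
      cand <- nodes
      for (nd in bad_nodes) {
        base <- ((nd - 1) %% ns) + 1
        layer_off <- nd - base
        nb <- nbr[[base]] + layer_off
        if (length(nb) < 2) next
        target <- colMeans(nodes[nb, , drop = FALSE])
        cand[nd, ] <- (1 - step) * nodes[nd, ] + step * target
      }
      if (project) {
        mv <- bad_nodes[rowSums((cand[bad_nodes, , drop = FALSE] -
                                   nodes[bad_nodes, , drop = FALSE])^2) > 0]
        if (length(mv)) {
          pr <- closest_point_on_surface(cand[mv, , drop = FALSE],
                                         sheet$grid$surface)
          cand[mv, ] <- pr$point
        }
      }
      sj_new <- scaled_jacobian_all(cand, hexes)
      if (sum(sj_new < sj_target) <= length(bad_el)) {
        nodes <- cand
        sj <- sj_new
        break
      }
      step <- step / 2
      if (step < 1e-3) break # no acceptable move this round
    }
    if (step < 1e-3 && sum(sj < sj_target) >= length(bad_el) &&
        identical(which(sj < sj_target), bad_el) && iter > 5) {
      # stalled: no further monotone improvement possible
      break
    }
  }
  if (any(sj < sj_target)) {
    worst <- order(sj)[seq_len(min(5, length(sj)))]
    optimize_failure(sprintf(
      "quality target SJ >= %.2f not reached after %d iterations; worst: %s",
      sj_target, max_iterations,
      paste(sprintf("el %d (SJ %.3f)", worst, sj[worst]), collapse = ", ")),
      worst = data.frame(element = worst, sj = sj[worst]))
  }
  sheet <- sheet_apply_nodes(sheet, nodes)
  sheet
}

# push updated node coordinates back into the grid arrays and rebuild
sheet_apply_nodes <- function(sheet, nodes) {
  g <- sheet$grid
  ns <- sheet$n_surface_nodes
  ij <- which(!is.na(sheet$node_grid), arr.ind = TRUE)
  ids <- sheet$node_grid[ij]
  for (r in seq_len(nrow(ij))) {
    g$bone_hits[ij[r, 1], ij[r, 2], ] <- nodes[ids[r], ]
    g$joint_hits[ij[r, 1], ij[r, 2], ] <- nodes[ids[r] + ns, ]
  }
  sheet$grid <- g
  sheet_rebuild(sheet)
}

# ---------------------------------------------------------------------------
# Subdivision
# ---------------------------------------------------------------------------

#' Subdivide every element 2x2 in-plane
#'
#' Each element is split along both in-plane directions (never through the
#' depth): the element count quadruples and the original corner nodes are
#' preserved. New mid-edge and centre nodes are projected onto the cartilage
#' surface.
#'
#' @param sheet a conforming `hex_sheet`.
#' @return the refined `hex_sheet`.
#' @export
subdivide_inplane <- function(sheet) {
  if (any(sheet$degenerate))
    stop("subdivide_inplane requires a repaired sheet")
  g <- sheet$grid
  m <- g$shape[1]; n <- g$shape[2]
  m2 <- 2L * m - 1L; n2 <- 2L * n - 1L
  mk <- function(old) {
    new <- array(NA_real_, c(m2, n2, 3))
    new[seq(1, m2, 2), seq(1, n2, 2), ] <- old
    new
  }
  bh <- mk(g$bone_hits); jh <- mk(g$joint_hits)
  valid2 <- matrix(FALSE, m2, n2)
  valid2[seq(1, m2, 2), seq(1, n2, 2)] <- g$valid
  fill_mid <- function(arr, i, j, pts) { arr[i, j, ] <- pts; arr }
  new_pts <- list()
  # u-direction midpoints
  for (j in seq_len(n)) for (i in seq_len(m - 1)) {
    if (!g$valid[i, j] || !g$valid[i + 1, j]) next
    valid2[2 * i, 2 * j - 1] <- TRUE
    bh[2 * i, 2 * j - 1, ] <- (g$bone_hits[i, j, ] + g$bone_hits[i + 1, j, ]) / 2
    jh[2 * i, 2 * j - 1, ] <- (g$joint_hits[i, j, ] + g$joint_hits[i + 1, j, ]) / 2
  }
  for (j in seq_len(n - 1)) for (i in seq_len(m)) {
    if (!g$valid[i, j] || !g$valid[i, j + 1]) next
    valid2[2 * i - 1, 2 * j] <- TRUE
    bh[2 * i - 1, 2 * j, ] <- (g$bone_hits[i, j, ] + g$bone_hits[i, j + 1, ]) / 2
    jh[2 * i - 1, 2 * j, ] <- (g$joint_hits[i, j, ] + g$joint_hits[i, j + 1, ]) / 2
  }
  cell_active2 <- matrix(FALSE, m2 - 1, n2 - 1)
  for (j in seq_len(n - 1)) for (i in seq_len(m - 1)) {
    cs <- rbind(c(i, j), c(i + 1, j), c(i + 1, j + 1), c(i, j + 1))
    if (!sheet$cell_active[i, j] || !all(g$valid[cs])) next
    valid2[2 * i, 2 * j] <- TRUE
    bh[2 * i, 2 * j, ] <- colMeans(matrix(g$bone_hits[cbind(
      rep(cs[, 1], 3), rep(cs[, 2], 3), rep(1:3, each = 4))], 4, 3))
    jh[2 * i, 2 * j, ] <- colMeans(matrix(g$joint_hits[cbind(
      rep(cs[, 1], 3), rep(cs[, 2], 3), rep(1:3, each = 4))], 4, 3))
    cell_active2[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- TRUE
  }
  # project new nodes onto the surface (cap the correction at half a pitch)
  newmask <- valid2
  newmask[seq(1, m2, 2), seq(1, n2, 2)] <- FALSE
  idx <- which(newmask)
  if (length(idx)) {
    for (arrname in c("bh", "jh")) {
      arr <- get(arrname)
      P <- cbind(arr[, , 1][idx], arr[, , 2][idx], arr[, , 3][idx])
      pr <- closest_point_on_surface(P, g$surface)
      move <- sqrt(rowSums((pr$point - P)^2))
      ok <- move <= sheet$grid$pitch / 2
      P[ok, ] <- pr$point[ok, , drop = FALSE]
      arr[, , 1][idx] <- P[, 1]; arr[, , 2][idx] <- P[, 2]
      arr[, , 3][idx] <- P[, 3]
      assign(arrname, arr)
    }
  }
  g$shape <- c(m2, n2)
  g$bone_hits <- bh; g$joint_hits <- jh; g$valid <- valid2
  g$origins <- NULL; g$directions <- NULL
  g$pitch <- g$pitch / 2
  created2 <- matrix(FALSE, m2, n2)
  created2[seq(1, m2, 2), seq(1, n2, 2)] <- sheet$created
  sheet$grid <- g
  sheet$cell_active <- cell_active2
  sheet$created <- created2
  sheet_rebuild(sheet)
}

#' Subdivide the sheet through the cartilage depth
#'
#' Splits every bone-to-joint column into `layers` linearly spaced segments,
#' turning the single-layer sheet into the final hexahedral mesh.
#'
#' @param sheet a conforming single-layer `hex_sheet`.
#' @param layers number of depth layers.
#' @return a `hex_mesh` with `nodes`, `hexes`, `layer_count`,
#'   `element_layer` (1 = bone-most) and `provenance`.
#' @export
subdivide_depth <- function(sheet, layers = 4) {
  stopifnot(layers >= 1)
  if (any(sheet$degenerate))
    stop("subdivide_depth requires a repaired sheet")
  ns <- sheet$n_surface_nodes
  bone <- sheet$nodes[seq_len(ns), , drop = FALSE]
  joint <- sheet$nodes[ns + seq_len(ns), , drop = FALSE]
  nodes <- do.call(rbind, lapply(0:layers, function(L)
    bone + (joint - bone) * (L / layers)))
  E <- nrow(sheet$hexes)
  hexes <- matrix(0L, E * layers, 8)
  elayer <- integer(E * layers)
  b <- sheet$hexes[, 1:4, drop = FALSE]
  for (L in seq_len(layers)) {
    lo <- (L - 1L) * ns; hi <- L * ns
    rows <- (L - 1L) * E + seq_len(E)
    hexes[rows, ] <- cbind(b + lo, b + hi)
    elayer[rows] <- L
  }
  structure(list(nodes = nodes, hexes = hexes, layer_count = layers,
                 element_layer = elayer,
                 n_surface_nodes = ns,
                 edge_node_flags = rep(sheet$edge_node_flags[seq_len(ns)],
                                       layers + 1),
                 provenance = sheet$provenance),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh: %d nodes, %d hexes, %d layers%s>\n",
              nrow(x$nodes), nrow(x$hexes), x$layer_count,
              if (length(x$provenance$fallbacks))
                paste0("; fallbacks: ",
                       paste(x$provenance$fallbacks, collapse = ", "))
              else "; no fallbacks"))
  invisible(x)
}

#' Conformity audit of a hex mesh or sheet
#'
#' Checks that every face is shared by at most two elements and counts
#' interior/boundary faces.
#' @param mesh a `hex_mesh` or `hex_sheet`.
#' @return list: `conforming`, `n_interior`, `n_boundary`.
#' @export
check_conformity <- function(mesh) {
  faces <- hex_faces(mesh$hexes)
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  counts <- table(key)
  list(conforming = all(counts <= 2),
       n_interior = sum(counts == 2),
       n_boundary = sum(counts == 1))
}

hex_faces <- function(hexes) {
  idx <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
               c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  do.call(rbind, lapply(seq_len(nrow(idx)), function(r)
    hexes[, idx[r, ], drop = FALSE]))
}

#' Mean in-plane edge length of a hex mesh (mm)
#'
#' Averages the lengths of the eight in-plane element edges (bone-side and
#' joint-side quad edges), excluding the four depth edges.
#' @param mesh a `hex_mesh` or `hex_sheet`.
#' @export
mean_inplane_edge_length <- function(mesh) {
  h <- mesh$hexes
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 5))
  e <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
    cbind(h[, pairs[r, 1]], h[, pairs[r, 2]])))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), , drop = FALSE]
  mean(sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                       mesh$nodes[e[, 2], , drop = FALSE])^2)))
}

# ---------------------------------------------------------------------------
# Orchestration with the fallback cascade
# ---------------------------------------------------------------------------

#' Default cartilage meshing configuration
#' @return named list of meshing parameters.
#' @export
cartilage_mesh_config <- function() {
  list(target_edge_mm = 1.0, depth_layers = 4L, sj_stage1 = 0,
       sj_stage2 = 0.5, max_iterations = 200L, bbox_scale = 0.9,
       blend = TRUE, min_feature_angle_deg = 35, joint_stop_angle_deg = 30,
       bone_share = 0.8, slope_deg = 45, relax_step = 0.1, sg_degree = 3L,
       sg_window = 7L, front_iter_cap = 2000L)
}

#' Mesh a cartilage surface into a blended hexahedral mesh
#'
#' Runs the full swept-extrusion pipeline: sweep grid, sheet connection,
#' degenerate repair, stage-1 untangling (scaled Jacobian >= 0), in-plane
#' subdivision, stage-2 optimization (>= 0.5), optional cartilage-to-bone
#' blending, and depth subdivision. On failure the fallback cascade is
#' walked -- disable bone fusion, reduce blend displacement, simplified
#' rectilinear grid (tibial), early in-plane subdivision -- and every
#' fallback that fired is recorded in the mesh provenance.
#'
#' @param cartilage_surface closed repaired [tri_surface()].
#' @param site `"femoral"`, `"tibial"`, or `"patellar"`.
#' @param bone_surface optional bone [tri_surface()] for interface fusion.
#' @param config see [cartilage_mesh_config()].
#' @return a `hex_mesh`.
#' @export
mesh_cartilage <- function(cartilage_surface,
                           site = c("femoral", "tibial", "patellar"),
                           bone_surface = NULL,
                           config = cartilage_mesh_config()) {
  site <- match.arg(site)
  config <- modifyList(cartilage_mesh_config(), config)
  attempts <- list(list(fuse = !is.null(bone_surface), blend_scale = 1,
                        grid = NULL, early = FALSE, fallbacks = character(0)))
  if (!is.null(bone_surface))
    attempts <- c(attempts, list(list(fuse = FALSE, blend_scale = 1,
                                      grid = NULL, early = FALSE,
                                      fallbacks = "no_bone_fusion")))
  attempts <- c(attempts, list(list(
    fuse = FALSE, blend_scale = 0.5, grid = NULL, early = FALSE,
    fallbacks = c("no_bone_fusion", "reduced_blend_displacement"))))
  if (site == "tibial")
    attempts <- c(attempts, list(list(
      fuse = FALSE, blend_scale = 0.5, grid = "rect", early = FALSE,
      fallbacks = c("no_bone_fusion", "reduced_blend_displacement",
                    "simplified_grid"))))
  attempts <- c(attempts, list(list(
    fuse = FALSE, blend_scale = 0.5,
    grid = if (site == "tibial") "rect" else NULL, early = TRUE,
    fallbacks = c("no_bone_fusion", "reduced_blend_displacement",
                  if (site == "tibial") "simplified_grid",
                  "early_inplane_subdivision"))))

  errors <- character(0)
  for (att in attempts) {
    res <- tryCatch(
      mesh_cartilage_once(cartilage_surface, site, bone_surface, config, att),
      hexcart_strategy_failure = function(e) e,
      hexcart_optimize_failure = function(e) e,
      hexcart_blend_failure = function(e) e)
    if (inherits(res, "hex_mesh")) return(res)
    errors <- c(errors, conditionMessage(res))
  }
  stop("all meshing fallbacks exhausted for site '", site, "':\n  ",
       paste(errors, collapse = "\n  "))
}

mesh_cartilage_once <- function(cartilage_surface, site, bone_surface,
                                config, att) {
  grid <- make_sweep_grid(cartilage_surface, site,
                          target_edge_mm = config$target_edge_mm,
                          strategy = att$grid,
                          pitch_factor = if (att$early) 1 else 2,
                          bbox_scale = config$bbox_scale)
  sheet <- build_hex_sheet(grid)
  recs <- classify_degenerates(sheet)
  sheet <- repair_degenerates(sheet, recs)
  sheet <- optimize_quality(sheet, config$sj_stage1, config$max_iterations)
  if (!att$early) sheet <- subdivide_inplane(sheet)
  sheet <- optimize_quality(sheet, config$sj_stage2, config$max_iterations)
  sheet$provenance$fallbacks <- att$fallbacks
  sheet$provenance$degenerate_records <-
    table(vapply(recs, `[[`, character(1), "klass"))
  if (isTRUE(config$blend)) {
    bcfg <- config
    bcfg$blend_scale <- att$blend_scale
    sheet <- blend_cartilage(sheet,
                             bone_surface = if (att$fuse) bone_surface,
                             config = bcfg)
  } else sheet$provenance$fusion <- "disabled"
  subdivide_depth(sheet, config$depth_layers)
}
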