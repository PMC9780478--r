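#' Cartilage-to-bone interface blending
#'
#' A linearly subdivided brick mesh meets the bone in a stair-step edge;
#' during contact simulations these protruding corners catch on articulating
#' meshes. Blending replaces the step with a ramp: bone-side edge nodes are
#' stretched outward and joint-side edge nodes compressed inward along the
#' edge-face normals until the edge profile reaches a target slope, the
#' resulting fold angles are kept above a minimum feature angle, element
#' intersections around holes and interior curves are resolved by
#' Savitzky-Golay filtering of the edge loops, and a graduated
#' advancing-front Laplacian smoothing distributes the deformation over at
#' most five edgewise element layers. Only node coordinates change, never
#' connectivity.
#'
#' @name blend
NULL

blend_failure <- function(msg) {
  stop(structure(class = c("hexcart_blend_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# ordered boundary loops of a quad mesh: list of integer vectors of node ids
quad_boundary_loops <- function(quads) {
  e <- rbind(quads[, c(1, 2), drop = FALSE], quads[, c(2, 3), drop = FALSE],
             quads[, c(3, 4), drop = FALSE], quads[, c(4, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bd <- e[key %in% names(tab)[tab == 1], , drop = FALSE]
  if (nrow(bd) == 0) return(list())
  nxt <- split(bd[, 2], bd[, 1])
  loops <- list()
  unused <- rep(TRUE, nrow(bd))
  used_edge <- new.env()
  for (r in seq_len(nrow(bd))) {
    ek <- paste(bd[r, 1], bd[r, 2])
    if (!is.null(used_edge[[ek]])) next
    loop <- bd[r, 1]
    cur <- bd[r, 1]
    repeat {
      cands <- nxt[[as.character(cur)]]
      found <- FALSE
      for (cn in cands) {
        ek2 <- paste(cur, cn)
        if (is.null(used_edge[[ek2]])) {
          used_edge[[ek2]] <- TRUE
          cur <- cn
          found <- TRUE
          break
        }
      }
      if (!found || cur == loop[1]) break
      loop <- c(loop, cur)
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

# face depth from the mesh edge by BFS over shared-edge adjacency:
# depth 1 = faces touching an edge node
quad_face_depth <- function(quads, edge_nodes) {
  nq <- nrow(quads)
  e <- rbind(quads[, c(1, 2), drop = FALSE], quads[, c(2, 3), drop = FALSE],
             quads[, c(3, 4), drop = FALSE], quads[, c(4, 1), drop = FALSE])
  fid <- rep(seq_len(nq), 4)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  adj_by_edge <- split(fid, key)
  adj <- vector("list", nq)
  for (fs in adj_by_edge)
    if (length(fs) == 2) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  depth <- rep(NA_integer_, nq)
  seed <- which(apply(matrix(quads %in% edge_nodes, nq), 1, any))
  depth[seed] <- 1L
  frontier <- seed
  d <- 1L
  while (length(frontier)) {
    d <- d + 1L
    nxtf <- unique(unlist(adj[frontier]))
    nxtf <- nxtf[is.na(depth[nxtf])]
    depth[nxtf] <- d
    frontier <- nxtf
  }
  depth
}

#' Initialize blending displacements
#'
#' Edge-node displacement vectors along the outward edge-face normals: the
#' bone-side node takes `bone_share` (80%) of the horizontal run and the
#' joint-side node the remainder (inward), sized so the blended edge profile
#' attains the target slope (45 degrees by default). If a bone surface is
#' supplied, displaced bone-side targets are snapped to the nearest point on
#' the bone surface.
#'
#' @param sheet an optimized single-layer `hex_sheet`.
#' @param bone_surface optional [tri_surface()] to fuse bone-side nodes to.
#' @param config blending parameters (see [cartilage_mesh_config()]).
#' @return a `blend_displacement`: paired bone/joint edge node ids, vectors
#'   (mm), per-node depth, and the current `relaxation_level`.
#' @export
init_blend_displacements <- function(sheet, bone_surface = NULL,
                                     config = cartilage_mesh_config()) {
  config <- modifyList(cartilage_mesh_config(), config)
  ns <- sheet$n_surface_nodes
  edge_b <- which(sheet$edge_node_flags[seq_len(ns)])
  if (length(edge_b) == 0) blend_failure("sheet has no edge nodes")
  nodes <- sheet$nodes
  depth_vec <- nodes[edge_b + ns, , drop = FALSE] - nodes[edge_b, , drop = FALSE]
  depth <- sqrt(rowSums(depth_vec^2))
  if (any(depth < 1e-9))
    blend_failure("open edge-loop pairing mismatch: zero-depth edge column")
  depth_dir <- depth_vec / depth

  # outward in-plane direction: away from the mean of interior neighbours,
  # orthogonalized against the local depth direction
  nid <- sheet$node_grid
  m <- nrow(nid); n <- ncol(nid)
  outward <- matrix(0, length(edge_b), 3)
  pos_of <- matrix(NA_integer_, length(edge_b), 2)
  lookup <- match(seq_len(ns), nid)
  for (k in seq_along(edge_b)) {
    flat <- lookup[edge_b[k]]
    i <- (flat - 1) %% m + 1; j <- (flat - 1) %/% m + 1
    pos_of[k, ] <- c(i, j)
    nbs <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nbs <- nbs[nbs[, 1] >= 1 & nbs[, 1] <= m & nbs[, 2] >= 1 & nbs[, 2] <= n, ,
               drop = FALSE]
    ids <- nid[nbs]
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0) next
    ctr <- colMeans(nodes[ids, , drop = FALSE])
    o <- nodes[edge_b[k], ] - ctr
    o <- o - sum(o * depth_dir[k, ]) * depth_dir[k, ]
    ol <- sqrt(sum(o^2))
    if (ol > 1e-9) outward[k, ] <- o / ol
  }
  run <- depth / tan(config$slope_deg * pi / 180) *
    (if (is.null(config$blend_scale)) 1 else config$blend_scale)
  bone_vec <- outward * (config$bone_share * run)
  joint_vec <- -outward * ((1 - config$bone_share) * run)

  fused <- rep(FALSE, length(edge_b))
  if (!is.null(bone_surface)) {
    target <- nodes[edge_b, , drop = FALSE] + bone_vec
    pr <- closest_point_on_surface(target, bone_surface)
    cap <- 2 * depth
    ok <- pr$distance <= cap
    bone_vec[ok, ] <- pr$point[ok, , drop = FALSE] -
      nodes[edge_b[ok], , drop = FALSE]
    fused <- ok
  }
  structure(list(bone_ids = edge_b, joint_ids = edge_b + ns,
                 bone_vec = bone_vec, joint_vec = joint_vec,
                 bone_factor = rep(1, length(edge_b)),
                 relaxation_level = 1, depth = depth,
                 grid_pos = pos_of, fused = fused),
            class = "blend_displacement")
}

# apply a displacement field to sheet nodes (returns the node matrix)
apply_blend <- function(sheet, disp) {
  nodes <- sheet$nodes
  nodes[disp$bone_ids, ] <- nodes[disp$bone_ids, , drop = FALSE] +
    disp$bone_vec * disp$bone_factor * disp$relaxation_level
  nodes[disp$joint_ids, ] <- nodes[disp$joint_ids, , drop = FALSE] +
    disp$joint_vec * disp$relaxation_level
  nodes
}

# fold angles (degrees, deviation-from-flat) across the joint-side rim:
# between each lateral wall quad of an edge column pair and the adjacent
# joint-surface quad; returns one angle per boundary joint edge
joint_rim_angles <- function(sheet, nodes) {
  jq <- sheet$joint_quads
  ns <- sheet$n_surface_nodes
  e <- rbind(jq[, c(1, 2)], jq[, c(2, 3)], jq[, c(3, 4)], jq[, c(4, 1)])
  fid <- rep(seq_len(nrow(jq)), 4)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bidx <- which(key %in% names(tab)[tab == 1])
  angs <- numeric(0)
  ids <- integer(0)
  for (r in bidx) {
    a <- e[r, 1]; b <- e[r, 2]
    wall <- rbind(nodes[a - ns, ], nodes[b - ns, ], nodes[b, ], nodes[a, ])
    nq1 <- quad_normal(wall)
    f <- fid[r]
    nq2 <- quad_normal(nodes[jq[f, ], , drop = FALSE])
    ang <- acos(pmax(-1, pmin(1, abs(sum(nq1 * nq2))))) * 180 / pi
    angs <- c(angs, ang)
    ids <- c(ids, a)
  }
  list(angles = angs, joint_nodes = ids)
}

quad_normal <- function(q) {
  n1 <- cross3(q[2, ] - q[1, ], q[3, ] - q[1, ])
  n2 <- cross3(q[3, ] - q[1, ], q[4, ] - q[1, ])
  n <- n1 + n2
  n / max(sqrt(sum(n^2)), 1e-12)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Enforce a minimum blended feature angle
#'
#' Bone-side displacement magnitudes of offending edge columns are relaxed
#' in 10% increments until every joint-side blended fold angle reaches the
#' minimum feature angle. Magnitudes are monotone non-increasing.
#'
#' @param sheet the `hex_sheet` being blended.
#' @param disp a `blend_displacement`.
#' @param min_angle_deg minimum feature angle (degrees, deviation from
#'   flat).
#' @param relax_step fractional reduction per increment.
#' @param max_rounds safety guard.
#' @return the adjusted `blend_displacement`.
#' @export
enforce_min_feature_angle <- function(sheet, disp, min_angle_deg = 35,
                                      relax_step = 0.1, max_rounds = 50) {
  ns <- sheet$n_surface_nodes
  for (round in seq_len(max_rounds)) {
    nodes <- apply_blend(sheet, disp)
    ja <- joint_rim_angles(sheet, nodes)
    bad <- ja$angles < min_angle_deg - 1e-9
    if (!any(bad)) break
    bad_bone <- unique(ja$joint_nodes[bad]) - ns
    k <- match(bad_bone, disp$bone_ids)
    k <- k[!is.na(k)]
    if (length(k) == 0) break
    disp$bone_factor[k] <- disp$bone_factor[k] * (1 - relax_step)
    if (all(disp$bone_factor[k] < 1e-3)) break
  }
  disp
}

# Savitzky-Golay smoothing of a closed loop of 3-D points (per coordinate,
# periodic padding)
sg_smooth_loop <- function(P, degree = 3, window = 7) {
  n <- nrow(P)
  if (n <= window) return(P)
  w <- (window - 1) %/% 2
  out <- P
  for (d in 1:3) {
    x <- c(P[(n - w + 1):n, d], P[, d], P[1:w, d])
    y <- signal::sgolayfilt(x, p = degree, n = window)
    out[, d] <- y[(w + 1):(w + n)]
  }
  out
}

# triangles of the boundary faces of edge elements, as a stacked corner
# matrix for the intersection kernel
edge_element_face_triangles <- function(sheet, nodes, depth_sel = 2) {
  ns <- sheet$n_surface_nodes
  edge_nodes <- which(sheet$edge_node_flags)
  el_sel <- which(apply(matrix(sheet$hexes %in% edge_nodes,
                               nrow(sheet$hexes)), 1, any))
  if (length(el_sel) == 0) return(NULL)
  faces <- hex_faces(sheet$hexes[el_sel, , drop = FALSE])
  tris <- rbind(faces[, c(1, 2, 3)], faces[, c(1, 3, 4)])
  T <- matrix(0, nrow(tris) * 3, 3)
  for (c2 in 1:3) T[seq(c2, by = 3, length.out = nrow(tris)), ] <-
    nodes[tris[, c2], , drop = FALSE]
  T
}

#' Resolve blending-induced element intersections
#'
#' Edge-node coordinates are smoothed with a degree-3 Savitzky-Golay filter
#' along each (arc-length ordered, periodically padded) edge loop; if face
#' intersections among the edge elements remain, the global displacement
#' magnitude is reduced in 10% steps until the configuration is
#' intersection-free.
#'
#' @param sheet the `hex_sheet` being blended.
#' @param disp a `blend_displacement`.
#' @param config blending parameters.
#' @return the adjusted `blend_displacement` with `sg_loops` attached
#'   (smoothed edge-node positions) and the final `relaxation_level`.
#' @export
resolve_intersections <- function(sheet, disp,
                                  config = cartilage_mesh_config()) {
  config <- modifyList(cartilage_mesh_config(), config)
  ns <- sheet$n_surface_nodes
  repeat {
    nodes <- apply_blend(sheet, disp)
    # the filter correction scales with the relaxation level so that zero
    # magnitude reverts exactly to the raw (intersection-free) edge
    for (quads in list(sheet$bone_quads, sheet$joint_quads)) {
      for (loop in quad_boundary_loops(quads)) {
        P <- nodes[loop, , drop = FALSE]
        S <- sg_smooth_loop(P, config$sg_degree, config$sg_window)
        nodes[loop, ] <- P + disp$relaxation_level * (S - P)
      }
    }
    T <- edge_element_face_triangles(sheet, nodes)
    n_int <- if (is.null(T)) 0 else cpp_tri_soup_intersections(T, T) / 2
    if (n_int == 0) {
      disp$smoothed_nodes <- nodes
      return(disp)
    }
    disp$relaxation_level <- disp$relaxation_level * (1 - config$relax_step)
    if (disp$relaxation_level < 1e-3)
      blend_failure(sprintf(
        "element intersections persist at zero blend magnitude (%d pairs)",
        n_int))
  }
}

#' Graduated advancing-front smoothing
#'
#' Independent Laplacian smoothing of the bone-side and joint-side quad
#' surfaces over an advancing front of faces anchored at the (fixed)
#' cartilage edge nodes. The bone-side front advances from an element depth
#' of two to five with the iteration count halved at each advance; the
#' joint-side front advances once. The initial iteration count is
#' `550 * n_surface / (n_surface - n_front)` (face counts, rounded up,
#' capped). Smoothing stops early rather than violate the quality floors:
#' interior elements keep scaled Jacobians above 0.5 and blended edge
#' elements stay positive.
#'
#' @param sheet a blended `hex_sheet` (node coordinates already displaced).
#' @param config blending parameters.
#' @return the smoothed `hex_sheet`.
#' @export
graduated_front_smoothing <- function(sheet,
                                      config = cartilage_mesh_config()) {
  config <- modifyList(cartilage_mesh_config(), config)
  ns <- sheet$n_surface_nodes
  nodes <- sheet$nodes
  edge_nodes <- which(sheet$edge_node_flags)
  hexes <- sheet$hexes
  edge_el <- apply(matrix(hexes %in% edge_nodes, nrow(hexes)), 1, any)

  sj_ok <- function(nd) {
    sj <- scaled_jacobian_all(nd, hexes)
    all(sj[edge_el] > 0) && all(sj[!edge_el] > 0.5)
  }

  smooth_side <- function(nodes, quads, depths, schedule) {
    nq <- nrow(quads)
    for (adv in seq_along(schedule)) {
      sel <- which(!is.na(depths) & depths <= schedule[[adv]]$depth)
      n_front <- length(sel)
      if (n_front == 0 || n_front >= nq) next
      iters <- schedule[[adv]]$iters
      front_nodes <- setdiff(unique(as.vector(quads[sel, , drop = FALSE])),
                             edge_nodes)
      # anchor nodes shared with faces outside the front
      outside <- unique(as.vector(quads[-sel, , drop = FALSE]))
      movable <- setdiff(front_nodes, outside)
      if (length(movable) == 0) next
      # neighbour map within the front faces
      e <- rbind(quads[sel, c(1, 2), drop = FALSE],
                 quads[sel, c(2, 3), drop = FALSE],
                 quads[sel, c(3, 4), drop = FALSE],
                 quads[sel, c(4, 1), drop = FALSE])
      nbrs <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
      nbrs <- lapply(nbrs, unique)
      check_every <- 25L
      it <- 0L
      while (it < iters) {
        chunk <- min(check_every, iters - it)
        cand <- nodes
        for (rep_i in seq_len(chunk)) {
          for (nd in movable) {
            nb <- nbrs[[as.character(nd)]]
            cand[nd, ] <- colMeans(cand[nb, , drop = FALSE])
          }
        }
        if (!sj_ok(cand)) break  # stop before elements skew
        nodes <- cand
        it <- it + chunk
      }
    }
    nodes
  }

  # bone side: depths two to five, iterations halved at each advance
  bq <- sheet$bone_quads
  bdepth <- quad_face_depth(bq, edge_nodes[edge_nodes <= ns])
  nf1 <- sum(!is.na(bdepth) & bdepth <= 2)
  iters_b <- front_iteration_schedule(nrow(bq), nf1, n_advances = 4,
                                      cap = config$front_iter_cap)
  sched_b <- lapply(1:4, function(adv)
    list(depth = adv + 1, iters = iters_b[adv]))
  nodes <- smooth_side(nodes, bq, bdepth, sched_b)

  # joint side: a single advance with the full initial count
  jq <- sheet$joint_quads
  jdepth <- quad_face_depth(jq, edge_nodes[edge_nodes > ns])
  nfj <- sum(!is.na(jdepth) & jdepth <= 2)
  iters_j <- front_iteration_schedule(nrow(jq), nfj, n_advances = 1,
                                      cap = config$front_iter_cap)
  sched_j <- list(list(depth = 2, iters = iters_j[1]))
  nodes_j <- smooth_side(nodes, jq, jdepth, sched_j)
  # joint-side stop: blended fold angles must stay above the stop angle
  ja <- joint_rim_angles(sheet, nodes_j)
  if (all(ja$angles >= config$joint_stop_angle_deg - 1e-9)) nodes <- nodes_j

  sheet_apply_nodes(sheet, nodes)
}

#' Advancing-front smoothing iteration schedule
#'
#' The initial iteration count is `550 * n_surface / (n_surface - n_front)`
#' (quadrilateral face counts, rounded up, capped), then halved (rounded up)
#' at each subsequent front advance.
#'
#' @param n_surface number of quad faces on the cartilage surface.
#' @param n_front number of faces in the first front selection.
#' @param n_advances number of front advances.
#' @param cap upper bound on any entry.
#' @return integer vector of length `n_advances`.
#' @export
front_iteration_schedule <- function(n_surface, n_front, n_advances = 4,
                                     cap = 2000L) {
  n0 <- min(cap, ceiling(550 * n_surface / max(n_surface - n_front, 1)))
  out <- integer(n_advances)
  out[1] <- n0
  if (n_advances > 1)
    for (k in 2:n_advances) out[k] <- ceiling(out[k - 1] / 2)
  out
}

#' Blend a cartilage sheet into its bone interface
#'
#' Orchestrates displacement initialization, feature-angle enforcement,
#' intersection resolution, and graduated front smoothing. Geometry-only:
#' node and element counts are unchanged. The provenance records the fusion
#' outcome (`"full"`, `"perimeter"`, or `"none"`).
#'
#' @param sheet an optimized single-layer `hex_sheet`.
#' @param bone_surface optional bone [tri_surface()].
#' @param config blending parameters (see [cartilage_mesh_config()]).
#' @return the blended `hex_sheet`.
#' @export
blend_cartilage <- function(sheet, bone_surface = NULL,
                            config = cartilage_mesh_config()) {
  config <- modifyList(cartilage_mesh_config(), config)
  n_nodes <- nrow(sheet$nodes)
  n_el <- nrow(sheet$hexes)
  ns <- sheet$n_surface_nodes

  disp <- init_blend_displacements(sheet, bone_surface, config)
  disp <- enforce_min_feature_angle(sheet, disp, config$min_feature_angle_deg,
                                    config$relax_step)
  disp <- resolve_intersections(sheet, disp, config)

  # fusion provenance: perimeter nodes are fused by the displacement snap;
  # full fusion additionally requires every interior bone-side node to sit
  # on the bone surface (within a tolerance of half the local depth)
  fusion <- "none"
  if (!is.null(bone_surface)) {
    if (all(disp$fused)) {
      interior_b <- setdiff(seq_len(ns), disp$bone_ids)
      if (length(interior_b)) {
        dint <- closest_point_on_surface(
          sheet$nodes[interior_b, , drop = FALSE], bone_surface)$distance
        fusion <- if (all(dint <= pmax(0.5 * mean(disp$depth), 0.25)))
          "full" else "perimeter"
      } else fusion <- "full"
    } else if (any(disp$fused)) fusion <- "perimeter"
  }

  nodes <- disp$smoothed_nodes
  sheet <- sheet_apply_nodes(sheet, nodes)
  sheet <- graduated_front_smoothing(sheet, config)

  stopifnot(nrow(sheet$nodes) == n_nodes, nrow(sheet$hexes) == n_el)
  sheet$provenance$fusion <- fusion
  sheet$provenance$blend_relaxation <- disp$relaxation_level
  sheet
}
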