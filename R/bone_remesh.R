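#' Uniform isotropic remeshing by Voronoi clustering
#'
#' Produces the rigid-body bone surface meshes: vertices of the input
#' surface are partitioned into compact clusters (Lloyd k-means on vertex
#' coordinates), each cluster becomes one output vertex at its centroid, and
#' the cluster-adjacency dual of the input triangulation becomes the output
#' triangulation. The cluster count is chosen from the surface area so the
#' output approximates an equilateral tiling with the requested edge length:
#' one vertex per `sqrt(3)/2 * target^2` of area, giving triangle count
#' close to `area / (sqrt(3)/4 * target^2)` and mean edge length close to
#' the target.
#'
#' @param surface watertight [tri_surface()] input; must be densely
#'   triangulated relative to the target (several input vertices per
#'   cluster).
#' @param target_edge_mm target mean triangle edge length (mm).
#' @param seed integer seed making the clustering deterministic.
#' @return a watertight [tri_surface()].
#' @export
remesh_uniform <- function(surface, target_edge_mm = 3.0, seed = 1L) {
  area <- surface_area(surface)
  n_clusters <- as.integer(round(area / (sqrt(3) / 2 * target_edge_mm^2)))
  if (n_clusters < 16)
    stop("target edge ", target_edge_mm,
         " mm too large relative to the surface feature size (would give ",
         n_clusters, " clusters)")
  V <- surface$vertices
  if (nrow(V) < 4 * n_clusters)
    stop("target edge ", target_edge_mm,
         " mm too large for this surface: need >= ", 4 * n_clusters,
         " input vertices, have ", nrow(V),
         " (refine the input or coarsen the target)")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  # a degenerate cluster topology (two clusters meeting along disjoint
  # boundary segments) cannot be triangulated; retry with derived sub-seeds
  out <- NULL
  for (attempt in 0:1) {
    set.seed(as.integer(seed) + attempt * 1000L)
    km <- suppressWarnings(stats::kmeans(V, centers = n_clusters,
                                         iter.max = 50, nstart = 1))
    cl <- regularize_clusters(surface, km$cluster, km$centers)

    # dual triangulation: every input triangle whose corners fall in three
    # distinct clusters witnesses a triple junction of the partition
    F <- surface$triangles
    c1 <- cl[F[, 1]]; c2 <- cl[F[, 2]]; c3 <- cl[F[, 3]]
    tri <- cbind(c1, c2, c3)
    distinct <- c1 != c2 & c2 != c3 & c1 != c3
    tri <- tri[distinct, , drop = FALSE]
    key <- apply(tri, 1, function(r) paste(sort(r), collapse = "-"))
    tri <- tri[!duplicated(key), , drop = FALSE]
    tri <- repair_dual(tri)

    # cluster representative points: centroid projected onto the surface
    cent <- matrix(0, n_clusters, 3)
    for (d in 1:3) cent[, d] <- tapply(V[, d],
                                       factor(cl, seq_len(n_clusters)), mean)
    bad <- !is.finite(cent[, 1])
    cent[bad, ] <- km$centers[bad, , drop = FALSE]
    proj <- closest_point_on_surface(cent, surface)$point
    cand <- drop_unused_vertices(tri_surface(proj, tri))
    cand <- orient_consistently(cand)
    if (is_watertight(cand) && max(surface_components(cand)) == 1) {
      out <- cand
      break
    }
  }
  if (is.null(out)) {
    # sharp, thin, or prism-like geometries can make every clustering
    # topologically degenerate; fall back to quadric simplification at the
    # equivalent triangle budget, which preserves watertightness and hits
    # the same edge-length target
    d <- cpp_qem_decimate(surface$vertices, surface$triangles,
                          as.integer(2 * n_clusters))
    cand <- orient_consistently(tri_surface(d$vertices, d$triangles))
    if (is_watertight(cand)) out <- cand
  }
  if (is.null(out))
    stop("uniform remeshing failed: clustering dual degenerate and ",
         "quadric fallback not watertight")
  out
}

# Clean a k-means vertex partition for dual remeshing: majority-vote label
# smoothing removes jagged cluster boundaries (which create spurious triple
# junctions on flat regions), then each cluster is made edge-connected by
# reassigning stray components to their dominant neighbour label.
regularize_clusters <- function(surface, cl, centers, passes = 8) {
  F <- surface$triangles
  nv <- nrow(surface$vertices)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  key <- paste(e[, 1], e[, 2])
  e <- e[!duplicated(key), , drop = FALSE]
  nbr <- split(e[, 2], e[, 1])
  nbr_of <- vector("list", nv)
  nbr_of[as.integer(names(nbr))] <- nbr
  V <- surface$vertices
  for (p in seq_len(passes)) {
    changed <- 0L
    for (vtx in seq_len(nv)) {
      nb <- nbr_of[[vtx]]
      if (length(nb) < 3) next
      tab <- table(cl[nb])
      top <- as.integer(names(tab)[tab == max(tab)])
      if (cl[vtx] %in% top) next
      # tie-break to the nearest cluster centre
      if (length(top) > 1) {
        d2 <- rowSums((centers[top, , drop = FALSE] -
                         matrix(V[vtx, ], length(top), 3,
                                byrow = TRUE))^2)
        top <- top[which.min(d2)]
      }
      cl[vtx] <- top[1]
      changed <- changed + 1L
    }
    if (changed == 0L) break
  }
  # connectivity: keep each label's largest component, reassign the rest
  repeat {
    parent <- seq_len(nv)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    same <- cl[e[, 1]] == cl[e[, 2]]
    for (r in which(same)) {
      a <- find(e[r, 1]); b <- find(e[r, 2])
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_len(nv), find, integer(1))
    stray <- logical(nv)
    for (lab in unique(cl)) {
      sel <- which(cl == lab)
      rs <- roots[sel]
      tab <- table(rs)
      main <- names(tab)[which.max(tab)]
      stray[sel[rs != as.integer(main)]] <- TRUE
    }
    if (!any(stray)) break
    moved <- 0L
    for (vtx in which(stray)) {
      nb <- nbr_of[[vtx]]
      labs <- cl[nb]
      labs <- labs[labs != cl[vtx]]
      if (length(labs) == 0) next
      tab <- table(labs)
      cl[vtx] <- as.integer(names(tab)[which.max(tab)])
      moved <- moved + 1L
    }
    if (moved == 0L) break
  }
  cl
}

# Local surgery on the cluster-adjacency dual: four-valence cluster
# junctions leave a handful of edges shared by one or three triangles.
# Triangles on overfull edges are dropped (most-defective first, lowest id
# tie-break) and the remaining boundary loops are fan-filled.
repair_dual <- function(tri) {
  edge_stats <- function(tri) {
    e <- rbind(tri[, c(1, 2), drop = FALSE], tri[, c(2, 3), drop = FALSE],
               tri[, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    list(e = e, key = key, counts = table(key))
  }
  for (pass in seq_len(20)) {
    es <- edge_stats(tri)
    if (all(es$counts == 2)) return(tri)
    over <- names(es$counts)[es$counts > 2]
    if (length(over)) {
      ntri <- nrow(tri)
      tri_key <- matrix(es$key, ntri, 3)
      ndef <- rowSums(matrix(es$counts[es$key] != 2, ntri, 3))
      drop <- integer(0)
      for (ok in over) {
        inc <- which(apply(tri_key == ok, 1, any))
        inc <- setdiff(inc, drop)
        n_extra <- sum(apply(tri_key[inc, , drop = FALSE] == ok, 1, any)) - 2
        if (n_extra <= 0) next
        ord <- inc[order(-ndef[inc], -inc)]
        drop <- c(drop, head(ord, n_extra))
      }
      if (length(drop)) {
        tri <- tri[-drop, , drop = FALSE]
        next
      }
    }
    # fill boundary loops by fans
    bd <- es$e[es$key %in% names(es$counts)[es$counts == 1], , drop = FALSE]
    if (nrow(bd) == 0) next
    nxt <- new.env()
    for (r in seq_len(nrow(bd)))
      assign(as.character(bd[r, 1]),
             c(mget(as.character(bd[r, 1]), envir = nxt,
                    ifnotfound = list(integer(0)))[[1]], bd[r, 2]),
             envir = nxt)
    visited <- new.env()
    added <- FALSE
    for (r in seq_len(nrow(bd))) {
      start <- bd[r, 1]
      if (!is.null(visited[[as.character(start)]])) next
      loop <- start
      cur <- start
      for (guard in seq_len(12)) {
        visited[[as.character(cur)]] <- TRUE
        cands <- mget(as.character(cur), envir = nxt,
                      ifnotfound = list(integer(0)))[[1]]
        cands <- cands[is.na(match(cands, loop[-1]))]
        if (length(cands) == 0) break
        cur <- cands[1]
        if (cur == start) break
        loop <- c(loop, cur)
      }
      if (cur == start && length(loop) >= 3 && length(loop) <= 8) {
        for (i in 2:(length(loop) - 1))
          tri <- rbind(tri, c(loop[1], loop[i], loop[i + 1]))
        added <- TRUE
      }
    }
    if (!added) break
  }
  tri
}

#' Mean triangle edge length of a surface (mm)
#' @param surface a [tri_surface()].
#' @export
mean_edge_length <- function(surface) {
  F <- surface$triangles
  V <- surface$vertices
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), , drop = FALSE]
  mean(sqrt(rowSums((V[e[, 1], , drop = FALSE] -
                       V[e[, 2], , drop = FALSE])^2)))
}
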