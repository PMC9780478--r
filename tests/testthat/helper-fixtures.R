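# Shared fixtures, memoized so expensive phantom builds run once per suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

slab_phantom <- function() fixture("slab", function()
  make_slab_phantom(20, 10, 3, voxel_spacing_mm = 0.5))

hole_phantom <- function() fixture("hole", function()
  make_slab_phantom(20, 12, 3,
                    hole_specs = list(list(center = c(0, 0), radius = 2)),
                    voxel_spacing_mm = 0.5))

condyle_phantom <- function() fixture("condyle", function()
  make_joint_phantom("femoral"))

# optimized single-layer slab sheet (through stage-2), reused by blend tests
slab_sheet <- function() fixture("slab_sheet", function() {
  ph <- slab_phantom()
  g <- make_sweep_grid(ph$surfaces$cartilage, "tibial", 1.0,
                       strategy = "rect")
  s <- build_hex_sheet(g)
  s <- repair_degenerates(s, classify_degenerates(s))
  s <- optimize_quality(s, 0, 200)
  s <- subdivide_inplane(s)
  optimize_quality(s, 0.5, 200)
})

# condyle sheet through stage-2 (acceptance target t3 path)
condyle_sheet <- function() fixture("condyle_sheet", function() {
  ph <- condyle_phantom()
  g <- make_sweep_grid(ph$surfaces$cartilage, "femoral", 1.0)
  s <- build_hex_sheet(g)
  s <- repair_degenerates(s, classify_degenerates(s))
  s <- optimize_quality(s, 0, 200)
  s <- subdivide_inplane(s)
  optimize_quality(s, 0.5, 200)
})

condyle_mesh <- function() fixture("condyle_mesh", function() {
  ph <- condyle_phantom()
  mesh_cartilage(ph$surfaces$cartilage, "femoral", ph$surfaces$bone)
})

# dense sphere surface (r = 20 mm) for bone remeshing
sphere20 <- function() fixture("sphere20", function()
  hexcart:::uv_ellipsoid(c(20, 20, 20), n_theta = 128, n_phi = 64,
                         asymmetry = 0))

atlas160 <- function() fixture("atlas160", function() make_template_atlas(160))

# hand-built flat sweep grid with a custom node validity mask: bone layer at
# z = 0, joint at z = 1, unit pitch; used to exercise the degenerate
# taxonomy deterministically
make_test_grid <- function(valid) {
  m <- nrow(valid); n <- ncol(valid)
  bh <- array(NA_real_, c(m, n, 3))
  jh <- array(NA_real_, c(m, n, 3))
  for (j in seq_len(n)) for (i in seq_len(m)) {
    bh[i, j, ] <- c(i, j, 0)
    jh[i, j, ] <- c(i, j, 1)
  }
  # a token surface for reprojection calls (large flat slabs)
  surf <- fixture("test_grid_surface", function() {
    v <- as.matrix(expand.grid(x = c(-50, 50), y = c(-50, 50),
                               z = c(0, 1)))
    tri_surface(v, rbind(c(1, 2, 4), c(1, 4, 3), c(5, 8, 6), c(5, 7, 8),
                         c(1, 6, 2), c(1, 5, 6), c(3, 4, 8), c(3, 8, 7),
                         c(1, 3, 7), c(1, 7, 5), c(2, 8, 4), c(2, 6, 8)))
  })
  g <- list(shape = c(m, n), bone_hits = bh, joint_hits = jh,
            valid = valid, strategy = "rect", site = "tibial", pitch = 1,
            surface = surf)
  class(g) <- "sweep_grid"
  g
}

# independent face-hash conformity audit (does not use check_conformity)
audit_conformity <- function(hexes) {
  fidx <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  keys <- character(0)
  for (r in seq_len(nrow(fidx)))
    keys <- c(keys, apply(hexes[, fidx[r, ], drop = FALSE], 1, function(f)
      paste(sort(f), collapse = "-")))
  all(table(keys) <= 2)
}

# brute-force scaled Jacobian oracle: explicit per-corner determinants via
# base R det(), independent of the package implementation
sj_oracle <- function(hex_nodes) {
  nxt <- c(2, 3, 4, 1); prv <- c(4, 1, 2, 3)
  vals <- numeric(8)
  for (i in 1:4) {
    x <- hex_nodes[i, ]
    u <- hex_nodes[nxt[i], ] - x
    v <- hex_nodes[prv[i], ] - x
    w <- hex_nodes[i + 4, ] - x
    J <- cbind(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)), w / sqrt(sum(w^2)))
    vals[i] <- det(J)
  }
  for (i in 1:4) {
    x <- hex_nodes[i + 4, ]
    u <- hex_nodes[prv[i] + 4, ] - x
    v <- hex_nodes[nxt[i] + 4, ] - x
    w <- hex_nodes[i, ] - x
    J <- cbind(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)), w / sqrt(sum(w^2)))
    vals[i + 4] <- det(J)
  }
  min(vals)
}

# brute-force morphological closing oracle: direct neighbourhood max / min
# over all kernel offsets (non-separable)
closing_oracle <- function(mask, width) {
  r <- (width - 1) %/% 2
  d <- dim(mask)
  p <- width
  big <- array(FALSE, d + 2L * p)
  big[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- mask
  dil <- array(FALSE, dim(big))
  for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
    sh <- hexcart:::shift_array(big, di, dj, dk)
    dil <- dil | sh
  }
  ero <- array(TRUE, dim(big))
  for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
    sh <- hexcart:::shift_array(dil, di, dj, dk)
    ero <- ero & sh
  }
  ero[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

# naive segment-through-triangle intersection oracle over two face sets
tri_intersects_oracle <- function(T1, T2) {
  seg_tri <- function(p, q, a, b, c) {
    d <- q - p
    n <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
           (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
           (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    den <- sum(n * d)
    if (abs(den) < 1e-14) return(FALSE)
    t <- sum(n * (a - p)) / den
    if (t <= 1e-7 || t >= 1 - 1e-7) return(FALSE)
    x <- p + t * d
    # barycentric inside test
    v0 <- b - a; v1 <- c - a; v2 <- x - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den2 <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / den2
    w <- (d00 * d21 - d01 * d20) / den2
    u > 1e-9 && w > 1e-9 && u + w < 1 - 1e-9
  }
  n1 <- nrow(T1) / 3; n2 <- nrow(T2) / 3
  count <- 0
  for (i in seq_len(n1)) {
    A <- T1[3 * i - 2, ]; B <- T1[3 * i - 1, ]; C <- T1[3 * i, ]
    for (j in seq_len(n2)) {
      a <- T2[3 * j - 2, ]; b <- T2[3 * j - 1, ]; c <- T2[3 * j, ]
      if (min(sapply(list(A, B, C), function(x)
        min(sum((x - a)^2), sum((x - b)^2), sum((x - c)^2)))) < 1e-16) next
      hit <- seg_tri(A, B, a, b, c) || seg_tri(B, C, a, b, c) ||
        seg_tri(C, A, a, b, c) ||
        seg_tri(a, b, A, B, C) || seg_tri(b, c, A, B, C) ||
        seg_tri(c, a, A, B, C)
      if (hit) count <- count + 1
    }
  }
  count
}
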