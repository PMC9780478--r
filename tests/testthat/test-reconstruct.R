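make_cube_volume <- function(n = 20, lo = 6, hi = 15) {
  codes <- array(0L, c(n, n, n))
  codes[lo:hi, lo:hi, lo:hi] <- 1L
  label_volume(codes, c(1, 1, 1), c(0, 0, 0), c(cube = 1L))
}

test_that("morphological closing matches a brute-force oracle", {
  vol <- make_cube_volume()
  # convex solid: closing is the identity
  closed <- close_labels(vol, 1L, "cartilage")
  expect_identical(closed$codes == 1L, vol$codes == 1L)
  # single interior void is filled
  holed <- vol
  holed$codes[10, 10, 10] <- 0L
  expect_true(close_labels(holed, 1L, "cartilage")$codes[10, 10, 10] == 1L)
  # 2-voxel slit: compare against the direct dilate-then-erode oracle
  slit <- vol
  slit$codes[10:11, 6:15, 6:15] <- 0L
  for (klass in c("cartilage", "bone")) {
    width <- if (klass == "cartilage") 5L else 3L
    got <- close_labels(slit, 1L, klass)$codes == 1L
    want <- closing_oracle(slit$codes == 1L, width)
    expect_identical(got, want)
  }
  # the 5-voxel cartilage kernel closes the slit in the interior
  expect_true(all(close_labels(slit, 1L, "cartilage")$codes[10:11, 8:13,
                                                            8:13] == 1L))
  expect_error(close_labels(vol, 99L, "cartilage"))
})

test_that("extract_surface produces closed surfaces at the right scale", {
  vol <- make_cube_volume()
  s <- extract_surface(vol, 1L)
  expect_true(is_watertight(s))
  expect_equal(euler_characteristic(s), 2)
  expect_gt(surface_volume(s), 0)

  n <- 25L
  g <- expand.grid(i = 0:24, j = 0:24, k = 0:24)
  mask <- array(sqrt((g$i - 12)^2 + (g$j - 12)^2 + (g$k - 12)^2) <= 8,
                c(n, n, n))
  sv <- label_volume(array(as.integer(mask), c(n, n, n)), c(1, 1, 1),
                     c(0, 0, 0), c(s = 1L))
  sph <- extract_surface(sv, 1L)
  expect_equal(surface_area(sph), 4 * pi * 64, tolerance = 0.05)

  # mask touching the volume boundary still yields a closed surface
  full <- label_volume(array(1L, c(8, 8, 8)), c(1, 1, 1))
  sb <- extract_surface(full, 1L)
  expect_true(is_watertight(sb))
  expect_error(extract_surface(vol, 7L), "absent")
})

test_that("keep_largest_component retains the max enclosed volume", {
  m <- array(0L, c(40, 25, 25))
  g <- expand.grid(i = 0:39, j = 0:24, k = 0:24)
  m[sqrt((g$i - 10)^2 + (g$j - 12)^2 + (g$k - 12)^2) <= 8] <- 1L
  m[sqrt((g$i - 30)^2 + (g$j - 12)^2 + (g$k - 12)^2) <= 4] <- 1L
  m[2:4, 2:4, 2:4] <- 1L # a third, small blob artifact
  s <- extract_surface(label_volume(m, c(1, 1, 1)), 1L)
  comp <- hexcart:::surface_components(s)
  expect_gte(max(comp), 3)
  # per-component signed-volume oracle
  vols <- vapply(seq_len(max(comp)), function(ci)
    surface_volume(tri_surface(s$vertices,
                               s$triangles[comp == ci, , drop = FALSE])),
    numeric(1))
  kept <- keep_largest_component(s)
  expect_equal(max(hexcart:::surface_components(kept)), 1)
  expect_equal(surface_volume(kept), max(vols), tolerance = 1e-9)
  # single component: identity
  expect_identical(keep_largest_component(kept)$triangles, kept$triangles)
})

test_that("simplify_smooth hits the decimation target and shrinks spheres", {
  n <- 25L
  g <- expand.grid(i = 0:24, j = 0:24, k = 0:24)
  mask <- array(sqrt((g$i - 12)^2 + (g$j - 12)^2 + (g$k - 12)^2) <= 8,
                c(n, n, n))
  sph <- extract_surface(label_volume(array(as.integer(mask), c(n, n, n)),
                                      c(1, 1, 1)), 1L)
  ss <- simplify_smooth(sph, 0.8, 0)
  expect_equal(nrow(ss$triangles), round(nrow(sph$triangles) * 0.2),
               tolerance = 0.02)
  expect_true(is_watertight(ss))
  # identity when both knobs are zero
  expect_identical(simplify_smooth(sph, 0, 0)$vertices, sph$vertices)
  # Laplacian shrinkage: mean radius decreases monotonically (unit
  # relaxation oracle on the analytic sphere)
  radii <- vapply(c(0, 3, 6, 9), function(it) {
    sm <- laplacian_smooth(ss, it, relaxation = 1)
    ctr <- colMeans(sm$vertices)
    mean(sqrt(rowSums(sweep(sm$vertices, 2, ctr)^2)))
  }, numeric(1))
  expect_true(all(diff(radii) < 0))
  expect_error(simplify_smooth(tri_surface(matrix(0, 3, 3),
                                           matrix(1:3, 1)), 0.8, 9),
               "fewer than 100")
})

test_that("repair_surface fixes orientation but preserves cartilage holes", {
  vol <- make_cube_volume()
  s <- extract_surface(vol, 1L)
  flipped <- s
  flipped$triangles[1:5, ] <- flipped$triangles[1:5, c(1, 3, 2)]
  r <- repair_surface(flipped, "bone_full")
  expect_gt(surface_volume(r), 0)
  expect_true(is_watertight(r))
  # watertight consistent surface: identity (up to no-op passes)
  r2 <- repair_surface(s, "bone_full")
  expect_equal(surface_volume(r2), surface_volume(s))

  # cartilage with a hole: boundary-edge count untouched
  holed <- hole_phantom()
  cs <- extract_surface(close_labels(holed$label_volume, "cartilage",
                                     "cartilage"), 1L)
  # puncture: remove one triangle to create a boundary
  open <- tri_surface(cs$vertices, cs$triangles[-1, ])
  before <- boundary_edge_count(open)
  rc <- repair_surface(open, "cartilage_normals_only")
  expect_equal(boundary_edge_count(rc), before)
})

test_that("full reconstruction stays within two voxel diagonals of truth", {
  lim <- 2 * sqrt(3) * 0.5
  for (ph in list(slab_phantom(), hole_phantom())) {
    cs <- reconstruct_tissue(ph$label_volume, "cartilage", "cartilage")
    expect_lt(hausdorff_distance(cs, ph$surfaces$cartilage), lim)
    expect_gt(surface_volume(cs), 0)
  }
  ph <- condyle_phantom()
  bs <- reconstruct_tissue(ph$label_volume, "bone", "bone")
  expect_true(is_watertight(bs))
  expect_lt(hausdorff_distance(bs, ph$surfaces$bone), lim)
})
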