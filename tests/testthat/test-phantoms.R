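test_that("flat slab phantom has the analytic voxel structure", {
  ph <- slab_phantom()
  m <- tissue_mask(ph$label_volume, "cartilage")
  expect_equal(sum(apply(m, 3, any)), 6) # 3 mm / 0.5 mm layers
  expect_equal(sum(m) * 0.5^3, 20 * 10 * 3)
  expect_true(is_watertight(ph$surfaces$cartilage))
  expect_true(is_watertight(ph$surfaces$bone))
  expect_equal(surface_volume(ph$surfaces$cartilage), 600, tolerance = 1e-9)
})

test_that("thickness below the resolvable limit is rejected", {
  expect_error(make_slab_phantom(thickness_mm = 0.8, voxel_spacing_mm = 0.5),
               "resolvable")
})

test_that("hole voxel count matches the analytic cylinder", {
  holed <- hole_phantom()
  # full slab with the same footprint for the voxel-count difference
  full12 <- fixture("slab12", function() make_slab_phantom(20, 12, 3))
  removed <- sum(tissue_mask(full12$label_volume, "cartilage")) -
    sum(tissue_mask(holed$label_volume, "cartilage"))
  analytic <- pi * 2^2 * 3 / 0.5^3
  # discretization error bounded by a one-voxel shell around the cylinder
  shell <- 2 * pi * 2 * 3 * 0.5 / 0.5^3
  expect_lt(abs(removed - analytic), shell)
  expect_true(is_watertight(holed$surfaces$cartilage))
})

test_that("curved slab reproduces circle-geometry sagittal height", {
  ph <- fixture("curved_slab", function()
    make_slab_phantom(20, 10, 3, curvature_radius_mm = 30))
  expected <- 30 - sqrt(30^2 - 10^2)
  expect_equal(ph$ground_truth$sagittal_height_mm, expected,
               tolerance = 1e-12)
  # cartilage z-range = thickness at the apex + sagittal drop at the edges
  # (the apex may fall between grid samples: allow half-pitch sag)
  cz <- ph$surfaces$cartilage$vertices[, 3]
  expect_equal(diff(range(cz)), 3 + expected, tolerance = 1e-3)
})

test_that("joint phantom styles have the promised structure", {
  phf <- condyle_phantom()
  # joint-side surface offset from bone by the thickness at the apex
  R <- phf$ground_truth$curvature_radius_mm
  V <- phf$surfaces$cartilage$vertices
  rho <- sqrt(V[, 1]^2 + (V[, 3] + R)^2)
  expect_equal(min(rho), R, tolerance = 1e-6)
  expect_equal(max(rho), R + phf$ground_truth$thickness_mm,
               tolerance = 1e-6)

  pht <- fixture("tibial_phantom", function() make_joint_phantom("tibial"))
  expect_setequal(names(pht$surfaces),
                  c("bone", "cartilage_medial", "cartilage_lateral"))
  expect_setequal(sort(unique(as.vector(pht$label_volume$codes))),
                  c(0L, 1L, 2L, 3L))

  php <- fixture("patellar_phantom", function()
    make_joint_phantom("patellar"))
  expect_true(is_watertight(php$surfaces$cartilage))
  comp <- hexcart:::surface_components(php$surfaces$cartilage)
  expect_equal(max(comp), 1)
})

test_that("ground-truth thickness is recoverable by ray probing", {
  ph <- slab_phantom()
  hits <- cast_rays(rbind(c(0, 0, 10)), rbind(c(0, 0, -1)),
                    ph$surfaces$cartilage)[[1]]
  expect_equal(length(hits), 2)
  expect_equal(diff(hits), 3, tolerance = 0.5)
})

test_that("template atlas sites are named, on-surface, and transform exactly", {
  at <- atlas160()
  expect_equal(nrow(at$sites), 160)
  expect_equal(anyDuplicated(at$sites$name), 0)
  d <- closest_point_on_surface(as.matrix(at$sites[, c("x", "y", "z")]),
                                at$femur_surface)$distance
  expect_lt(max(d), 1e-9)
  expect_equal(nrow(at$joint_axis_points), 2)

  th <- 0.4
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  tf <- similarity_transform(Rz, c(1, 2, 3), 1.25)
  moved <- transform_surface(at$femur_surface, tf$rotation, tf$translation,
                             tf$scale)
  expected <- apply_transform(tf, as.matrix(at$sites[, c("x", "y", "z")]))
  # sites are mesh vertices, so their transforms coincide with vertices of
  # the transformed surface
  mind <- vapply(seq_len(160), function(i)
    min(rowSums(sweep(moved$vertices, 2, expected[i, ])^2)), numeric(1))
  expect_lt(max(mind), 1e-18)
})

test_that("voxelize_surface matches analytic volumes and rejects open input", {
  cube <- tri_surface(
    as.matrix(expand.grid(0:1, 0:1, 0:1))[, c(1, 2, 3)],
    rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
          c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
          c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6)))
  lv <- voxelize_surface(cube, 0.1)
  expect_equal(sum(lv$codes) * 0.1^3, 1, tolerance = 0.07)

  sph <- hexcart:::uv_ellipsoid(c(5, 5, 5), 48, 24, asymmetry = 0)
  lv2 <- voxelize_surface(sph, 0.25)
  expect_equal(sum(lv2$codes) * 0.25^3, 4 / 3 * pi * 125, tolerance = 0.05)

  open <- tri_surface(cube$vertices, cube$triangles[-1, ])
  expect_error(voxelize_surface(open, 0.1), "not closed")
})

test_that("voxelize then extract round-trips within one voxel diagonal", {
  sph <- hexcart:::uv_ellipsoid(c(5, 5, 5), 48, 24, asymmetry = 0)
  lv <- voxelize_surface(sph, 0.25)
  back <- extract_surface(lv, 1L)
  expect_lt(hausdorff_distance(back, sph), sqrt(3) * 0.25)
})

test_that("phantoms are deterministic given parameters", {
  a <- make_slab_phantom(12, 8, 2.5)
  b <- make_slab_phantom(12, 8, 2.5)
  expect_identical(a$label_volume$codes, b$label_volume$codes)
  expect_identical(a$surfaces$cartilage$vertices,
                   b$surfaces$cartilage$vertices)
})
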