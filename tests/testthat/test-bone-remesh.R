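test_that("sphere remesh hits the target edge length and stays watertight", {
  sph <- sphere20()
  rm1 <- remesh_uniform(sph, 3, seed = 7)
  expect_true(is_watertight(rm1))
  expect_equal(max(hexcart:::surface_components(rm1)), 1)
  expect_equal(mean_edge_length(rm1), 3, tolerance = 0.2)
  # triangle count close to the equilateral-tiling estimate
  est <- surface_area(sph) / (sqrt(3) / 4 * 9)
  expect_equal(nrow(rm1$triangles), est, tolerance = 0.3)
  # volume preserved within 2% on smooth input
  expect_equal(surface_volume(rm1), surface_volume(sph), tolerance = 0.02)
})

test_that("remeshing is deterministic for a fixed seed", {
  sph <- sphere20()
  a <- remesh_uniform(sph, 3, seed = 11)
  b <- remesh_uniform(sph, 3, seed = 11)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
})

test_that("a target larger than the surface is rejected", {
  small <- hexcart:::uv_ellipsoid(c(4, 4, 4), 16, 8, asymmetry = 0)
  expect_error(remesh_uniform(small, 6), "too large")
})
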