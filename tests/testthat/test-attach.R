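test_that("similarity transforms compose and invert to high precision", {
  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE)
  tf <- similarity_transform(R, c(3, -1, 7), 1.3)
  set.seed(5)
  p <- matrix(rnorm(60, sd = 20), 20, 3)
  back <- apply_transform(invert_transform(tf), apply_transform(tf, p))
  expect_lt(max(abs(back - p)), 1e-8)
  expect_error(similarity_transform(diag(c(1, 1, -1))), "proper rotation")
  expect_error(similarity_transform(scale = -2))
})

test_that("ICP on identical meshes returns the identity", {
  at <- atlas160()
  tf <- register_icp(at$femur_surface, at$femur_surface)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tf$translation)), 1e-6)
  expect_lt(abs(tf$scale - 1), 1e-6)
  expect_lt(attr(tf, "residual"), 1e-6)
})

test_that("ICP recovers a known similarity transform within 1%", {
  at <- atlas160()
  th <- 25 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  known <- similarity_transform(Rz, c(5, -3, 2), 1.1)
  moved <- transform_surface(at$femur_surface, known$rotation,
                             known$translation, known$scale)
  rec <- register_icp(moved, at$femur_surface)
  inv <- invert_transform(known)
  expect_lt(abs(rec$scale - inv$scale) / inv$scale, 0.01)
  expect_lt(max(abs(rec$rotation - inv$rotation)), 0.01)
  expect_lt(max(abs(rec$translation - inv$translation)) /
              sqrt(sum(inv$translation^2)), 0.01)
  # residual sequence is non-increasing
  res <- attr(rec, "residuals")
  expect_true(all(diff(res) <= 1e-6))
})

test_that("attachment sites map exactly on the template itself", {
  at <- atlas160()
  m <- map_attachment_sites(similarity_transform(), at,
                            list(femur = at$femur_surface))
  expect_equal(nrow(m), 162) # 160 sites + 2 joint-axis landmarks
  expect_equal(sum(grepl("^site_", m$name)), 160)
  got <- as.matrix(m[1:160, c("x", "y", "z")])
  expect_equal(unname(got), unname(as.matrix(at$sites[, c("x", "y", "z")])),
               tolerance = 1e-12)
})

test_that("sites on a transformed subject map within mesh resolution", {
  at <- atlas160()
  th <- 0.3
  Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
               3, 3, byrow = TRUE)
  known <- similarity_transform(Ry, c(-4, 6, 1), 0.95)
  moved <- transform_surface(at$femur_surface, known$rotation,
                             known$translation, known$scale)
  rec <- register_icp(moved, at$femur_surface)
  m <- map_attachment_sites(rec, at, list(femur = moved))
  fwd <- apply_transform(known, as.matrix(at$sites[, c("x", "y", "z")]))
  err <- sqrt(rowSums((as.matrix(m[1:160, c("x", "y", "z")]) - fwd)^2))
  expect_lt(max(err), mean_edge_length(at$femur_surface))
  expect_lt(median(err), 1e-6) # vertex sites match vertex-for-vertex
  expect_error(map_attachment_sites(rec, at, list(
    femur = tri_surface(matrix(0, 0, 3), matrix(0L, 0, 3)))), "empty")
})

test_that("mapping is deterministic with lowest-node-id tie-breaks", {
  at <- atlas160()
  a <- map_attachment_sites(similarity_transform(), at,
                            list(femur = at$femur_surface))
  b <- map_attachment_sites(similarity_transform(), at,
                            list(femur = at$femur_surface))
  expect_identical(a, b)
  # explicit tie: two coincident candidate nodes -> lowest id wins
  dup <- at$femur_surface
  dup$vertices <- rbind(dup$vertices, dup$vertices[m_id <- 10, ])
  dup$triangles <- rbind(dup$triangles,
                         c(nrow(dup$vertices), 1, 2)) # keep it referenced
  atlas1 <- at
  atlas1$sites <- at$sites[at$sites$x == at$femur_surface$vertices[m_id, 1] &
                             at$sites$y == at$femur_surface$vertices[m_id, 2],
                           , drop = FALSE]
  if (nrow(atlas1$sites) > 0) {
    mm <- map_attachment_sites(similarity_transform(), atlas1,
                               list(femur = dup))
    expect_true(all(mm$node_id[seq_len(nrow(atlas1$sites))] == m_id))
  }
})
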