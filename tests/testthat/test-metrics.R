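unit_cube_nodes <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
        c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
}

test_that("scaled Jacobian matches the corner-determinant oracle", {
  cube <- unit_cube_nodes()
  expect_equal(scaled_jacobian(cube), 1.0, tolerance = 1e-12)
  # swapping two corners inverts the element
  inv <- cube
  inv[c(1, 2), ] <- inv[c(2, 1), ]
  expect_lt(scaled_jacobian(inv), 0)
  # sheared cubes agree with the brute-force oracle to 1e-10
  for (theta in c(5, 20, 45, 70) * pi / 180) {
    S <- diag(3); S[1, 3] <- tan(theta)
    sheared <- cube %*% t(S)
    expect_equal(scaled_jacobian(sheared), sj_oracle(sheared),
                 tolerance = 1e-10)
  }
  # random perturbed elements, fixed seed
  set.seed(42)
  for (k in 1:10) {
    h <- cube + matrix(rnorm(24, sd = 0.2), 8, 3)
    expect_equal(scaled_jacobian(h), sj_oracle(h), tolerance = 1e-10)
  }
})

test_that("scaled Jacobian is invariant to rigid motion and uniform scale", {
  set.seed(7)
  cube <- unit_cube_nodes() + matrix(rnorm(24, sd = 0.1), 8, 3)
  base <- scaled_jacobian(cube)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  moved <- 2.5 * cube %*% t(R) + matrix(c(10, -4, 2), 8, 3, byrow = TRUE)
  expect_equal(scaled_jacobian(moved), base, tolerance = 1e-12)
})

test_that("feature angles follow the deviation-from-flat convention", {
  # two quads meeting along a shared edge at a controlled fold
  mk <- function(fold_deg) {
    a <- fold_deg * pi / 180
    list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                          c(1 + cos(a), 0, sin(a)), c(1 + cos(a), 1, sin(a))),
         faces = rbind(c(1, 2, 3, 4), c(2, 5, 6, 3)))
  }
  expect_equal(feature_angle(mk(0), c(2, 3)), 0, tolerance = 1e-9)
  expect_equal(feature_angle(mk(90), c(2, 3)), 90, tolerance = 1e-9)
  expect_equal(feature_angle(mk(45), c(2, 3)), 45, tolerance = 1e-9)
  expect_error(feature_angle(mk(45), c(1, 3)), "exactly 2")
})

flat_strip <- function(xs, ys = c(0, 1, 2), z = 0) {
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, z)
  nx <- length(xs)
  tris <- list()
  for (j in seq_len(length(ys) - 1)) for (i in seq_len(nx - 1)) {
    a <- (j - 1) * nx + i
    tris[[length(tris) + 1]] <- c(a, a + 1, a + nx + 1)
    tris[[length(tris) + 1]] <- c(a, a + nx + 1, a + nx)
  }
  tri_surface(V, do.call(rbind, tris))
}

test_that("surface deviation is exact on offset slabs", {
  a <- flat_strip(seq(0, 10, 0.5))
  b <- flat_strip(seq(0, 10, 0.5), z = 0.5)
  rep <- surface_deviation(a, b)
  expect_equal(rep$coverage, 100)
  expect_equal(unname(rep$summary["median"]), 0.5, tolerance = 1e-9)
  expect_equal(max(rep$distance), 0.5, tolerance = 1e-9)
  # identical surfaces: all zero
  rep0 <- surface_deviation(a, a)
  expect_equal(max(rep0$distance), 0)
  expect_equal(rep0$coverage, 100)
})

test_that("rays beyond the normal cutoff are excluded from coverage", {
  # reference plane at z = 1 covering x >= 5: nodes left of x = 5 see the
  # reference edge, at a known angle from their +z normal
  ref <- flat_strip(seq(5, 15, 0.5), z = 1)
  x25 <- 5 - tan(25 * pi / 180) # nearest point at 25 deg off-normal
  x15 <- 5 - tan(15 * pi / 180) # 15 deg off-normal
  pred <- flat_strip(c(x25 - 2, x25 - 1, x25, x15, 6, 7))
  rep <- surface_deviation(pred, ref, max_normal_dev_deg = 20)
  v <- pred$vertices
  expect_false(any(rep$included[abs(v[, 1] - x25) < 1e-9]))
  expect_true(all(rep$included[abs(v[, 1] - x15) < 1e-9]))
  expect_true(all(rep$included[v[, 1] > 5]))
})

test_that("deviation KDE integrates to one", {
  set.seed(3)
  a <- flat_strip(seq(0, 10, 0.25))
  b <- flat_strip(seq(0, 10, 0.25), z = 0.4)
  b$vertices[, 3] <- b$vertices[, 3] + runif(nrow(b$vertices), 0, 0.2)
  rep <- surface_deviation(a, b)
  k <- rep$kde
  expect_false(is.null(k))
  area <- sum(diff(k$x) * (head(k$y, -1) + tail(k$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
})

test_that("Dice coefficient matches voxel-count closed forms", {
  n <- 20L
  a <- array(0L, c(n, n, n)); a[1:10, 1:10, 1:10] <- 1L
  va <- label_volume(a, c(1, 1, 1))
  expect_equal(dice_coefficient(va, va, 1L), 1.0)
  b <- array(0L, c(n, n, n)); b[11:20, 1:10, 1:10] <- 1L
  vb <- label_volume(b, c(1, 1, 1))
  expect_equal(dice_coefficient(va, vb, 1L), 0.0)
  # 10^3 cube shifted by 5 voxels: 2 * 500 / 2000
  cshift <- array(0L, c(n, n, n)); cshift[6:15, 1:10, 1:10] <- 1L
  vc <- label_volume(cshift, c(1, 1, 1))
  expect_equal(dice_coefficient(va, vc, 1L), 0.5)
  expect_error(dice_coefficient(va, label_volume(array(0L, c(2, 2, 2)),
                                                 c(1, 1, 1))), "same grid")
})

test_that("min-max RMS matches the closed form and normalization rules", {
  x <- sin(seq(0, 2 * pi, length.out = 50)) * 4 + 10
  expect_equal(minmax_rms(x, x), list(rms = 0, rms_percent_of_range = 0))
  off <- minmax_rms(x, x + 1.5)
  expect_equal(off$rms, 1.5, tolerance = 1e-12)
  expect_equal(off$rms_percent_of_range, 100 * 1.5 / diff(range(x)),
               tolerance = 1e-12)
  # percentage invariant to a common affine rescaling
  aff <- minmax_rms(3 * x + 7, 3 * (x + 1.5) + 7)
  expect_equal(aff$rms_percent_of_range, off$rms_percent_of_range,
               tolerance = 1e-9)
})
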