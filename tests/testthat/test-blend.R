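test_that("blend displacements split the depth 80/20 at a 45-degree slope", {
  sheet <- slab_sheet()
  disp <- init_blend_displacements(sheet)
  t <- 3 # slab thickness: local depth at every edge column
  expect_equal(unname(sqrt(rowSums(disp$bone_vec^2))),
               rep(0.8 * t, length(disp$bone_ids)), tolerance = 1e-6)
  expect_equal(unname(sqrt(rowSums(disp$joint_vec^2))),
               rep(0.2 * t, length(disp$joint_ids)), tolerance = 1e-6)
  # resulting profile: horizontal run equals depth -> 45 degrees
  run <- sqrt(rowSums((disp$bone_vec - disp$joint_vec)^2))
  slope <- atan(disp$depth / run) * 180 / pi
  expect_equal(unname(slope), rep(45, length(run)), tolerance = 1)
  # bone-side stretches outward, joint-side compresses inward
  expect_lt(max(rowSums(disp$bone_vec * disp$joint_vec)), 0)
})

test_that("bone fusion lands displaced nodes on the bone surface", {
  sheet <- slab_sheet()
  ph <- slab_phantom()
  disp <- init_blend_displacements(sheet, ph$surfaces$bone)
  target <- sheet$nodes[disp$bone_ids, ] + disp$bone_vec
  d <- closest_point_on_surface(target, ph$surfaces$bone)$distance
  expect_lt(max(d), 1e-3)
  expect_true(all(disp$fused))
})

test_that("feature-angle enforcement relaxes in 10% increments, monotonically", {
  sheet <- slab_sheet()
  disp <- init_blend_displacements(sheet)
  # compliant at 45 degrees: no reduction
  out <- enforce_min_feature_angle(sheet, disp, 35)
  expect_equal(out$bone_factor, disp$bone_factor)
  # engineered violation: triple the bone-side run so the ramp flattens
  shallow <- disp
  shallow$bone_vec <- disp$bone_vec * 3
  out2 <- enforce_min_feature_angle(sheet, shallow, 35)
  expect_true(any(out2$bone_factor < 1))
  # factors move in multiples of 0.9
  f <- unique(round(out2$bone_factor, 10))
  k <- log(f) / log(0.9)
  expect_equal(k, round(k), tolerance = 1e-6)
  # final configuration complies (dihedral oracle over the blended rim)
  nodes <- hexcart:::apply_blend(sheet, out2)
  ja <- hexcart:::joint_rim_angles(sheet, nodes)
  expect_gte(min(ja$angles), 35 - 1e-6)
  # monotone non-increasing relative to the initial factors
  expect_true(all(out2$bone_factor <= shallow$bone_factor + 1e-12))
})

test_that("Savitzky-Golay filtering preserves cubics exactly", {
  s <- seq(0, 2 * pi, length.out = 40)
  P <- cbind(0.5 * s^3 - s^2 + 2 * s, s^3, 1 + s - 0.2 * s^3)
  sm <- hexcart:::sg_smooth_loop(P, degree = 3, window = 7)
  # interior samples (away from the periodic seam) are reproduced exactly
  interior <- 5:35
  expect_equal(sm[interior, ], P[interior, ], tolerance = 1e-8)
})

test_that("intersection resolution relaxes by 10% and ends intersection-free", {
  ph <- fixture("blend_hole", function()
    make_slab_phantom(20, 12, 3,
                      hole_specs = list(list(center = c(0, 0), radius = 2.5))))
  g <- make_sweep_grid(ph$surfaces$cartilage, "tibial", 1.0,
                       strategy = "rect")
  s <- build_hex_sheet(g)
  s <- repair_degenerates(s, classify_degenerates(s))
  s <- optimize_quality(s, 0, 200)
  s <- subdivide_inplane(s)
  s <- optimize_quality(s, 0.5, 200)
  disp <- init_blend_displacements(s)
  # exaggerate the displacement so hole-edge elements must collide
  disp$bone_vec <- disp$bone_vec * 4
  disp$joint_vec <- disp$joint_vec * 4
  out <- resolve_intersections(s, disp)
  # relaxation level is a power of 0.9
  k <- log(out$relaxation_level) / log(0.9)
  expect_equal(k, round(k), tolerance = 1e-9)
  # independent triangle-triangle oracle sees no crossings
  T <- hexcart:::edge_element_face_triangles(s, out$smoothed_nodes)
  expect_equal(tri_intersects_oracle(T, T) / 2, 0)
})

test_that("front smoothing schedule halves per advance and is capped", {
  sched <- front_iteration_schedule(400, 100, n_advances = 4)
  expect_equal(sched[1], ceiling(550 * 400 / 300))
  for (k in 2:4) expect_equal(sched[k], ceiling(sched[k - 1] / 2))
  expect_equal(front_iteration_schedule(1000, 999, 1, cap = 2000L)[1], 2000)
})

test_that("blending changes geometry but never connectivity, within 5 layers", {
  ph <- fixture("wide_slab", function() make_slab_phantom(30, 20, 3))
  g <- make_sweep_grid(ph$surfaces$cartilage, "tibial", 1.0,
                       strategy = "rect")
  s <- build_hex_sheet(g)
  s <- repair_degenerates(s, classify_degenerates(s))
  s <- optimize_quality(s, 0, 200)
  s <- subdivide_inplane(s)
  s <- optimize_quality(s, 0.5, 200)
  blended <- blend_cartilage(s, ph$surfaces$bone)
  expect_equal(nrow(blended$nodes), nrow(s$nodes))
  expect_equal(blended$hexes, s$hexes)
  expect_equal(blended$provenance$fusion, "full")
  # edge nodes moved, deep interior nodes did not: nodes on faces deeper
  # than five element layers from the edge stay put
  edge_nodes <- which(s$edge_node_flags)
  bdepth <- hexcart:::quad_face_depth(s$bone_quads, edge_nodes)
  deep_faces <- which(!is.na(bdepth) & bdepth > 5)
  deep_nodes <- setdiff(unique(as.vector(s$bone_quads[deep_faces, ])),
                        unique(as.vector(
                          s$bone_quads[which(bdepth <= 5), ])))
  expect_gt(length(deep_nodes), 0)
  expect_equal(blended$nodes[deep_nodes, ], s$nodes[deep_nodes, ],
               tolerance = 1e-12)
  # quality floors: interior > 0.5, blended edge layer > 0
  sj <- scaled_jacobian_all(blended$nodes, blended$hexes)
  edge_el <- apply(matrix(blended$hexes %in% edge_nodes,
                          nrow(blended$hexes)), 1, any)
  expect_gt(min(sj[edge_el]), 0)
  expect_gt(min(sj[!edge_el]), 0.5)
})

test_that("the blended slab edge ramps monotonically with no overhang", {
  sheet <- slab_sheet()
  ph <- slab_phantom()
  blended <- blend_cartilage(sheet, ph$surfaces$bone)
  ns <- blended$n_surface_nodes
  edge_b <- which(blended$edge_node_flags[seq_len(ns)])
  for (k in edge_b) {
    b <- blended$nodes[k, ]; j <- blended$nodes[k + ns, ]
    # bone-side edge node sits farther from the slab centre than the
    # joint-side node (outward ramp, no overhang)
    expect_gte(sqrt(sum(b[1:2]^2)), sqrt(sum(j[1:2]^2)) - 1e-9)
    # and below it in depth
    expect_lt(b[3], j[3])
  }
})

test_that("edge node constraints hold during graduated smoothing", {
  sheet <- slab_sheet()
  disp <- init_blend_displacements(sheet)
  disp <- resolve_intersections(sheet, disp)
  moved <- hexcart:::sheet_apply_nodes(sheet, disp$smoothed_nodes)
  sm <- graduated_front_smoothing(moved)
  edge_nodes <- which(moved$edge_node_flags)
  expect_equal(sm$nodes[edge_nodes, ], moved$nodes[edge_nodes, ],
               tolerance = 1e-12)
})
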