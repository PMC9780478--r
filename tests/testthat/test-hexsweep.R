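test_that("rectilinear sweep grid covers a flat slab at the grid pitch", {
  ph <- slab_phantom()
  g <- make_sweep_grid(ph$surfaces$cartilage, "tibial", 1.0,
                       strategy = "rect")
  expect_true(all(g$valid))
  # hit spacing equals the grid pitch (2 x target before subdivision)
  bx <- g$bone_hits[, 1, 1]
  expect_equal(diff(bx), rep(diff(bx)[1], length(bx) - 1), tolerance = 1e-6)
  expect_equal(mean(diff(bx)), 2, tolerance = 0.1)
  # paired rays: bone and joint hits exist exactly where valid
  expect_false(any(is.na(g$bone_hits[, , 1][g$valid])))
  expect_false(any(is.na(g$joint_hits[, , 1][g$valid])))
  expect_equal(is.na(g$bone_hits[, , 1]), is.na(g$joint_hits[, , 1]))
})

test_that("a central hole invalidates exactly its footprint", {
  ph <- hole_phantom()
  g <- make_sweep_grid(ph$surfaces$cartilage, "tibial", 1.0,
                       strategy = "rect")
  # independent ray oracle: nodes are invalid iff the vertical line at the
  # node misses the cartilage (inside the hole footprint)
  m <- g$shape[1]; n <- g$shape[2]
  for (j in seq_len(n)) for (i in seq_len(m)) {
    # reconstruct the planar position of this ray from neighbouring hits
    p <- if (g$valid[i, j]) g$bone_hits[i, j, 1:2] else NA
    if (!g$valid[i, j]) next
    r <- sqrt(sum(p^2))
    expect_true(r > 2 - 0.75 || r < 2) # never deep inside the hole disc
  }
  inv <- which(!g$valid, arr.ind = TRUE)
  expect_gt(nrow(inv), 0)
})

test_that("hex sheets have the promised counts and orientation", {
  ph <- slab_phantom()
  g <- make_sweep_grid(ph$surfaces$cartilage, "tibial", 1.0,
                       strategy = "rect")
  sheet <- build_hex_sheet(g)
  m <- g$shape[1]; n <- g$shape[2]
  expect_equal(nrow(sheet$hexes), (m - 1) * (n - 1))
  expect_equal(nrow(sheet$nodes), 2 * sum(g$valid))
  expect_true(all(scaled_jacobian_all(sheet$nodes, sheet$hexes) > 0))
  expect_true(audit_conformity(sheet$hexes))
})

test_that("boundary notches produce six-node degenerate elements", {
  valid <- matrix(TRUE, 6, 6)
  valid[3, 1] <- FALSE # notch on the border
  sheet <- build_hex_sheet(make_test_grid(valid))
  expect_gte(sum(sheet$degenerate), 1)
  deg <- sheet$hexes[sheet$degenerate, , drop = FALSE]
  expect_true(all(apply(deg, 1, function(h) length(unique(h)) == 6)))
})

test_that("degenerate taxonomy matches the documented patch table", {
  klass_at <- function(valid) {
    sheet <- build_hex_sheet(make_test_grid(valid))
    recs <- classify_degenerates(sheet)
    list(recs = recs, sheet = sheet)
  }
  # peak: lone invalid grid corner
  v <- matrix(TRUE, 5, 5); v[1, 1] <- FALSE
  r <- klass_at(v)$recs
  expect_equal(length(r), 1)
  expect_equal(r[[1]]$klass, "peak")
  expect_equal(length(r[[1]]$element_ids), 1)

  # step: invalid node on a border edge -> two elements, shared indices
  v <- matrix(TRUE, 5, 5); v[3, 1] <- FALSE
  r <- klass_at(v)$recs
  expect_equal(length(r), 1)
  expect_equal(r[[1]]$klass, "step")
  expect_equal(length(r[[1]]$element_ids), 2)
  expect_equal(r[[1]]$shared_topological_indices, c(3, 1))

  # stair: diagonal invalid pair -> three elements at each node
  v <- matrix(TRUE, 6, 6); v[3, 3] <- FALSE; v[4, 4] <- FALSE
  r <- klass_at(v)$recs
  expect_setequal(vapply(r, `[[`, character(1), "klass"),
                  c("stair", "stair"))
  expect_true(all(vapply(r, function(x) length(x$element_ids),
                         integer(1)) == 3))

  # mirror: diagonal invalid run of three -> middle node sees two diagonal
  # elements
  v <- matrix(TRUE, 7, 7)
  v[3, 3] <- FALSE; v[4, 4] <- FALSE; v[5, 5] <- FALSE
  r <- klass_at(v)$recs
  expect_true("mirror" %in% vapply(r, `[[`, character(1), "klass"))

  # corner: interior 2x2 hole -> four single-element internal corners
  v <- matrix(TRUE, 7, 7)
  v[4:5, 4:5] <- FALSE
  r <- klass_at(v)$recs
  expect_equal(sort(vapply(r, `[[`, character(1), "klass")),
               rep("corner", 4))
})

test_that("repair eliminates degenerates and is idempotent", {
  cases <- list(
    peak = { v <- matrix(TRUE, 5, 5); v[1, 1] <- FALSE; v },
    step = { v <- matrix(TRUE, 5, 5); v[3, 1] <- FALSE; v },
    stair = { v <- matrix(TRUE, 6, 6); v[3, 3] <- FALSE; v[4, 4] <- FALSE; v },
    corner = { v <- matrix(TRUE, 7, 7); v[4:5, 4:5] <- FALSE; v })
  for (nm in names(cases)) {
    sheet <- build_hex_sheet(make_test_grid(cases[[nm]]))
    n_el <- nrow(sheet$hexes)
    recs <- classify_degenerates(sheet)
    rep1 <- repair_degenerates(sheet, recs)
    expect_equal(sum(rep1$degenerate), 0, info = nm)
    expect_length(classify_degenerates(rep1), 0)
    expect_true(all(apply(rep1$hexes, 1, function(h)
      length(unique(h)) == 8)), info = nm)
    expect_true(audit_conformity(rep1$hexes), info = nm)
    if (nm == "peak") expect_equal(nrow(rep1$hexes), n_el - 1)
    # idempotent
    rep2 <- repair_degenerates(rep1, classify_degenerates(rep1))
    expect_equal(rep2$hexes, rep1$hexes, info = nm)
  }
  # clean sheet: classification empty, repair is the identity
  clean <- build_hex_sheet(make_test_grid(matrix(TRUE, 4, 4)))
  expect_length(classify_degenerates(clean), 0)
  expect_equal(repair_degenerates(clean, list())$hexes, clean$hexes)
})

test_that("quality optimization untangles and never hangs", {
  sheet <- slab_sheet()
  sj0 <- scaled_jacobian_all(sheet$nodes, sheet$hexes)
  # already-compliant: unchanged
  opt <- optimize_quality(sheet, 0, 50)
  expect_equal(opt$nodes, sheet$nodes, tolerance = 1e-12)
  # manually invert one interior node
  bad <- sheet
  ns <- bad$n_surface_nodes
  interior <- setdiff(seq_len(ns), which(bad$edge_node_flags[seq_len(ns)]))
  nd <- interior[which.min(rowSums(bad$nodes[interior, 1:2]^2))]
  nodes <- bad$nodes
  nodes[nd, 3] <- nodes[nd + ns, 3] + 1 # bone node above the joint node
  bad <- hexcart:::sheet_apply_nodes(bad, nodes)
  expect_lt(min(scaled_jacobian_all(bad$nodes, bad$hexes)), 0)
  fixed <- optimize_quality(bad, 0, 200)
  expect_gte(min(scaled_jacobian_all(fixed$nodes, fixed$hexes)), 0)
  # unreachable target terminates with an error, not a hang: a uniformly
  # sheared slab keeps its shear under neighbourhood averaging
  sheared <- sheet
  nodes_s <- sheared$nodes
  nodes_s[, 1] <- nodes_s[, 1] + 0.9 * nodes_s[, 3]
  sheared <- hexcart:::sheet_apply_nodes(sheared, nodes_s)
  expect_lt(min(scaled_jacobian_all(sheared$nodes, sheared$hexes)), 0.8)
  expect_error(optimize_quality(sheared, 0.99, 5),
               class = "hexcart_optimize_failure")
})

test_that("in-plane subdivision quadruples elements and preserves corners", {
  ph <- slab_phantom()
  g <- make_sweep_grid(ph$surfaces$cartilage, "tibial", 1.0,
                       strategy = "rect")
  s <- build_hex_sheet(g)
  s <- repair_degenerates(s, classify_degenerates(s))
  s2 <- subdivide_inplane(s)
  expect_equal(nrow(s2$hexes), 4 * nrow(s$hexes))
  # original corner node coordinates survive exactly
  orig <- round(s$nodes, 9)
  new <- round(s2$nodes, 9)
  key_o <- apply(orig, 1, paste, collapse = ",")
  key_n <- apply(new, 1, paste, collapse = ",")
  expect_true(all(key_o %in% key_n))
  expect_true(audit_conformity(s2$hexes))
})

test_that("depth subdivision gives linearly spaced layers", {
  sheet <- slab_sheet()
  m1 <- subdivide_depth(sheet, 1)
  expect_equal(nrow(m1$hexes), nrow(sheet$hexes))
  expect_equal(nrow(m1$nodes), nrow(sheet$nodes))
  m4 <- subdivide_depth(sheet, 4)
  expect_equal(nrow(m4$hexes), 4 * nrow(sheet$hexes))
  expect_equal(nrow(m4$nodes), sheet$n_surface_nodes * 5)
  # uniform slab: each layer is t/4 thick
  z <- sort(unique(round(m4$nodes[, 3], 6)))
  expect_equal(z, seq(0, 3, by = 0.75), tolerance = 1e-6)
  expect_true(audit_conformity(m4$hexes))
})

test_that("meshing a slab phantom needs no fallbacks", {
  ph <- slab_phantom()
  mesh <- mesh_cartilage(ph$surfaces$cartilage, "tibial",
                         ph$surfaces$bone)
  expect_length(mesh$provenance$fallbacks, 0)
  expect_equal(mesh$layer_count, 4)
  expect_true(check_conformity(mesh)$conforming)
  # no duplicate nodes within 1e-6 mm
  key <- apply(round(mesh$nodes / 1e-6), 1, paste, collapse = ",")
  expect_equal(anyDuplicated(key), 0)
})

test_that("an edge hole on the tibial interior grid triggers the fallback", {
  ph <- fixture("tibial_edge_hole", function()
    make_joint_phantom("tibial",
                       hole_specs = list(list(center = c(-9.9, 0),
                                              radius = 2))))
  mesh <- mesh_cartilage(ph$surfaces$cartilage_medial, "tibial",
                         ph$surfaces$bone)
  expect_true("simplified_grid" %in% mesh$provenance$fallbacks)
  expect_true(check_conformity(mesh)$conforming)
})

test_that("the condyle mesh meets the final quality gates", {
  mesh <- condyle_mesh()
  sj <- scaled_jacobian_all(mesh$nodes, mesh$hexes)
  edge_el <- apply(matrix(mesh$hexes %in% which(mesh$edge_node_flags),
                          nrow(mesh$hexes)), 1, any)
  expect_gt(min(sj[edge_el]), 0)
  expect_gte(min(sj[!edge_el]), 0.5 - 1e-9)
  expect_equal(mean_inplane_edge_length(mesh), 1, tolerance = 0.25)
  expect_true(check_conformity(mesh)$conforming)
})

test_that("cartilage meshing is deterministic", {
  ph <- slab_phantom()
  a <- mesh_cartilage(ph$surfaces$cartilage, "tibial", ph$surfaces$bone)
  b <- mesh_cartilage(ph$surfaces$cartilage, "tibial", ph$surfaces$bone)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$hexes, b$hexes)
})
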