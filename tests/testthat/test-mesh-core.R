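test_that("facet geometry matches closed forms", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  g <- compute_geometry(m)
  expect_equal(g$areas, 0.5)
  expect_equal(as.numeric(g$normals), c(0, 0, 1))
  expect_equal(as.numeric(g$centroids), c(1/3, 1/3, 0))

  ## uniform scaling: areas by s^2, edges by s
  s <- 2.5
  g2 <- compute_geometry(surface_mesh(m$vertices * s, m$faces))
  expect_equal(g2$areas, g$areas * s^2)
  expect_equal(g2$avg_edge, g$avg_edge * s)

  ## degenerate facet is rejected with its index
  bad <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      rbind(c(1, 2, 3)))
  expect_error(compute_geometry(bad), "facet at index 1")
})

test_that("fine icosphere area approaches the analytic sphere area", {
  g <- compute_geometry(icosphere(1, 18))
  expect_lt(abs(sum(g$areas) - 4 * pi) / (4 * pi), 0.001)
})

test_that("icosphere is watertight, outward, with 20 k^2 facets at exact radius", {
  for (k in c(1, 3, 8)) {
    m <- icosphere(0.08, k, center = c(0.01, -0.02, 0.005))
    expect_equal(nrow(m$faces), 20L * k^2)
    expect_true(check_watertight(m)$watertight)
    expect_gt(signed_volume(m), 0)
    r <- sqrt(rowSums(sweep(m$vertices, 2, c(0.01, -0.02, 0.005))^2))
    expect_equal(r, rep(0.08, length(r)), tolerance = 1e-12)
  }
})

test_that("watertight audit flags boundary edges of an open mesh", {
  m <- icosphere(1, 2)
  expect_true(check_watertight(m)$watertight)
  open <- surface_mesh(m$vertices, m$faces[-1, ])
  audit <- check_watertight(open)
  expect_false(audit$watertight)
  expect_equal(nrow(audit$boundary_edges), 3L)
})

test_that("4:1 subdivision conserves area exactly and splits into quarters", {
  m <- icosphere(1, 3)
  g0 <- compute_geometry(m)
  rr <- subdivide_4to1(m, 7L)
  g1 <- compute_geometry(rr$mesh)
  ## one split facet: +3 facets; three border bisections: +3
  expect_equal(nrow(rr$mesh$faces), nrow(m$faces) + 6L)
  expect_equal(sum(g1$areas), sum(g0$areas), tolerance = 1e-14)
  kids <- which(rr$parent == 7L)
  expect_length(kids, 4L)
  expect_equal(g1$areas[kids], rep(g0$areas[7] / 4, 4), tolerance = 1e-14)
  expect_true(check_watertight(rr$mesh)$watertight)
  expect_gt(signed_volume(rr$mesh), 0)
})

test_that("subdivision stays watertight and area-exact for random selections", {
  set.seed(42)
  m <- icosphere(1, 4)
  a0 <- sum(compute_geometry(m)$areas)
  for (rep in 1:5) {
    sel <- sample(nrow(m$faces), sample(1:60, 1))
    rr <- subdivide_4to1(m, sel)
    expect_true(check_watertight(rr$mesh)$watertight)
    expect_equal(sum(compute_geometry(rr$mesh)$areas), a0, tolerance = 1e-13)
    expect_gt(signed_volume(rr$mesh), 0)
    ## vertex growth equals the number of distinct split edges
    expect_equal(nrow(rr$mesh$vertices) - nrow(m$vertices),
                 length(rr$new_vertices))
    ## parent map is total and consistent
    expect_true(all(rr$parent %in% seq_len(nrow(m$faces))))
  }
})

test_that("empty selection and full selection behave", {
  m <- icosphere(1, 2)
  rr <- subdivide_4to1(m, integer(0))
  expect_identical(rr$mesh$faces, m$faces)
  rr4 <- subdivide_4to1(m, seq_len(nrow(m$faces)))
  expect_equal(nrow(rr4$mesh$faces), 4L * nrow(m$faces))
})

test_that("Taubin smoothing is identity at 0 passes and keeps planar patches planar", {
  m <- icosphere(1, 3)
  expect_identical(taubin_smooth(m, 1:5, passes = 0), m)
  expect_error(taubin_smooth(m, 1:5, shrink_factor = 0.62),
               "inflate > 0")
  ## new vertices with fully coplanar neighborhoods stay in the plane:
  ## refine the cube uniformly twice, then split a facet in the interior of
  ## the z = 0 face (all its new midpoints are interior to that face)
  cm <- cube_mesh()
  for (i in 1:2) cm <- subdivide_4to1(cm, seq_len(nrow(cm$faces)))$mesh
  onface <- which(apply(cm$faces, 1, function(f)
    all(cm$vertices[f, 3] == 0)))
  ctrs <- compute_geometry(cm)$centroids[onface, , drop = FALSE]
  pick <- onface[which.min((ctrs[, 1] - 0.5)^2 + (ctrs[, 2] - 0.5)^2)]
  rr <- subdivide_4to1(cm, pick)
  sm <- taubin_smooth(rr$mesh, rr$new_vertices, passes = 3)
  expect_equal(max(abs(sm$vertices[rr$new_vertices, 3])), 0,
               tolerance = 1e-12)
})

test_that("refine + smooth cycles keep sphere vertex radii near nominal", {
  m <- icosphere(0.08, 4)
  set.seed(7)
  for (cycle in 1:4) {
    sel <- sample(nrow(m$faces), 40)
    rr <- subdivide_4to1(m, sel)
    m <- taubin_smooth(rr$mesh, rr$new_vertices, passes = 1)
  }
  r <- sqrt(rowSums(m$vertices^2))
  expect_lt(abs(mean(r) - 0.08) / 0.08, 0.01)
  expect_true(check_watertight(m)$watertight)
})
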