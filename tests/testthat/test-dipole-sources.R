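test_that("primary potential and fields match dipole closed forms", {
  sig <- 0.3
  m <- c(0, 0, 2e-9)
  dip <- dipole_set(c(0, 0, 0), m, sig)
  d <- 0.025
  ## on-axis: |phi| = |m|/(4 pi sigma d^2), |E| = 2|m|/(4 pi sigma d^3)
  expect_equal(primary_potential(dip, c(0, 0, d)),
               2e-9 / (4 * pi * sig * d^2))
  expect_equal(sqrt(sum(primary_efield(dip, c(0, 0, d))^2)),
               2 * 2e-9 / (4 * pi * sig * d^3))
  ## odd symmetry through the dipole
  p <- c(0.01, -0.02, 0.015)
  expect_equal(primary_potential(dip, p), -primary_potential(dip, -p))
  ## 1/sigma scaling
  dip2 <- dipole_set(c(0, 0, 0), m, 2 * sig)
  expect_equal(primary_potential(dip2, p), primary_potential(dip, p) / 2)
  ## E decays as d^-3 along a fixed direction
  u <- c(1, 2, 2) / 3
  e1 <- sqrt(sum(primary_efield(dip, 0.01 * u)^2))
  e2 <- sqrt(sum(primary_efield(dip, 0.02 * u)^2))
  expect_equal(e1 / e2, 8, tolerance = 1e-12)
  expect_error(primary_potential(dip, c(0, 0, 1e-12)), "singular|dipole")
})

test_that("primary E field equals the numerical gradient of the potential", {
  dip <- dipole_set(c(0.001, 0.002, 0.003), c(1e-9, -2e-9, 0.5e-9), 0.4)
  set.seed(3)
  pts <- matrix(rnorm(30, sd = 0.02), ncol = 3)
  pts <- pts[sqrt(rowSums(sweep(pts, 2, dip$positions[1, ])^2)) > 0.008, ]
  E <- primary_efield(dip, pts)
  h <- 1e-7
  for (k in 1:3) {
    e <- rep(0, 3); e[k] <- h
    num <- -(primary_potential(dip, sweep(pts, 2, -e)) -
               primary_potential(dip, sweep(pts, 2, e))) / (2 * h)
    expect_equal(num, E[, k], tolerance = 1e-6)
  }
})

test_that("infinite-medium B field follows the Biot-Savart closed form", {
  m <- c(0, 0, 3e-9)
  dip <- dipole_set(c(0, 0, 0), m, 0.3)
  ## parallel displacement: zero field
  expect_equal(primary_bfield(dip, c(0, 0, 0.02)),
               matrix(0, 1, 3))
  ## perpendicular at distance d: mu0 |m| / (4 pi d^2)
  d <- 0.015
  B <- primary_bfield(dip, c(d, 0, 0))
  expect_equal(sqrt(sum(B^2)), 1e-7 * 3e-9 / d^2)
  ## moment flip
  dipf <- dipole_set(c(0, 0, 0), -m, 0.3)
  p <- c(0.01, 0.02, -0.005)
  expect_equal(primary_bfield(dipf, p), -primary_bfield(dip, p))
})

test_that("fields are additive over the dipole set", {
  set.seed(5)
  pos <- matrix(rnorm(9, sd = 0.01), 3)
  mom <- matrix(rnorm(9, sd = 1e-9), 3)
  pts <- matrix(rnorm(15, sd = 0.05), 5)
  all3 <- dipole_set(pos, mom, 0.3)
  singles <- lapply(1:3, function(i)
    dipole_set(pos[i, , drop = FALSE], mom[i, , drop = FALSE], 0.3))
  expect_equal(primary_potential(all3, pts),
               Reduce(`+`, lapply(singles, primary_potential, points = pts)))
  expect_equal(primary_bfield(all3, pts),
               Reduce(`+`, lapply(singles, primary_bfield, points = pts)))
})

test_that("analytic facet flux average matches the quadrature oracle", {
  ## facet one edge length away from the dipole
  p1 <- c(0, 0, 0.01); p2 <- c(0.012, 0, 0.011); p3 <- c(0.004, 0.011, 0.009)
  dip <- dipole_set(c(0.004, 0.004, 0), c(2e-9, 1e-9, 3e-9), 0.3)
  model <- assemble(list(compartment(
    "t", tetra_mesh(p1, p2, p3, c(0.005, 0.004, 0.03)), 1, 0)))
  nrm <- as.numeric(model$normals[1, ])   # facet 1 is the base triangle
  area <- model$areas[1]
  ## use the exported per-facet field with a large analytic radius
  Ein <- facet_normal_field(dip, model, analytic_radius = 100)
  oracle <- tri_quadrature(function(p) {
    sum(primary_efield(dip, p) * nrm)
  }, p1, p2, p3, n = 200) / area
  expect_equal(unname(Ein[1]), oracle, tolerance = 1e-4)
  ## analytic_radius = 0 reduces to centroid evaluation
  Ein0 <- facet_normal_field(dip, model, analytic_radius = 0)
  ctr <- (p1 + p2 + p3) / 3
  expect_equal(unname(Ein0[1]), sum(primary_efield(dip, ctr) * nrm))
})

test_that("facet average converges to the centroid value for far/small facets", {
  dip <- dipole_set(c(0, 0, 0), c(0, 0, 2e-9), 0.3)
  base <- rbind(c(0.03, 0, 0.04), c(0.042, 0, 0.041), c(0.034, 0.011, 0.039))
  ctr <- colMeans(base)
  m0 <- assemble(list(compartment(
    "t", tetra_mesh(base[1, ], base[2, ], base[3, ], ctr + c(0, 0, 0.05)),
    1, 0)))
  nrm <- as.numeric(m0$normals[1, ])
  vals <- sapply(c(1, 0.25, 0.0625), function(s) {
    tri <- sweep(sweep(base, 2, ctr) * s, 2, ctr, `+`)
    m <- tetra_mesh(tri[1, ], tri[2, ], tri[3, ], ctr + c(0, 0, 0.05))
    facet_normal_field(dip, assemble(list(compartment("t", m, 1, 0))),
                       analytic_radius = 100)[1]
  })
  ctrval <- sum(primary_efield(dip, ctr) * nrm)
  errs <- abs(vals - ctrval)
  expect_lt(errs[3], errs[1])            # Richardson shrink
  expect_lt(abs(vals[3] - ctrval) / abs(ctrval), 1e-3)  # small far facet
})

test_that("dipole files round trip", {
  dip <- dipole_set(rbind(c(0, 0, 0.07), c(0.01, 0, 0.06)),
                    rbind(c(4e-11, 0, 0), c(0, 1e-11, 2e-11)), 0.275)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_dipoles(dip, tmp)
  r <- read_dipoles(tmp)
  expect_equal(r$positions, dip$positions)
  expect_equal(r$moments, dip$moments)
  expect_equal(r$sigma, dip$sigma)
})
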