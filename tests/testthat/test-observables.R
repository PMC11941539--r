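test_that("error metrics satisfy their defining identities exactly", {
  set.seed(9)
  a <- rnorm(40)
  expect_equal(rdm(a, a), 0)
  expect_equal(rdm(a, 2 * a), 0)        # scale invariance
  expect_equal(rdm(a, -a), 2)
  expect_equal(relative_l2(a, a), 0)
  expect_equal(relative_l2(2 * a, a), 1)
  b <- rnorm(40)
  b <- b - sum(a * b) / sum(a * a) * a  # orthogonalize
  b <- b * sqrt(sum(a^2) / sum(b^2))
  expect_equal(relative_l2(a, b), sqrt(2))
  expect_error(rdm(a, rep(0, 40)), "zero-norm")
  expect_error(relative_l2(a, rep(0, 40)), "zero-norm")
  expect_error(rdm(a, b[1:10]), "length")
})

test_that("potential metrics are gauge invariant after mean removal", {
  set.seed(10)
  a <- rnorm(30)
  b <- rnorm(30)
  e0 <- error_report(a, b, "potential")
  e1 <- error_report(a + 5, b - 3, "potential")
  expect_equal(e0$rdm, e1$rdm)
  expect_equal(e0$relative_l2, e1$relative_l2)
  ## vector fields are flattened, three components per point
  A <- matrix(rnorm(30), 10)
  B <- matrix(rnorm(30), 10)
  expect_equal(error_report(A, B, "field")$rdm,
               rdm(as.numeric(A), as.numeric(B)))
})

test_that("a contrast-free model returns exactly the primary potential", {
  model <- assemble(list(compartment("x", icosphere(0.09, 3), 0.3, 0.3)))
  dip <- dipole_set(c(0, 0, 0.05), c(1e-9, 0, 2e-9), 0.3)
  nf <- precompute_nearfield(model, 16)
  sol <- solve_charge(model, initial_estimate(
    model, facet_normal_field(dip, model, 3)), nf)
  pts <- icosphere(0.089, 2)$vertices
  expect_equal(potential_at(sol, model, dip, pts),
               primary_potential(dip, pts))
  ## zero-mean gauge
  phi <- potential_at(sol, model, dip, pts, zero_mean = TRUE)
  expect_equal(mean(phi), 0, tolerance = 1e-15 * max(abs(phi)))
})

## single-shell homogeneous solve shared by the magnetic-field tests
local({
  model <- single_shell_model(radius = 0.092, k = 9, sigma = 0.3)
  dip <- dipole_set(c(0, 0, 0.06), c(2e-9, 0, 0), 0.3)
  nf <- precompute_nearfield(model, 64)
  sol <- solve_charge(model, initial_estimate(
    model, facet_normal_field(dip, model, 3)), nf, tol = 1e-6)
  meg_pts <- offset_observation_surface(model$compartments[[1]]$mesh, 0.010)
  B <- magnetic_field_at(sol, model, dip, meg_pts)

  test_that("computed B matches the Sarvas field on the homogeneous sphere", {
    Bref <- sphere_meg_field(c(0, 0, 0), dip, meg_pts)
    er <- error_report(B, Bref, "field")
    expect_lt(er$rdm, 0.05)
    expect_lt(er$relative_l2, 0.06)
  })

  test_that("the conductor contribution to exterior B is tangential", {
    B0 <- primary_bfield(dip, meg_pts)
    rhat <- meg_pts / sqrt(rowSums(meg_pts^2))
    rB <- rowSums(B * rhat)
    rB0 <- rowSums(B0 * rhat)
    expect_lt(max(abs(rB - rB0)) / max(abs(rB0)), 0.02)
  })

  test_that("a radial dipole is nearly magnetically silent in the BEM too", {
    dipr <- dipole_set(c(0, 0, 0.06), c(0, 0, 2e-9), 0.3)
    solr <- solve_charge(model, initial_estimate(
      model, facet_normal_field(dipr, model, 3)), nf, tol = 1e-6)
    Br <- magnetic_field_at(solr, model, dipr, meg_pts)
    ## suppression is bounded by the discretization error of the secondary
    ## term (same order as the tangential-dipole B error)
    expect_lt(max(sqrt(rowSums(Br^2))) / max(sqrt(rowSums(B^2))), 0.06)
  })

  test_that("interior evaluation points are rejected", {
    expect_error(magnetic_field_at(sol, model, dip, c(0, 0, 0.05)),
                 "outside")
  })
})
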