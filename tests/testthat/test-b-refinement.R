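test_that("facet selection implements the total-charge threshold", {
  ## 100 unit-area facets: one charge 100, the rest 1; k = 10
  areas <- rep(1, 100)
  cc <- c(100, rep(1, 99))
  expect_identical(select_facets(areas, cc, 10), 1L)
  ## mean |q| = 1.99, threshold 19.9: only the large facet exceeds it
  expect_identical(select_facets(areas, cc, 10), which(abs(cc) > 10 * 1.99))
  ## all equal: nothing selected for k >= 1
  expect_length(select_facets(areas, rep(3, 100), 1), 0)
  ## all-zero estimate: empty selection
  expect_length(select_facets(areas, rep(0, 100), 5), 0)
  expect_error(select_facets(areas, 1:5, 5), "length")
  expect_error(refinement_config(k = 0), "k must be > 0")
  expect_error(refinement_config(steps = -1), "steps")
  ## per-group means select within each group
  g <- rep(1:2, each = 50)
  cc2 <- c(10, rep(1, 49), 1000, rep(100, 49))
  expect_identical(select_facets(areas, cc2, 5, groups = g), c(1L, 51L))
})

test_that("refinement localizes around the dipole and preserves the mesh contract", {
  spec <- four_layer_sphere_spec(0.014)
  model <- assemble(generate_sphere_shells(spec))
  dip <- validation_dipole(spec, "tangential")
  cfg <- refinement_config(k = 5, steps = 4)
  rmodel <- b_refine(model, dip, cfg)
  ## growth stays modest (< 3x on the sphere fixture)
  expect_lt(rmodel$n_facets, 3 * model$n_facets)
  expect_gt(rmodel$n_facets, model$n_facets)
  ## every compartment remains watertight and outward
  for (cp in rmodel$compartments) {
    expect_true(check_watertight(cp$mesh)$watertight)
    expect_gt(signed_volume(cp$mesh), 0)
  }
  ## refined (smaller-than-original) facets sit near the dipole
  small <- rmodel$areas < 0.5 * min(model$areas)
  d <- sqrt(rowSums(sweep(rmodel$centroids, 2, dip$positions[1, ])^2))
  expect_lt(max(d[small]), 20 * model$avg_edge)
  ## child facets inherit their compartment's contrast
  expect_true(all(rmodel$K %in% unique(model$K)))
  ## history tracks each step
  expect_length(attr(rmodel, "refinement_history"), 5)
})

test_that("b_refine is deterministic and steps = 0 is the identity", {
  spec <- four_layer_sphere_spec(0.016)
  model <- assemble(generate_sphere_shells(spec))
  dip <- validation_dipole(spec, "radial")
  expect_identical(b_refine(model, dip, refinement_config(steps = 0))$faces,
                   model$faces)
  cfg <- refinement_config(k = 6, steps = 2)
  r1 <- b_refine(model, dip, cfg)
  r2 <- b_refine(model, dip, cfg)
  expect_identical(r1$vertices, r2$vertices)
  expect_identical(r1$faces, r2$faces)
})

test_that("an astronomically large threshold leaves the model untouched", {
  spec <- four_layer_sphere_spec(0.016)
  model <- assemble(generate_sphere_shells(spec))
  dip <- validation_dipole(spec)
  r <- refine_step(model, dip, refinement_config(k = 1e9, steps = 1))
  expect_identical(r$faces, model$faces)
  expect_identical(attr(r, "n_selected"), 0L)
})

test_that("parameter sweep tabulates errors and matches the unrefined baseline at huge k", {
  spec <- sphere_spec(radii = c(0.092, 0.080), sigma_in = c(0.3, 0.6),
                      sigma_out = c(0, 0.3), edge_length = 0.02,
                      names = c("outer", "inner"))
  model <- assemble(generate_sphere_shells(spec))
  dip <- dipole_set(c(0, 0, 0.070), c(2e-9, 0, 0), 0.6)
  eeg_pts <- model$compartments[[1]]$mesh$vertices
  ref <- list(eeg_points = eeg_pts,
              eeg = sphere_eeg_potential(
                layered_sphere(c(0, 0, 0), spec$radii, spec$sigma_in),
                dip, eeg_pts))
  tab <- parameter_sweep(model, dip, k_grid = c(1e9, 6), steps_grid = 2,
                         neighbors_grid = 16, reference = ref)
  expect_true(all(tab$ok))
  expect_equal(nrow(tab), 2)
  ## k -> infinity reproduces the unrefined baseline exactly
  nf <- precompute_nearfield(model, 16)
  sol <- solve_charge(model, initial_estimate(
    model, facet_normal_field(dip, model, 3)), nf)
  phi <- potential_at(sol, model, dip, eeg_pts, zero_mean = TRUE)
  base <- error_report(phi, ref$eeg, "potential")
  expect_equal(tab$rdm_potential[tab$k == 1e9], base$rdm, tolerance = 1e-10)
  ## refinement does not hurt on this fixture (1-pp band)
  expect_lt(tab$rdm_potential[tab$k == 6],
            tab$rdm_potential[tab$k == 1e9] + 0.01)
})
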