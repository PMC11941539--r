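## small real lead field: homogeneous shell, 8 well-separated interior dipoles
make_tiny_leadfield <- function() {
  model <- single_shell_model(radius = 0.09, k = 5, sigma = 0.3)
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  pos <- cbind(0.05 * cos(ang), 0.05 * sin(ang), 0.02)
  ori <- cbind(0, 0, rep(1, 8))
  electrodes <- model$compartments[[1]]$mesh$vertices[seq(1, 252, by = 9), ]
  build_leadfield(model, pos, ori, electrodes, sigma = 0.3,
                  config = refinement_config(steps = 0, neighbor_count = 16),
                  tol = 1e-6)
}
LF <- make_tiny_leadfield()

test_that("lead-field columns are the zero-mean forward potentials of unit dipoles", {
  expect_equal(dim(LF$L), c(28L, 8L))
  expect_false(any(LF$failed))
  expect_equal(colMeans(LF$L), rep(0, 8), tolerance = 1e-12 * max(abs(LF$L)))
  ## rebuild one column directly
  model <- single_shell_model(radius = 0.09, k = 5, sigma = 0.3)
  dip <- dipole_set(LF$positions[3, , drop = FALSE],
                    LF$orientations[3, , drop = FALSE], 0.3)
  nf <- precompute_nearfield(model, 16)
  sol <- solve_charge(model, initial_estimate(
    model, facet_normal_field(dip, model, 3)), nf, tol = 1e-6)
  phi <- potential_at(sol, model, dip, LF$electrodes, zero_mean = TRUE)
  expect_equal(LF$L[, 3], phi, tolerance = 1e-10)
})

test_that("noiseless single-dipole measurements are recovered by both solvers", {
  w_true <- rep(0, 8)
  w_true[5] <- 2e-9
  v <- synthesize_measurements(LF, w_true, noise_level = 0)
  expect_equal(v, as.numeric(LF$L %*% w_true))
  for (est in list(localize_pinv(LF, v), localize_mnls(LF, v))) {
    expect_equal(which.max(abs(est$weights)), 5L)
    expect_length(est$weights, 8)
  }
  ## full-column-rank lead field: the two methods coincide
  wp <- localize_pinv(LF, v)$weights
  wm <- localize_mnls(LF, v)$weights
  expect_lt(rel_diff(wp, wm), 1e-8)
  ## linearity and the zero map
  expect_equal(localize_pinv(LF, 2 * v)$weights, 2 * wp, tolerance = 1e-10)
  expect_equal(localize_pinv(LF, rep(0, 28))$weights, rep(0, 8))
})

test_that("minimum-norm solution is a least-squares optimum", {
  set.seed(21)
  v <- synthesize_measurements(LF, rnorm(8, sd = 1e-9), noise_level = 0.05,
                               seed = 77)
  w <- localize_mnls(LF, v)$weights
  r0 <- sum((LF$L %*% w - v)^2)
  for (i in 1:5) {
    dw <- rnorm(8)
    dw <- 1e-6 * dw / sqrt(sum(dw^2)) * sqrt(sum(w^2))
    expect_gte(sum((LF$L %*% (w + dw) - v)^2), r0 - 1e-25)
  }
})

test_that("measurement synthesis is exactly reproducible under a seed", {
  w <- rnorm(8, sd = 1e-9)
  v1 <- synthesize_measurements(LF, w, noise_level = 0.1, seed = 123)
  v2 <- synthesize_measurements(LF, w, noise_level = 0.1, seed = 123)
  expect_identical(v1, v2)
  expect_error(synthesize_measurements(LF, w, noise_level = -1), ">= 0")
  expect_error(synthesize_measurements(LF, w[1:3]), "per dipole")
})

test_that("self-variance normalization rescales channels individually", {
  v <- c(2, -4, 8)
  expect_equal(normalize_measurements(v, c(1, 2, 4)), c(2, -2, 2))
  expect_equal(normalize_measurements(v, rep(2, 3)), v / 2)
  expect_error(normalize_measurements(v, c(1, 0, 4)), "channel")
  ## normalization with equal variances keeps the recovery argmax
  w_true <- rep(0, 8); w_true[2] <- 1e-9
  meas <- synthesize_measurements(LF, w_true, 0)
  est <- localize_pinv(LF$L / 3, normalize_measurements(meas, rep(3, 28)))
  expect_equal(which.max(abs(est$weights)), 2L)
})

test_that("noisy recovery succeeds in nearly all seeded repetitions", {
  w_true <- rep(0, 8)
  w_true[4] <- 2e-9
  hits <- 0
  for (s in 1:100) {
    v <- synthesize_measurements(LF, w_true, noise_level = 0.01, seed = s)
    hits <- hits + (which.max(abs(localize_pinv(LF, v)$weights)) == 4L)
  }
  expect_gte(hits, 95)
})

test_that("swapping electrodes swaps lead-field rows; thresholded sets nest", {
  L2 <- LF$L[c(2, 1, 3:28), ]
  expect_equal(L2[1, ], LF$L[2, ])
  expect_equal(L2[2, ], LF$L[1, ])
  set.seed(31)
  w <- rnorm(200)
  sets <- lapply(c(70, 80, 90), function(p)
    which(abs(w) > stats::quantile(abs(w), p / 100)))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[1]]))
})
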