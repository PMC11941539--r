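#' Build a lead-field matrix from repeated forward solves
#'
#' Column `j` is the zero-mean-gauge electrode potential of unit dipole `j`
#' (1 A·m along its orientation). When all dipoles fall within a 7 mm ball
#' the mesh is b-refined once for the whole cluster and the refined model and
#' near-field tables are reused across columns; otherwise each dipole gets
#' its own refinement pass.
#'
#' @param model a `head_model`.
#' @param positions k x 3 dipole positions (m).
#' @param orientations k x 3 unit orientation vectors.
#' @param electrodes e x 3 electrode positions on/near the skin (m).
#' @param sigma source-medium conductivity (S/m).
#' @param config a [refinement_config()] (steps = 0 skips refinement).
#' @param tol,max_iter solver settings.
#' @param cluster_diameter reuse threshold for one shared refinement (m).
#' @return A `lead_field`: `L` (electrodes x dipoles, V per A·m),
#'   `electrodes`, `positions`, `orientations`, `failed` (columns whose solve
#'   did not converge).
#' @export
build_leadfield <- function(model, positions, orientations, electrodes,
                            sigma, config = refinement_config(steps = 0),
                            tol = 1e-6, max_iter = 200,
                            cluster_diameter = 0.007) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  orientations <- matrix(as.numeric(orientations), ncol = 3)
  electrodes <- matrix(as.numeric(electrodes), ncol = 3)
  k <- nrow(positions)
  stopifnot(nrow(orientations) == k)
  orientations <- orientations / sqrt(rowSums(orientations^2))
  spread <- if (k > 1) max(stats::dist(positions)) else 0
  shared <- spread <= cluster_diameter || config$steps == 0
  L <- matrix(NA_real_, nrow(electrodes), k)
  failed <- logical(k)

  solve_one <- function(rmodel, nf, dip) {
    Ein <- facet_normal_field(dip, rmodel, config$analytic_radius,
                              avg_edge = model$avg_edge)
    sol <- solve_charge(rmodel, initial_estimate(rmodel, Ein), nf,
                        tol = tol, max_iter = max_iter)
    list(phi = potential_at(sol, rmodel, dip, electrodes, zero_mean = TRUE),
         converged = sol$converged)
  }

  if (shared) {
    cluster <- dipole_set(positions, orientations, sigma)
    rmodel <- if (config$steps > 0) b_refine(model, cluster, config) else model
    nf <- precompute_nearfield(rmodel, config$neighbor_count)
    for (j in seq_len(k)) {
      dip <- dipole_set(positions[j, , drop = FALSE],
                        orientations[j, , drop = FALSE], sigma)
      res <- solve_one(rmodel, nf, dip)
      L[, j] <- res$phi
      failed[j] <- !res$converged
    }
  } else {
    for (j in seq_len(k)) {
      dip <- dipole_set(positions[j, , drop = FALSE],
                        orientations[j, , drop = FALSE], sigma)
      rmodel <- b_refine(model, dip, config)
      nf <- precompute_nearfield(rmodel, config$neighbor_count)
      res <- solve_one(rmodel, nf, dip)
      L[, j] <- res$phi
      failed[j] <- !res$converged
    }
  }
  if (any(failed))
    warning(sum(failed), " lead-field column(s) flagged: solver not converged")
  structure(list(L = L, electrodes = electrodes, positions = positions,
                 orientations = orientations, failed = failed),
            class = "lead_field")
}

#' Normalize electrode voltages by per-channel variances
#'
#' @param voltages measurement vector (or channels x trials matrix).
#' @param variances per-channel variance estimates (> 0).
#' @return Voltages divided channel-wise by their variances.
#' @export
normalize_measurements <- function(voltages, variances) {
  v <- as.matrix(voltages)
  if (length(variances) != nrow(v)) stop("one variance per channel required")
  bad <- which(!is.finite(variances) | variances <= 0)
  if (length(bad))
    stop("non-positive variance for channel(s): ",
         paste(bad, collapse = ", "))
  out <- v / variances
  if (is.vector(voltages)) out[, 1] else out
}

leadfield_matrix <- function(leadfield) {
  if (inherits(leadfield, "lead_field")) leadfield$L else as.matrix(leadfield)
}

#' Source weights by Moore-Penrose pseudoinverse
#'
#' `w = pinv(L) v` with singular values below `tol * max(sv)` truncated.
#'
#' @param leadfield a `lead_field` or plain matrix (electrodes x dipoles).
#' @param measurements electrode voltage vector.
#' @param tol relative rank-truncation tolerance; default
#'   `max(dim(L)) * .Machine$double.eps`.
#' @return A `source_estimate`: `weights` (A·m), `method`.
#' @export
localize_pinv <- function(leadfield, measurements, tol = NULL) {
  L <- leadfield_matrix(leadfield)
  v <- as.numeric(measurements)
  if (length(v) != nrow(L)) stop("measurement length must match electrode count")
  if (is.null(tol)) tol <- max(dim(L)) * .Machine$double.eps
  sv <- svd(L)
  keep <- sv$d > tol * sv$d[1]
  w <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% v) / sv$d[keep])
  structure(list(weights = as.numeric(w), method = "pseudoinverse"),
            class = "source_estimate")
}

#' Source weights by minimum-norm least squares
#'
#' The minimum-Euclidean-norm solution of `min ||L w - v||`, computed through
#' the normal equations of the adjoint problem (`w = L' (L L')^- v`), as a
#' sanity check against [localize_pinv()].
#'
#' @inheritParams localize_pinv
#' @return A `source_estimate`: `weights`, `method`.
#' @export
localize_mnls <- function(leadfield, measurements) {
  L <- leadfield_matrix(leadfield)
  v <- as.numeric(measurements)
  if (length(v) != nrow(L)) stop("measurement length must match electrode count")
  G <- L %*% t(L)
  y <- tryCatch(solve(G, v), error = function(e) {
    ## rank-deficient gram matrix: eigen-truncated inverse
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * max(dim(L)) * .Machine$double.eps
    eg$vectors[, keep, drop = FALSE] %*%
      ((t(eg$vectors[, keep, drop = FALSE]) %*% v) / eg$values[keep])
  })
  structure(list(weights = as.numeric(t(L) %*% y), method = "minimum-norm"),
            class = "source_estimate")
}

#' Synthesize electrode measurements from known source weights
#'
#' `v = L w` plus Gaussian noise with standard deviation
#' `noise_level * rms(L w)`; reproducible under `seed`.
#'
#' @param leadfield a `lead_field` or matrix.
#' @param weights true per-dipole weights (A·m).
#' @param noise_level relative noise level (>= 0).
#' @param seed RNG seed (optional).
#' @return Voltage vector.
#' @export
synthesize_measurements <- function(leadfield, weights, noise_level = 0,
                                    seed = NULL) {
  if (noise_level < 0) stop("noise_level must be >= 0")
  L <- leadfield_matrix(leadfield)
  if (length(weights) != ncol(L)) stop("one weight per dipole required")
  v <- as.numeric(L %*% weights)
  if (noise_level > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_level * sqrt(mean(v^2)))
  }
  v
}
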