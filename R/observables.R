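#' Electric potential of a charge solution
#'
#' `phi(r) = phi_i(r) + (1/4 pi) sum_f c_f * S_f(r)`, where `S_f` is the
#' exact single-layer potential integral of facet `f` when the point is
#' within `near_radius` of its centroid and the centroid point-charge value
#' `A_f / |r - c_f|` otherwise. The analytic near integral is finite even at
#' facet vertices, so on-surface electrodes are handled exactly.
#'
#' @param solution a `charge_solution`.
#' @param model the `head_model` the solution was computed on.
#' @param dipoles a [dipole_set()].
#' @param points n x 3 evaluation points (m).
#' @param zero_mean subtract the mean over the returned points (the zero-mean
#'   potential gauge).
#' @param near_radius analytic-integration distance in meters; default 5
#'   average edge lengths.
#' @return Potentials in volts.
#' @export
potential_at <- function(solution, model, dipoles, points, zero_mean = FALSE,
                         near_radius = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(near_radius)) near_radius <- 5 * model$avg_edge
  phi <- primary_potential(dipoles, points) +
    cpp_charge_potential(points, model$vertices, model$faces, model$centroids,
                         model$areas, solution$c, near_radius)
  if (zero_mean) phi <- phi - mean(phi)
  phi
}

# Midpoint-subdivide the facets listed in `which` `level` times (quadrature
# only: flat children of the same flat facet, areas split exactly), returning
# the sub-facet centroids/areas/normals/jump for the Geselowitz sum.
quad_surface <- function(model, levels) {
  out <- list()
  for (lev in sort(unique(levels))) {
    ids <- which(levels == lev)
    if (!length(ids)) next
    f <- model$faces[ids, , drop = FALSE]
    v <- model$vertices
    p1 <- v[f[, 1], , drop = FALSE]
    p2 <- v[f[, 2], , drop = FALSE]
    p3 <- v[f[, 3], , drop = FALSE]
    jump <- model$jump[ids]
    nrm <- model$normals[ids, , drop = FALSE]
    if (lev > 0) {
      for (s in seq_len(lev)) {
        m12 <- (p1 + p2) / 2; m23 <- (p2 + p3) / 2; m31 <- (p3 + p1) / 2
        p1 <- rbind(p1, m12, m31, m12)
        p2 <- rbind(m12, p2, m23, m23)
        p3 <- rbind(m31, m23, p3, m31)
        jump <- rep(jump, 4)
        nrm <- rbind(nrm, nrm, nrm, nrm)
      }
    }
    e1 <- p2 - p1; e2 <- p3 - p1
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    out[[length(out) + 1]] <- list(centroids = (p1 + p2 + p3) / 3,
                                   areas = sqrt(rowSums(cr^2)) / 2,
                                   normals = nrm, jump = jump)
  }
  list(centroids = do.call(rbind, lapply(out, `[[`, "centroids")),
       areas = unlist(lapply(out, `[[`, "areas")),
       normals = do.call(rbind, lapply(out, `[[`, "normals")),
       jump = unlist(lapply(out, `[[`, "jump")))
}

#' Magnetic field of a charge solution
#'
#' Primary Biot-Savart dipole term plus the surface-potential secondary term
#' of the piecewise-homogeneous conductor:
#' `B(r) = B0(r) - (mu0/4 pi) sum_f (sigma_in - sigma_out)_f phi(c_f) A_f
#'  n_f x (r - c_f)/|r - c_f|^3`,
#' where the sum runs over quadrature sub-facets: each facet is
#' midpoint-subdivided until its sub-facet size is small against its distance
#' to the closest observation point (observation shells sit only ~one facet
#' size away from the skin, where single-point quadrature is badly wrong).
#' Points must lie strictly outside the outermost surface.
#'
#' @inheritParams potential_at
#' @param max_quad_level cap on per-facet subdivision (default 3).
#' @return n x 3 matrix of B vectors (tesla).
#' @export
magnetic_field_at <- function(solution, model, dipoles, points,
                              near_radius = NULL, max_quad_level = 3) {
  points <- matrix(as.numeric(points), ncol = 3)
  ## outside check against the outermost compartment's bounding sphere
  outer <- which.max(vapply(model$compartments,
                            function(cp) max(rowSums(cp$mesh$vertices^2)),
                            numeric(1)))
  ov <- model$compartments[[outer]]$mesh$vertices
  ctr <- colMeans(ov)
  rmin <- sqrt(min(rowSums(sweep(ov, 2, ctr)^2)))
  pr <- sqrt(rowSums(sweep(points, 2, ctr)^2))
  if (any(pr < rmin))
    stop("magnetic field evaluation points must lie outside the model")
  ## per-facet quadrature depth from the size/distance ratio
  d <- cpp_min_dist(model$centroids, points)
  size <- sqrt(2 * model$areas)
  lev <- pmin(pmax(ceiling(log2(size / (0.35 * d))), 0), max_quad_level)
  qs <- quad_surface(model, lev)
  phi_q <- potential_at(solution, model, dipoles, qs$centroids,
                        near_radius = near_radius)
  primary_bfield(dipoles, points) +
    cpp_bfield_secondary(points, qs$centroids, qs$areas, qs$normals,
                         qs$jump, phi_q)
}

#' Relative difference measure (RDM)
#'
#' `|| a/||a|| - b/||b|| ||`: the scale-invariant topography error, in
#' `[0, 2]`. Matrix inputs (vector fields) are flattened, three components
#' per point, before norm-taking.
#'
#' @param a field vector (or n x 3 matrix).
#' @param b reference vector of the same shape.
#' @return Dimensionless RDM.
#' @export
rdm <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("rdm undefined for zero-norm input")
  sqrt(sum((a / na - b / nb)^2))
}

#' Relative L2-norm error
#'
#' `||a - b|| / ||b||`.
#'
#' @param a field vector (or n x 3 matrix).
#' @param b reference vector of the same shape (nonzero norm).
#' @return Dimensionless relative error.
#' @export
relative_l2 <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("relative_l2 undefined for zero-norm reference")
  sqrt(sum((a - b)^2)) / nb
}

#' RDM and relative-L2 error report
#'
#' Potentials are mean-removed before both metrics (they are defined up to a
#' gauge constant); vector fields are flattened three components per point.
#'
#' @param a computed field (vector for potentials, n x 3 for B).
#' @param b reference field of the same shape.
#' @param type `"potential"` or `"field"`.
#' @return An `error_report` list: `rdm`, `relative_l2`.
#' @export
error_report <- function(a, b, type = c("potential", "field")) {
  type <- match.arg(type)
  if (type == "potential") {
    a <- as.numeric(a) - mean(as.numeric(a))
    b <- as.numeric(b) - mean(as.numeric(b))
  }
  structure(list(rdm = rdm(a, b), relative_l2 = relative_l2(a, b)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report: RDM %.3f%%  relative L2 %.3f%%\n",
              100 * x$rdm, 100 * x$relative_l2))
  invisible(x)
}
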