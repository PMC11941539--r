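#' Layered concentric-sphere conductor
#'
#' @param center sphere center (m).
#' @param radii interface radii, outer to inner, strictly decreasing (m).
#' @param sigmas conductivity of the region just inside each radius (S/m),
#'   same order as `radii`; the exterior conductivity is 0 (air).
#' @return A `layered_sphere` object.
#' @export
layered_sphere <- function(center, radii, sigmas) {
  if (length(radii) != length(sigmas)) stop("radii/sigmas length mismatch")
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (any(sigmas < 0)) stop("conductivities must be >= 0")
  structure(list(center = center, radii = radii, sigmas = sigmas),
            class = "layered_sphere")
}

# Legendre P_n(x) and Q_n = sin(theta) P_n'(x) by upward recurrence,
# vectorized over x; returns the two length(x) vectors for one n given the
# running (P_{n-1}, P_n) pair.
legendre_step <- function(n, x, Pnm1, Pn) {
  ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
}

#' Multilayer-sphere EEG potential (Legendre series)
#'
#' Closed-form reference potential of current dipoles inside the innermost
#' region of a piecewise-homogeneous concentric-sphere conductor with
#' insulating exterior. Per degree, the radial two-term solutions of all
#' layers are coupled by potential/current continuity and the outer Neumann
#' condition; the series is truncated adaptively.
#'
#' @param sphere a [layered_sphere()].
#' @param dipoles a [dipole_set()]; every dipole must lie strictly inside the
#'   innermost interface and off the center.
#' @param points n x 3 evaluation points on or inside the outer radius (m).
#' @param tol relative truncation tolerance (default 1e-10); `tol = 0` runs
#'   exactly `max_terms` terms (fixed truncation, useful for convergence
#'   studies).
#' @param max_terms series cap (default 400); exceeding it without reaching
#'   a positive `tol` is an error reporting the achieved tolerance.
#' @return Potentials in volts.
#' @export
sphere_eeg_potential <- function(sphere, dipoles, points, tol = 1e-10,
                                 max_terms = 400) {
  stopifnot(inherits(sphere, "layered_sphere"))
  points <- matrix(as.numeric(points), ncol = 3)
  R <- rev(sphere$radii)          # inner to outer interface radii
  sig <- rev(sphere$sigmas)       # region conductivities, innermost first
  L <- length(R)
  pr <- sweep(points, 2, sphere$center)
  r <- sqrt(rowSums(pr^2))
  if (any(r > R[L] * (1 + 1e-9))) stop("points must lie on or inside the outer radius")
  r <- pmin(r, R[L])
  ## region of each point: smallest j with r <= R[j]
  region <- rep(1L, length(r))
  for (j in seq_len(L)) region[r > R[j] * (1 + 1e-12)] <- j + 1L
  region <- pmin(region, L)

  out <- numeric(nrow(points))
  for (d in seq_len(nrow(dipoles$positions))) {
    bvec <- dipoles$positions[d, ] - sphere$center
    b <- sqrt(sum(bvec^2))
    if (b >= R[1]) stop("dipole must lie strictly inside the innermost interface")
    if (b < 1e-12) stop("dipole at the sphere center is not supported")
    zh <- bvec / b
    mom <- dipoles$moments[d, ]
    mr <- sum(mom * zh)
    mt_vec <- mom - mr * zh
    mt <- sqrt(sum(mt_vec^2))
    xh <- if (mt > 0) mt_vec / mt else {
      tmp <- if (abs(zh[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      tmp <- tmp - sum(tmp * zh) * zh
      tmp / sqrt(sum(tmp^2))
    }
    costh <- pmin(1, pmax(-1, (pr %*% zh)[, 1] / pmax(r, 1e-300)))
    sinth <- sqrt(pmax(0, 1 - costh^2))
    cosph <- ifelse(sinth > 1e-12,
                    (pr %*% xh)[, 1] / pmax(r * sinth, 1e-300), 0)

    tb <- b / R[1]
    acc <- numeric(length(r))
    Pnm1 <- rep(1, length(r))      # P_0
    Pn <- costh                    # P_1
    peak <- 0
    quiet <- 0L
    for (n in seq_len(max_terms)) {
      coef <- solve_layer_coefficients(n, R, sig, tb)
      ## source strengths: dipole sits in region 1, so its expansion uses the
      ## innermost conductivity
      cr <- mr * n / (4 * pi * sig[1] * b^2)
      ct <- mt / (4 * pi * sig[1] * b^2)
      Qn <- ifelse(sinth > 1e-12, n * (Pnm1 - costh * Pn) / sinth, 0)
      term <- numeric(length(r))
      for (j in unique(region)) {
        pj <- region == j
        rj <- r[pj]
        ua <- (rj / R[j])^n
        ub <- if (j == 1) 0 else (R[j - 1] / rj)^(n + 1)
        radial_r <- coef$A[j, 1] * ua + (if (j == 1) 0 else coef$B[j, 1] * ub)
        radial_t <- coef$A[j, 2] * ua + (if (j == 1) 0 else coef$B[j, 2] * ub)
        if (j == 1) {
          src <- (b / rj)^(n + 1)
          radial_r <- radial_r + src
          radial_t <- radial_t + src
        }
        term[pj] <- cr * radial_r * Pn[pj] + ct * radial_t * Qn[pj] * cosph[pj]
      }
      acc <- acc + term
      mx <- max(abs(term))
      peak <- max(peak, max(abs(acc)))
      if (tol > 0) {
        if (peak > 0 && mx < tol * peak) {
          quiet <- quiet + 1L
          if (quiet >= 3L) break
        } else quiet <- 0L
        if (n == max_terms && quiet < 3L)
          stop(sprintf("series not converged in %d terms (achieved %.1e relative)",
                       max_terms, mx / max(peak, 1e-300)))
      }
      Pnext <- legendre_step(n, costh, Pnm1, Pn)
      Pnm1 <- Pn
      Pn <- Pnext
    }
    out <- out + acc
  }
  out
}

# Per-degree layer coefficients. Regions 1..L (innermost first), interface
# radii R (inner to outer), region conductivities sig, dipole radius ratio
# tb = b/R[1]. The region-1 source term is normalized to coefficient 1 on
# the (b/r)^(n+1) basis; returns scaled homogeneous coefficients A (on
# (r/R_j)^n) and B (on (R_{j-1}/r)^(n+1)) for both the radial and tangential
# source columns (identical here because the normalized source is the same).
solve_layer_coefficients <- function(n, R, sig, tb) {
  L <- length(R)
  nun <- 2L * L - 1L
  M <- matrix(0, nun, nun)
  rhs <- numeric(nun)
  ## unknown order: A1, A2, B2, A3, B3, ...
  iA <- function(j) if (j == 1) 1L else 2L * (j - 1L)
  iB <- function(j) 2L * (j - 1L) + 1L
  row <- 0L
  for (j in seq_len(L - 1)) {
    rb <- if (j == 1) 0 else (R[j - 1] / R[j])^(n + 1)
    ra <- (R[j] / R[j + 1])^n
    src_v <- if (j == 1) tb^(n + 1) else 0
    ## potential continuity
    row <- row + 1L
    M[row, iA(j)] <- 1
    if (j > 1) M[row, iB(j)] <- rb
    M[row, iA(j + 1)] <- -ra
    M[row, iB(j + 1)] <- -1
    rhs[row] <- -src_v
    ## current continuity (times R_j)
    row <- row + 1L
    M[row, iA(j)] <- sig[j] * n
    if (j > 1) M[row, iB(j)] <- -sig[j] * (n + 1) * rb
    M[row, iA(j + 1)] <- -sig[j + 1] * n * ra
    M[row, iB(j + 1)] <- sig[j + 1] * (n + 1)
    rhs[row] <- sig[j] * (n + 1) * src_v
  }
  ## outer Neumann condition at R_L
  row <- row + 1L
  rbL <- if (L == 1) 0 else (R[L - 1] / R[L])^(n + 1)
  M[row, iA(L)] <- n
  if (L > 1) M[row, iB(L)] <- -(n + 1) * rbL
  rhs[row] <- if (L == 1) (n + 1) * tb^(n + 1) else 0
  sol <- solve(M, rhs)
  A <- matrix(0, L, 2)
  B <- matrix(0, L, 2)
  A[1, ] <- sol[1]
  if (L > 1) for (j in 2:L) {
    A[j, ] <- sol[iA(j)]
    B[j, ] <- sol[iB(j)]
  }
  list(A = A, B = B)
}

#' Surface potential of a dipole in a homogeneous sphere (closed form)
#'
#' Independent closed-form oracle obtained from the Legendre generating
#' functions (no per-degree linear solves): surface potential of a current
#' dipole inside a homogeneous conducting sphere with insulating exterior.
#'
#' @param radius sphere radius (m).
#' @param sigma conductivity (S/m).
#' @param dipoles a [dipole_set()] strictly inside the sphere, off-center.
#' @param points n x 3 points on the sphere surface.
#' @param center sphere center.
#' @return Potentials in volts.
#' @export
homogeneous_sphere_potential <- function(radius, sigma, dipoles, points,
                                         center = c(0, 0, 0)) {
  points <- matrix(as.numeric(points), ncol = 3)
  pr <- sweep(points, 2, center)
  out <- numeric(nrow(points))
  for (d in seq_len(nrow(dipoles$positions))) {
    bvec <- dipoles$positions[d, ] - center
    b <- sqrt(sum(bvec^2))
    zh <- bvec / b
    mom <- dipoles$moments[d, ]
    mr <- sum(mom * zh)
    mt_vec <- mom - mr * zh
    mt <- sqrt(sum(mt_vec^2))
    xh <- if (mt > 0) mt_vec / mt else c(0, 0, 0)
    r <- sqrt(rowSums(pr^2))
    x <- pmin(1, pmax(-1, (pr %*% zh)[, 1] / r))
    st <- sqrt(pmax(0, 1 - x^2))
    cp <- ifelse(st > 1e-12 & mt > 0, (pr %*% xh)[, 1] / (r * st), 0)
    t <- b / radius
    rho <- sqrt(1 - 2 * t * x + t^2)
    Sr <- 2 * t * (x - t) / rho^3 + 1 / rho - 1
    St <- st * (2 * t / rho^3 + t * (rho + 1) / (rho * (1 - t * x + rho)))
    out <- out + (mr * Sr + mt * St * cp) / (4 * pi * sigma * b * radius)
  }
  out
}

#' Sarvas MEG field of a spherically symmetric conductor
#'
#' Closed-form exterior magnetic field of current dipoles in any spherically
#' symmetric conductivity profile; independent of the profile itself.
#' Radial dipoles are magnetically silent.
#'
#' @param center conductor center (m).
#' @param dipoles a [dipole_set()].
#' @param points n x 3 exterior points (m).
#' @param radius optional outermost conductor radius used to reject interior
#'   points.
#' @return n x 3 matrix of B vectors (tesla).
#' @export
sphere_meg_field <- function(center, dipoles, points, radius = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  pr <- sweep(points, 2, center)
  if (!is.null(radius) && any(rowSums(pr^2) < radius^2))
    stop("points must lie strictly outside the conductor")
  out <- matrix(0, nrow(points), 3)
  for (d in seq_len(nrow(dipoles$positions))) {
    r0 <- dipoles$positions[d, ] - center
    Q <- dipoles$moments[d, ]
    Qx <- c(Q[2] * r0[3] - Q[3] * r0[2],
            Q[3] * r0[1] - Q[1] * r0[3],
            Q[1] * r0[2] - Q[2] * r0[1])
    a_vec <- sweep(pr, 2, r0)
    a <- sqrt(rowSums(a_vec^2))
    rn <- sqrt(rowSums(pr^2))
    adotr <- rowSums(a_vec * pr)
    F <- a * (rn * a + rn^2 - (pr %*% r0)[, 1])
    gF <- (a^2 / rn + adotr / a + 2 * a + 2 * rn) * pr -
      outer(a + 2 * rn + adotr / a, r0)
    Qxr <- matrix(Qx, nrow(points), 3, byrow = TRUE)
    out <- out + 1e-7 * (F * Qxr - (pr %*% Qx)[, 1] * gF) / F^2
  }
  out
}
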