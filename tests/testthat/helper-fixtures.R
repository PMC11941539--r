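# Shared fixtures and independent quadrature oracles, built in code.

# Unit cube [0,1]^3 with outward-oriented triangulation (8 vertices, 12 facets)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 (normal +z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_mesh(v, f)
}

# single closed shell with skin-air contrast (K = 1)
single_shell_model <- function(radius = 0.09, k = 6, sigma = 0.465) {
  assemble(list(compartment("shell", icosphere(radius, k), sigma, 0)))
}

# mild-contrast two-shell model for solver tests
two_shell_model <- function(edge = 0.012) {
  spec <- sphere_spec(radii = c(0.092, 0.080), sigma_in = c(0.3, 0.6),
                      sigma_out = c(0, 0.3), edge_length = edge,
                      names = c("outer", "inner"))
  assemble(generate_sphere_shells(spec))
}

# midpoint barycentric quadrature over a triangle: independent oracle for
# facet integrals (O(n^2) points; exact enough for 1e-4..1e-6 comparisons)
tri_quadrature <- function(f, p1, p2, p3, n = 120) {
  h <- 1 / n
  s <- 0
  npts <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1 - i)) {
    u <- (3 * i + 1) / (3 * n); v <- (3 * j + 1) / (3 * n)
    s <- s + f(p1 + u * (p2 - p1) + v * (p3 - p1))
    npts <- npts + 1
    if (j < n - 1 - i) {
      u <- (3 * i + 2) / (3 * n); v <- (3 * j + 2) / (3 * n)
      s <- s + f(p1 + u * (p2 - p1) + v * (p3 - p1))
      npts <- npts + 1
    }
  }
  cr <- cross3(p2 - p1, p3 - p1)
  area <- sqrt(sum(cr^2)) / 2
  s * area / npts
}

# closed outward-oriented tetrahedron over a base triangle
tetra_mesh <- function(p1, p2, p3, apex) {
  m <- surface_mesh(rbind(p1, p2, p3, apex),
                    rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4)))
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rel_diff <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
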