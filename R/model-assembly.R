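#' Conductivity compartment
#'
#' One closed conductivity interface together with the conductivities just
#' inside and just outside it (S/m).
#'
#' @param name compartment label.
#' @param mesh a closed, outward-oriented [surface_mesh()].
#' @param sigma_in conductivity just inside the interface (S/m).
#' @param sigma_out conductivity just outside the interface (S/m).
#' @return A `compartment` object.
#' @export
compartment <- function(name, mesh, sigma_in, sigma_out) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (sigma_in < 0 || sigma_out < 0) stop("conductivities must be >= 0")
  if (sigma_in == 0 && sigma_out == 0)
    stop("sigma_in and sigma_out cannot both be zero")
  structure(list(name = name, mesh = mesh,
                 sigma_in = sigma_in, sigma_out = sigma_out),
            class = "compartment")
}

#' Assemble a nested-compartment conductor model
#'
#' Concatenates the facets of all compartments into the global arrays the BEM
#' operator works on, and computes per-facet conductivity contrast
#' `K = (sigma_in - sigma_out) / (sigma_in + sigma_out)` and jump
#' `sigma_in - sigma_out`. Facet indexing is stable: compartment order, then
#' facet order within each compartment.
#'
#' @param compartments list of [compartment()] objects (outermost first by
#'   convention; any order is accepted).
#' @return A `head_model`: compartments plus concatenated `vertices`, `faces`,
#'   `centroids`, `areas`, `normals`, `K`, `jump`, `facet_compartment`, and
#'   the global average edge length `avg_edge`.
#' @export
assemble <- function(compartments) {
  if (inherits(compartments, "compartment")) compartments <- list(compartments)
  stopifnot(length(compartments) >= 1)
  verts <- list(); faces <- list(); geom <- list()
  K <- list(); jump <- list(); fc <- list()
  off <- 0L
  for (i in seq_along(compartments)) {
    cp <- compartments[[i]]
    stopifnot(inherits(cp, "compartment"))
    wt <- check_watertight(cp$mesh)
    if (!wt$watertight)
      stop("compartment '", cp$name, "' is not watertight")
    if (signed_volume(cp$mesh) <= 0)
      stop("compartment '", cp$name, "' is not outward-oriented")
    g <- compute_geometry(cp$mesh)
    nf <- nrow(cp$mesh$faces)
    verts[[i]] <- cp$mesh$vertices
    faces[[i]] <- cp$mesh$faces + off
    off <- off + nrow(cp$mesh$vertices)
    geom[[i]] <- g
    Ki <- (cp$sigma_in - cp$sigma_out) / (cp$sigma_in + cp$sigma_out)
    K[[i]] <- rep(Ki, nf)
    jump[[i]] <- rep(cp$sigma_in - cp$sigma_out, nf)
    fc[[i]] <- rep(i, nf)
  }
  el <- vapply(geom, `[[`, numeric(1), "avg_edge")
  nf_each <- vapply(compartments, function(cp) nrow(cp$mesh$faces), integer(1))
  structure(list(
    compartments = compartments,
    vertices = do.call(rbind, verts),
    faces = do.call(rbind, faces),
    centroids = do.call(rbind, lapply(geom, `[[`, "centroids")),
    areas = unlist(lapply(geom, `[[`, "areas")),
    normals = do.call(rbind, lapply(geom, `[[`, "normals")),
    K = unlist(K),
    jump = unlist(jump),
    facet_compartment = unlist(fc),
    n_facets = sum(nf_each),
    facets_per_compartment = nf_each,
    avg_edge = sum(el * nf_each) / sum(nf_each)
  ), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("head_model: %d compartments, %d facets, avg edge %.2f mm\n",
              length(x$compartments), x$n_facets, 1e3 * x$avg_edge))
  for (i in seq_along(x$compartments)) {
    cp <- x$compartments[[i]]
    cat(sprintf("  %-8s %6d facets  sigma_in %.3f  sigma_out %.3f  K %+.3f\n",
                cp$name, nrow(cp$mesh$faces), cp$sigma_in, cp$sigma_out,
                (cp$sigma_in - cp$sigma_out) / (cp$sigma_in + cp$sigma_out)))
  }
  invisible(x)
}

#' Concentric-sphere model specification
#'
#' @param radii interface radii in meters, outer to inner, strictly
#'   decreasing.
#' @param sigma_in,sigma_out per-interface conductivities (S/m), same order.
#' @param edge_length target average edge length (m).
#' @param center sphere center.
#' @param names interface labels.
#' @param facet_cap refuse specs implying more facets than this.
#' @return A `sphere_spec` list.
#' @export
sphere_spec <- function(radii, sigma_in, sigma_out, edge_length,
                        center = c(0, 0, 0),
                        names = paste0("shell", seq_along(radii)),
                        facet_cap = 2e6) {
  stopifnot(length(radii) == length(sigma_in),
            length(radii) == length(sigma_out))
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  structure(list(radii = radii, sigma_in = sigma_in, sigma_out = sigma_out,
                 edge_length = edge_length, center = center, names = names,
                 facet_cap = facet_cap),
            class = "sphere_spec")
}

#' Four-layer sphere fixture specification
#'
#' The concentric skin/skull/CSF/brain validation model: interface radii
#' 92/86/80/78 mm (2 mm CSF-brain gap) and SimNIBS conductivities
#' skin 0.465, skull 0.010, CSF 1.654, brain 0.275 S/m, air outside.
#'
#' @param edge_length target average edge length (m); default 8.5 mm puts the
#'   fixture at the coarse end of the resolution family.
#' @return A [sphere_spec()].
#' @export
four_layer_sphere_spec <- function(edge_length = 0.0085) {
  sigma <- c(skin = 0.465, skull = 0.010, csf = 1.654, brain = 0.275)
  sphere_spec(radii = c(0.092, 0.086, 0.080, 0.078),
              sigma_in = c(sigma[["skin"]], sigma[["skull"]], sigma[["csf"]],
                           sigma[["brain"]]),
              sigma_out = c(0, sigma[["skin"]], sigma[["skull"]],
                            sigma[["csf"]]),
              edge_length = edge_length,
              names = c("skin", "skull", "csf", "brain"))
}

#' Generate concentric icosphere shells
#'
#' Each shell is an icosphere whose per-edge subdivision order is chosen so
#' the measured average edge length is within 15 % of the target; vertices
#' lie exactly at the nominal radius.
#'
#' @param spec a [sphere_spec()].
#' @return List of [compartment()] objects, same order as `spec$radii`.
#' @export
generate_sphere_shells <- function(spec) {
  stopifnot(inherits(spec, "sphere_spec"))
  lapply(seq_along(spec$radii), function(i) {
    r <- spec$radii[i]
    ## icosahedron edge for unit circumradius is ~1.0515; projection shrinks
    ## interior edges slightly, so search around the nominal k
    k0 <- max(1L, as.integer(round(1.0515 * r / spec$edge_length)))
    best <- NULL
    for (k in unique(pmax(1L, k0 + (-1:1)))) {
      if (20 * k^2 > spec$facet_cap)
        stop("target edge length implies more than facet_cap facets")
      mesh <- icosphere(r, k, spec$center)
      ae <- compute_geometry(mesh)$avg_edge
      err <- abs(ae - spec$edge_length) / spec$edge_length
      if (is.null(best) || err < best$err) best <- list(mesh = mesh, err = err)
    }
    if (best$err > 0.15)
      warning(sprintf("shell %d: achieved edge length misses target by %.0f%%",
                      i, 100 * best$err))
    compartment(spec$names[i], best$mesh, spec$sigma_in[i], spec$sigma_out[i])
  })
}

#' Outward area-weighted vertex normals
#'
#' @param mesh a [surface_mesh()].
#' @return An n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  g <- compute_geometry(mesh)
  wn <- g$normals * g$areas
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- tapply(wn[, k], mesh$faces[, j], sum)
      idx <- as.integer(names(acc))
      n[idx, k] <- n[idx, k] + acc
    }
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Offset observation surface
#'
#' Displaces every vertex of a closed mesh along its outward vertex normal,
#' e.g. the MEG observation shell 10 mm outside the skin.
#'
#' @param mesh a closed [surface_mesh()].
#' @param distance offset distance in meters (>= 0).
#' @return An n x 3 matrix of observation points.
#' @export
offset_observation_surface <- function(mesh, distance) {
  if (distance < 0) stop("distance must be >= 0")
  mesh$vertices + distance * vertex_normals(mesh)
}
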