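#' Triangulated closed surface mesh
#'
#' A `surface_mesh` stores vertex coordinates (meters) and triangular facets.
#' Facets are 1-based vertex-index triples wound counter-clockwise when viewed
#' from outside, so the geometric facet normal points outward and the signed
#' enclosed volume of a closed mesh is positive.
#'
#' @param vertices numeric matrix, one vertex per row (x, y, z in meters).
#' @param faces integer matrix, one facet per row (three 1-based vertex ids).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) stop("empty mesh: no facets")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  rng <- range(faces)
  if (rng[1] < 1L || rng[2] > nrow(vertices)) stop("facet vertex index out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
    stop("facet references a repeated vertex")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d facets\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Per-facet geometry
#'
#' Facet areas (half cross-product magnitude), centroids (vertex means), unit
#' outward normals (normalized cross product in winding order), and the mesh
#' average edge length.
#'
#' @param mesh a [surface_mesh()].
#' @return A `facet_geometry` list with `areas`, `centroids`, `normals`,
#'   `avg_edge`.
#' @export
compute_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cn <- sqrt(rowSums(cr^2))
  areas <- cn / 2
  if (any(areas <= 0 | !is.finite(areas))) {
    bad <- which(areas <= 0 | !is.finite(areas))[1]
    stop(sprintf("degenerate (zero-area) facet at index %d", bad))
  }
  normals <- cr / cn
  centroids <- (p1 + p2 + p3) / 3
  el <- c(sqrt(rowSums((p2 - p1)^2)),
          sqrt(rowSums((p3 - p2)^2)),
          sqrt(rowSums((p1 - p3)^2)))
  structure(list(areas = areas, centroids = centroids, normals = normals,
                 avg_edge = mean(el)),
            class = "facet_geometry")
}

#' Signed enclosed volume of a closed mesh
#'
#' Positive for outward-oriented closed surfaces (divergence theorem on the
#' tetrahedra spanned by the origin and each facet).
#'
#' @param mesh a [surface_mesh()].
#' @return Signed volume in cubic meters.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
        p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
        p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# Directed edge table: rows (from, to) for the 3 edges of every facet in
# winding order. Row block f, f+m, f+2m belongs to facet f.
directed_edges <- function(faces) {
  rbind(cbind(faces[, 1], faces[, 2]),
        cbind(faces[, 2], faces[, 3]),
        cbind(faces[, 3], faces[, 1]))
}

edge_key <- function(e) {
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Watertightness / manifoldness audit
#'
#' A closed oriented (watertight) mesh has every undirected edge shared by
#' exactly two facets that traverse it in opposite directions. Report-only:
#' never throws.
#'
#' @param mesh a [surface_mesh()].
#' @return List with `watertight` (logical), `boundary_edges` (undirected
#'   edges with one incident facet), `nonmanifold_edges` (more than two), and
#'   `misoriented_edges` (two incident facets traversing in the same
#'   direction).
#' @export
check_watertight <- function(mesh) {
  de <- directed_edges(mesh$faces)
  key <- edge_key(de)
  cnt <- table(key)
  bad1 <- names(cnt)[cnt == 1]
  badm <- names(cnt)[cnt > 2]
  ## among edges seen exactly twice, both traversals must be opposite:
  ## directed duplicates indicate inconsistent winding
  dkey <- paste(de[, 1], de[, 2])
  ddup <- unique(dkey[duplicated(dkey)])
  two <- names(cnt)[cnt == 2]
  mis <- intersect(two, edge_key(do.call(rbind, lapply(
    strsplit(ddup, " "), function(s) matrix(as.integer(s), 1)))))
  if (length(ddup) == 0) mis <- character(0)
  parse_edges <- function(k) {
    if (length(k) == 0) return(matrix(integer(0), 0, 2))
    do.call(rbind, lapply(strsplit(k, " "), as.integer))
  }
  list(watertight = length(bad1) == 0 && length(badm) == 0 && length(mis) == 0,
       boundary_edges = parse_edges(bad1),
       nonmanifold_edges = parse_edges(badm),
       misoriented_edges = parse_edges(mis))
}

#' 4:1 barycentric subdivision with border closure
#'
#' Each selected facet is split into four congruent children through its edge
#' midpoints (children have exactly a quarter of the parent area). Unselected
#' facets that acquire exactly one hanging midpoint are bisected through that
#' midpoint and the opposite vertex; facets acquiring two or three hanging
#' midpoints are promoted to a full 4:1 split (closure rule), which keeps the
#' result watertight with bounded aspect ratios.
#'
#' @param mesh a closed [surface_mesh()].
#' @param facet_ids integer vector of facet indices to split.
#' @return A `refinement_result`: `mesh` (new [surface_mesh()]), `parent`
#'   (integer vector mapping each new facet to its originating facet), and
#'   `new_vertices` (indices of vertices created by the split).
#' @export
subdivide_4to1 <- function(mesh, facet_ids) {
  facet_ids <- unique(as.integer(facet_ids))
  m <- nrow(mesh$faces)
  if (length(facet_ids) > 0 && (min(facet_ids) < 1 || max(facet_ids) > m))
    stop("facet id out of range")
  wt <- check_watertight(mesh)
  if (!wt$watertight) stop("subdivide_4to1 requires a watertight mesh")
  if (length(facet_ids) == 0) {
    return(structure(list(mesh = mesh, parent = seq_len(m),
                          new_vertices = integer(0)),
                     class = "refinement_result"))
  }
  f <- mesh$faces
  fkey <- function(ids) {
    ## per-facet edge keys as m x 3 matrix
    cbind(paste(pmin(f[ids, 1], f[ids, 2]), pmax(f[ids, 1], f[ids, 2])),
          paste(pmin(f[ids, 2], f[ids, 3]), pmax(f[ids, 2], f[ids, 3])),
          paste(pmin(f[ids, 3], f[ids, 1]), pmax(f[ids, 3], f[ids, 1])))
  }
  allkeys <- fkey(seq_len(m))
  sel <- rep(FALSE, m)
  sel[facet_ids] <- TRUE
  split_edges <- unique(as.vector(allkeys[sel, , drop = FALSE]))
  ## closure: promote facets with >= 2 hanging midpoints until stable
  repeat {
    nsplit <- matrix(allkeys %in% split_edges, nrow = m)
    cnt <- rowSums(nsplit)
    promote <- which(!sel & cnt >= 2)
    if (length(promote) == 0) break
    sel[promote] <- TRUE
    split_edges <- unique(c(split_edges,
                            as.vector(allkeys[promote, , drop = FALSE])))
  }
  ## midpoint vertex for every split edge
  ep <- do.call(rbind, lapply(strsplit(split_edges, " "), as.integer))
  mid <- (mesh$vertices[ep[, 1], , drop = FALSE] +
            mesh$vertices[ep[, 2], , drop = FALSE]) / 2
  nv0 <- nrow(mesh$vertices)
  midx <- nv0 + seq_len(nrow(ep))
  names(midx) <- split_edges
  verts <- rbind(mesh$vertices, mid)

  faces_out <- vector("list", m)
  parent_out <- vector("list", m)
  for (i in seq_len(m)) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    ks <- allkeys[i, ]
    hit <- ks %in% split_edges
    if (sel[i]) {
      mab <- midx[[ks[1]]]; mbc <- midx[[ks[2]]]; mca <- midx[[ks[3]]]
      faces_out[[i]] <- rbind(c(a, mab, mca), c(mab, b, mbc),
                              c(mca, mbc, cc), c(mab, mbc, mca))
      parent_out[[i]] <- rep(i, 4L)
    } else if (sum(hit) == 1) {
      e <- which(hit)
      mm <- midx[[ks[e]]]
      ## bisect through the hanging midpoint and the opposite vertex
      tri <- switch(e,
                    rbind(c(a, mm, cc), c(mm, b, cc)),   # edge a-b, opposite cc
                    rbind(c(b, mm, a), c(mm, cc, a)),    # edge b-c, opposite a
                    rbind(c(cc, mm, b), c(mm, a, b)))    # edge c-a, opposite b
      faces_out[[i]] <- tri
      parent_out[[i]] <- rep(i, 2L)
    } else {
      faces_out[[i]] <- f[i, , drop = FALSE]
      parent_out[[i]] <- i
    }
  }
  out <- surface_mesh(verts, do.call(rbind, faces_out))
  structure(list(mesh = out, parent = unlist(parent_out),
                 new_vertices = as.integer(midx)),
            class = "refinement_result")
}

# vertex -> neighboring-vertex adjacency list from the undirected edge set
vertex_adjacency <- function(mesh) {
  de <- directed_edges(mesh$faces)
  split(de[, 2], de[, 1])
}

#' Taubin smoothing on a vertex subset
#'
#' Two-factor umbrella-Laplacian smoothing: each pass moves the selected
#' vertices once with the positive (inflate-direction) factor and once with
#' the negative factor. With factors (+0.60, -0.62) this suppresses the
#' faceting introduced by barycentric subdivision while avoiding global
#' shrinkage. Only vertices in `vertex_ids` move; their neighborhoods are
#' read from the full mesh.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex_ids vertices allowed to move.
#' @param passes number of (+, -) pass pairs; 0 returns the mesh unchanged.
#' @param shrink_factor negative factor (default -0.62).
#' @param inflate_factor positive factor, applied first (default +0.60);
#'   Taubin stability needs `|shrink_factor| > inflate_factor`.
#' @return The smoothed [surface_mesh()].
#' @export
taubin_smooth <- function(mesh, vertex_ids, passes = 1,
                          shrink_factor = -0.62, inflate_factor = 0.60) {
  vertex_ids <- unique(as.integer(vertex_ids))
  if (length(vertex_ids) == 0 || passes == 0) return(mesh)
  if (min(vertex_ids) < 1 || max(vertex_ids) > nrow(mesh$vertices))
    stop("vertex id out of range")
  if (!(inflate_factor > 0 && shrink_factor < 0 &&
          abs(shrink_factor) > inflate_factor))
    stop("factors must satisfy inflate > 0, shrink < 0, |shrink| > inflate")
  adj <- vertex_adjacency(mesh)
  v <- mesh$vertices
  nbrs <- adj[as.character(vertex_ids)]
  step <- function(v, lambda) {
    mv <- t(vapply(nbrs, function(nb) colMeans(v[nb, , drop = FALSE]),
                   numeric(3)))
    v[vertex_ids, ] <- v[vertex_ids, , drop = FALSE] +
      lambda * (mv - v[vertex_ids, , drop = FALSE])
    v
  }
  for (p in seq_len(passes)) {
    v <- step(v, inflate_factor)
    v <- step(v, shrink_factor)
  }
  surface_mesh(v, mesh$faces)
}

#' Icosphere generator
#'
#' Subdivides each icosahedron face into `k^2` congruent triangles and
#' projects all vertices exactly onto the sphere, giving `20 * k^2` facets.
#' Arbitrary `k` (not only powers of two) lets a target edge length be hit
#' closely.
#'
#' @param radius sphere radius (m).
#' @param k per-edge subdivision order (k = 1 is the raw icosahedron).
#' @param center sphere center (length-3, m).
#' @return A watertight, outward-oriented [surface_mesh()] whose vertices all
#'   lie exactly at `radius` from `center`.
#' @export
icosphere <- function(radius = 1, k = 1, center = c(0, 0, 0)) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (k > 1) {
    ## barycentric k-section of each face with shared lattice points de-duped
    key_env <- new.env(hash = TRUE)
    verts <- list()
    nvert <- 0L
    get_pt <- function(fi, i, j, p1, p2, p3) {
      ## lattice point (i, j) on face fi; key by rounded coordinates so
      ## points shared across faces (edges/corners) merge
      p <- ((k - i - j) * p1 + i * p2 + j * p3) / k
      p <- p / sqrt(sum(p^2))
      kk <- paste(round(p * 1e12), collapse = " ")
      id <- key_env[[kk]]
      if (is.null(id)) {
        nvert <<- nvert + 1L
        verts[[nvert]] <<- p
        id <- nvert
        key_env[[kk]] <- id
      }
      id
    }
    faces <- list()
    nf <- 0L
    for (fi in seq_len(nrow(f))) {
      p1 <- v[f[fi, 1], ]; p2 <- v[f[fi, 2], ]; p3 <- v[f[fi, 3], ]
      idx <- matrix(0L, k + 1, k + 1)
      for (i in 0:k) for (j in 0:(k - i))
        idx[i + 1, j + 1] <- get_pt(fi, i, j, p1, p2, p3)
      for (i in 0:(k - 1)) for (j in 0:(k - 1 - i)) {
        nf <- nf + 1L
        faces[[nf]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 1], idx[i + 1, j + 2])
        if (j < k - 1 - i) {
          nf <- nf + 1L
          faces[[nf]] <- c(idx[i + 2, j + 1], idx[i + 2, j + 2], idx[i + 1, j + 2])
        }
      }
    }
    v <- do.call(rbind, verts)
    f <- do.call(rbind, faces)
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  mesh <- surface_mesh(v, f)
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}
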