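#' Read a triangulated surface from STL, OFF or PLY
#'
#' STL (both ASCII and binary dialects), OFF, and ASCII PLY are supported.
#' Coordinates are multiplied by `unit_scale` to give meters; surface files
#' are assumed to be in millimeters by default. STL stores a triangle soup,
#' so vertices closer than 1e-9 m after scaling are merged to recover
#' connectivity; OFF/PLY vertices are merged with the same tolerance.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"off"`, `"ply"`; default guesses from the
#'   file extension.
#' @param unit_scale factor converting file units to meters (default 1e-3).
#' @return A [surface_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "stl", "off", "ply"),
                         unit_scale = 1e-3) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "off", "ply"))
      stop("cannot guess mesh format from extension: ", ext)
    format <- ext
  }
  mesh <- switch(format,
                 stl = read_stl(path),
                 off = read_off(path),
                 ply = read_ply(path))
  if (nrow(mesh$faces) == 0L) stop("empty mesh: no facets in ", path)
  mesh$vertices <- mesh$vertices * unit_scale
  merge_duplicate_vertices(mesh, tol = 1e-9)
}

#' Write a triangulated surface to STL, OFF or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"stl"` (ASCII), `"stl_binary"`, `"off"`, or `"ply"`.
#' @param unit_scale factor converting meters to file units (default 1e3,
#'   i.e. files are written in millimeters, matching [read_surface()]).
#' @return Invisibly, `path`.
#' @export
write_surface <- function(mesh, path,
                          format = c("stl", "stl_binary", "off", "ply"),
                          unit_scale = 1e3) {
  format <- match.arg(format)
  v <- mesh$vertices * unit_scale
  f <- mesh$faces
  switch(format,
         stl = write_stl_ascii(v, f, path),
         stl_binary = write_stl_binary(v, f, path),
         off = write_off(v, f, path),
         ply = write_ply(v, f, path))
  invisible(path)
}

merge_duplicate_vertices <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  newid <- match(key, key[first])   # original index -> kept-vertex index
  surface_mesh(v[first, , drop = FALSE],
               matrix(newid[mesh$faces], ncol = 3))
}

is_binary_stl <- function(path) {
  head <- readBin(path, "raw", n = 512)
  ## keep printable ASCII only: binary records would otherwise trip the
  ## string translation
  keep <- (head >= as.raw(32) & head <= as.raw(126)) | head == as.raw(10)
  txt <- rawToChar(head[keep])
  !(grepl("^\\s*solid", txt) && grepl("facet", txt, fixed = TRUE))
}

read_stl <- function(path) {
  if (is_binary_stl(path)) return(read_stl_binary(path))
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("unparseable ASCII STL: ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, nums)
  if (any(!is.finite(v))) stop("unparseable ASCII STL: ", path)
  surface_mesh(v, matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!length(ntri) || ntri <= 0) stop("unparseable binary STL: ", path)
  rec <- readBin(con, "raw", n = ntri * 50)
  if (length(rec) < ntri * 50) stop("truncated binary STL: ", path)
  rec <- matrix(rec, nrow = 50)
  coords <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12 * ntri, size = 4,
                    endian = "little")
  coords <- matrix(coords, nrow = 12)           # per-tri: normal + 3 vertices
  v <- matrix(as.vector(coords[4:12, ]), ncol = 3, byrow = TRUE)
  surface_mesh(v, matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE))
}

write_stl_ascii <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  fmt <- function(p) sprintf("%.12g %.12g %.12g", p[, 1], p[, 2], p[, 3])
  block <- paste0("facet normal ", fmt(n), "\n outer loop\n  vertex ",
                  fmt(p1), "\n  vertex ", fmt(p2), "\n  vertex ", fmt(p3),
                  "\n endloop\nendfacet")
  writeLines(block, con)
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(v, f, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(n[i, ], p1[i, ], p2[i, ], p3[i, ])), con,
             size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF") stop("unparseable OFF: ", path)
  hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  v <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  fl <- strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+")
  f <- do.call(rbind, lapply(fl, function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("OFF reader supports triangles only")
    x[2:4] + 1L
  }))
  surface_mesh(v, f)
}

write_off <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1]) != "ply") stop("unparseable PLY: ", path)
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
  endh <- which(trimws(lines) == "end_header")[1]
  ev <- grep("^element vertex", lines[1:endh], value = TRUE)
  ef <- grep("^element face", lines[1:endh], value = TRUE)
  if (!length(ev) || !length(ef)) stop("unparseable PLY header: ", path)
  nv <- as.integer(strsplit(trimws(ev), "\\s+")[[1]][3])
  nf <- as.integer(strsplit(trimws(ef), "\\s+")[[1]][3])
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  v <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(body[(nv + 1):(nv + nf)]), "\\s+"),
                             function(x) {
                               x <- as.integer(x)
                               if (x[1] != 3L) stop("PLY reader supports triangles only")
                               x[2:4] + 1L
                             }))
  surface_mesh(v, f)
}

write_ply <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}
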