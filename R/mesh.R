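#' Triangulated surface meshes
#'
#' Minimal triangle-mesh container used to ingest deposited surface meshes
#' (STL, PLY) and to export labelled surfaces. Vertex coordinates are in um.
#'
#' @param vertices Numeric n x 3 matrix (um).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `vt_mesh`.
#' @export
vt_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3")
  if (nrow(faces) == 0L) stop("empty mesh")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "vt_mesh")
}

#' @export
print.vt_mesh <- function(x, ...) {
  cat(sprintf("<vt_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox (um): [%g, %g] x [%g, %g] x [%g, %g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  watertight: %s\n", is_watertight(x)))
  invisible(x)
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' triangles with opposite orientation (each directed edge appears once).
#'
#' @param mesh A [vt_mesh].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
              cbind(f[, 3], f[, 1]))
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  !anyDuplicated(key) && all(rkey %in% key)
}

#' Read a surface mesh (STL or PLY)
#'
#' STL is detected as binary or ASCII automatically; duplicate vertices are
#' merged so that topological checks (watertightness) are meaningful.
#' PLY support covers ASCII files with x/y/z vertex properties and
#' triangular faces.
#'
#' @param path Path to an `.stl` or `.ply` file.
#' @return A [vt_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop("unknown mesh format: .", ext))
}

#' Write a surface mesh
#'
#' `.stl` writes ASCII STL; `.ply` writes ASCII PLY, with an integer
#' per-face `label` property when `face_labels` is given (used to export
#' cluster / order color-mappings).
#'
#' @param mesh A [vt_mesh].
#' @param path Output path.
#' @param face_labels Optional integer vector, one label per face (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, face_labels = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = write_stl(mesh, path),
    ply = write_ply(mesh, path, face_labels),
    stop("unknown mesh format: .", ext))
  invisible(path)
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 84)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") && {
    txt <- tryCatch(readLines(path, n = 3, warn = FALSE),
                    error = function(e) "")
    any(grepl("facet", txt))
  }
  tri <- if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    vals <- lapply(strsplit(trimws(vlines), "\\s+"),
                   function(p) as.numeric(p[2:4]))
    do.call(rbind, vals)
  } else {
    ntri <- readBin(hdr[81:84], "integer", size = 4, endian = "little")
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 84)
    out <- matrix(0, nrow = 3 * ntri, ncol = 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "double", n = 12, size = 4, endian = "little")
      out[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], ncol = 3, byrow = TRUE)
      readBin(con, "raw", n = 2)
    }
    out
  }
  if (is.null(tri) || nrow(tri) == 0L || nrow(tri) %% 3 != 0)
    stop("malformed STL: ", path)
  # merge identical vertices
  key <- apply(tri, 1, function(v) paste(sprintf("%.9g", v), collapse = "_"))
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  vt_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vasctree", con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    a <- v[f[1], ]; b <- v[f[2], ]; cc <- v[f[3], ]
    nrm <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
             (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
             (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", cc[1], cc[2], cc[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid vasctree", con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply" || !any(grepl("format ascii", lines)))
    stop("only ASCII PLY is supported")
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(fparts, function(p) {
    if (as.integer(p[1]) != 3L) stop("only triangular PLY faces supported")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  vt_mesh(verts, faces)
}

write_ply <- function(mesh, path, face_labels = NULL) {
  nf <- nrow(mesh$faces)
  if (!is.null(face_labels) && length(face_labels) != nf)
    stop("`face_labels` must have one label per face")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment vasctree surface",
    paste("element vertex", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    if (!is.null(face_labels)) "property int label",
    "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (is.null(face_labels)) {
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  } else {
    writeLines(sprintf("3 %d %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L,
                       as.integer(face_labels)), con)
  }
}

#' Voxelize a watertight surface mesh
#'
#' A voxel becomes vessel iff its center lies inside the closed surface
#' (parity ray casting). The grid covers the mesh bounding box padded by one
#' voxel on every side.
#'
#' @param mesh A watertight [vt_mesh].
#' @param spacing Length-3 (or scalar) voxel spacing, um.
#' @return A binary mask [vt_volume].
#' @export
voxelize_mesh <- function(mesh, spacing) {
  if (!inherits(mesh, "vt_mesh")) stop("`mesh` must be a vt_mesh")
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 2L
  origin <- lo - 0.5 * spacing
  res <- cpp_voxelize_mesh(mesh$vertices, mesh$faces - 1L,
                           dims, spacing, origin)
  vt_volume(array(res, dim = dims), spacing, origin)
}

#' Synthetic geometry: axis-aligned box mesh
#'
#' @param center Length-3 center (um).
#' @param size Length-3 (or scalar) edge lengths (um).
#' @return A watertight [vt_mesh] with 12 triangles.
#' @export
mesh_box <- function(center = c(0, 0, 0), size = c(1, 1, 1)) {
  if (length(size) == 1L) size <- rep(size, 3)
  h <- size / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(sweep(as.matrix(s), 2, h, "*"), 2, center, "+")
  # outward-oriented triangles over the 8 corner vertices
  f <- rbind(c(1, 3, 2), c(2, 3, 4),  # z-
             c(5, 6, 7), c(6, 8, 7),  # z+
             c(1, 2, 5), c(2, 6, 5),  # y-
             c(3, 7, 4), c(4, 7, 8),  # y+
             c(1, 5, 3), c(3, 5, 7),  # x-
             c(2, 4, 6), c(4, 8, 6))  # x+
  vt_mesh(v, f)
}

#' Synthetic geometry: icosphere mesh
#'
#' Subdivided icosahedron projected onto the sphere; watertight at every
#' subdivision level.
#'
#' @param center Length-3 center (um).
#' @param radius Sphere radius (um).
#' @param subdiv Number of subdivision rounds (>= 0).
#' @return A watertight [vt_mesh].
#' @export
mesh_sphere <- function(center = c(0, 0, 0), radius = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  vt_mesh(v, f)
}
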