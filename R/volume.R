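#' 3D volume with physical voxel spacing
#'
#' Container for a 3-D scalar grid (greyscale intensity or binary mask) with
#' anisotropic physical voxel spacing. Data are stored as a native R array
#' indexed `[x, y, z]` (1-based, column-major); the physical position of the
#' center of voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`.
#' All lengths are micrometres.
#'
#' A *mask* is simply a `vt_volume` whose data array is `logical`
#' (`TRUE` = vessel, `FALSE` = background), defined on the same grid as its
#' source volume.
#'
#' @param data 3-D numeric or logical array.
#' @param spacing Numeric length-3, physical voxel edge lengths in um
#'   (x, y, z); all components must be positive.
#' @param origin Numeric length-3, physical coordinate (um) of the center of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `vt_volume`.
#' @examples
#' v <- vt_volume(array(0, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume(v)  # 8 um^3
#' @export
vt_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (um)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (um)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vt_volume")
}

#' @export
print.vt_volume <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (is.logical(x$data)) "mask" else "greyscale"
  cat(sprintf("<vt_volume> %s, %d x %d x %d voxels\n", kind, d[1], d[2], d[3]))
  cat(sprintf("  spacing  %g x %g x %g um\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin   (%g, %g, %g) um\n",
              x$origin[1], x$origin[2], x$origin[3]))
  if (is.logical(x$data)) {
    cat(sprintf("  vessel voxels: %d (%.2f%%)\n", sum(x$data),
                100 * mean(x$data)))
  } else {
    r <- range(x$data, finite = TRUE)
    cat(sprintf("  intensity range: [%g, %g]\n", r[1], r[2]))
  }
  invisible(x)
}

#' @rdname vt_volume
#' @param x A `vt_volume`.
#' @export
is_vt_volume <- function(x) inherits(x, "vt_volume")

#' @rdname vt_volume
#' @export
voxel_volume <- function(x) {
  stopifnot(is_vt_volume(x))
  prod(x$spacing)
}

as_mask <- function(x) {
  stopifnot(is_vt_volume(x))
  if (!is.logical(x$data)) stop("expected a binary mask (logical data)")
  x
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

# ---------------------------------------------------------------------------
# File formats. NRRD and MetaImage (MHA) carry spacing/origin natively and
# round-trip lossless raw doubles; TIFF stacks carry no spacing metadata, so
# reading a TIFF requires `spacing_override`.
# ---------------------------------------------------------------------------

#' Read a volume from disk
#'
#' Supported formats: NRRD (`.nrrd`), MetaImage (`.mha`), and TIFF stacks
#' (`.tif`/`.tiff`, one slice per directory entry). NRRD/MHA spacing and
#' origin metadata are honored; TIFF has no spacing metadata, so
#' `spacing_override` is mandatory for TIFF input.
#'
#' @param path Path to the file.
#' @param spacing_override Optional length-3 numeric (um) overriding any
#'   spacing metadata in the file.
#' @return A [vt_volume].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vol <- switch(ext,
    nrrd = read_nrrd(path),
    mha = read_mha(path),
    tif = ,
    tiff = read_tiff_stack(path),
    stop("unknown volume format: .", ext,
         " (supported: .nrrd, .mha, .tif/.tiff)"))
  if (!is.null(spacing_override)) {
    spacing_override <- as.numeric(spacing_override)
    if (length(spacing_override) != 3L || any(spacing_override <= 0))
      stop("`spacing_override` must be 3 positive numbers (um)")
    vol$spacing <- spacing_override
  }
  if (is.null(vol$spacing))
    stop("file carries no spacing metadata; supply `spacing_override`")
  vt_volume(vol$data, vol$spacing, vol$origin %||% c(0, 0, 0))
}

#' Write a volume to disk
#'
#' The format is chosen from the file extension (see [read_volume]). NRRD
#' and MHA preserve data, spacing and origin bit-exactly (doubles, or bytes
#' for logical masks); TIFF stores 32-bit float slices and no spacing.
#'
#' @param vol A [vt_volume].
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_vt_volume(vol))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = write_nrrd(vol, path),
    mha = write_mha(vol, path),
    tif = ,
    tiff = write_tiff_stack(vol, path),
    stop("unknown volume format: .", ext))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not a NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- sub("^([^:]+):=?\\s*(.*)$", "\\1\x01\\2", line)
    parts <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
    hdr[[tolower(trimws(parts[1]))]] <- trimws(parts[2])
  }
  sizes <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD volumes are supported")
  type <- hdr$type
  enc <- hdr$encoding %||% "raw"
  if (enc != "raw") stop("only raw-encoded NRRD is supported")
  n <- prod(sizes)
  data <- switch(type,
    double = readBin(con, "double", n, size = 8, endian = "little"),
    float = readBin(con, "double", n, size = 4, endian = "little"),
    int = ,
    int32 = readBin(con, "integer", n, size = 4, endian = "little"),
    uchar = ,
    uint8 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                               endian = "little")),
    stop("unsupported NRRD type: ", type))
  spacing <- NULL
  if (!is.null(hdr$`space directions`)) {
    vecs <- regmatches(hdr$`space directions`,
                       gregexpr("\\(([^)]*)\\)", hdr$`space directions`))[[1]]
    mat <- t(vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3)))
    spacing <- sqrt(rowSums(mat^2))
  } else if (!is.null(hdr$spacings)) {
    spacing <- as.numeric(strsplit(hdr$spacings, "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(hdr$`space origin`))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr$`space origin`),
                                  ",")[[1]])
  arr <- array(data, dim = sizes)
  if (identical(hdr$`vasctree logical`, "1")) arr <- array(arr > 0.5, dim = sizes)
  list(data = arr, spacing = spacing, origin = origin)
}

write_nrrd <- function(vol, path) {
  logical_data <- is.logical(vol$data)
  int_data <- is.integer(vol$data)
  type <- if (logical_data) "uint8" else if (int_data) "int32" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$data)
  hdr <- c(
    "NRRD0004",
    "# vasctree volume",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    if (logical_data) "vasctree logical:=1",
    "")
  writeLines(hdr, con)
  if (logical_data) {
    writeBin(as.integer(vol$data), con, size = 1, endian = "little")
  } else if (int_data) {
    writeBin(as.vector(vol$data), con, size = 4, endian = "little")
  } else {
    writeBin(as.vector(vol$data), con, size = 8, endian = "little")
  }
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of MHA header")
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only MHA with ElementDataFile = LOCAL is supported")
  sizes <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  n <- prod(sizes)
  data <- switch(hdr$ElementType,
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1,
                                   signed = FALSE, endian = "little")),
    stop("unsupported MHA ElementType: ", hdr$ElementType))
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else NULL
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  arr <- array(data, dim = sizes)
  if (identical(hdr$VasctreeLogical, "1")) arr <- array(arr > 0.5, dim = sizes)
  list(data = arr, spacing = spacing, origin = origin)
}

write_mha <- function(vol, path) {
  logical_data <- is.logical(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste0("DimSize = ", paste(d, collapse = " ")),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    if (logical_data) "VasctreeLogical = 1",
    paste0("ElementType = ", if (logical_data) "MET_UCHAR" else "MET_DOUBLE"),
    "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (logical_data) {
    writeBin(as.integer(vol$data), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  }
}

read_tiff_stack <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(slices)) slices <- list(slices)
  nz <- length(slices)
  s1 <- slices[[1]]
  if (length(dim(s1)) > 2L) s1 <- s1[, , 1]  # first channel only
  ny <- nrow(s1); nx <- ncol(s1)
  arr <- array(0, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) {
    s <- slices[[z]]
    if (length(dim(s)) > 2L) s <- s[, , 1]
    arr[, , z] <- t(s)
  }
  list(data = arr, spacing = NULL, origin = c(0, 0, 0))
}

write_tiff_stack <- function(vol, path) {
  d <- dim(vol$data)
  dat <- vol$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim = d)
  slices <- lapply(seq_len(d[3]), function(z) t(dat[, , z]))
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
}

#' Resample a volume onto a new voxel spacing
#'
#' Re-grids the volume over the same physical extent. Greyscale volumes are
#' interpolated trilinearly by default; binary masks must use
#' nearest-neighbour ("nearest") to stay two-valued. Down-sampling a mask
#' below the scale of its structures loses them, emulating the resolution /
#' field-of-view trade-off across imaging modalities.
#'
#' @param vol A [vt_volume].
#' @param new_spacing Length-3 positive numeric, target spacing (um).
#' @param mode `"linear"` or `"nearest"`.
#' @return A resampled [vt_volume].
#' @export
resample_volume <- function(vol, new_spacing,
                            mode = c("linear", "nearest")) {
  stopifnot(is_vt_volume(vol))
  mode <- match.arg(mode)
  new_spacing <- as.numeric(new_spacing)
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 3)
  if (length(new_spacing) != 3L || any(new_spacing <= 0))
    stop("`new_spacing` must be positive (um)")
  logical_data <- is.logical(vol$data)
  if (logical_data && mode == "linear")
    stop("binary masks must be resampled with mode = \"nearest\"")
  d <- dim(vol$data)
  if (isTRUE(all.equal(new_spacing, vol$spacing))) return(vol)
  extent <- d * vol$spacing
  new_dim <- pmax(1L, as.integer(round(extent / new_spacing)))
  ratio <- new_spacing / vol$spacing
  dat <- if (logical_data) array(as.numeric(vol$data), dim = d) else vol$data
  res <- cpp_resample(as.numeric(dat), as.integer(d), new_dim, ratio,
                      if (mode == "nearest") 0L else 1L)
  arr <- array(res, dim = new_dim)
  if (logical_data) arr <- array(arr > 0.5, dim = new_dim)
  start <- vol$origin - 0.5 * vol$spacing
  vt_volume(arr, new_spacing, start + 0.5 * new_spacing)
}
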