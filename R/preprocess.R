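#' 3x3x3 median filter
#'
#' Noise suppression used before density-based segmentation: each output
#' voxel is the median of its 3x3x3 neighbourhood, with reflected borders.
#' On binary masks the voxelwise median (majority vote) is taken and the
#' result stays logical.
#'
#' @param vol A [vt_volume] with at least 3 voxels per axis.
#' @return A filtered [vt_volume] on the same grid.
#' @export
median_filter3 <- function(vol) {
  stopifnot(is_vt_volume(vol))
  d <- dim(vol$data)
  if (any(d < 3L)) stop("median_filter3 needs >= 3 voxels per axis")
  logical_data <- is.logical(vol$data)
  dat <- if (logical_data) array(as.numeric(vol$data), dim = d) else vol$data
  res <- array(cpp_median3(as.numeric(dat), as.integer(d)), dim = d)
  if (logical_data) res <- array(res > 0.5, dim = d)
  vt_volume(res, vol$spacing, vol$origin)
}

#' Density-based region growing
#'
#' Semiautomatic vessel segmentation: the mask is the set of voxels
#' 26-connected to a seed through voxels whose intensity lies inside the
#' window `[low, high]` (the density window of the radiopaque cast).
#'
#' @param vol A greyscale [vt_volume].
#' @param seeds Integer matrix (n x 3) of 1-based voxel indices (x, y, z),
#'   or a length-3 vector for a single seed.
#' @param low,high Intensity window, `low <= high`; every seed's intensity
#'   must lie inside the window.
#' @return A binary mask [vt_volume].
#' @export
region_grow <- function(vol, seeds, low, high) {
  stopifnot(is_vt_volume(vol))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  seeds <- round(as.matrix(seeds))
  if (ncol(seeds) != 3L) stop("`seeds` must be an n x 3 index matrix")
  if (low > high) stop("`low` must be <= `high`")
  d <- dim(vol$data)
  inside <- seeds[, 1] >= 1 & seeds[, 1] <= d[1] &
    seeds[, 2] >= 1 & seeds[, 2] <= d[2] &
    seeds[, 3] >= 1 & seeds[, 3] <= d[3]
  if (!all(inside)) stop("seed outside the grid")
  lin <- (seeds[, 1] - 1) + d[1] * (seeds[, 2] - 1) +
    d[1] * d[2] * (seeds[, 3] - 1)
  ival <- vol$data[lin + 1]
  if (any(ival < low | ival > high))
    stop("seed intensity outside the window [low, high]")
  res <- cpp_region_grow(as.numeric(vol$data), as.integer(d),
                         as.numeric(lin), low, high)
  vt_volume(array(res, dim = d), vol$spacing, vol$origin)
}

#' Fill cavities and bridge small gaps in a vessel mask
#'
#' Remodels minor discontinuities of a vascular cast: morphological closing
#' with a ball of radius `max_gap / 2` bridges gaps up to `max_gap` wide,
#' and interior cavities (background fully enclosed by vessel,
#' 6-connectivity) are filled. The two steps are iterated to a fixed point,
#' so the operation is extensive (output contains the input) and idempotent.
#'
#' @param mask A binary mask [vt_volume].
#' @param max_gap Largest gap to bridge, um (>= 0). The default closes gaps
#'   up to 3 voxels wide.
#' @return A binary mask [vt_volume] on the same grid.
#' @export
fill_holes <- function(mask, max_gap = 3 * max(mask$spacing)) {
  mask <- as_mask(mask)
  if (max_gap < 0) stop("`max_gap` must be >= 0")
  d <- dim(mask$data)
  r <- max_gap / 2
  pad <- pmax(1L, as.integer(ceiling(r / mask$spacing)) + 1L)
  pd <- d + 2L * pad
  m <- array(FALSE, dim = pd)
  m[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <-
    mask$data
  for (iter in 1:5) {
    before <- m
    if (r > 0) {
      # closing: dilation (distance-to-vessel <= r), then erosion
      dist_to_fg <- cpp_edt(as.logical(!m), as.integer(pd), mask$spacing,
                            FALSE)
      dil <- array(dist_to_fg <= r, dim = pd)
      dist_to_bg <- cpp_edt(as.logical(dil), as.integer(pd), mask$spacing,
                            FALSE)
      m <- array(dil & dist_to_bg > r, dim = pd)
      m <- m | before  # closing is extensive; guard against voxel rounding
    }
    # cavity fill: background not 6-connected to the border
    reach <- array(cpp_background_from_border(as.logical(m), as.integer(pd)),
                   dim = pd)
    m <- m | (!m & !reach)
    if (identical(m, before)) break
  }
  out <- m[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
           pad[3] + seq_len(d[3])]
  vt_volume(array(out, dim = d), mask$spacing, mask$origin)
}

#' Label connected components of a mask
#'
#' @param mask A binary mask [vt_volume].
#' @param connectivity 26 (vessel, default) or 6.
#' @return Integer array of component labels (0 = background) with the mask
#'   grid dimensions.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  d <- dim(mask$data)
  array(cpp_label_components(as.logical(mask$data), as.integer(d),
                             as.integer(connectivity)), dim = d)
}

# drop 26-connected components smaller than min_voxels
filter_small_components <- function(mask, min_voxels) {
  mask <- as_mask(mask)
  if (min_voxels <= 1) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  mask$data <- array(lab %in% keep & mask$data, dim = dim(mask$data))
  mask
}
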