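#' Specification of a synthetic vascular-tree phantom
#'
#' Describes a branching tubular network with tapering radii that emulates
#' a radiopaque-cast vascular tree: at every junction each daughter radius
#' is `parent radius x radius_ratio` (default Murray's law, `2^(-1/3)`, so
#' daughter radii cubed sum to the parent radius cubed) and each daughter
#' length is `parent length x length_ratio`. Daughter directions sit on a
#' cone of half-angle `branch_angle` around the parent direction, azimuths
#' evenly spaced and rotated by 90 degrees per level (with optional jitter),
#' which keeps the default symmetric tree self-intersection free. Casting
#' gaps (contrast discontinuities) can be carved at random positions of
#' randomly flagged segments.
#'
#' @param depth Number of levels (1 = a single root segment).
#' @param daughters Daughters per junction (>= 1).
#' @param root_radius Root segment radius, um.
#' @param radius_ratio Daughter/parent radius ratio per level.
#' @param root_length Root segment length, um (default 3 x root_radius,
#'   a typical proximal length-to-radius ratio).
#' @param length_ratio Daughter/parent length ratio per level.
#' @param branch_angle Cone half-angle of daughters, degrees.
#' @param angle_jitter Uniform jitter applied to polar and azimuthal
#'   angles, degrees.
#' @param casting_gap_rate Probability that a segment carries a casting-gap
#'   artifact (0..1).
#' @param gap_scale Carved-sphere radius as a multiple of the local vessel
#'   radius (> 1 guarantees a visible break in the cast).
#' @param seed Integer seed; identical spec + seed gives an identical
#'   phantom.
#' @param spacing Default rasterization voxel spacing, um.
#' @return A `vt_phantom_spec` list.
#' @export
phantom_spec <- function(depth = 4, daughters = 2, root_radius = 20,
                         radius_ratio = 2^(-1 / 3),
                         root_length = 3 * root_radius,
                         length_ratio = 0.8, branch_angle = 37,
                         angle_jitter = 0, casting_gap_rate = 0,
                         gap_scale = 1.5, seed = 1L, spacing = 1) {
  stopifnot(depth >= 1, daughters >= 1, root_radius > 0, radius_ratio > 0,
            root_length > 0, length_ratio > 0,
            casting_gap_rate >= 0, casting_gap_rate <= 1, spacing > 0)
  structure(list(depth = as.integer(depth), daughters = as.integer(daughters),
                 root_radius = root_radius, radius_ratio = radius_ratio,
                 root_length = root_length, length_ratio = length_ratio,
                 branch_angle = branch_angle, angle_jitter = angle_jitter,
                 casting_gap_rate = casting_gap_rate, gap_scale = gap_scale,
                 seed = as.integer(seed), spacing = spacing),
            class = "vt_phantom_spec")
}

#' Islet-like phantom preset
#'
#' A dense cluster of fine branches (three daughters per junction, tip
#' radius about 6 um) emulating the capillary-dense endocrine regions seen
#' at phase-contrast resolution.
#'
#' @param seed Integer seed.
#' @return A `vt_phantom_spec`.
#' @export
islet_phantom_spec <- function(seed = 1L) {
  phantom_spec(depth = 4, daughters = 3, root_radius = 18,
               radius_ratio = 0.7, root_length = 70, length_ratio = 0.75,
               branch_angle = 45, angle_jitter = 10, seed = seed,
               spacing = 2)
}

# unit vectors orthogonal to d
ortho_frame <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

# minimal distance between two 3D segments
segseg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    s <- 0; t <- min(1, max(0, f / e))
  } else {
    cc <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(1, max(0, -cc / a))
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > eps) min(1, max(0, (b * f - cc * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(1, max(0, -cc / a))
      } else if (t > 1) {
        t <- 1; s <- min(1, max(0, (b - cc) / a))
      }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

#' Generate a synthetic vascular tree with full ground truth
#'
#' Recursively grows the tree described by a [phantom_spec]; daughter
#' directions are rejected and resampled (up to 50 tries per daughter) if
#' the new segment would intersect a non-adjacent existing segment.
#' Ground-truth generation, Horsfield and Strahler labels are attached.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec A `vt_phantom_spec`.
#' @return A `vt_phantom`: `$segments` (id, parent, level, endpoints um,
#'   radius um, length um, truth labels), `$analytic_volume_um3` (sum of
#'   cylinder volumes pi r^2 L; junction overlap not corrected, recorded by
#'   `$overlap_corrected = FALSE`), and the spec.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "vt_phantom_spec"))
  set.seed(spec$seed)
  deg2rad <- pi / 180
  segs <- list(list(id = 1L, parent = 0L, level = 1L,
                    p = c(0, 0, 0), q = c(0, 0, spec$root_length),
                    d = c(0, 0, 1), radius = spec$root_radius,
                    length = spec$root_length))
  queue <- 1L  # ids of segments still needing daughters
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    cur <- segs[[id]]
    if (cur$level >= spec$depth) next
    fr <- ortho_frame(cur$d)
    base_az <- 90 * cur$level * deg2rad
    dlen <- cur$length * spec$length_ratio
    drad <- cur$radius * spec$radius_ratio
    np <- cur$q
    for (j in seq_len(spec$daughters)) {
      placed <- FALSE
      for (try in 1:50) {
        # past the first attempt the direction is resampled: jittered cone
        # angle, fully randomized azimuth (deterministic via the seed)
        th <- spec$branch_angle + stats::runif(1, -spec$angle_jitter,
                                               spec$angle_jitter)
        az <- base_az + 2 * pi * (j - 1) / spec$daughters +
          stats::runif(1, -spec$angle_jitter, spec$angle_jitter) * deg2rad
        if (try > 1) {
          az <- stats::runif(1, 0, 2 * pi)
          th <- th * stats::runif(1, 0.6, 1.2)
        }
        th <- th * deg2rad
        nd <- cos(th) * cur$d +
          sin(th) * (cos(az) * fr$u + sin(az) * fr$v)
        nd <- nd / sqrt(sum(nd^2))
        nq <- np + dlen * nd
        # reject if intersecting a non-adjacent existing segment
        ok <- TRUE
        for (s in segs) {
          # skip segments sharing the junction point (parent, siblings)
          if (s$id == id || sum((s$q - np)^2) < 1e-12 ||
              sum((s$p - np)^2) < 1e-12) next
          dmin <- segseg_dist(np, nq, s$p, s$q)
          if (dmin <= drad + s$radius) { ok <- FALSE; break }
        }
        if (ok) {
          nid <- length(segs) + 1L
          segs[[nid]] <- list(id = nid, parent = id, level = cur$level + 1L,
                              p = np, q = nq, d = nd, radius = drad,
                              length = dlen)
          queue <- c(queue, nid)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("phantom spec infeasible: could not place a daughter without ",
             "self-intersection (segment ", id, ", level ", cur$level, ")")
    }
  }
  df <- do.call(rbind, lapply(segs, function(s) {
    data.frame(id = s$id, parent = s$parent, level = s$level,
               x0 = s$p[1], y0 = s$p[2], z0 = s$p[3],
               x1 = s$q[1], y1 = s$q[2], z1 = s$q[3],
               radius_um = s$radius, length_um = s$length)
  }))
  tree <- as_rooted_tree(df$parent)
  df$generation <- as.integer(assign_generations(tree)[as.character(df$id)])
  df$horsfield <- as.integer(assign_horsfield_orders(tree)[as.character(df$id)])
  df$strahler <- as.integer(assign_strahler(tree)[as.character(df$id)])
  structure(list(spec = spec, segments = df,
                 analytic_volume_um3 = sum(pi * df$radius_um^2 *
                                             df$length_um),
                 overlap_corrected = FALSE),
            class = "vt_phantom")
}

#' @export
print.vt_phantom <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<vt_phantom> %d segments, depth %d, %d tip segment(s)\n",
              nrow(s), max(s$level), sum(!s$id %in% s$parent)))
  cat(sprintf("  radius (um): root %.3g, tip %.3g; analytic volume %.4g um^3\n",
              max(s$radius_um), min(s$radius_um), x$analytic_volume_um3))
  invisible(x)
}

#' Rasterize a phantom tree to a voxel mask
#'
#' Segments are drawn as capsules (cylinders with hemispherical ends, so
#' junctions have no notches); a voxel is vessel iff its center lies inside
#' a capsule. If the spec carries a positive `casting_gap_rate`, flagged
#' segments get a sphere of `gap_scale x` the local radius carved out at a
#' random position along their axis (reproducible from the spec seed).
#'
#' @param phantom A `vt_phantom`.
#' @param spacing Voxel spacing, um (scalar or length 3); defaults to the
#'   spec's spacing. A warning is issued when the smallest radius is
#'   resolved by fewer than 2 voxels.
#' @param margin Extra margin around the tree bounding box, voxels.
#' @return A binary mask [vt_volume].
#' @export
rasterize_tree <- function(phantom, spacing = NULL, margin = 2L) {
  stopifnot(inherits(phantom, "vt_phantom"))
  spacing <- spacing %||% phantom$spec$spacing
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  s <- phantom$segments
  if (min(s$radius_um) < 2 * max(spacing))
    warning("spacing resolves the smallest radius with < 2 voxels; ",
            "fine segments may be lost")
  p0 <- as.matrix(s[, c("x0", "y0", "z0")])
  p1 <- as.matrix(s[, c("x1", "y1", "z1")])
  lo <- pmin(apply(p0, 2, min), apply(p1, 2, min)) - max(s$radius_um)
  hi <- pmax(apply(p0, 2, max), apply(p1, 2, max)) + max(s$radius_um)
  origin <- lo - margin * spacing
  dims <- as.integer(ceiling((hi - origin) / spacing)) + margin
  res <- cpp_rasterize_capsules(dims, spacing, origin, p0, p1, s$radius_um)
  mask <- array(res, dim = dims)
  if (phantom$spec$casting_gap_rate > 0) {
    set.seed(phantom$spec$seed + 7919L)
    flagged <- stats::runif(nrow(s)) < phantom$spec$casting_gap_rate
    if (any(flagged)) {
      t <- stats::runif(sum(flagged), 0.25, 0.75)
      cen <- p0[flagged, , drop = FALSE] +
        (p1[flagged, , drop = FALSE] - p0[flagged, , drop = FALSE]) * t
      mask <- array(
        cpp_carve_spheres(as.logical(mask), dims, spacing, origin, cen,
                          phantom$spec$gap_scale * s$radius_um[flagged]),
        dim = dims)
    }
  }
  vt_volume(mask, spacing, origin)
}

#' Degrade a volume to a coarser imaging modality
#'
#' Emulates viewing a high-resolution cast at a coarser scale (the
#' field-of-view / resolution trade-off between synchrotron, micro-CT,
#' volume tomography and clinical CT): Gaussian blur in physical units
#' (partial-volume averaging), additive Gaussian noise (seeded), then
#' resampling to the coarser spacing. Structures thinner than about two
#' target voxels are lost on re-thresholding.
#'
#' @param vol A [vt_volume] (masks are converted to 0/1 greyscale).
#' @param target_spacing Target voxel spacing, um (>= source spacing).
#' @param blur_sigma Gaussian sigma, um (default half the target spacing).
#' @param noise_sd Additive noise SD in intensity units.
#' @param seed Integer seed for the noise.
#' @return A greyscale [vt_volume] at the target spacing.
#' @export
degrade_volume <- function(vol, target_spacing,
                           blur_sigma = max(target_spacing) / 2,
                           noise_sd = 0, seed = 1L) {
  stopifnot(is_vt_volume(vol))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (any(target_spacing < vol$spacing - 1e-9))
    stop("target spacing must be at least as coarse as the source")
  d <- dim(vol$data)
  dat <- if (is.logical(vol$data)) array(as.numeric(vol$data), dim = d)
    else vol$data
  if (blur_sigma > 0) {
    dat <- array(cpp_gauss_blur(as.numeric(dat), as.integer(d),
                                blur_sigma / vol$spacing), dim = d)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    dat <- dat + array(stats::rnorm(length(dat), 0, noise_sd), dim = d)
  }
  g <- vt_volume(dat, vol$spacing, vol$origin)
  if (isTRUE(all.equal(target_spacing, vol$spacing))) return(g)
  resample_volume(g, target_spacing, mode = "linear")
}
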