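#' Davies-Bouldin cluster validity index
#'
#' `DB = (1/k) sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is the
#' mean Euclidean distance of group members to their centroid and `M_ij`
#' the distance between centroids. Lower is better (well-separated, compact
#' groups). Coincident centroids give `Inf`.
#'
#' @param X Numeric feature matrix (n x d).
#' @param labels Group labels, length n, at least 2 non-empty groups.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.vector(labels)
  groups <- unique(labels)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  cen <- t(vapply(groups, function(g) colMeans(X[labels == g, , drop = FALSE]),
                  numeric(ncol(X))))
  S <- vapply(seq_len(k), function(i) {
    Xi <- X[labels == groups[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, cen[i, ])^2)))
  }, numeric(1))
  db_i <- vapply(seq_len(k), function(i) {
    r <- vapply(seq_len(k), function(j) {
      if (j == i) return(-Inf)
      M <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (M == 0) return(Inf)
      (S[i] + S[j]) / M
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(db_i)
}

#' Dunn cluster validity index
#'
#' `Dunn = min_{i != j} d_single(i, j) / max_i diam_complete(i)`: the
#' smallest single-linkage inter-group distance divided by the largest
#' complete-linkage intra-group diameter, Euclidean metric. Higher is
#' better. A zero maximal intra-group diameter (all groups are repeated
#' points) gives `Inf` by convention.
#'
#' @inheritParams davies_bouldin
#' @return Non-negative scalar (possibly `Inf`).
#' @export
dunn_index <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.vector(labels)
  groups <- unique(labels)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  D <- as.matrix(stats::dist(X))
  idx <- lapply(groups, function(g) which(labels == g))
  diam <- vapply(idx, function(i) {
    if (length(i) < 2L) return(0)
    max(D[i, i])
  }, numeric(1))
  sep <- Inf
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sep <- min(sep, min(D[idx[[i]], idx[[j]]]))
    }
  }
  if (max(diam) == 0) return(Inf)
  sep / max(diam)
}

#' Compare groupings by cluster validity indices
#'
#' Computes Davies-Bouldin and Dunn for each labelling scheme (typically
#' generation, Horsfield order, Strahler order and GMM clusters) on the same
#' feature matrix, to judge which grouping yields the most compact,
#' best-separated classes. Schemes with fewer than 2 groups are reported as
#' undefined (`NA`) rather than failing the comparison.
#'
#' @param X Feature matrix (n x d), rows aligned with each labelling.
#' @param schemes Named list of label vectors (each of length `nrow(X)`).
#' @return A data.frame of class `vt_validity_report` with columns `scheme`,
#'   `n_groups`, `davies_bouldin`, `dunn`.
#' @export
compare_groupings <- function(X, schemes) {
  if (is.null(names(schemes)) || any(names(schemes) == ""))
    stop("`schemes` must be a named list")
  rows <- lapply(names(schemes), function(nm) {
    lab <- schemes[[nm]]
    if (length(lab) != nrow(X))
      stop("labels of scheme '", nm, "' do not match the feature matrix")
    ng <- length(unique(lab))
    if (ng < 2L) {
      data.frame(scheme = nm, n_groups = ng, davies_bouldin = NA_real_,
                 dunn = NA_real_)
    } else {
      data.frame(scheme = nm, n_groups = ng,
                 davies_bouldin = davies_bouldin(X, lab),
                 dunn = dunn_index(X, lab))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vt_validity_report", "data.frame")
  out
}

#' Map segment labels back onto the 3D geometry
#'
#' Every included vessel voxel takes the label of its owning segment (the
#' nearest-polyline partition computed by [reduce_to_segments]), giving the
#' 3-D color-mapping of a categorization (Strahler order, GMM cluster, ...).
#' Optionally also labels a surface mesh: each face takes the label of the
#' segment owning the voxel nearest its centroid.
#'
#' @param sg A `vt_segment_graph`.
#' @param labels Integer labels named by segment id, covering all segments.
#' @param mesh Optional [vt_mesh] of the same vessel surface to label.
#' @return A list with `volume` (integer-labelled [vt_volume], 0 =
#'   background) and, if `mesh` was given, `face_labels`.
#' @export
map_labels_to_geometry <- function(sg, labels, mesh = NULL) {
  stopifnot(inherits(sg, "vt_segment_graph"))
  ids <- as.character(sg$segments$id)
  if (!all(ids %in% names(labels)))
    stop("`labels` must cover every segment")
  lut <- integer(max(sg$segments$id))
  lut[sg$segments$id] <- as.integer(labels[ids])
  lab_arr <- array(0L, dim = sg$dim)
  sel <- sg$owner > 0L
  lab_arr[sel] <- lut[sg$owner[sel]]
  vol <- vt_volume(lab_arr, sg$spacing, sg$origin)
  out <- list(volume = vol)
  if (!is.null(mesh)) {
    cen <- (mesh$vertices[mesh$faces[, 1], ] +
              mesh$vertices[mesh$faces[, 2], ] +
              mesh$vertices[mesh$faces[, 3], ]) / 3
    vx <- pmin(pmax(round(sweep(sweep(cen, 2, sg$origin), 2, sg$spacing,
                                "/")) + 1, 1),
               matrix(sg$dim, nrow(cen), 3, byrow = TRUE))
    lin <- (vx[, 1] - 1) + sg$dim[1] * (vx[, 2] - 1) +
      sg$dim[1] * sg$dim[2] * (vx[, 3] - 1) + 1
    # nearest labelled voxel: fall back to the owning segment of the
    # nearest polyline voxel for faces whose centroid voxel is background
    fl <- lab_arr[lin]
    if (any(fl == 0L)) {
      owner_any <- nearest_owner(sg)
      fl[fl == 0L] <- lut[owner_any[lin[fl == 0L]]]
    }
    out$face_labels <- fl
  }
  out
}

# owner label extended over the whole grid (nearest polyline voxel,
# regardless of the mask) - used for labelling surfaces
nearest_owner <- function(sg) {
  seed_vox <- unlist(sg$vox)
  seed_seg <- rep(sg$segments$id,
                  vapply(sg$vox, length, integer(1)))
  first <- !duplicated(seed_vox)
  array(cpp_nearest_seed(as.integer(sg$dim), sg$spacing,
                         as.numeric(seed_vox[first] - 1),
                         as.integer(seed_seg[first])),
        dim = sg$dim)
}
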