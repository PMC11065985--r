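#' Pipeline run configuration
#'
#' Materializes every tunable of the analysis chain (preprocess ->
#' thickness -> graph -> orders -> clustering) with its default, so a saved
#' configuration reloads to an identical run. Exactly one of `input` (a
#' volume file) or `phantom` (a [phantom_spec]) must be given. A single
#' global seed drives every stochastic stage through fixed per-stage
#' offsets.
#'
#' @param input Path to a volume file (NRRD/MHA/TIFF), or `NULL`.
#' @param phantom A `vt_phantom_spec`, or `NULL`.
#' @param spacing Optional spacing override for `input`, um.
#' @param median_filter Apply the 3x3x3 median filter to greyscale input.
#' @param region_grow `list(seeds, low, high)` for density-based
#'   segmentation of greyscale input; `NULL` thresholds at `threshold`.
#' @param threshold Intensity threshold used when no region-grow window is
#'   given (greyscale input only).
#' @param fill_gaps `max_gap` in um for [fill_holes], or `NULL` to skip.
#' @param min_component_voxels,range_max,bin_width Thickness parameters
#'   (see [local_thickness], [diameter_histogram]).
#' @param spur_voxels Spur-pruning length in voxels (see [prune_spurs]).
#' @param adaptive_prune Also prune terminal twigs shorter than the local
#'   vessel diameter.
#' @param diameter_stat Segment diameter summary (`"median"` or `"mean"`).
#' @param root_strategy Root selection (see [build_rooted_tree]).
#' @param k_range,constellations,log_transform,standardize,n_init,tol GMM
#'   clustering parameters (see [select_gmm], [build_features]).
#' @param seed Global integer seed.
#' @param out_dir Output directory (created if missing).
#' @return A `vt_config` list.
#' @export
vt_config <- function(input = NULL, phantom = NULL, spacing = NULL,
                      median_filter = FALSE, region_grow = NULL,
                      threshold = 0.5, fill_gaps = NULL,
                      min_component_voxels = 8, range_max = 25000,
                      bin_width = NULL, spur_voxels = 5,
                      adaptive_prune = TRUE,
                      diameter_stat = "median",
                      root_strategy = "largest_diameter",
                      k_range = 1:9,
                      constellations = gmm_constellations(),
                      log_transform = TRUE, standardize = TRUE,
                      n_init = 10, tol = 1e-6, seed = 1L,
                      out_dir = tempfile("vasctree_run_")) {
  if (is.null(input) == is.null(phantom))
    stop("exactly one of `input` or `phantom` must be given")
  structure(list(input = input,
                 phantom = if (!is.null(phantom)) unclass(phantom),
                 spacing = spacing, median_filter = median_filter,
                 region_grow = region_grow, threshold = threshold,
                 fill_gaps = fill_gaps,
                 min_component_voxels = min_component_voxels,
                 range_max = range_max, bin_width = bin_width,
                 spur_voxels = spur_voxels, adaptive_prune = adaptive_prune,
                 diameter_stat = diameter_stat,
                 root_strategy = root_strategy,
                 k_range = as.integer(k_range),
                 constellations = constellations,
                 log_transform = log_transform, standardize = standardize,
                 n_init = as.integer(n_init), tol = tol,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "vt_config")
}

#' Save / load a run configuration as JSON
#'
#' `load_config(save_config(cfg))` reproduces an identical run.
#'
#' @param config A `vt_config`.
#' @param path JSON path.
#' @return `save_config`: `path` invisibly; `load_config`: a `vt_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "vt_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[setdiff(names(x), "phantom")]
  if (!is.null(x$phantom)) args$phantom <- do.call(phantom_spec, x$phantom)
  do.call(vt_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full vascular-network analysis pipeline
#'
#' Executes, in order: input loading (file or phantom), preprocessing
#' (median filter, segmentation, gap filling), sphere-based local thickness
#' with the volume-by-diameter histogram, skeletonization and reduction to
#' the vessel-segment graph, rooting and the three branching
#' classifications, GMM clustering with BIC selection, validity comparison,
#' and label back-mapping. All tabular artifacts are written into
#' `config$out_dir`; re-running with the same config and seed reproduces
#' them byte-identically.
#'
#' @param config A `vt_config`.
#' @return A `vt_run` report (see [export_report]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vt_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p)
    manifest <<- c(manifest, p)
    p
  }

  phantom <- NULL
  vol <- stage("read", {
    if (!is.null(config$phantom)) {
      spec <- do.call(phantom_spec, config$phantom)
      phantom <- generate_tree(spec)
      rasterize_tree(phantom)
    } else {
      read_volume(config$input, spacing_override = config$spacing)
    }
  })

  mask <- stage("segment", {
    if (is.logical(vol$data)) {
      vol
    } else {
      v <- if (config$median_filter) median_filter3(vol) else vol
      if (!is.null(config$region_grow)) {
        rg <- config$region_grow
        region_grow(v, matrix(unlist(rg$seeds), ncol = 3, byrow = TRUE),
                    rg$low, rg$high)
      } else {
        vt_volume(array(v$data >= config$threshold, dim = dim(v$data)),
                  v$spacing, v$origin)
      }
    }
  })
  if (!is.null(config$fill_gaps))
    mask <- stage("fill_holes", fill_holes(mask, config$fill_gaps))

  tmap <- stage("thickness", local_thickness(
    mask, min_component_voxels = config$min_component_voxels,
    range_max = config$range_max))
  hist <- stage("thickness", diameter_histogram(
    tmap, bin_width = config$bin_width %||% (2 * max(tmap$spacing))))
  stats <- volume_weighted_stats(tmap)
  emit("diameter_histogram.csv", function(p) write_histogram_csv(hist, p))
  emit("thickness_map.nrrd", function(p) {
    th <- tmap$data
    th[is.na(th)] <- 0
    write_volume(vt_volume(th, tmap$spacing, tmap$origin), p)
    rm(th)
  })
  if (!is.null(config$phantom)) rm(vol)  # phantom mask == vol; keep `mask`
  gc(FALSE)

  sg <- stage("graph", {
    skel <- skeletonize(vt_volume(tmap$mask, tmap$spacing, tmap$origin))
    g <- extract_graph(skel)
    g <- prune_spurs(g, min_len = config$spur_voxels * max(mask$spacing),
                     adaptive = if (config$adaptive_prune) tmap)
    reduce_to_segments(g, tmap, diameter_stat = config$diameter_stat)
  })

  tree <- stage("orders", build_rooted_tree(sg, strategy = config$root_strategy))
  labs <- stage("orders", list(
    generation = assign_generations(tree),
    horsfield = assign_horsfield_orders(tree),
    strahler = assign_strahler(tree)))

  tab <- segment_table(sg)
  keep <- tab$id %in% tree$segment_ids  # cycle segments carry no order
  for (nm in names(labs))
    tab[[nm]] <- ifelse(keep, as.integer(labs[[nm]][as.character(tab$id)]),
                        NA_integer_)

  clust <- stage("cluster", {
    X <- build_features(tab, log_transform = config$log_transform,
                        standardize = config$standardize)
    sel <- select_gmm(X, k_range = config$k_range,
                      constellations = config$constellations,
                      seed = config$seed + 101L, n_init = config$n_init,
                      tol = config$tol)
    cls <- predict(sel$best, X)
    list(sel = sel, X = X, labels = cls)
  })
  tab$gmm_cluster <- as.integer(clust$labels[as.character(tab$id)])

  summaries <- stage("orders", {
    out <- lapply(names(labs), function(nm)
      summarize_by_group(tab[keep, , drop = FALSE], labs[[nm]]))
    gl <- clust$labels
    attr(gl, "scheme") <- "gmm"
    out$gmm <- summarize_by_group(tab, gl)
    names(out) <- c(names(labs), "gmm")
    out
  })

  validity <- stage("cluster", {
    schemes <- lapply(labs, function(l) as.integer(l[as.character(tab$id[keep])]))
    schemes$gmm <- as.integer(clust$labels[as.character(tab$id[keep])])
    compare_groupings(clust$X[keep, , drop = FALSE], schemes)
  })

  stage("map", {
    geo <- map_labels_to_geometry(sg, clust$labels)
    emit("gmm_labels.nrrd", function(p) write_volume(geo$volume, p))
    rm(geo)
  })
  gc(FALSE)

  emit("segment_table.csv", function(p)
    utils::write.csv(tab, p, row.names = FALSE))
  emit("bic_table.csv", function(p)
    utils::write.csv(clust$sel$bic_table, p, row.names = FALSE))
  emit("validity_report.csv", function(p)
    utils::write.csv(validity, p, row.names = FALSE))
  emit("group_summaries.csv", function(p)
    utils::write.csv(do.call(rbind, summaries), p, row.names = FALSE))
  emit("segment_graph.graphml", function(p) write_graphml(sg, p))
  emit("segments.swc", function(p) write_swc(sg, tree, p))
  cfg_path <- emit("run_config.json", function(p) save_config(config, p))

  report <- structure(list(
    package_version = as.character(utils::packageVersion("vasctree")),
    config = config,
    config_path = cfg_path,
    phantom = phantom,
    n_vessel_voxels = sum(tmap$mask),
    vessel_volume_um3 = stats$total_volume_um3,
    diameter_stats = stats,
    n_segments = nrow(tab),
    n_nodes = nrow(sg$nodes),
    n_removed_cycle_segments = length(tree$removed),
    n_orders = vapply(labs, function(l) length(unique(l)), integer(1)),
    selected_k = clust$sel$best$k,
    selected_constellation = clust$sel$best$constellation,
    validity = validity,
    histogram = hist,
    manifest = manifest,
    segment_graph = sg,
    tree = tree,
    table = tab,
    bic_table = clust$sel$bic_table,
    summaries = summaries),
    class = "vt_run")
  report
}

#' @export
print.vt_run <- function(x, ...) {
  cat("<vt_run> vascular network analysis\n")
  cat(sprintf("  vessel voxels: %d (%.4g um^3)\n", x$n_vessel_voxels,
              x$vessel_volume_um3))
  cat(sprintf("  segments: %d (%d node(s), %d cycle segment(s) removed)\n",
              x$n_segments, x$n_nodes, x$n_removed_cycle_segments))
  cat(sprintf("  distinct orders: generation %d, horsfield %d, strahler %d\n",
              x$n_orders[["generation"]], x$n_orders[["horsfield"]],
              x$n_orders[["strahler"]]))
  cat(sprintf("  GMM: k = %d (%s) by BIC\n", x$selected_k,
              x$selected_constellation))
  cat(sprintf("  outputs: %s\n", x$config$out_dir))
  invisible(x)
}

#' @export
summary.vt_run <- function(object, ...) {
  print(object)
  cat("\nValidity indices (lower DB / higher Dunn = better separation):\n")
  print(as.data.frame(object$validity), row.names = FALSE)
  cat("\nMean vessel diameter (volume-weighted):",
      sprintf("%.4g um (SD %.4g)\n", object$diameter_stats$mean_um,
              object$diameter_stats$sd_um))
  invisible(object)
}

#' Export a run report
#'
#' Writes `report.json` (versions, configuration echo, per-stage summaries
#' and the file manifest), a human-readable `report.txt`, and PNG plots of
#' the diameter histogram and the BIC table. Re-export overwrites the same
#' files.
#'
#' @param report A `vt_run` from [run_pipeline].
#' @param path Output directory (defaults to the run's out_dir).
#' @return Path of `report.json`, invisibly.
#' @export
export_report <- function(report, path = report$config$out_dir) {
  stopifnot(inherits(report, "vt_run"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    package_version = report$package_version,
    config = unclass(report$config),
    n_vessel_voxels = report$n_vessel_voxels,
    vessel_volume_um3 = report$vessel_volume_um3,
    diameter_stats = report$diameter_stats,
    n_segments = report$n_segments,
    n_nodes = report$n_nodes,
    n_removed_cycle_segments = report$n_removed_cycle_segments,
    n_orders = as.list(report$n_orders),
    selected_k = report$selected_k,
    selected_constellation = report$selected_constellation,
    validity = report$validity,
    manifest = report$manifest)
  jp <- file.path(path, "report.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, dataframe = "rows")
  txt <- utils::capture.output(summary(report))
  writeLines(txt, file.path(path, "report.txt"))
  grDevices::png(file.path(path, "diameter_histogram.png"), 800, 500)
  plot(report$histogram, main = "Volume distribution by vessel diameter")
  grDevices::dev.off()
  grDevices::png(file.path(path, "bic_table.png"), 800, 500)
  bt <- report$bic_table
  graphics::matplot(
    x = sort(unique(bt$k)),
    y = vapply(split(bt$bic, bt$constellation), function(v) v,
               numeric(length(unique(bt$k)))),
    type = "b", pch = 1, lty = 1,
    xlab = "number of clusters k", ylab = "BIC (larger is better)")
  graphics::legend("bottomright", legend = unique(bt$constellation),
                   col = seq_along(unique(bt$constellation)), lty = 1,
                   cex = 0.8)
  grDevices::dev.off()
  invisible(jp)
}
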