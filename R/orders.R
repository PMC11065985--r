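#' Branching classifications of a rooted vessel tree
#'
#' The three classic arborization labels, attributed to segments (edges):
#'
#' * **Generation** (centrifugal): the root segment is generation 1; each
#'   daughter branch after a junction with two or more daughters increases
#'   the generation by 1. Pass-through junctions with a single daughter
#'   (possible after cycle-segment removal) inherit the label unchanged.
#' * **Horsfield order** (centripetal): terminal segments are order 1; at
#'   every junction where two or more vessels meet, the parent takes the
#'   highest daughter order plus one.
#' * **Strahler order** (centripetal): terminal segments are order 1; the
#'   parent order increases by one only when the maximal daughter order is
#'   attained by two or more daughters, otherwise the highest order
#'   continues.
#'
#' On every tree, Strahler <= Horsfield segmentwise, both equal 1 exactly on
#' terminal segments, and generations are non-decreasing from root to tip.
#'
#' @param tree A `vt_rooted_tree` (see [build_rooted_tree] and
#'   [as_rooted_tree]).
#' @return An integer vector of labels named by segment id, with attribute
#'   `scheme`.
#' @name branching_orders
NULL

order_labels <- function(values, ids, scheme) {
  out <- as.integer(values)
  names(out) <- ids
  attr(out, "scheme") <- scheme
  out
}

#' @rdname branching_orders
#' @export
assign_generations <- function(tree) {
  stopifnot(inherits(tree, "vt_rooted_tree"))
  lab <- integer(0)
  for (sid in tree$segment_ids) {  # BFS order: parent precedes child
    key <- as.character(sid)
    par <- tree$parent[[key]]
    if (par == 0L) {
      lab[key] <- 1L
    } else {
      nd <- length(tree$children[[as.character(par)]])
      lab[key] <- lab[[as.character(par)]] + (nd >= 2L)
    }
  }
  order_labels(lab[as.character(tree$segment_ids)], tree$segment_ids,
               "generation")
}

#' @rdname branching_orders
#' @export
assign_horsfield_orders <- function(tree) {
  stopifnot(inherits(tree, "vt_rooted_tree"))
  lab <- integer(0)
  for (sid in rev(tree$segment_ids)) {  # reverse BFS = children first
    key <- as.character(sid)
    ch <- tree$children[[key]]
    if (length(ch) == 0L) {
      lab[key] <- 1L
    } else {
      m <- max(vapply(as.character(ch), function(k) lab[[k]], integer(1)))
      lab[key] <- m + (length(ch) >= 2L)
    }
  }
  order_labels(lab[as.character(tree$segment_ids)], tree$segment_ids,
               "horsfield")
}

#' @rdname branching_orders
#' @export
assign_strahler <- function(tree) {
  stopifnot(inherits(tree, "vt_rooted_tree"))
  lab <- integer(0)
  for (sid in rev(tree$segment_ids)) {
    key <- as.character(sid)
    ch <- tree$children[[key]]
    if (length(ch) == 0L) {
      lab[key] <- 1L
    } else {
      v <- vapply(as.character(ch), function(k) lab[[k]], integer(1))
      m <- max(v)
      lab[key] <- m + (sum(v == m) >= 2L)
    }
  }
  order_labels(lab[as.character(tree$segment_ids)], tree$segment_ids,
               "strahler")
}

#' Per-group morphometric summary
#'
#' Aggregates the segment table by a labelling (branching order or cluster):
#' segment count, mean/min/max segment diameter, mean segment length and
#' total segment volume per label. Counts sum to the number of labelled
#' segments and volumes to their total volume.
#'
#' @param table Segment table (from [segment_table]) with columns `id`,
#'   `diameter_um`, `length_um`, `volume_um3`.
#' @param labels Integer labels named by segment id (from the `assign_*`
#'   functions or a clustering); must cover every row of `table`.
#' @return A data.frame with one row per label, sorted by label, of class
#'   `vt_group_summary`.
#' @export
summarize_by_group <- function(table, labels) {
  ids <- as.character(table$id)
  if (!all(ids %in% names(labels)))
    stop("`labels` must cover every segment in `table`")
  lab <- labels[ids]
  groups <- sort(unique(lab))
  out <- do.call(rbind, lapply(groups, function(g) {
    rows <- table[lab == g, , drop = FALSE]
    data.frame(scheme = attr(labels, "scheme") %||% "labels",
               label = g,
               n = nrow(rows),
               d_mean = mean(rows$diameter_um),
               d_min = min(rows$diameter_um),
               d_max = max(rows$diameter_um),
               len_mean = mean(rows$length_um),
               vol_total = sum(rows$volume_um3))
  }))
  rownames(out) <- NULL
  class(out) <- c("vt_group_summary", "data.frame")
  out
}
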