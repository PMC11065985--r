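#' Skeletonize a vessel mask
#'
#' Topology-preserving 3-D thinning to a one-voxel-wide, 26-connected curve
#' skeleton: border voxels that are simple points (deletable without
#' changing the numbers of connected components, cavities or tunnels) and
#' are not curve endpoints are removed in six directional subiterations
#' until stability.
#'
#' @param mask A non-empty binary mask [vt_volume].
#' @return A binary skeleton mask [vt_volume] on the same grid.
#' @export
skeletonize <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask$data)) stop("empty mask")
  d <- dim(mask$data)
  sk <- cpp_thin(as.logical(mask$data), as.integer(d))
  dim(sk) <- d
  vt_volume(sk, mask$spacing, mask$origin)
}

# 26-neighbourhood ids for each skeleton voxel; returns list with
# per-voxel neighbour count and a M x 26 matrix of skeleton-voxel ids (0 =
# none). Voxel ids are positions in `idx` (sorted linear indices).
skel_adjacency <- function(skel_lgl, d) {
  idx <- which(skel_lgl)
  m <- length(idx)
  id_arr <- array(0L, dim = d)
  id_arr[idx] <- seq_len(m)
  co <- arrayInd(idx, d)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  nb <- matrix(0L, nrow = m, ncol = nrow(off))
  for (k in seq_len(nrow(off))) {
    sh <- co + matrix(off[k, ], nrow = m, ncol = 3, byrow = TRUE)
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    lin <- (sh[ok, 1] - 1) + d[1] * (sh[ok, 2] - 1) +
      d[1] * d[2] * (sh[ok, 3] - 1) + 1
    nb[ok, k] <- id_arr[lin]
  }
  list(idx = idx, coords = co, nb = nb, degree = rowSums(nb > 0))
}

#' Extract a spatial graph from a voxel skeleton
#'
#' Skeleton voxels with a number of skeleton neighbours different from 2
#' become nodes (26-adjacent clusters of such voxels are merged into one
#' junction node, anchored at the lexicographically smallest voxel); chains
#' of degree-2 voxels become edges carrying their full voxel polyline.
#' Pure cycles without any node voxel are anchored at their smallest voxel
#' and returned as self-loop edges.
#'
#' @param skel A skeleton mask [vt_volume] (from [skeletonize]).
#' @return A `vt_spatial_graph`: nodes (id, physical coordinates um, anchor
#'   voxel), edges (endpoint node ids, polyline in um, polyline voxels).
#' @export
extract_graph <- function(skel) {
  skel <- as_mask(skel)
  d <- dim(skel$data)
  if (!any(skel$data)) stop("empty skeleton")
  adj <- skel_adjacency(as.vector(skel$data), d)
  m <- length(adj$idx)
  is_node <- adj$degree != 2L
  # cluster node voxels (26-connected components among node voxels)
  cluster <- integer(m)
  nextc <- 0L
  for (v in which(is_node)) {
    if (cluster[v] != 0L) next
    nextc <- nextc + 1L
    queue <- v
    cluster[v] <- nextc
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nbs <- adj$nb[cur, ]
      nbs <- nbs[nbs > 0]
      nbs <- nbs[is_node[nbs] & cluster[nbs] == 0L]
      cluster[nbs] <- nextc
      queue <- c(queue, nbs)
    }
  }
  # anchor = smallest linear index in each cluster
  anchors <- vapply(seq_len(nextc), function(cl) {
    min(adj$idx[cluster == cl])
  }, numeric(1))
  # renumber clusters by anchor order for determinism
  ord <- order(anchors)
  remap <- integer(nextc)
  remap[ord] <- seq_len(nextc)
  cluster[cluster > 0] <- remap[cluster[cluster > 0]]
  anchors <- anchors[ord]

  to_phys <- function(lin) {
    co <- arrayInd(lin, d)
    sweep(sweep(co - 1, 2, skel$spacing, "*"), 2, skel$origin, "+")
  }

  edges <- list()
  visited <- rep(FALSE, m)
  walk_chain <- function(start_member, first) {
    # walk a degree-2 chain from a node member voxel
    chain <- integer(0)
    prev <- start_member
    cur <- first
    repeat {
      chain <- c(chain, cur)
      visited[cur] <<- TRUE
      if (is_node[cur]) break  # safety; callers pass degree-2 first
      nbs <- adj$nb[cur, ]
      nbs <- nbs[nbs > 0]
      nxt <- nbs[nbs != prev]
      if (length(nxt) == 0L) break  # dead end (isolated chain)
      prev <- cur
      cur <- nxt[[1]]
      if (is_node[cur]) {
        chain <- c(chain, cur)
        break
      }
      if (visited[cur]) {  # closed back onto the chain (cycle)
        chain <- c(chain, cur)
        break
      }
    }
    chain
  }
  # edges from node clusters through degree-2 chains
  for (cl in seq_len(nextc)) {
    members <- which(cluster == cl)
    for (mem in members) {
      nbs <- adj$nb[mem, ]
      nbs <- nbs[nbs > 0]
      for (nbv in nbs) {
        if (is_node[nbv] || visited[nbv]) next
        chain <- walk_chain(mem, nbv)
        last <- chain[length(chain)]
        to_cl <- if (is_node[last]) cluster[last] else cl
        vox_ids <- c(mem, chain)
        lin <- adj$idx[vox_ids]
        # polyline endpoints coincide with node (anchor) coordinates
        lin_full <- lin
        if (lin[1] != anchors[cl]) lin_full <- c(anchors[cl], lin_full)
        if (lin_full[length(lin_full)] != anchors[to_cl])
          lin_full <- c(lin_full, anchors[to_cl])
        edges[[length(edges) + 1]] <- list(from = cl, to = to_cl,
                                           vox = lin_full)
      }
    }
    # direct node-member to node-member contacts across clusters cannot
    # occur: adjacent node voxels always share a cluster
  }
  # pure cycles: remaining unvisited degree-2 voxels
  remaining <- which(!visited & !is_node)
  while (length(remaining)) {
    anchor_v <- remaining[which.min(adj$idx[remaining])]
    nextc <- nextc + 1L
    anchors <- c(anchors, adj$idx[anchor_v])
    cluster[anchor_v] <- nextc
    visited[anchor_v] <- TRUE  # so the walk stops when the loop closes
    nbs <- adj$nb[anchor_v, ]
    nbs <- nbs[nbs > 0]
    chain <- walk_chain(anchor_v, nbs[[1]])
    lin <- adj$idx[c(anchor_v, chain)]
    if (lin[length(lin)] != adj$idx[anchor_v])
      lin <- c(lin, adj$idx[anchor_v])
    edges[[length(edges) + 1]] <- list(from = nextc, to = nextc, vox = lin)
    remaining <- which(!visited & !is_node)
  }
  # isolated single voxels (degree 0) become bare nodes
  iso <- which(adj$degree == 0L & cluster == 0L)
  for (v in iso) {
    nextc <- nextc + 1L
    cluster[v] <- nextc
    anchors <- c(anchors, adj$idx[v])
  }
  node_xyz <- to_phys(anchors)
  nodes <- data.frame(id = seq_len(nextc), x = node_xyz[, 1],
                      y = node_xyz[, 2], z = node_xyz[, 3],
                      anchor = anchors)
  edges <- lapply(edges, function(e) {
    e$pts <- to_phys(e$vox)
    e
  })
  structure(list(nodes = nodes, edges = edges, spacing = skel$spacing,
                 origin = skel$origin, dim = d),
            class = "vt_spatial_graph")
}

#' @export
print.vt_spatial_graph <- function(x, ...) {
  cat(sprintf("<vt_spatial_graph> %d nodes, %d edges\n",
              nrow(x$nodes), length(x$edges)))
  if (length(x$edges)) {
    len <- vapply(x$edges, function(e) polyline_length(e$pts), numeric(1))
    cat(sprintf("  edge length (um): min %.3g, median %.3g, max %.3g\n",
                min(len), stats::median(len), max(len)))
  }
  invisible(x)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

graph_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  for (e in g$edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  deg
}

#' Prune short terminal spurs from a spatial graph
#'
#' Terminal edges (one endpoint of degree 1) shorter than `min_len` are
#' removed iteratively, shortest first; an edge is kept if its removal would
#' empty its connected component. Degree-2 nodes left behind are re-merged
#' so edges remain maximal chains. With `adaptive = TRUE`, a terminal edge
#' is also pruned when it is shorter than the local vessel diameter at its
#' junction end (such twigs lie inside the vessel body and are thinning
#' artifacts).
#'
#' @param g A `vt_spatial_graph`.
#' @param min_len Minimum terminal edge length to keep, um (>= 0).
#' @param adaptive Optional `vt_thickness`; enables diameter-adaptive spur
#'   removal using the local thickness at the junction node.
#' @return A pruned `vt_spatial_graph`.
#' @export
prune_spurs <- function(g, min_len, adaptive = NULL) {
  stopifnot(inherits(g, "vt_spatial_graph"))
  if (min_len < 0) stop("`min_len` must be >= 0")
  edges <- g$edges
  repeat {
    if (length(edges) <= 1L) break
    deg <- integer(nrow(g$nodes))
    for (e in edges) {
      deg[e$from] <- deg[e$from] + 1L
      deg[e$to] <- deg[e$to] + 1L
    }
    len <- vapply(edges, function(e) polyline_length(e$pts), numeric(1))
    thr <- rep(min_len, length(edges))
    if (!is.null(adaptive)) {
      for (i in seq_along(edges)) {
        e <- edges[[i]]
        t1 <- deg[e$from] == 1L
        t2 <- deg[e$to] == 1L
        if (xor(t1, t2)) {
          jn <- if (t1) e$to else e$from
          av <- adaptive$data[g$nodes$anchor[jn]]
          # a twig shorter than the local vessel *radius* cannot leave the
          # vessel body; genuine branches must
          if (is.finite(av)) thr[i] <- max(thr[i], av / 2)
        }
      }
    }
    is_spur <- vapply(seq_along(edges), function(i) {
      e <- edges[[i]]
      (deg[e$from] == 1L) != (deg[e$to] == 1L) && len[i] < thr[i]
    }, logical(1))
    if (!any(is_spur)) break
    drop <- which(is_spur)[which.min(len[is_spur])]
    edges <- edges[-drop]
  }
  g$edges <- edges
  merge_degree2(g)
}

# merge chains at nodes of degree 2 (not self-loops) and drop isolated nodes
merge_degree2 <- function(g) {
  edges <- g$edges
  repeat {
    deg <- integer(nrow(g$nodes))
    for (e in edges) {
      deg[e$from] <- deg[e$from] + 1L
      deg[e$to] <- deg[e$to] + 1L
    }
    merged <- FALSE
    for (v in which(deg == 2L)) {
      inc <- which(vapply(edges, function(e) e$from == v || e$to == v,
                          logical(1)))
      if (length(inc) != 2L) next  # self-loop at v
      e1 <- edges[[inc[1]]]; e2 <- edges[[inc[2]]]
      # orient e1 to end at v, e2 to start at v
      if (e1$from == v) {
        e1$vox <- rev(e1$vox); e1$pts <- e1$pts[rev(seq_len(nrow(e1$pts))), , drop = FALSE]
        e1$from <- e1$to; e1$to <- v
      }
      if (e2$to == v) {
        e2$vox <- rev(e2$vox); e2$pts <- e2$pts[rev(seq_len(nrow(e2$pts))), , drop = FALSE]
        e2$to <- e2$from; e2$from <- v
      }
      new_e <- list(from = e1$from, to = e2$to,
                    vox = c(e1$vox, e2$vox[-1]),
                    pts = rbind(e1$pts, e2$pts[-1, , drop = FALSE]))
      edges <- edges[-inc]
      edges[[length(edges) + 1]] <- new_e
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  g$edges <- edges
  g
}

#' Reduce a spatial graph to the vessel-segment graph
#'
#' One vessel segment per edge — a piece of vessel between two bifurcations
#' or between a bifurcation and a terminal node — each with a unique,
#' deterministic integer identifier. Per segment: arc length of the
#' polyline; diameter summarised from the local-thickness values sampled at
#' the polyline voxels (`median` by default, robust to the junction zones
#' where the inscribed sphere still belongs to the parent vessel; `mean`
#' available); volume as the summed voxel volume of all included vessel
#' voxels whose Euclidean-nearest polyline voxel belongs to this segment,
#' which partitions the mask so segment volumes sum exactly to the vessel
#' volume.
#'
#' @param g A pruned `vt_spatial_graph`.
#' @param tmap A `vt_thickness` on the same grid.
#' @param diameter_stat `"median"` or `"mean"`.
#' @return A `vt_segment_graph` with `$segments` (the segment table),
#'   `$nodes`, `$polylines`, and `$owner` (integer array mapping every
#'   included vessel voxel to its owning segment id).
#' @export
reduce_to_segments <- function(g, tmap,
                               diameter_stat = c("median", "mean")) {
  stopifnot(inherits(g, "vt_spatial_graph"), inherits(tmap, "vt_thickness"))
  diameter_stat <- match.arg(diameter_stat)
  if (!identical(dim(tmap$data), g$dim))
    stop("grid mismatch between graph and thickness map")
  edges <- g$edges
  if (length(edges) == 0L) stop("graph has no edges")
  # deterministic orientation and ordering
  edges <- lapply(edges, function(e) {
    a1 <- g$nodes$anchor[e$from]; a2 <- g$nodes$anchor[e$to]
    if (a2 < a1 || (a1 == a2 && e$vox[2] > e$vox[length(e$vox) - 1])) {
      e$vox <- rev(e$vox)
      e$pts <- e$pts[rev(seq_len(nrow(e$pts))), , drop = FALSE]
      tmp <- e$from; e$from <- e$to; e$to <- tmp
    }
    e
  })
  keym <- t(vapply(edges, function(e) {
    c(g$nodes$anchor[e$from], g$nodes$anchor[e$to], length(e$vox), e$vox[2])
  }, numeric(4)))
  ord <- order(keym[, 1], keym[, 2], keym[, 3], keym[, 4])
  edges <- edges[ord]

  stat_fun <- if (diameter_stat == "median") stats::median else mean
  n_seg <- length(edges)
  len <- vapply(edges, function(e) polyline_length(e$pts), numeric(1))
  diam <- vapply(edges, function(e) {
    v <- tmap$data[e$vox]
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NA_real_)
    stat_fun(v)
  }, numeric(1))

  # nearest-polyline partition of the included vessel voxels
  seed_vox <- unlist(lapply(edges, `[[`, "vox"))
  seed_seg <- rep(seq_len(n_seg),
                  vapply(edges, function(e) length(e$vox), integer(1)))
  first <- !duplicated(seed_vox)  # shared anchors go to the lowest id
  owner <- cpp_nearest_seed(as.integer(g$dim), g$spacing,
                            as.numeric(seed_vox[first] - 1),
                            as.integer(seed_seg[first]))
  dim(owner) <- g$dim
  owner[!tmap$mask] <- 0L
  counts <- tabulate(owner[owner > 0L], nbins = n_seg)
  vol <- counts * voxel_volume(tmap)

  segments <- data.frame(
    id = seq_len(n_seg),
    from = vapply(edges, `[[`, integer(1) + 0L, "from"),
    to = vapply(edges, `[[`, integer(1) + 0L, "to"),
    length_um = len,
    diameter_um = diam,
    volume_um3 = vol,
    n_polyline = vapply(edges, function(e) length(e$vox), integer(1)))
  structure(list(nodes = g$nodes, segments = segments,
                 polylines = lapply(edges, `[[`, "pts"),
                 vox = lapply(edges, `[[`, "vox"),
                 owner = owner, spacing = g$spacing, origin = g$origin,
                 dim = g$dim, diameter_stat = diameter_stat),
            class = "vt_segment_graph")
}

#' @export
print.vt_segment_graph <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<vt_segment_graph> %d segments, %d nodes\n",
              nrow(s), nrow(x$nodes)))
  cat(sprintf("  diameter (um): min %.3g, median %.3g, max %.3g (%s)\n",
              min(s$diameter_um, na.rm = TRUE),
              stats::median(s$diameter_um, na.rm = TRUE),
              max(s$diameter_um, na.rm = TRUE), x$diameter_stat))
  cat(sprintf("  total segment volume: %.6g um^3\n", sum(s$volume_um3)))
  invisible(x)
}

#' Segment morphometrics as a plain data.frame
#'
#' @param sg A `vt_segment_graph`.
#' @return The segment table (one row per vessel segment).
#' @export
segment_table <- function(sg) {
  stopifnot(inherits(sg, "vt_segment_graph"))
  sg$segments
}

#' Root a segment graph as a vessel tree
#'
#' Selects a root node (by default the terminal node incident to the
#' largest-diameter segment, ties broken by the smaller node id), builds a
#' breadth-first spanning tree, and records any cycle-closing segments that
#' had to be excluded from the ordering (anastomoses or casting artifacts).
#'
#' @param sg A connected `vt_segment_graph`.
#' @param strategy `"largest_diameter"` or `"node_id"`.
#' @param root Optional explicit root node id (overrides `strategy`).
#' @return A `vt_rooted_tree`: parent relation over segments, BFS order,
#'   root node, and ids of removed cycle-closing segments.
#' @export
build_rooted_tree <- function(sg, strategy = c("largest_diameter", "node_id"),
                              root = NULL) {
  stopifnot(inherits(sg, "vt_segment_graph"))
  strategy <- match.arg(strategy)
  s <- sg$segments
  n_nodes <- nrow(sg$nodes)
  deg <- tabulate(c(s$from, s$to), nbins = n_nodes)
  # connectivity check
  gr <- igraph::graph_from_data_frame(
    data.frame(from = s$from, to = s$to, seg = s$id),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes)))
  comp <- igraph::components(gr)
  used_nodes <- unique(c(s$from, s$to))
  if (length(unique(comp$membership[used_nodes])) > 1L)
    stop("segment graph is disconnected; analyze components separately")
  if (is.null(root)) {
    terminals <- which(deg == 1L)
    if (length(terminals) == 0L) {
      root <- min(used_nodes)
    } else if (strategy == "node_id") {
      root <- min(terminals)
    } else {
      score <- vapply(terminals, function(v) {
        inc <- s$diameter_um[s$from == v | s$to == v]
        max(inc, na.rm = TRUE)
      }, numeric(1))
      best <- score == max(score)
      root <- min(terminals[best])
    }
  }
  # BFS over the multigraph, tracking which segment discovered each node
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(s))) {
    adj[[s$from[i]]] <- c(adj[[s$from[i]]], i)
    adj[[s$to[i]]] <- c(adj[[s$to[i]]], i)
  }
  visited_node <- rep(FALSE, n_nodes)
  seg_used <- rep(FALSE, nrow(s))
  parent_seg <- integer(nrow(s))  # parent segment id per tree segment
  in_tree <- rep(FALSE, nrow(s))
  bfs_order <- integer(0)
  visited_node[root] <- TRUE
  queue <- list(list(node = root, seg = 0L))
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    inc <- adj[[cur$node]]
    inc <- inc[order(s$id[inc])]
    for (i in inc) {
      if (seg_used[i]) next
      other <- if (s$from[i] == cur$node) s$to[i] else s$from[i]
      if (visited_node[other] && !(s$from[i] == s$to[i])) {
        next  # cycle-closing segment; left unused
      }
      if (s$from[i] == s$to[i]) next  # self-loop: always cycle-closing
      seg_used[i] <- TRUE
      in_tree[i] <- TRUE
      parent_seg[i] <- cur$seg
      bfs_order <- c(bfs_order, i)
      visited_node[other] <- TRUE
      queue[[length(queue) + 1]] <- list(node = other, seg = s$id[i])
    }
  }
  removed <- s$id[!in_tree]
  parent <- parent_seg[in_tree]
  ids <- s$id[in_tree]
  names(parent) <- ids
  children <- split(ids[parent != 0L], parent[parent != 0L])
  structure(list(root_node = root, segment_ids = s$id[bfs_order],
                 parent = parent, children = children, removed = removed,
                 n_segments = length(ids)),
            class = "vt_rooted_tree")
}

#' Build a rooted segment tree from a parent vector
#'
#' Programmatic constructor used for synthetic trees and ground truth: the
#' parent vector gives, for every segment, the id of its parent segment
#' (0 for the root segment).
#'
#' @param parent Integer vector; `parent[i]` is the parent of segment `i`
#'   (0 exactly once, at the root segment).
#' @return A `vt_rooted_tree`.
#' @export
as_rooted_tree <- function(parent) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (sum(parent == 0L) != 1L) stop("exactly one root segment required")
  if (any(parent < 0L | parent > n)) stop("parent ids out of range")
  ids <- seq_len(n)
  # BFS order from the root segment
  kids <- split(ids[parent != 0L], parent[parent != 0L])
  order_out <- integer(0)
  queue <- ids[parent == 0L]
  seen <- rep(FALSE, n)
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    order_out <- c(order_out, cur)
    ch <- kids[[as.character(cur)]]
    ch <- ch[!seen[ch]]
    seen[ch] <- TRUE
    queue <- c(queue, ch)
  }
  if (length(order_out) != n) stop("parent relation is not a connected tree")
  names(parent) <- ids
  structure(list(root_node = NA_integer_, segment_ids = order_out,
                 parent = parent, children = kids, removed = integer(0),
                 n_segments = n),
            class = "vt_rooted_tree")
}

#' @export
print.vt_rooted_tree <- function(x, ...) {
  cat(sprintf("<vt_rooted_tree> %d segments, root node %s\n",
              x$n_segments, x$root_node))
  if (length(x$removed))
    cat(sprintf("  %d cycle-closing segment(s) excluded: %s\n",
                length(x$removed), paste(x$removed, collapse = ", ")))
  invisible(x)
}

#' Export a segment graph as GraphML
#'
#' Nodes carry physical coordinates (um); edges carry the segment id,
#' length, diameter and volume, so the graph can be re-imported or inspected
#' in standard network tools.
#'
#' @param sg A `vt_segment_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(sg, path) {
  stopifnot(inherits(sg, "vt_segment_graph"))
  s <- sg$segments
  gr <- igraph::graph_from_data_frame(
    data.frame(from = s$from, to = s$to, id = s$id,
               length_um = s$length_um, diameter_um = s$diameter_um,
               volume_um3 = s$volume_um3),
    directed = FALSE,
    vertices = data.frame(name = sg$nodes$id, x = sg$nodes$x,
                          y = sg$nodes$y, z = sg$nodes$z))
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' Export segment polylines as SWC
#'
#' One sample per polyline point with a parent pointer, the standard
#' morphology-tracing exchange format.
#'
#' @param sg A `vt_segment_graph`.
#' @param tree A `vt_rooted_tree` over `sg` (defines sample parentage).
#' @param path Output `.swc` path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(sg, tree, path) {
  stopifnot(inherits(sg, "vt_segment_graph"), inherits(tree, "vt_rooted_tree"))
  rows <- list()
  counter <- 0L
  tail_sample <- integer(nrow(sg$segments))  # sample id at far end
  for (sid in tree$segment_ids) {
    pts <- sg$polylines[[sid]]
    r <- sg$segments$diameter_um[sid] / 2
    par_seg <- tree$parent[[as.character(sid)]]
    prev <- if (par_seg == 0L) -1L else tail_sample[par_seg]
    # orient polyline away from the parent
    if (par_seg != 0L) {
      par_to <- sg$segments$to[par_seg]; par_from <- sg$segments$from[par_seg]
      if (sg$segments$to[sid] %in% c(par_to, par_from)) {
        pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      }
    }
    for (i in seq_len(nrow(pts))) {
      counter <- counter + 1L
      rows[[counter]] <- sprintf("%d 3 %.6g %.6g %.6g %.6g %d", counter,
                                 pts[i, 1], pts[i, 2], pts[i, 3], r, prev)
      prev <- counter
    }
    tail_sample[sid] <- counter
  }
  writeLines(c("# vasctree SWC export (um)", unlist(rows)), path)
  invisible(path)
}
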