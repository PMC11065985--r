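# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (no distance transforms, no ridge reduction, no
# shared traversal code) so agreement is evidence, not tautology.

# exact Euclidean distance of every object voxel to the nearest background
# voxel center (grid border counts as background), by direct enumeration
oracle_inscribed_radius <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  phys <- sweep(idx, 2, spacing, "*")
  obj <- which(as.vector(mask))
  bg <- which(!as.vector(mask))
  r <- numeric(length(obj))
  bgt <- t(phys[bg, , drop = FALSE])
  for (i in seq_along(obj)) {
    v <- phys[obj[i], ]
    din <- if (length(bg)) sqrt(min(colSums((bgt - v)^2))) else Inf
    ix <- idx[obj[i], ]
    dborder <- min((ix + 1) * spacing, (d - ix) * spacing)
    r[i] <- min(din, dborder)
  }
  list(obj = obj, phys = phys[obj, , drop = FALSE], r = r)
}

# largest-inscribed-ball local thickness by painting every object voxel's
# maximal ball (the definition, evaluated directly)
oracle_local_thickness <- function(mask, spacing = c(1, 1, 1)) {
  o <- oracle_inscribed_radius(mask, spacing)
  th <- numeric(length(o$obj))
  pt <- t(o$phys)
  for (i in seq_along(o$obj)) {
    v <- o$phys[i, ]
    covered <- sqrt(colSums((pt - v)^2)) < o$r[i] - 1e-12
    th[covered] <- pmax(th[covered], 2 * o$r[i])
  }
  out <- array(NA_real_, dim = dim(mask))
  out[o$obj] <- th
  out
}

# breadth-first flood fill over an admissible voxel set (26-connectivity)
oracle_flood <- function(admissible, seed_lin) {
  d <- dim(admissible)
  out <- array(FALSE, dim = d)
  queue <- seed_lin[admissible[seed_lin]]
  out[queue] <- TRUE
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    co <- arrayInd(cur, d)
    for (k in seq_len(nrow(off))) {
      p <- co + off[k, ]
      if (any(p < 1) || any(p > d)) next
      lin <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
      if (admissible[lin] && !out[lin]) {
        out[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
  }
  out
}

# --- recursive branching-order oracles on a parent vector ----------------
# children[[i]] lists daughters of segment i; root has parent 0
oracle_children <- function(parent) {
  n <- length(parent)
  ch <- vector("list", n)
  for (i in seq_len(n)) if (parent[i] != 0) {
    ch[[parent[i]]] <- c(ch[[parent[i]]], i)
  }
  ch
}

oracle_generation <- function(parent) {
  ch <- oracle_children(parent)
  lab <- integer(length(parent))
  rec <- function(i, g) {
    lab[i] <<- g
    kids <- ch[[i]]
    for (k in kids) rec(k, g + (length(kids) >= 2))
  }
  rec(which(parent == 0), 1L)
  lab
}

oracle_horsfield <- function(parent) {
  ch <- oracle_children(parent)
  lab <- integer(length(parent))
  rec <- function(i) {
    kids <- ch[[i]]
    if (length(kids) == 0) return(lab[i] <<- 1L)
    v <- vapply(kids, rec, integer(1))
    lab[i] <<- max(v) + (length(kids) >= 2)
  }
  rec(which(parent == 0))
  lab
}

oracle_strahler <- function(parent) {
  ch <- oracle_children(parent)
  lab <- integer(length(parent))
  rec <- function(i) {
    kids <- ch[[i]]
    if (length(kids) == 0) return(lab[i] <<- 1L)
    v <- vapply(kids, rec, integer(1))
    m <- max(v)
    lab[i] <<- m + (sum(v == m) >= 2)
  }
  rec(which(parent == 0))
  lab
}

# random segment tree as a parent vector (segment 1 is the root)
random_parent_vector <- function(n) {
  if (n == 1) return(0L)
  c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
}
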