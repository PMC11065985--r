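# Digital test shapes, built in code (no fixture files).

make_ball <- function(radius, dim = rep(2L * radius + 5L, 3), spacing = 1) {
  ctr <- (dim + 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                               z = seq_len(dim[3])))
  a <- array(colSums((t(idx) - ctr)^2) <= radius^2, dim = dim)
  vt_volume(a, rep(spacing, 3))
}

# cylinder along x
make_cylinder <- function(radius, length, pad = 3L, spacing = 1) {
  dim <- c(length, 2L * radius + 2L * pad + 1L, 2L * radius + 2L * pad + 1L)
  cy <- (dim[2] + 1) / 2
  cz <- (dim[3] + 1) / 2
  a <- array(FALSE, dim = dim)
  for (y in seq_len(dim[2])) for (z in seq_len(dim[3]))
    if ((y - cy)^2 + (z - cz)^2 <= radius^2) a[, y, z] <- TRUE
  vt_volume(a, rep(spacing, 3))
}

# union of capsules given endpoint matrix (n x 6) and radii, unit spacing
make_capsules <- function(p0, p1, radius, dim) {
  a <- array(FALSE, dim = dim)
  idx <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                               z = seq_len(dim[3])))
  inside <- rep(FALSE, nrow(idx))
  for (s in seq_len(nrow(p0))) {
    u <- p1[s, ] - p0[s, ]
    L2 <- sum(u * u)
    w <- sweep(idx, 2, p0[s, ])
    t <- pmax(0, pmin(1, (w %*% u) / L2))
    d2 <- rowSums((w - t %*% t(u))^2)
    inside <- inside | d2 <= radius[s]^2
  }
  vt_volume(array(inside, dim = dim), c(1, 1, 1))
}
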