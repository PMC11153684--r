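# Internal geometry and 3D raster helpers. World coordinates are
# voxel index * spacing with 0-based indices, axis order (x, y, z).

# world coordinate of 1-based voxel index triplet(s); idx may be a matrix n x 3
vox_to_world <- function(idx, spacing) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(idx - 1, 2, spacing, `*`)
}

# nearest 1-based voxel index for world point(s); clamped into the volume
world_to_vox <- function(p, spacing, shape) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  idx <- round(sweep(p, 2, spacing, `/`)) + 1
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), shape[a])
  storage.mode(idx) <- "integer"
  idx
}

in_bounds <- function(idx, shape) {
  idx[, 1] >= 1 & idx[, 1] <= shape[1] &
    idx[, 2] >= 1 & idx[, 2] <= shape[2] &
    idx[, 3] >= 1 & idx[, 3] <= shape[3]
}

# Euclidean distance from points (n x 3) to the 3D segment a--b; returns n distances
point_segment_distance <- function(p, a, b) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  ab <- b - a
  den <- sum(ab * ab)
  if (den < .Machine$double.eps) {
    d <- sweep(p, 2, a, `-`)
    return(sqrt(rowSums(d * d)))
  }
  t_par <- (sweep(p, 2, a, `-`) %*% ab) / den
  t_par <- pmin(pmax(as.vector(t_par), 0), 1)
  proj <- cbind(a[1] + t_par * ab[1], a[2] + t_par * ab[2], a[3] + t_par * ab[3])
  sqrt(rowSums((p - proj)^2))
}

# integer voxel offsets within a ball of radius r_mm under anisotropic spacing
ball_offsets <- function(r_mm, spacing) {
  n <- pmax(0L, as.integer(floor(r_mm / spacing)))
  off <- as.matrix(expand.grid(x = -n[1]:n[1], y = -n[2]:n[2], z = -n[3]:n[3]))
  keep <- rowSums(sweep(off, 2, spacing, `*`)^2) <= r_mm^2
  unname(off[keep, , drop = FALSE])
}

# 26-connected neighbor offsets
offsets26 <- local({
  o <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  unname(o[rowSums(abs(o)) > 0, , drop = FALSE])
})

# Label 26-connected components of a 3D logical/0-1 array by vectorized
# wavefront BFS. Returns an integer array, 0 = background, labels start at 1
# in order of the smallest linear index contained in each component.
label_components_3d <- function(mask) {
  shape <- dim(mask)
  lab <- array(0L, shape)
  fg <- which(mask > 0)
  if (length(fg) == 0L) return(lab)
  # precompute linear offsets of the 26-neighborhood
  lin_off <- offsets26[, 1] + offsets26[, 2] * shape[1] + offsets26[, 3] * shape[1] * shape[2]
  coords <- arrayInd(fg, shape)
  inside <- array(FALSE, shape)
  inside[fg] <- TRUE
  # guard against wrap-around: neighbors computed per-axis
  nxt <- 1L
  remaining <- array(FALSE, shape)
  remaining[fg] <- TRUE
  seeds <- fg # ordered; which() is ascending
  for (s in seeds) {
    if (!remaining[s]) next
    frontier <- s
    remaining[s] <- FALSE
    lab[s] <- nxt
    while (length(frontier)) {
      ci <- arrayInd(frontier, shape)
      cand_list <- vector("list", nrow(offsets26))
      for (k in seq_len(nrow(offsets26))) {
        nb <- ci
        nb[, 1] <- nb[, 1] + offsets26[k, 1]
        nb[, 2] <- nb[, 2] + offsets26[k, 2]
        nb[, 3] <- nb[, 3] + offsets26[k, 3]
        ok <- in_bounds(nb, shape)
        if (!any(ok)) next
        nb <- nb[ok, , drop = FALSE]
        cand_list[[k]] <- nb[, 1] + (nb[, 2] - 1L) * shape[1] + (nb[, 3] - 1L) * shape[1] * shape[2]
      }
      cand <- unique(unlist(cand_list))
      cand <- cand[remaining[cand]]
      if (length(cand)) {
        remaining[cand] <- FALSE
        lab[cand] <- nxt
      }
      frontier <- cand
    }
    nxt <- nxt + 1L
  }
  lab
}

# Geodesic BFS (26-connectivity) over a set of foreground linear indices,
# starting from `start` (linear index). Returns integer array of step counts,
# -1 outside the reachable set.
geodesic_steps <- function(mask, start) {
  shape <- dim(mask)
  g <- array(-1L, shape)
  g[start] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    ci <- arrayInd(frontier, shape)
    cand_list <- vector("list", nrow(offsets26))
    for (k in seq_len(nrow(offsets26))) {
      nb <- ci
      nb[, 1] <- nb[, 1] + offsets26[k, 1]
      nb[, 2] <- nb[, 2] + offsets26[k, 2]
      nb[, 3] <- nb[, 3] + offsets26[k, 3]
      ok <- in_bounds(nb, shape)
      if (!any(ok)) next
      nb <- nb[ok, , drop = FALSE]
      cand_list[[k]] <- nb[, 1] + (nb[, 2] - 1L) * shape[1] + (nb[, 3] - 1L) * shape[1] * shape[2]
    }
    cand <- unique(unlist(cand_list))
    cand <- cand[mask[cand] > 0 & g[cand] < 0L]
    if (length(cand)) g[cand] <- d
    frontier <- cand
  }
  g
}

# linear indices of voxels whose center lies within radial distance r of the
# axis sl--el with axial projection inside [0, |el - sl|] (flat-capped
# cylinder, as a vessel segment continues into its neighbors rather than
# ending in a hemispherical cap)
cylinder_voxels <- function(sl, el, r, shape, spacing) {
  lo <- pmin(sl, el) - r
  hi <- pmax(sl, el) + r
  i0 <- pmax(1L, floor(lo / spacing) + 1L)
  i1 <- pmin(shape, ceiling(hi / spacing) + 1L)
  if (any(i0 > i1)) return(integer(0))
  grid <- as.matrix(expand.grid(x = i0[1]:i1[1], y = i0[2]:i1[2], z = i0[3]:i1[3]))
  w <- vox_to_world(grid, spacing)
  ab <- el - sl
  len2 <- sum(ab * ab)
  rel <- sweep(w, 2, sl, `-`)
  t_par <- as.vector(rel %*% ab) / len2
  perp2 <- rowSums(rel^2) - t_par^2 * len2
  keep <- t_par >= 0 & t_par <= 1 & perp2 <= r^2
  g <- grid[keep, , drop = FALSE]
  g[, 1] + (g[, 2] - 1L) * shape[1] + (g[, 3] - 1L) * shape[1] * shape[2]
}

# voxel mask of a solid ellipsoid (axis-aligned semi-axes, world mm)
ellipsoid_mask <- function(shape, spacing, center, semi) {
  ax <- (seq_len(shape[1]) - 1) * spacing[1]
  ay <- (seq_len(shape[2]) - 1) * spacing[2]
  az <- (seq_len(shape[3]) - 1) * spacing[3]
  dx2 <- ((ax - center[1]) / semi[1])^2
  dy2 <- ((ay - center[2]) / semi[2])^2
  dz2 <- ((az - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

point_in_ellipsoid <- function(p, center, semi, margin = 0) {
  s <- pmax(semi - margin, .Machine$double.eps)
  sum(((p - center) / s)^2) <= 1
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
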