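#' Detect cylinder-approximated vessels in a volume
#'
#' Stand-in vessel detector for CT-like volumes with bright tubular vessels
#' inside the lungs. The steps are:
#' 1. threshold vessel-intensity voxels inside the lung mask (optionally
#'    excluding a ball around a known tumor);
#' 2. split the voxel set into 26-connected components;
#' 3. extract a centerline per component by geodesic binning: breadth-first
#'    geodesic depth from a farthest endpoint voxel is quantized into bins,
#'    each bin's voxels are clustered into connected groups, and adjacent
#'    clusters are linked, yielding a centerline graph whose degree-3+ nodes
#'    are branch points;
#' 4. split the centerline at branch points into simple arcs and fit each arc
#'    a cylinder: center `c` = member-voxel centroid, direction = principal
#'    axis (oriented along the arc), height from the arc's centerline length,
#'    and radius `r` = 1.5 x mean perpendicular distance of member voxels to
#'    the axis (the factor corrects the solid-cylinder mean, 2R/3, back to R).
#'    Orientation angles are recovered by inverting the endpoint formula of
#'    [segment_endpoints()].
#'
#' @param volume a [volume_image()].
#' @param lung 3D binary lung mask (array or `lung_mask` object).
#' @param intensity_threshold voxels above this are vessel candidates.
#' @param exclude_tumor optional [tumor_spec()]; a ball of its size + 1 mm is
#'   removed from the candidates.
#' @param min_voxels components smaller than this are discarded.
#' @param bin_width geodesic bin width (BFS steps) for centerline clustering.
#' @return a [vessel_segments()] table (zero rows possible is an error; an
#'   empty detection returns `NULL` with a message).
#' @export
detect_vessels <- function(volume, lung, intensity_threshold = 0.5,
                           exclude_tumor = NULL, min_voxels = 12L,
                           bin_width = 1L) {
  mask_arr <- lung_mask_array(lung)
  stopifnot(identical(dim(mask_arr), dim(volume$data)))
  cand <- (volume$data > intensity_threshold) & (mask_arr > 0)
  if (!is.null(exclude_tumor)) {
    shape <- dim(cand)
    ctr <- world_to_vox(exclude_tumor$location, volume$spacing, shape)
    off <- ball_offsets(exclude_tumor$size + 1, volume$spacing)
    nb <- sweep(off, 2, as.numeric(ctr), `+`)
    nb <- nb[in_bounds(nb, shape), , drop = FALSE]
    cand[nb[, 1] + (nb[, 2] - 1) * shape[1] + (nb[, 3] - 1) * shape[1] * shape[2]] <- FALSE
  }
  if (!any(cand)) {
    message("detect_vessels: no vessel voxels above threshold")
    return(NULL)
  }
  lab <- label_components_3d(cand)
  segs <- list()
  for (cid in seq_len(max(lab))) {
    vox <- which(lab == cid)
    if (length(vox) < min_voxels) next
    segs <- c(segs, component_segments(lab == cid, volume$spacing, bin_width))
  }
  if (!length(segs)) {
    message("detect_vessels: no component large enough to fit")
    return(NULL)
  }
  df <- do.call(rbind, lapply(segs, as.data.frame))
  vessel_segments(df)
}

# Extract fitted cylinder segments from one connected voxel component.
component_segments <- function(comp_mask, spacing, bin_width) {
  shape <- dim(comp_mask)
  vox_lin <- which(comp_mask)
  # farthest-point start: BFS from smallest linear index, then from farthest
  g0 <- geodesic_steps(comp_mask, vox_lin[1])
  far <- vox_lin[which.max(g0[vox_lin])]
  g <- geodesic_steps(comp_mask, far)
  depth <- g[vox_lin]
  bins <- depth %/% as.integer(bin_width)

  # cluster each geodesic bin into connected groups
  cluster_id <- array(0L, shape)
  n_clust <- 0L
  clusters <- list() # list of linear-index vectors
  for (b in sort(unique(bins))) {
    sel <- vox_lin[bins == b]
    sub <- array(FALSE, shape)
    sub[sel] <- TRUE
    sublab <- label_components_3d(sub)
    for (k in seq_len(max(sublab))) {
      n_clust <- n_clust + 1L
      members <- which(sublab == k)
      clusters[[n_clust]] <- members
      cluster_id[members] <- n_clust
    }
  }
  if (n_clust == 1L) {
    arc <- list(seq_len(n_clust))
    pairs <- matrix(integer(0), 0, 2)
    junction <- FALSE
  } else {
    # adjacency between clusters: scan 26-neighbors of every voxel
    pairs <- cluster_adjacency(cluster_id, vox_lin, shape)
    deg <- tabulate(c(pairs), nbins = n_clust)
    junction <- deg >= 3
    arc <- centerline_arcs(n_clust, pairs, junction)
  }
  cents <- t(vapply(clusters, function(m) colMeans(vox_to_world(arrayInd(m, shape), spacing)),
                    numeric(3)))
  adj_of <- function(cl) {
    hit <- pairs[, 1] == cl | pairs[, 2] == cl
    setdiff(unique(c(pairs[hit, ])), cl)
  }
  out <- list()
  for (a in arc) {
    members <- unlist(clusters[a])
    if (length(members) < 4) next
    # extend the arc with centroids of junction clusters touching its ends,
    # recovering centerline length otherwise swallowed by the branch point
    ext <- integer(0)
    for (endc in unique(c(a[1], a[length(a)])))
      ext <- c(ext, intersect(adj_of(endc), which(junction)))
    fit <- fit_cylinder(arrayInd(members, shape),
                        if (length(ext)) cents[unique(ext), , drop = FALSE] else NULL,
                        spacing)
    if (!is.null(fit)) out[[length(out) + 1L]] <- fit
  }
  out
}

# unique cluster-id pairs (i < j) that touch via 26-connectivity
cluster_adjacency <- function(cluster_id, vox_lin, shape) {
  ci <- arrayInd(vox_lin, shape)
  own <- cluster_id[vox_lin]
  pr <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(offsets26))) {
    nb <- ci
    nb[, 1] <- nb[, 1] + offsets26[k, 1]
    nb[, 2] <- nb[, 2] + offsets26[k, 2]
    nb[, 3] <- nb[, 3] + offsets26[k, 3]
    ok <- in_bounds(nb, shape)
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * shape[1] + (nb[ok, 3] - 1L) * shape[1] * shape[2]
    other <- cluster_id[lin]
    sel <- other > 0L & other != own[ok]
    if (any(sel)) pr <- rbind(pr, cbind(pmin(own[ok][sel], other[sel]),
                                        pmax(own[ok][sel], other[sel])))
  }
  unique(pr)
}

# split the cluster graph into simple arcs terminated at junctions/endpoints:
# connected components of the subgraph induced on non-junction clusters, each
# ordered by walking from a chain end (junction clusters are excluded)
centerline_arcs <- function(n, pairs, junction) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(v) if (is.null(v)) integer(0) else sort(unique(v)))
  jn <- which(junction)
  sub_adj <- lapply(seq_len(n), function(v)
    if (junction[v]) integer(0) else setdiff(adj[[v]], jn))
  seen <- logical(n)
  seen[jn] <- TRUE
  arcs <- list()
  for (s in which(!junction)) {
    if (seen[s]) next
    comp <- s; seen[s] <- TRUE; frontier <- s
    while (length(frontier)) {
      nb <- unique(unlist(sub_adj[frontier]))
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    degs <- vapply(comp, function(v) length(sub_adj[[v]]), integer(1))
    start <- if (any(degs <= 1)) comp[which(degs <= 1)[1]] else comp[1]
    chain <- start; v <- start
    repeat {
      nb <- setdiff(sub_adj[[v]], chain)
      if (!length(nb)) break
      v <- nb[1]
      chain <- c(chain, v)
    }
    arcs[[length(arcs) + 1L]] <- chain
  }
  arcs
}

# cylinder fit from member voxels, optionally extended by junction centroids
fit_cylinder <- function(vox_idx, junction_pts, spacing) {
  w <- vox_to_world(vox_idx, spacing)
  ctr <- colMeans(w)
  # direction: principal axis of the member voxels
  v <- prcomp(w, center = TRUE)$rotation[, 1]
  pts <- if (is.null(junction_pts)) w else rbind(w, junction_pts)
  along_all <- as.vector(sweep(pts, 2, ctr, `-`) %*% v)
  L <- diff(range(along_all)) # centerline length as projected extent
  if (L < .Machine$double.eps) return(NULL)
  # orient along increasing arc order (sign of v is arbitrary from PCA):
  # point it so the far junction (if any) or the larger spread is positive
  disp <- L * v
  ang <- angles_from_displacement(disp)
  # radius: perpendicular spread around the axis through the centroid
  rel <- sweep(w, 2, ctr, `-`)
  along <- as.vector(rel %*% v)
  perp <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
  r <- 1.5 * mean(perp)
  r <- max(r, min(spacing) / 2) # a one-voxel-thin vessel is half a voxel wide
  data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
             h = ang$h, r = r, o_xy = ang$o_xy, o_xz = ang$o_xz)
}

lung_mask_array <- function(lung) {
  if (inherits(lung, "lung_mask")) lung$mask else lung
}
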