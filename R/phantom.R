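#' Primary tumor specification
#'
#' @param location world coordinates of the tumor center (mm, length 3).
#' @param size tumor radius (mm), > 0.
#' @return object of class `tumor_spec`.
#' @export
tumor_spec <- function(location, size) {
  location <- as.numeric(location)
  stopifnot(length(location) == 3, all(is.finite(location)),
            is.finite(size), size > 0)
  structure(list(location = location, size = as.numeric(size)),
            class = "tumor_spec")
}

#' Phantom specification
#'
#' Defines a synthetic CT-like chest volume: two ellipsoidal lungs, a
#' branching cylindrical vessel tree grown inside the first lung, a spherical
#' primary tumor, and planted ground-truth metastasis sites near distal
#' vessel endpoints. Intensities follow a four-level piecewise-constant model
#' (background 0.1, lung 0.3, vessel 0.7, tumor 0.9) with additive Gaussian
#' noise. Metastasis sites are ground truth only — they are not painted into
#' the volume, emulating a scan taken before the metastases become visible.
#'
#' @param shape voxel counts (x, y, z), each >= 16.
#' @param voxel_spacing mm per voxel, each > 0.
#' @param lung_ellipsoids list of two lists, each `list(center=, semi=)` in
#'   world mm (axis-aligned semi-axes).
#' @param vessel_tree list: `root_start` (world mm), `root_o_xy`, `root_o_xz`
#'   (radians), `root_h` (mm), `root_radius` (mm, > 0), `depth` (>= 1),
#'   `n_children`, `murray_exponent` (child-radius closure rule, see
#'   [child_radii()]), `height_ratio` (child height / parent height),
#'   `branch_angle` (radian perturbation range `c(lo, hi)` applied to both
#'   orientation angles).
#' @param tumor a [tumor_spec()] or `NULL` to place one automatically beside
#'   the vessel root.
#' @param n_metastases number of planted metastasis sites.
#' @param met_radius radius of each planted metastasis ball (mm).
#' @param noise_sd standard deviation of the additive intensity noise, >= 0.
#' @param seed RNG seed; identical spec + seed gives bit-identical phantoms.
#' @return validated spec list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         voxel_spacing = c(1, 1, 1),
                         lung_ellipsoids = default_lungs(shape, voxel_spacing),
                         vessel_tree = default_vessel_tree(lung_ellipsoids),
                         tumor = NULL,
                         n_metastases = 3L,
                         met_radius = 1.5,
                         noise_sd = 0.02,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 16),
            length(voxel_spacing) == 3, all(voxel_spacing > 0),
            length(lung_ellipsoids) == 2,
            vessel_tree$root_radius > 0, vessel_tree$depth >= 1,
            n_metastases >= 0, met_radius > 0, noise_sd >= 0)
  structure(list(shape = shape, voxel_spacing = as.numeric(voxel_spacing),
                 lung_ellipsoids = lung_ellipsoids, vessel_tree = vessel_tree,
                 tumor = tumor, n_metastases = as.integer(n_metastases),
                 met_radius = met_radius, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

default_lungs <- function(shape, spacing) {
  ext <- (shape - 1) * spacing
  list(
    list(center = c(0.31, 0.50, 0.50) * ext, semi = c(0.16, 0.27, 0.36) * ext),
    list(center = c(0.69, 0.50, 0.50) * ext, semi = c(0.16, 0.27, 0.36) * ext)
  )
}

default_vessel_tree <- function(lungs) {
  l <- lungs[[1]]
  list(root_start = l$center + c(0, -0.45, -0.55) * l$semi,
       root_o_xy = pi / 2,      # direction u = (0, sqrt(2)/2, cos(o_xz))
       root_o_xz = 0.65,
       root_h = 0.45 * l$semi[3],
       root_radius = 1.6,
       depth = 4L,
       n_children = 2L,
       murray_exponent = 3,
       height_ratio = 0.75,
       branch_angle = c(0.35, 0.8))
}

#' Murray-style child radii
#'
#' Radii of `n` equal children of a parent vessel under the closure rule
#' `n * r_child^exponent = r_parent^exponent`, so that total conductive
#' capacity is conserved in the sense of Murray's law (exponent 3).
#'
#' @param parent_radius parent radius (mm), > 0.
#' @param n_children number of children, >= 1.
#' @param exponent closure exponent, > 0.
#' @return numeric vector of `n_children` equal radii.
#' @examples
#' child_radii(2, 2, 3) # 2 / 2^(1/3) = 1.5874...
#' @export
child_radii <- function(parent_radius, n_children, exponent = 3) {
  stopifnot(parent_radius > 0, n_children >= 1, exponent > 0)
  rep(parent_radius / n_children^(1 / exponent), n_children)
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Builds the volume and exact (noise-free) ground truth described by a
#' [phantom_spec()]. The vessel tree is grown recursively: children start at
#' the parent's end location, get radii from [child_radii()], heights shrunk
#' by `height_ratio`, and orientation angles perturbed within `branch_angle`;
#' candidate branches whose far end would leave the lung ellipsoid are
#' re-sampled (and shortened as a last resort) so the tree stays inside the
#' lung. Metastasis sites are drawn among leaf endpoints distal to the tumor,
#' weighted by vessel radius — wider distal vessels are likelier seeding
#' sites — which intentionally correlates the planted truth with what the
#' transport model predicts (see the methods vignette for why this coupling
#' is declared openly).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume_image()]) and `truth`: list with
#'   `lung_mask` (0/1 array), `vessel_segments` ([vessel_segments()] table),
#'   `vessel_tree_edges` (data.frame `parent, child` in segment-table row
#'   order), `tumor`, `metastasis_mask` (0/1 array), `metastasis_sites`
#'   (matrix of world coordinates) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  shape <- spec$shape; spacing <- spec$voxel_spacing
  lungs <- spec$lung_ellipsoids

  lung_mask <- ellipsoid_mask(shape, spacing, lungs[[1]]$center, lungs[[1]]$semi) |
    ellipsoid_mask(shape, spacing, lungs[[2]]$center, lungs[[2]]$semi)

  tree <- grow_tree(spec)
  segs <- tree$segments
  root_sl <- c(segs$slx[1], segs$sly[1], segs$slz[1])
  if (!any(vapply(lungs, function(l) point_in_ellipsoid(root_sl, l$center, l$semi),
                  logical(1))))
    stop("vessel tree root does not intersect a lung ellipsoid")

  tumor <- spec$tumor
  if (is.null(tumor)) {
    loc <- root_sl + c(-0.45 * lungs[[1]]$semi[1] * 0.55, 2, 2)
    tumor <- tumor_spec(loc, size = 4)
  }

  vessel_mask <- array(FALSE, shape)
  for (i in seq_len(nrow(segs))) {
    lin <- cylinder_voxels(c(segs$slx[i], segs$sly[i], segs$slz[i]),
                           c(segs$elx[i], segs$ely[i], segs$elz[i]),
                           segs$r[i], shape, spacing)
    vessel_mask[lin] <- TRUE
  }

  tumor_mask <- array(FALSE, shape)
  off <- ball_offsets(tumor$size, spacing)
  ctr <- world_to_vox(tumor$location, spacing, shape)
  nb <- sweep(off, 2, as.numeric(ctr), `+`)
  nb <- nb[in_bounds(nb, shape), , drop = FALSE]
  tumor_mask[nb[, 1] + (nb[, 2] - 1) * shape[1] + (nb[, 3] - 1) * shape[1] * shape[2]] <- TRUE

  met <- plant_metastases(spec, tree, tumor, lung_mask, lungs)

  vol <- array(0.1, shape)
  vol[lung_mask] <- 0.3
  vol[vessel_mask] <- 0.7
  vol[tumor_mask] <- 0.9
  if (spec$noise_sd > 0) vol <- vol + array(rnorm(prod(shape), 0, spec$noise_sd), shape)

  truth <- list(lung_mask = array(as.integer(lung_mask), shape),
                vessel_segments = segs,
                vessel_tree_edges = tree$edges,
                tumor = tumor,
                metastasis_mask = met$mask,
                metastasis_sites = met$sites,
                spec = spec)
  list(volume = volume_image(vol, spacing), truth = truth)
}

# Recursive containment-steered growth of the branching cylinder tree.
grow_tree <- function(spec) {
  vt <- spec$vessel_tree
  lung <- spec$lung_ellipsoids[[1]]
  rows <- list(); edges_p <- integer(0); edges_c <- integer(0)

  add_segment <- function(start, o_xy, o_xz, h, r, depth, parent) {
    u <- as.vector(direction_from_angles(o_xy, o_xz))
    el <- start + h * u
    ctr <- (start + el) / 2
    rows[[length(rows) + 1L]] <<- data.frame(
      cx = ctr[1], cy = ctr[2], cz = ctr[3], h = h, r = r,
      o_xy = o_xy %% (2 * pi), o_xz = o_xz, depth = depth)
    id <- length(rows)
    if (parent > 0) { edges_p <<- c(edges_p, parent); edges_c <<- c(edges_c, id) }
    if (depth < vt$depth) {
      rs <- child_radii(r, vt$n_children, vt$murray_exponent)
      h_child <- h * vt$height_ratio
      for (k in seq_len(vt$n_children)) {
        sgn <- if (k %% 2 == 1) 1 else -1
        br <- steer_branch(el, o_xy, o_xz, h_child, rs[k], sgn, vt, lung)
        if (!is.null(br))
          add_segment(el, br$o_xy, br$o_xz, br$h, rs[k], depth + 1L, id)
      }
    }
    invisible(id)
  }
  add_segment(vt$root_start, vt$root_o_xy, vt$root_o_xz, vt$root_h,
              vt$root_radius, 1L, 0L)
  segs <- vessel_segments(do.call(rbind, rows))
  list(segments = segs,
       edges = data.frame(parent = edges_p, child = edges_c))
}

# sample a child orientation whose far end stays inside the lung ellipsoid;
# tries both lateral signs and progressively shorter branches before giving up
steer_branch <- function(start, o_xy, o_xz, h, r, sgn, vt, lung, tries = 40L) {
  best <- NULL
  for (attempt in seq_len(tries)) {
    d1 <- runif(1, vt$branch_angle[1], vt$branch_angle[2])
    d2 <- runif(1, vt$branch_angle[1], vt$branch_angle[2])
    s1 <- if (attempt <= tries / 2) sgn else -sgn
    oxy <- (o_xy + s1 * d1) %% (2 * pi)
    oxz <- clamp(o_xz + s1 * d2 * (if (attempt %% 2 == 0) -1 else 1),
                 0.05, pi - 0.05)
    el <- start + h * as.vector(direction_from_angles(oxy, oxz))
    if (point_in_ellipsoid(el, lung$center, lung$semi, margin = r + 1))
      return(list(o_xy = oxy, o_xz = oxz, h = h))
    if (is.null(best)) best <- list(o_xy = oxy, o_xz = oxz)
  }
  for (shrink in c(0.7, 0.5, 0.35, 0.25)) {
    el <- start + h * shrink * as.vector(direction_from_angles(best$o_xy, best$o_xz))
    if (point_in_ellipsoid(el, lung$center, lung$semi, margin = r + 1))
      return(list(o_xy = best$o_xy, o_xz = best$o_xz, h = h * shrink))
  }
  NULL
}

plant_metastases <- function(spec, tree, tumor, lung_mask, lungs) {
  shape <- spec$shape; spacing <- spec$voxel_spacing
  mask <- array(0L, shape)
  if (spec$n_metastases == 0L)
    return(list(mask = mask, sites = matrix(numeric(0), 0, 3)))
  segs <- tree$segments
  leaves <- setdiff(segs$id, tree$edges$parent)
  ep <- cbind(segs$elx[leaves], segs$ely[leaves], segs$elz[leaves])
  dist_tumor <- sqrt(rowSums(sweep(ep, 2, tumor$location, `-`)^2))
  distal <- dist_tumor >= stats::median(dist_tumor)
  if (sum(distal) >= spec$n_metastases) {
    leaves <- leaves[distal]; ep <- ep[distal, , drop = FALSE]
  }
  w <- segs$r[leaves]
  k <- min(spec$n_metastases, length(leaves))
  pick <- sample.int(length(leaves), k, prob = w / sum(w))
  lung1 <- lungs[[1]]
  sites <- matrix(0, k, 3)
  for (m in seq_len(k)) {
    # nudge the site toward the lung center so the planted ball stays in tissue
    site <- ep[pick[m], ]
    dirc <- lung1$center - site
    nrmc <- sqrt(sum(dirc^2))
    if (nrmc > 0) site <- site + dirc / nrmc * min(2, nrmc)
    sites[m, ] <- site
    off <- ball_offsets(spec$met_radius, spacing)
    ctr <- world_to_vox(site, spacing, shape)
    nb <- sweep(off, 2, as.numeric(ctr), `+`)
    nb <- nb[in_bounds(nb, shape), , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1) * shape[1] + (nb[, 3] - 1) * shape[1] * shape[2]
    lin <- lin[lung_mask[lin]] # containment: metastasis voxels are lung tissue
    mask[lin] <- 1L
  }
  list(mask = mask, sites = sites)
}

#' Write a phantom to disk
#'
#' Volume and ground-truth masks as NIfTI, vessel segments and tree edges as
#' a JSON sidecar, and the spec as YAML.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spc <- phantom$volume$spacing
  paths <- c(
    volume = file.path(dir, "volume.nii.gz"),
    lung_mask = file.path(dir, "lung_mask.nii.gz"),
    metastasis_mask = file.path(dir, "metastasis_mask.nii.gz"),
    vessels = file.path(dir, "vessels.json"),
    spec = file.path(dir, "spec.yaml"))
  write_volume(phantom$volume, paths["volume"])
  write_volume(volume_image(phantom$truth$lung_mask + 0, spc), paths["lung_mask"])
  write_volume(volume_image(phantom$truth$metastasis_mask + 0, spc), paths["metastasis_mask"])
  jsonlite::write_json(list(segments = as.data.frame(phantom$truth$vessel_segments),
                            edges = phantom$truth$vessel_tree_edges,
                            tumor = phantom$truth$tumor[c("location", "size")]),
                       paths["vessels"], digits = NA, auto_unbox = TRUE)
  sp <- phantom$truth$spec
  yaml::write_yaml(lapply(unclass(sp), function(x) if (is.language(x)) NULL else x),
                   paths["spec"])
  invisible(paths)
}
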