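#' Uniform spatial sampling grid
#'
#' Lattice points at strides `alpha = (alpha_x, alpha_y, alpha_z)` voxels per
#' axis, starting at the origin voxel, in deterministic z-major order (z
#' varies slowest, then y, then x).
#'
#' @param shape volume voxel counts (x, y, z).
#' @param alpha integer strides per axis, each in `[1, shape]`.
#' @param spacing voxel spacing (mm) for the world coordinates.
#' @return data.frame with voxel indices `ix, iy, iz` (1-based) and world
#'   coordinates `x, y, z` (mm).
#' @export
sample_grid <- function(shape, alpha, spacing = c(1, 1, 1)) {
  alpha <- as.integer(alpha)
  stopifnot(length(alpha) == 3, all(alpha >= 1), all(alpha <= shape))
  g <- expand.grid(ix = seq(1L, shape[1], by = alpha[1]),
                   iy = seq(1L, shape[2], by = alpha[2]),
                   iz = seq(1L, shape[3], by = alpha[3]))
  w <- vox_to_world(as.matrix(g), spacing)
  g$x <- w[, 1]; g$y <- w[, 2]; g$z <- w[, 3]
  g
}

#' Generate the metastasis probability heatmap
#'
#' Evaluates the biophysical model at every grid point: points outside the
#' lung mask are assigned 0 without model evaluation; for the rest, the
#' settled cell count at stop time `T` is computed along the unique
#' spanning-tree path from the tumor's nearest vessel. Counts are
#' L1-normalized into a probability field stored at the lattice points. If
#' every count is zero the heatmap is all-zero with `normalized = FALSE` and
#' a warning.
#'
#' @param volume a [volume_image()] (provides shape and spacing).
#' @param tumor a [tumor_spec()].
#' @param lung lung mask (array or `lung_mask`).
#' @param tree spanning-tree `vessel_graph`.
#' @param alpha grid strides, see [sample_grid()].
#' @param params a [model_params()].
#' @return object of class `heatmap`: list with `values` (3D array, shape of
#'   the volume, nonzero only at lattice points), `grid` (data.frame with
#'   per-point `count` and `prob`), `normalized`, `alpha`, `spacing`.
#' @export
generate_heatmap <- function(volume, tumor, lung, tree, alpha = c(4, 4, 4),
                             params = model_params()) {
  shape <- dim(volume$data)
  spacing <- volume$spacing
  mask <- lung_mask_array(lung)
  stopifnot(identical(dim(mask), shape))
  grid <- sample_grid(shape, alpha, spacing)
  if (nrow(grid) == 0) stop("empty sampling grid")
  cache <- heatmap_cache(tree, tumor, params)
  counts <- numeric(nrow(grid))
  inside <- mask[cbind(grid$ix, grid$iy, grid$iz)] > 0
  for (k in which(inside)) {
    counts[k] <- predict_cell_count(tree, tumor, mask,
                                    c(grid$x[k], grid$y[k], grid$z[k]),
                                    params, spacing, cache = cache)$c
  }
  total <- sum(counts)
  grid$count <- counts
  values <- array(0, shape)
  if (total > 0) {
    grid$prob <- counts / total
    normalized <- TRUE
  } else {
    warning("all settled-cell counts are zero; heatmap left unnormalized")
    grid$prob <- counts
    normalized <- FALSE
  }
  values[cbind(grid$ix, grid$iy, grid$iz)] <- grid$prob
  structure(list(values = values, grid = grid, normalized = normalized,
                 alpha = as.integer(alpha), spacing = spacing),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  nz <- sum(x$grid$prob > 0)
  cat("<heatmap> ", nrow(x$grid), " grid points (alpha ",
      paste(x$alpha, collapse = "x"), "), ", nz, " nonzero, ",
      if (x$normalized) "L1-normalized" else "NOT normalized", "\n", sep = "")
  invisible(x)
}

#' Dense display map by trilinear upsampling
#'
#' Interpolates the lattice values to every voxel for visualization. The
#' result is a derived display artifact: it is not L1-normalized and must
#' not be used for scoring normalization checks.
#'
#' @param hm a `heatmap`.
#' @return 3D array, shape of the source volume.
#' @export
heatmap_dense <- function(hm) {
  shape <- dim(hm$values)
  gx <- sort(unique(hm$grid$ix)); gy <- sort(unique(hm$grid$iy)); gz <- sort(unique(hm$grid$iz))
  vals <- array(hm$grid$prob, dim = c(length(gx), length(gy), length(gz)))
  interp_axis <- function(a, knots, n) {
    # linear interpolation weights from lattice knots to 1..n
    pos <- seq_len(n)
    lo <- findInterval(pos, knots, rightmost.closed = TRUE)
    lo <- clamp(lo, 1, length(knots) - if (length(knots) > 1) 1 else 0)
    if (length(knots) == 1) return(list(lo = rep(1L, n), hi = rep(1L, n), w = rep(0, n)))
    hi <- lo + 1L
    w <- (pos - knots[lo]) / (knots[hi] - knots[lo])
    w <- clamp(w, 0, 1)
    list(lo = lo, hi = hi, w = w)
  }
  ax <- interp_axis(1, gx, shape[1]); ay <- interp_axis(2, gy, shape[2]); az <- interp_axis(3, gz, shape[3])
  # interpolate axis by axis
  v1 <- vals[ax$lo, , , drop = FALSE] * (1 - ax$w) + vals[ax$hi, , , drop = FALSE] * ax$w
  v2 <- v1[, ay$lo, , drop = FALSE] * rep(1 - ay$w, each = shape[1]) +
        v1[, ay$hi, , drop = FALSE] * rep(ay$w, each = shape[1])
  wz_lo <- rep(1 - az$w, each = shape[1] * shape[2])
  wz_hi <- rep(az$w, each = shape[1] * shape[2])
  v3 <- v2[, , az$lo, drop = FALSE] * wz_lo + v2[, , az$hi, drop = FALSE] * wz_hi
  array(v3, shape)
}

#' Write heatmap artifacts
#'
#' NIfTI volume aligned to the input image plus a CSV of the grid-point
#' probabilities.
#'
#' @param hm a `heatmap`.
#' @param nifti_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_heatmap <- function(hm, nifti_path = NULL, csv_path = NULL) {
  if (!is.null(nifti_path))
    write_volume(volume_image(hm$values, hm$spacing), nifti_path)
  if (!is.null(csv_path))
    utils::write.csv(hm$grid[, c("x", "y", "z", "prob")], csv_path, row.names = FALSE)
  invisible(list(nifti = nifti_path, csv = csv_path))
}
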