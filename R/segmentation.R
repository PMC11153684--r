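#' Adaptive Canny edge detection on a 2D slice
#'
#' Canny edges with hysteresis thresholds derived from the slice's intensity
#' median: `low = (1 - k) * median`, `high = (1 + k) * median`. The slice is
#' Gaussian-smoothed, Sobel gradients and their magnitude computed, thin
#' edges kept by non-maximum suppression along the quantized gradient
#' direction, and weak edges retained only when 8-connected to a strong
#' edge. A constant slice yields an empty edge map.
#'
#' @param slice2d numeric matrix, at least 3 x 3.
#' @param k adaptive threshold constant in (0, 1).
#' @param sigma Gaussian smoothing standard deviation (pixels).
#' @return logical matrix of edge pixels.
#' @export
canny_slice <- function(slice2d, k = 0.33, sigma = 1) {
  stopifnot(is.matrix(slice2d), nrow(slice2d) >= 3, ncol(slice2d) >= 3,
            k > 0, k < 1)
  med <- median(slice2d)
  lo_thr <- max((1 - k) * med, 1e-8)
  hi_thr <- max((1 + k) * med, 2e-8)

  sm <- gaussian_smooth(slice2d, sigma)
  sob_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # gradient along rows (x)
  sob_y <- t(sob_x)
  gx <- conv2_same(sm, sob_x)
  gy <- conv2_same(sm, sob_y)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) < 1e-12) return(matrix(FALSE, nrow(slice2d), ncol(slice2d)))

  nms <- nonmax_suppress(mag, gx, gy)
  strong <- nms & (mag > hi_thr)
  weak <- nms & (mag > lo_thr)
  if (!any(strong)) return(matrix(FALSE, nrow(slice2d), ncol(slice2d)))
  hysteresis(strong, weak)
}

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(2.5 * sigma))
  kern1 <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  kern1 <- kern1 / sum(kern1)
  kern <- outer(kern1, kern1)
  conv2_same(m, kern)
}

# 2D correlation with replicate padding (avoids wrap-around halos at borders)
conv2_same <- function(m, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(seq_len(nr + 2 * kr) - kr, 1, nr)
  ci <- clamp(seq_len(nc + 2 * kc) - kc, 1, nc)
  pad <- m[ri, ci]
  out <- EBImage::filter2(pad, kern, boundary = 0)
  out[kr + seq_len(nr), kc + seq_len(nc)]
}

nonmax_suppress <- function(mag, gx, gy) {
  nr <- nrow(mag); nc <- ncol(mag)
  ang <- atan2(gy, gx) %% pi # direction modulo pi
  sector <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4
  # sector 0: gradient along x (rows); 1: diagonal (+1,+1); 2: along y; 3: diagonal (+1,-1)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(1, -1))
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    d <- offs[[as.character(s)]]
    nb1 <- shift(mag, d[1], d[2])
    nb2 <- shift(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= nb1 & mag > nb2)
  }
  keep
}

hysteresis <- function(strong, weak) {
  lab <- EBImage::bwlabel(weak)
  keep_labels <- unique(lab[strong])
  keep_labels <- keep_labels[keep_labels > 0]
  out <- array(lab %in% keep_labels, dim(weak))
  matrix(out, nrow(weak), ncol(weak))
}

#' Detect the two lung ellipses in an edge map
#'
#' Bounded discretized Hough-style search for the two highest-scoring,
#' center-separated ellipses. For every semi-axis pair `(a, b)` a rasterized
#' elliptical ring is correlated with the (dilated) edge map — an FFT
#' convolution scores all centers at once — and a candidate's score is the
#' fraction of its perimeter supported by edges. The best-scoring ellipse is
#' taken first; the second is the best whose center is farther than
#' `min_sep` from the first. Ellipses are axis-aligned (rotation 0): the
#' per-slice lung cross-sections this targets are close to axis-aligned, and
#' a full 5-parameter search would add cost without benefit here.
#'
#' @param edges logical/0-1 matrix from [canny_slice()].
#' @param a_range,b_range candidate semi-axis ranges in pixels,
#'   `c(min, max)`.
#' @param axis_step step between candidate semi-axes (pixels).
#' @param min_score minimum perimeter-support fraction for a valid ellipse.
#' @param min_sep minimum center separation (pixels); default `a1 + 2` where
#'   `a1` is the first ellipse's x semi-axis.
#' @param slice slice label used in error messages.
#' @return list of two `list(cx, cy, a, b, phi = 0, score)`, ordered by
#'   center x.
#' @export
hough_two_ellipses <- function(edges, a_range = c(4, 18), b_range = c(4, 26),
                               axis_step = 1L, min_score = 0.5,
                               min_sep = NULL, slice = NA) {
  edges <- edges > 0
  if (!any(edges)) stop("empty edge map (slice ", slice, ")")
  ed <- EBImage::dilate(edges + 0, EBImage::makeBrush(3, "box"))
  best <- hough_score_maps(ed, a_range, b_range, axis_step)
  e1 <- hough_pick(best, exclude = NULL, min_sep = 0)
  if (is.null(e1) || e1$score < min_score)
    stop("fewer than two ellipse candidates above the vote threshold (slice ",
         slice, ")")
  if (is.null(min_sep)) min_sep <- e1$a + 2
  e2 <- hough_pick(best, exclude = c(e1$cx, e1$cy), min_sep = min_sep)
  if (is.null(e2) || e2$score < min_score)
    stop("fewer than two ellipse candidates above the vote threshold (slice ",
         slice, ")")
  out <- list(e1, e2)
  # coarse-to-fine: the dilated-edge scoring has a +/-1 px tolerance, so lock
  # the parameters onto the raw edges with a small local search
  refine_win <- if (axis_step > 1L) 2L else 1L # cover the coarse grid's gap
  out <- lapply(out, function(e) refine_ellipse(edges, e, window = refine_win))
  out[order(vapply(out, `[[`, numeric(1), "cx"))]
}

# local re-fit of one ellipse on the raw (undilated) edge map; axis and
# center perturbations are scanned in order of increasing change, so ties
# keep the smallest adjustment (deterministic)
refine_ellipse <- function(edges, e, window = 1L) {
  nr <- nrow(edges); nc <- ncol(edges)
  dab <- expand.grid(da = -window:window, db = -window:window)
  dab <- dab[order(abs(dab$da) + abs(dab$db)), ]
  dxy <- expand.grid(dcx = -window:window, dcy = -window:window)
  dxy <- dxy[order(abs(dxy$dcx) + abs(dxy$dcy)), ]
  best <- -1; sel <- c(0L, 0L, 0L, 0L)
  for (k in seq_len(nrow(dab))) {
    a <- e$a + dab$da[k]; b <- e$b + dab$db[k]
    if (a < 2 || b < 2) next
    th <- seq(0, 2 * pi, length.out = max(32L, ceiling(2 * pi * max(a, b))))
    pts <- unique(cbind(round(a * cos(th)), round(b * sin(th))))
    for (m in seq_len(nrow(dxy))) {
      px <- pts[, 1] + e$cx + dxy$dcx[m]
      py <- pts[, 2] + e$cy + dxy$dcy[m]
      ok <- px >= 1 & px <= nr & py >= 1 & py <= nc
      if (!any(ok)) next
      sc <- sum(edges[cbind(px[ok], py[ok])]) / nrow(pts)
      if (sc > best) { best <- sc; sel <- c(dxy$dcx[m], dxy$dcy[m], dab$da[k], dab$db[k]) }
    }
  }
  e$cx <- e$cx + sel[1]; e$cy <- e$cy + sel[2]
  e$a <- e$a + sel[3]; e$b <- e$b + sel[4]
  e$score_raw <- best
  e
}

# score all centers for each (a, b); returns per-pixel best score and axes
hough_score_maps <- function(edge_dil, a_range, b_range, axis_step) {
  nr <- nrow(edge_dil); nc <- ncol(edge_dil)
  a_vals <- seq(a_range[1], a_range[2], by = axis_step)
  b_vals <- seq(b_range[1], b_range[2], by = axis_step)
  score <- matrix(-1, nr, nc)
  best_a <- matrix(0L, nr, nc); best_b <- matrix(0L, nr, nc)
  for (a in a_vals) for (b in b_vals) {
    kern <- ellipse_ring_kernel(a, b)
    s <- EBImage::filter2(edge_dil, kern$kernel, boundary = 0) / kern$n
    upd <- s > score
    if (any(upd)) {
      score[upd] <- s[upd]
      best_a[upd] <- a
      best_b[upd] <- b
    }
  }
  # forbid centers whose ellipse would leave the image
  rr <- row(score); cc <- col(score)
  bad <- rr - best_a < 1 | rr + best_a > nr | cc - best_b < 1 | cc + best_b > nc
  score[bad] <- -1
  list(score = score, a = best_a, b = best_b)
}

ellipse_ring_kernel <- function(a, b) {
  th <- seq(0, 2 * pi, length.out = max(32L, ceiling(2 * pi * max(a, b))))
  pts <- unique(cbind(round(a * cos(th)), round(b * sin(th))))
  kern <- matrix(0, 2 * a + 1, 2 * b + 1)
  kern[cbind(pts[, 1] + a + 1, pts[, 2] + b + 1)] <- 1
  list(kernel = kern, n = nrow(pts))
}

# Among candidates within `slack` of the best support fraction, prefer the
# largest-area ellipse: small rings over image clutter easily reach full
# perimeter support, while the lung boundary is the largest consistent model.
hough_pick <- function(best, exclude, min_sep, slack = 0.05) {
  score <- best$score
  if (!is.null(exclude)) {
    rr <- row(score); cc <- col(score)
    score[sqrt((rr - exclude[1])^2 + (cc - exclude[2])^2) <= min_sep] <- -1
  }
  smax <- max(score)
  if (smax <= 0) return(NULL)
  eligible <- which(score >= smax - slack)
  area <- best$a[eligible] * best$b[eligible]
  m <- eligible[which.max(area)] # first maximum: deterministic scan order
  ij <- arrayInd(m, dim(score))
  list(cx = ij[1, 1], cy = ij[1, 2],
       a = best$a[m], b = best$b[m], phi = 0, score = score[m])
}

#' Close lung contours and fill the interior
#'
#' For each detected ellipse, edge components 8-connected to the ellipse's
#' rasterized ring are accreted, the union is morphologically closed with
#' growing disc radii until the contour closes, and the interior is filled —
#' the inner side of the two shapes is the healthy-tissue area.
#'
#' @param edges logical/0-1 edge matrix.
#' @param ellipses list of two ellipses from [hough_two_ellipses()].
#' @param max_close_iter bound on closing radius growth.
#' @param margin window margin (pixels) around each ellipse within which
#'   edges may be accreted.
#' @param slice slice label for error messages.
#' @return list of two logical matrices (filled regions).
#' @export
close_lung_contours <- function(edges, ellipses, max_close_iter = 4L,
                                margin = 4L, slice = NA) {
  edges <- edges > 0
  lapply(ellipses, function(e) {
    ring <- ellipse_ring_mask(dim(edges), e)
    win <- matrix(FALSE, nrow(edges), ncol(edges))
    r0 <- clamp(e$cx - e$a - margin, 1, nrow(edges)); r1 <- clamp(e$cx + e$a + margin, 1, nrow(edges))
    c0 <- clamp(e$cy - e$b - margin, 1, ncol(edges)); c1 <- clamp(e$cy + e$b + margin, 1, ncol(edges))
    win[r0:r1, c0:c1] <- TRUE
    lab <- EBImage::bwlabel((edges & win) + 0)
    ring_d <- EBImage::dilate(ring + 0, EBImage::makeBrush(3, "box")) > 0
    keep <- setdiff(unique(lab[ring_d]), 0)
    contour <- (lab %in% keep)
    contour <- matrix(contour, nrow(edges), ncol(edges)) | ring
    target_area <- pi * e$a * e$b / 2
    for (it in 0:max_close_iter) {
      # it = 0: an already-closed contour fills without any morphology
      closed <- if (it == 0) contour + 0 else
        EBImage::closing(contour + 0, EBImage::makeBrush(2 * it + 1, "disc"))
      filled <- EBImage::fillHull(closed) > 0
      if (filled[e$cx, e$cy] && sum(filled) >= target_area)
        return(filled & win)
    }
    stop("could not close lung contour (slice ", slice, ")")
  })
}

ellipse_ring_mask <- function(shape, e) {
  kern <- ellipse_ring_kernel(e$a, e$b)$kernel
  out <- matrix(FALSE, shape[1], shape[2])
  pr <- which(kern > 0, arr.ind = TRUE)
  rr <- pr[, 1] - (e$a + 1) + e$cx
  cc <- pr[, 2] - (e$b + 1) + e$cy
  ok <- rr >= 1 & rr <= shape[1] & cc >= 1 & cc <= shape[2]
  out[cbind(rr[ok], cc[ok])] <- TRUE
  out
}

#' Reconstruct the 3D lung mask from per-slice regions
#'
#' Stacks the per-slice filled regions along z, interpolates slices whose
#' segmentation failed from their nearest successful neighbors (logged via
#' `message()`), applies iterative Laplacian smoothing to the binary field
#' (each voxel moved toward the mean of its 6-neighbors with weight `w` for
#' a fixed number of iterations) and re-binarizes at 0.5.
#'
#' @param slices list of per-slice results, one per z: a logical matrix
#'   (union of the two filled regions), `NULL` for a failed slice, or
#'   `"empty"` for a slice known to contain no lung.
#' @param shape volume shape (x, y, z).
#' @param iterations smoothing iterations.
#' @param w smoothing weight in `[0, 1]`.
#' @param ellipse_table optional per-slice ellipse parameter data.frame
#'   retained for inspection.
#' @return object of class `lung_mask`: list with `mask` (0/1 integer
#'   array) and `ellipses` (provenance table).
#' @export
reconstruct_lung_mask <- function(slices, shape, iterations = 10L, w = 0.5,
                                  ellipse_table = NULL) {
  stopifnot(length(slices) == shape[3])
  stack <- array(0, shape)
  failed <- which(vapply(slices, is.null, logical(1)))
  good <- which(vapply(slices, function(s) is.matrix(s), logical(1)))
  for (z in good) stack[, , z] <- slices[[z]] + 0
  if (length(failed)) {
    message("interpolating ", length(failed), " failed slice(s): ",
            paste(failed, collapse = ", "))
    for (z in failed) {
      if (!length(good)) break
      nb <- good[which.min(abs(good - z))]
      stack[, , z] <- stack[, , nb]
    }
  }
  sm <- stack
  if (shape[3] == 1) {
    for (it in seq_len(iterations)) sm[, , 1] <- (1 - w) * sm[, , 1] +
        w * neighbor_mean_2d(sm[, , 1])
  } else {
    for (it in seq_len(iterations)) sm <- (1 - w) * sm + w * neighbor_mean_3d(sm)
  }
  mask <- array(as.integer(sm >= 0.5), shape)
  structure(list(mask = mask, ellipses = ellipse_table), class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat("<lung_mask> ", paste(dim(x$mask), collapse = " x "), " voxels, ",
      sum(x$mask), " tissue voxels\n", sep = "")
  invisible(x)
}

neighbor_mean_3d <- function(a) {
  shape <- dim(a)
  shift3 <- function(axis, by) {
    idx <- lapply(shape, seq_len)
    src <- clamp(idx[[axis]] + by, 1, shape[axis]) # replicate border
    idx[[axis]] <- src
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  (shift3(1, 1) + shift3(1, -1) + shift3(2, 1) + shift3(2, -1) +
     shift3(3, 1) + shift3(3, -1)) / 6
}

neighbor_mean_2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[clamp(seq_len(nr) - 1, 1, nr), ]
  dn <- m[clamp(seq_len(nr) + 1, 1, nr), ]
  lf <- m[, clamp(seq_len(nc) - 1, 1, nc)]
  rt <- m[, clamp(seq_len(nc) + 1, 1, nc)]
  (up + dn + lf + rt) / 4
}

#' Detect the primary tumor
#'
#' If a manual annotation is supplied it is returned verbatim (mirroring the
#' clinician-tagged pathway). Otherwise the detector thresholds the volume
#' adaptively at `median + frac * (max - median)`, labels 3D connected
#' components, and returns the centroid and equivalent-sphere radius of the
#' component with the highest mean intensity.
#'
#' @param volume a [volume_image()].
#' @param manual optional [tumor_spec()] passed through unchanged.
#' @param frac adaptive threshold position in (0, 1).
#' @param min_voxels minimum component size.
#' @return a [tumor_spec()].
#' @export
detect_primary_tumor <- function(volume, manual = NULL, frac = 0.8,
                                 min_voxels = 5L) {
  if (!is.null(manual)) {
    stopifnot(inherits(manual, "tumor_spec"))
    return(manual)
  }
  v <- volume$data
  med <- median(v); mx <- max(v)
  if (!is.finite(mx) || mx - med < 1e-9) stop("no tumor found")
  thr <- med + frac * (mx - med)
  cand <- v > thr
  if (!any(cand)) stop("no tumor found")
  lab <- label_components_3d(cand)
  sizes <- tabulate(lab[lab > 0])
  ok <- which(sizes >= min_voxels)
  if (!length(ok)) stop("no tumor found")
  mean_int <- vapply(ok, function(l) mean(v[lab == l]), numeric(1))
  best <- ok[which.max(mean_int)]
  vox <- which(lab == best)
  w <- vox_to_world(arrayInd(vox, dim(v)), volume$spacing)
  vol_mm3 <- length(vox) * prod(volume$spacing)
  tumor_spec(colMeans(w), size = (3 * vol_mm3 / (4 * pi))^(1 / 3))
}

#' Segment the lungs from a volume
#'
#' Full per-slice pipeline: adaptive Canny edges, two-ellipse Hough
#' detection, contour closure and filling, then 3D reconstruction with
#' Laplacian smoothing. The search is tracked: the middle slice (largest
#' lung cross-section) is searched over the full semi-axis range, and
#' neighboring slices reuse the previous slice's ellipse parameters within a
#' +/- `track_window` window, falling back to a full search on failure.
#' Slices with fewer than `min_edge_pixels` edge pixels are treated as
#' lung-free. If `tumor` is given, a ball of its size + 1 mm is removed from
#' the healthy-tissue mask (settlement targets must be healthy tissue, not
#' tumor).
#'
#' @param volume a [volume_image()].
#' @param canny_k adaptive Canny constant.
#' @param a_range,b_range,axis_step,min_score Hough parameters, see
#'   [hough_two_ellipses()].
#' @param track_window semi-axis/center tracking window (pixels).
#' @param min_edge_pixels below this many edge pixels a slice is lung-free.
#' @param smoothing_iterations,smoothing_weight see
#'   [reconstruct_lung_mask()].
#' @param tumor optional [tumor_spec()] to carve out of the mask.
#' @return a `lung_mask` (with per-slice ellipse provenance in `$ellipses`).
#' @export
segment_lungs <- function(volume, canny_k = 0.33,
                          a_range = NULL, b_range = NULL, axis_step = 1L,
                          min_score = 0.5, track_window = 4L,
                          min_edge_pixels = 20L,
                          smoothing_iterations = 10L, smoothing_weight = 0.5,
                          tumor = NULL) {
  shape <- dim(volume$data)
  if (is.null(a_range)) a_range <- c(3, max(4, floor(shape[1] / 4)))
  if (is.null(b_range)) b_range <- c(3, max(4, floor(shape[2] / 2.2)))
  slices <- vector("list", shape[3])
  prov <- list()
  order_z <- slice_order(shape[3])
  prev <- NULL # tracked ellipse pair keyed by previous processed neighbor
  tracked <- vector("list", shape[3])
  for (z in order_z) {
    edges <- canny_slice(volume$data[, , z], k = canny_k)
    if (sum(edges) < min_edge_pixels) {
      slices[[z]] <- "empty"
      next
    }
    nb_z <- nearest_processed_neighbor(z, tracked)
    guess <- if (!is.null(nb_z)) tracked[[nb_z]] else NULL
    res <- try_slice(edges, guess, a_range, b_range, axis_step, min_score,
                     track_window, z)
    if (is.null(res)) {
      slices[[z]] <- NULL
    } else {
      slices[[z]] <- res$region
      tracked[[z]] <- res$ellipses
      for (e in res$ellipses)
        prov[[length(prov) + 1L]] <- data.frame(z = z, cx = e$cx, cy = e$cy,
                                                a = e$a, b = e$b,
                                                score = e$score)
    }
  }
  slices <- lapply(slices, function(s) if (identical(s, "empty"))
    matrix(FALSE, shape[1], shape[2]) else s)
  lm <- reconstruct_lung_mask(slices, shape,
                              iterations = smoothing_iterations,
                              w = smoothing_weight,
                              ellipse_table = if (length(prov)) do.call(rbind, prov) else NULL)
  if (!is.null(tumor)) {
    off <- ball_offsets(tumor$size + 1, volume$spacing)
    ctr <- world_to_vox(tumor$location, volume$spacing, shape)
    nb <- sweep(off, 2, as.numeric(ctr), `+`)
    nb <- nb[in_bounds(nb, shape), , drop = FALSE]
    lm$mask[nb[, 1] + (nb[, 2] - 1) * shape[1] + (nb[, 3] - 1) * shape[1] * shape[2]] <- 0L
  }
  lm
}

# middle slice first, then alternating outward so tracking has a neighbor
slice_order <- function(nz) {
  mid <- ceiling(nz / 2)
  rest <- setdiff(seq_len(nz), mid)
  rest <- rest[order(abs(rest - mid), rest)]
  c(mid, rest)
}

nearest_processed_neighbor <- function(z, tracked) {
  done <- which(!vapply(tracked, is.null, logical(1)))
  if (!length(done)) return(NULL)
  done[which.min(abs(done - z))]
}

try_slice <- function(edges, guess, a_range, b_range, axis_step, min_score,
                      track_window, z) {
  attempt <- function(ar, br) {
    tryCatch({
      ell <- hough_two_ellipses(edges, a_range = ar, b_range = br,
                                axis_step = axis_step, min_score = min_score,
                                slice = z)
      regions <- close_lung_contours(edges, ell, slice = z)
      list(region = regions[[1]] | regions[[2]], ellipses = ell)
    }, error = function(e) NULL)
  }
  if (!is.null(guess)) {
    amin <- max(a_range[1], min(guess[[1]]$a, guess[[2]]$a) - track_window)
    amax <- min(a_range[2], max(guess[[1]]$a, guess[[2]]$a) + track_window)
    bmin <- max(b_range[1], min(guess[[1]]$b, guess[[2]]$b) - track_window)
    bmax <- min(b_range[2], max(guess[[1]]$b, guess[[2]]$b) + track_window)
    res <- attempt(c(amin, amax), c(bmin, bmax))
    if (!is.null(res)) return(res)
  }
  attempt(a_range, b_range)
}
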