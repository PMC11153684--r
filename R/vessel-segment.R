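#' Cylinder vessel segments
#'
#' A blood vessel is approximated by a cylinder `b = (c, h, r, o_xy, o_xz)`:
#' center of mass `c` (mm, world coordinates), height `h` (mm), average radius
#' `r` (mm), and two orientation angles, `o_xy` in `[0, 2*pi]` and `o_xz` in
#' `[0, pi]`. The start and end locations are derived from the angles through
#' the direction vector
#' `u = c(cos(o_xy), cos(pi/4 - o_xy), cos(o_xz))`:
#' `sl = c - h/2 * u` and `el = c + h/2 * u`. Note that `u` is not unit
#' length in general, so the Euclidean span `||el - sl||` equals `h * ||u||`,
#' not `h`; the same convention is used consistently throughout the package
#' (see the methods vignette for discussion).
#'
#' `vessel_segments()` validates and completes a segment table, adding the
#' derived endpoint columns `slx..elz`.
#'
#' @param df data.frame with columns `cx, cy, cz, h, r, o_xy, o_xz` (one row
#'   per segment); an `id` column is added/overwritten as `1:n`.
#' @return data.frame of class `vessel_segments` with derived endpoint columns.
#' @export
vessel_segments <- function(df) {
  need <- c("cx", "cy", "cz", "h", "r", "o_xy", "o_xz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing segment columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty segment table")
  if (any(df$h <= 0)) stop("segment heights must be > 0")
  if (any(df$r <= 0)) stop("segment radii must be > 0")
  if (any(df$o_xy < 0 | df$o_xy > 2 * pi)) stop("o_xy out of [0, 2*pi]")
  if (any(df$o_xz < 0 | df$o_xz > pi)) stop("o_xz out of [0, pi]")
  df$id <- seq_len(nrow(df))
  ep <- segment_endpoints(df)
  df$slx <- ep$sl[, 1]; df$sly <- ep$sl[, 2]; df$slz <- ep$sl[, 3]
  df$elx <- ep$el[, 1]; df$ely <- ep$el[, 2]; df$elz <- ep$el[, 3]
  class(df) <- c("vessel_segments", "data.frame")
  df
}

#' Direction vector of a segment's orientation angles
#'
#' Evaluates `u = c(cos(o_xy), cos(pi/4 - o_xy), cos(o_xz))`. Vectorized.
#'
#' @param o_xy,o_xz orientation angles (radians).
#' @return n x 3 matrix of direction vectors (not unit length in general).
#' @export
direction_from_angles <- function(o_xy, o_xz) {
  cbind(cos(o_xy), cos(pi / 4 - o_xy), cos(o_xz))
}

#' Start and end locations of cylinder segments
#'
#' Evaluates the endpoint formulas `sl = c - h/2 * u`, `el = c + h/2 * u`
#' with `u = c(cos(o_xy), cos(pi/4 - o_xy), cos(o_xz))`. The midpoint of
#' `sl` and `el` is always `c`.
#'
#' @param b one segment (list/row with `cx, cy, cz, h, o_xy, o_xz`) or a
#'   multi-row segment data.frame.
#' @return list with matrices `sl` and `el` (n x 3, world mm).
#' @examples
#' b <- list(cx = 0, cy = 0, cz = 0, h = 2, o_xy = 0, o_xz = 0)
#' segment_endpoints(b) # sl = (-1, -sqrt(2)/2, -1), el = (1, sqrt(2)/2, 1)
#' @export
segment_endpoints <- function(b) {
  u <- direction_from_angles(b$o_xy, b$o_xz)
  ctr <- cbind(b$cx, b$cy, b$cz)
  half <- b$h / 2 * u
  list(sl = ctr - half, el = ctr + half)
}

# Invert the endpoint formula: find (h > 0, o_xy, o_xz) with h * u = w for a
# displacement w = el - sl. Exact in x and y whenever a representation
# exists; o_xz is clamped when |w_z| > h (the printed direction vector cannot
# represent such displacements). Returns list(h, o_xy, o_xz, exact).
angles_from_displacement <- function(w, eps = 1e-12) {
  wx <- w[1]; wy <- w[2]; wz <- w[3]
  if (abs(wx) < eps && abs(wy) < eps) {
    # (near-)pure-z displacement: unrepresentable; best effort along z
    h <- max(abs(wz), eps)
    o_xy <- pi / 2 # u = (0, sqrt(2)/2, cos(o_xz)); y-error of h*sqrt(2)/2 unavoidable
    o_xz <- if (wz >= 0) 0 else pi
    return(list(h = h, o_xy = o_xy, o_xz = o_xz, exact = FALSE))
  }
  if (abs(wx) < eps) {
    # cos(o_xy) = 0: o_xy in {pi/2, 3*pi/2}; pick sign so h > 0
    o_xy <- if (wy > 0) pi / 2 else 3 * pi / 2
    h <- wy / cos(pi / 4 - o_xy)
  } else {
    t0 <- atan(sqrt(2) * wy / wx - 1)
    o_xy <- if (cos(t0) * wx > 0) t0 else t0 + pi
    o_xy <- o_xy %% (2 * pi)
    h <- wx / cos(o_xy)
  }
  cz <- wz / h
  exact <- abs(cz) <= 1
  o_xz <- acos(clamp(cz, -1, 1))
  list(h = h, o_xy = o_xy, o_xz = o_xz, exact = exact)
}
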