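# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures on disk.

# vessel_graph built directly from a segment table and an explicit edge list
# (bypassing the search-radius construction) for flow / path / MST tests
make_graph <- function(segs, edges) {
  nodes <- vessel_segments(segs)
  if (nrow(edges) && is.null(edges$weight))
    edges$weight <- pmin(nodes$r[edges$i], nodes$r[edges$j])
  if (nrow(edges) && is.null(edges$gap)) edges$gap <- 0
  lungmetmap:::new_vessel_graph(nodes, edges, is_tree = FALSE)
}

as_tree <- function(g) { g$is_tree <- TRUE; g }

# segment row with a representable orientation whose displacement is w_dir
# scaled so the printed direction convention holds
seg_row <- function(c_xyz, o_xy, o_xz, h, r) {
  data.frame(cx = c_xyz[1], cy = c_xyz[2], cz = c_xyz[3],
             h = h, r = r, o_xy = o_xy, o_xz = o_xz)
}

# a chain of n collinear segments along +y (o_xy = pi/2, o_xz = pi/2 gives
# direction (0, sqrt(2)/2, 0)); consecutive endpoints touch
chain_segments <- function(n, h = 10, r = 1, gap = 0) {
  u_y <- sqrt(2) / 2
  span <- h * u_y
  cy <- (seq_len(n) - 1) * (span + gap) + span / 2
  do.call(rbind, lapply(cy, function(y) seg_row(c(0, y, 0), pi / 2, pi / 2, h, r)))
}

# random representable segment table
random_segments <- function(n, scale = 40) {
  data.frame(cx = runif(n, 0, scale), cy = runif(n, 0, scale),
             cz = runif(n, 0, scale), h = runif(n, 2, 12),
             r = runif(n, 0.5, 3), o_xy = runif(n, 0, 2 * pi),
             o_xz = runif(n, 0, pi))
}

# random connected graph over n nodes: random spanning tree + extra edges
random_connected_graph <- function(n, extra = 2, weights = NULL) {
  segs <- random_segments(n)
  edges <- data.frame(i = integer(0), j = integer(0))
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    edges <- rbind(edges, data.frame(i = min(u, v), j = max(u, v)))
  }
  all_pairs <- t(combn(n, 2))
  have <- paste(edges$i, edges$j)
  avail <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), , drop = FALSE]
  if (extra > 0 && nrow(avail)) {
    pick <- sample.int(nrow(avail), min(extra, nrow(avail)))
    edges <- rbind(edges, data.frame(i = avail[pick, 1], j = avail[pick, 2]))
  }
  edges$gap <- runif(nrow(edges), 0, 2)
  g <- make_graph(segs, edges)
  if (!is.null(weights)) g$edges$weight <- weights
  g
}

# brute-force maximum spanning tree weight by enumerating all edge subsets
# of size n-1 that form a spanning tree
brute_force_mst_weight <- function(g) {
  n <- nrow(g$nodes)
  e <- g$edges
  best <- -Inf
  for (sel in combn(nrow(e), n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (k in sel) {
      ri <- find(e$i[k]); rj <- find(e$j[k])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- max(best, sum(e$weight[sel]))
  }
  best
}

# phantom spec with fewer, thicker, well-separated branches (fast + easy to
# recover); tumor placed away from the tree so detection tests are clean
well_separated_spec <- function(seed = 3, depth = 3L, noise_sd = 0) {
  lungs <- lungmetmap:::default_lungs(c(64, 64, 64), c(1, 1, 1))
  vt <- utils::modifyList(
    lungmetmap:::default_vessel_tree(lungs),
    list(depth = as.integer(depth), root_radius = 2.4, root_h = 9,
         height_ratio = 0.75, branch_angle = c(0.5, 0.85)))
  phantom_spec(noise_sd = noise_sd, seed = seed, vessel_tree = vt,
               tumor = tumor_spec(c(45, 32, 32), 4))
}

# rasterize an axis-aligned ellipse ring into a logical matrix
raster_ellipse_ring <- function(nr, nc, cx, cy, a, b) {
  th <- seq(0, 2 * pi, length.out = 8 * max(a, b))
  pts <- unique(cbind(round(cx + a * cos(th)), round(cy + b * sin(th))))
  ok <- pts[, 1] >= 1 & pts[, 1] <= nr & pts[, 2] >= 1 & pts[, 2] <= nc
  m <- matrix(FALSE, nr, nc)
  m[pts[ok, , drop = FALSE]] <- TRUE
  m
}

# independent point-to-cylinder-surface distance used as nearest_vessel oracle
oracle_surface_distance <- function(p, seg) {
  a <- c(seg$slx, seg$sly, seg$slz)
  b <- c(seg$elx, seg$ely, seg$elz)
  ab <- b - a
  tt <- sum((p - a) * ab) / sum(ab^2)
  tt <- min(max(tt, 0), 1)
  max(sqrt(sum((p - (a + tt * ab))^2)) - seg$r, 0)
}
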