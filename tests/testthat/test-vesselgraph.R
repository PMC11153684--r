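test_that("endpoint formulas match direct substitution and are symmetric about c", {
  b <- list(cx = 0, cy = 0, cz = 0, h = 2, o_xy = 0, o_xz = 0)
  ep <- segment_endpoints(b)
  expect_equal(as.vector(ep$sl), c(-1, -sqrt(2) / 2, -1), tolerance = 1e-15)
  expect_equal(as.vector(ep$el), c(1, sqrt(2) / 2, 1), tolerance = 1e-15)

  withr::with_seed(11, {
    segs <- random_segments(1000)
    ep <- segment_endpoints(segs)
    mid <- (ep$sl + ep$el) / 2
    expect_lt(max(abs(mid - as.matrix(segs[, c("cx", "cy", "cz")]))), 1e-12)
    # span is h * ||u||, not h
    u <- direction_from_angles(segs$o_xy, segs$o_xz)
    expect_equal(sqrt(rowSums((ep$el - ep$sl)^2)), segs$h * sqrt(rowSums(u^2)),
                 tolerance = 1e-12)
  })

  b2 <- list(cx = 5, cy = 5, cz = 5, h = 0.001, o_xy = 1, o_xz = 1)
  ep2 <- segment_endpoints(b2)
  expect_lt(max(abs(ep2$sl - 5)), 1e-3)
  expect_lt(max(abs(ep2$el - 5)), 1e-3)
})

test_that("graph construction connects touching segments in one round and growing R bridges gaps", {
  # two collinear touching segments: R0 larger than the 0 gap, one edge
  segs <- chain_segments(2)
  g <- build_vessel_graph(segs, graph_build_params(R0 = 2, delta_R = 1))
  expect_equal(nrow(g$edges), 1)
  expect_false(g$is_tree)

  # far-apart pair: stalled rounds = ceil((gap - R0) / delta_R)
  gap <- 7.3
  segs2 <- chain_segments(2, gap = gap)
  R0 <- 2; dR <- 1
  need <- ceiling((gap - R0) / dR) + 1 # stalled rounds + the adding round
  expect_error(build_vessel_graph(segs2, graph_build_params(R0, dR, max_rounds = need - 1)),
               "not connected")
  g2 <- build_vessel_graph(segs2, graph_build_params(R0, dR, max_rounds = need))
  expect_equal(nrow(g2$edges), 1)

  # single segment: trivially connected with zero edges
  g1 <- build_vessel_graph(chain_segments(1))
  expect_equal(nrow(g1$edges), 0)
})

test_that("graph construction halts and connects on random segment clouds", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      segs <- random_segments(12)
      g <- build_vessel_graph(segs, graph_build_params(R0 = 1, delta_R = 2))
      expect_true(lungmetmap:::graph_connected(g))
      expect_gte(nrow(g$edges), nrow(g$nodes) - 1)
    }
  })
})

test_that("maximum-radius spanning tree drops the weakest cycle edge and matches brute force", {
  # triangle with weights 3, 2, 1 keeps {3, 2}
  segs <- random_segments(3)
  edges <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), gap = 0, weight = c(3, 2, 1))
  tr <- max_radius_spanning_tree(make_graph(segs, edges))
  expect_setequal(tr$edges$weight, c(3, 2))
  expect_true(tr$is_tree)

  # an input that is already a tree is returned unchanged
  tree_in <- make_graph(segs, data.frame(i = c(1, 2), j = c(2, 3), gap = 0, weight = c(1, 2)))
  tr2 <- max_radius_spanning_tree(tree_in)
  expect_equal(tr2$edges[, c("i", "j")], tree_in$edges[, c("i", "j")])

  expect_error(max_radius_spanning_tree(make_graph(random_segments(3),
                                                   data.frame(i = 1, j = 2, gap = 0, weight = 1))),
               "not connected")

  withr::with_seed(21, {
    for (rep in 1:12) {
      n <- sample(3:6, 1)
      g <- random_connected_graph(n, extra = sample(0:3, 1))
      g$edges$weight <- runif(nrow(g$edges), 0, 5)
      tr <- max_radius_spanning_tree(g)
      expect_equal(nrow(tr$edges), n - 1)
      expect_equal(sum(tr$edges$weight), brute_force_mst_weight(g), tolerance = 1e-12)
      # independent oracle: igraph maximum spanning tree via negated weights
      ig <- igraph::graph_from_data_frame(g$edges[, c("i", "j")], directed = FALSE,
                                          vertices = data.frame(name = seq_len(n)))
      igraph::E(ig)$weight <- -g$edges$weight
      w_ig <- -sum(igraph::E(igraph::mst(ig))$weight)
      expect_equal(sum(tr$edges$weight), w_ig, tolerance = 1e-12)
    }
  })
})

test_that("nearest vessel handles containment, ties, and matches a brute-force scan", {
  segs <- vessel_segments(chain_segments(2, gap = 10))
  g <- make_graph(chain_segments(2, gap = 10), data.frame(i = 1, j = 2, gap = 10, weight = 1))
  # point on segment 1's centerline
  p_on <- c(segs$slx[1], segs$sly[1], segs$slz[1])
  id <- nearest_vessel(g, p_on)
  expect_equal(as.integer(id), 1L)
  expect_equal(attr(id, "distance"), 0)
  # midpoint between the two segments is a tie: lower id wins
  p_mid <- (c(segs$elx[1], segs$ely[1], segs$elz[1]) +
            c(segs$slx[2], segs$sly[2], segs$slz[2])) / 2
  expect_equal(as.integer(nearest_vessel(g, p_mid)), 1L)

  withr::with_seed(4, {
    segs5 <- random_segments(5)
    g5 <- build_vessel_graph(segs5, graph_build_params(R0 = 5, delta_R = 5))
    for (k in 1:20) {
      p <- runif(3, 0, 40)
      d_all <- vapply(seq_len(5), function(i)
        oracle_surface_distance(p, g5$nodes[i, ]), numeric(1))
      expect_equal(as.integer(nearest_vessel(g5, p)), which.min(d_all))
    }
  })
})

test_that("path enumeration matches exhaustive search under the length bound", {
  # identity path
  g <- make_graph(chain_segments(3), data.frame(i = c(1, 2), j = c(2, 3), gap = 0, weight = 1))
  expect_equal(enumerate_paths(g, 2, 2, nu = 1), list(2L))

  # path graph A-B-C with generous bound: single path
  paths <- enumerate_paths(g, 1, 3, nu = 1e6)
  expect_equal(paths, list(c(1L, 2L, 3L)))
  # tight bound: total length = 3 h = 30, excluded at nu = 30 (strict <)
  expect_length(enumerate_paths(g, 1, 3, nu = 30), 0)
  expect_length(enumerate_paths(g, 1, 3, nu = 30.0001), 1)

  path_len <- function(g, p) {
    len <- sum(g$nodes$h[p])
    if (length(p) > 1) for (k in seq_len(length(p) - 1)) {
      e <- g$edges
      hit <- (e$i == p[k] & e$j == p[k + 1]) | (e$j == p[k] & e$i == p[k + 1])
      len <- len + min(e$gap[hit])
    }
    len
  }
  withr::with_seed(31, {
    for (rep in 1:10) {
      g5 <- random_connected_graph(5, extra = sample(2:4, 1))
      nu <- runif(1, 15, 45)
      S <- sample(5, 1); T <- sample(5, 1)
      mine <- enumerate_paths(g5, S, T, nu)
      # oracle: igraph exhaustive simple-path enumeration, filtered by length
      ig <- igraph::graph_from_data_frame(g5$edges[, c("i", "j")], directed = FALSE,
                                          vertices = data.frame(name = 1:5))
      all_p <- igraph::all_simple_paths(ig, from = as.character(S), to = as.character(T))
      all_p <- lapply(all_p, function(v) as.integer(igraph::as_ids(v)))
      if (S == T) all_p <- list(S) # igraph returns none for S == T
      keep <- Filter(function(p) path_len(g5, p) < nu, all_p)
      key <- function(l) sort(vapply(l, paste, character(1), collapse = "-"))
      expect_equal(key(mine), key(keep))
    }
  })
})

test_that("the spanning tree of a noise-free phantom is the generating tree", {
  for (seed in c(3, 8)) {
    ph <- generate_phantom(well_separated_spec(seed = seed))
    tr <- ph$truth
    g <- build_vessel_graph(tr$vessel_segments)
    tree <- max_radius_spanning_tree(g)
    node_to_orig <- order(-tr$vessel_segments$h)
    rec <- cbind(node_to_orig[tree$edges$i], node_to_orig[tree$edges$j])
    rec <- rec[order(pmin(rec[, 1], rec[, 2]), pmax(rec[, 1], rec[, 2])), , drop = FALSE]
    gen <- as.matrix(tr$vessel_tree_edges)
    gen <- cbind(pmin(gen[, 1], gen[, 2]), pmax(gen[, 1], gen[, 2]))
    gen <- gen[order(gen[, 1], gen[, 2]), , drop = FALSE]
    expect_equal(unname(cbind(pmin(rec[, 1], rec[, 2]), pmax(rec[, 1], rec[, 2]))),
                 unname(gen))
  }
})

test_that("vessel detection recovers single cylinders and depth-2 branch counts", {
  # single representable cylinder along +y: r = 2 mm, h = 20
  df <- seg_row(c(32, 32, 32), pi / 2, pi / 2, 20, 2)
  b <- vessel_segments(df)
  vol <- array(0.1, c(64, 64, 64))
  lin <- lungmetmap:::cylinder_voxels(c(b$slx, b$sly, b$slz),
                                      c(b$elx, b$ely, b$elz), 2,
                                      c(64, 64, 64), c(1, 1, 1))
  vol[lin] <- 0.7
  fit <- detect_vessels(volume_image(vol), array(1L, c(64, 64, 64)))
  expect_equal(nrow(fit), 1)
  expect_lt(abs(fit$r - 2), 0.5)
  expect_lt(abs(fit$h - 20), 2)

  # empty lung mask: nothing to detect
  expect_null(suppressMessages(
    detect_vessels(volume_image(vol), array(0L, c(64, 64, 64)))))

  # depth-2 tree (3 branches) detects exactly 3 segments
  lungs <- lungmetmap:::default_lungs(c(64, 64, 64), c(1, 1, 1))
  vt <- utils::modifyList(lungmetmap:::default_vessel_tree(lungs),
                          list(depth = 2L, root_radius = 2.4, root_h = 11,
                               height_ratio = 0.8, branch_angle = c(0.55, 0.9)))
  for (seed in c(1, 5)) {
    ph <- generate_phantom(phantom_spec(noise_sd = 0, seed = seed, vessel_tree = vt,
                                        tumor = tumor_spec(c(45, 32, 32), 4)))
    segs <- detect_vessels(ph$volume, ph$truth$lung_mask,
                           exclude_tumor = ph$truth$tumor)
    expect_equal(nrow(segs), 3)
    # each detected centroid lies close to a true segment's surface
    for (i in seq_len(nrow(segs))) {
      d <- min(vapply(seq_len(3), function(j)
        oracle_surface_distance(c(segs$cx[i], segs$cy[i], segs$cz[i]),
                                ph$truth$vessel_segments[j, ]), numeric(1)))
      expect_lt(d, 2)
    }
  }
})
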