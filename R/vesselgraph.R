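#' Vessel flow graph construction by iterative search radius
#'
#' Builds the graph `G = (B, E)` over cylinder vessel segments. Segments are
#' sorted by height `h` (descending) and edges are inserted in rounds: each
#' segment whose start location `sl` lies within the current search radius
#' `R` of another segment's start or end location is connected to the closest
#' such segment (closest in endpoint distance) that it is not already linked
#' to. If a full round inserts no edge, the radius grows by `delta_R`. The
#' process halts as soon as the graph is connected (the cardiovascular system
#' is connected, so connectivity is the construction's stopping criterion).
#'
#' @param segments a [vessel_segments()] table.
#' @param params list with `R0` (initial search radius, mm), `delta_R`
#'   (increment, mm) and `max_rounds` (safety cap); see [graph_build_params()].
#' @return A `vessel_graph`: list with `nodes` (segments, re-indexed in
#'   descending-`h` order), `edges` (data.frame `i, j, gap, weight` where
#'   `gap` is the endpoint distance used at insertion and `weight` is
#'   `min(r_i, r_j)`), and `is_tree = FALSE`.
#' @export
build_vessel_graph <- function(segments, params = graph_build_params()) {
  if (!inherits(segments, "vessel_segments")) segments <- vessel_segments(segments)
  n <- nrow(segments)
  ord <- order(-segments$h) # stable sort, ties keep original order
  nodes <- segments[ord, , drop = FALSE]
  nodes$id <- seq_len(n)
  rownames(nodes) <- NULL

  if (n == 1) {
    return(new_vessel_graph(nodes, empty_edges(), is_tree = FALSE))
  }

  sl <- as.matrix(nodes[, c("slx", "sly", "slz")])
  el <- as.matrix(nodes[, c("elx", "ely", "elz")])
  # distance from sl_i to nearest endpoint (sl_j or el_j) of each j
  d_sl <- as.matrix(stats::dist(sl))
  d_cross <- cross_dist(sl, el) # d_cross[i, j] = ||sl_i - el_j||
  d_near <- pmin(d_sl, d_cross)
  diag(d_near) <- Inf

  R <- params$R0
  parent <- seq_len(n) # union-find
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  linked <- matrix(FALSE, n, n)
  ei <- integer(0); ej <- integer(0); egap <- numeric(0)
  n_comp <- n
  rounds <- 0L
  while (n_comp > 1L) {
    rounds <- rounds + 1L
    if (rounds > params$max_rounds) {
      comp <- vapply(seq_len(n), find, integer(1))
      stop("graph not connected after ", params$max_rounds,
           " rounds; components: ",
           paste(tapply(seq_len(n), comp, paste, collapse = ","), collapse = " | "))
    }
    added <- FALSE
    for (i in seq_len(n)) {
      cand <- which(d_near[i, ] <= R & !linked[i, ])
      if (!length(cand)) next
      # closest candidate; distances within 1e-9 mm count as tied and the
      # lowest id wins (endpoint coincidences at junctions would otherwise
      # be broken by floating-point noise)
      cd <- d_near[i, cand]
      j <- cand[cd <= min(cd) + 1e-9][1]
      linked[i, j] <- linked[j, i] <- TRUE
      ei <- c(ei, min(i, j)); ej <- c(ej, max(i, j)); egap <- c(egap, d_near[i, j])
      ri <- find(i); rj <- find(j)
      if (ri != rj) { parent[ri] <- rj; n_comp <- n_comp - 1L }
      added <- TRUE
    }
    if (!added) R <- R + params$delta_R
  }
  edges <- data.frame(i = ei, j = ej, gap = egap)
  edges$weight <- pmin(nodes$r[edges$i], nodes$r[edges$j])
  new_vessel_graph(nodes, edges, is_tree = FALSE)
}

#' Parameters for vessel graph construction
#'
#' @param R0 initial search radius (mm), > 0.
#' @param delta_R radius increment per stalled round (mm), > 0.
#' @param max_rounds safety cap on insertion rounds.
#' @return validated parameter list.
#' @export
graph_build_params <- function(R0 = 2, delta_R = 1, max_rounds = 1000L) {
  stopifnot(R0 > 0, delta_R > 0, max_rounds >= 1)
  list(R0 = R0, delta_R = delta_R, max_rounds = as.integer(max_rounds))
}

new_vessel_graph <- function(nodes, edges, is_tree) {
  structure(list(nodes = nodes, edges = edges, is_tree = is_tree),
            class = "vessel_graph")
}

empty_edges <- function() data.frame(i = integer(0), j = integer(0),
                                     gap = numeric(0), weight = numeric(0))

#' @export
print.vessel_graph <- function(x, ...) {
  cat("<vessel_graph> ", nrow(x$nodes), " segments, ", nrow(x$edges), " edges",
      if (x$is_tree) " (spanning tree)", "\n", sep = "")
  invisible(x)
}

cross_dist <- function(a, b) {
  # ||a_i - b_j|| by direct differencing: the expanded quadratic form loses
  # ~8 digits to cancellation, which matters for coincident endpoints
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b)))
    out[, j] <- sqrt((a[, 1] - b[j, 1])^2 + (a[, 2] - b[j, 2])^2 +
                     (a[, 3] - b[j, 3])^2)
  out
}

graph_connected <- function(g) {
  n <- nrow(g$nodes)
  if (n <= 1) return(TRUE)
  adj <- adjacency_list(g)
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nb <- unique(unlist(adj[frontier]))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

adjacency_list <- function(g) {
  n <- nrow(g$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else sort(unique(v)))
}

#' Maximum-radius spanning tree
#'
#' Reduces a connected vessel graph to the spanning tree that maximizes total
#' edge weight, where an edge's weight is `min(r_i, r_j)` of its incident
#' segments — the hemodynamically limiting bore of the connection. Kruskal's
#' algorithm with deterministic tie-breaking: equal-weight edges are taken in
#' order of the smaller `(i, j)` node index pair.
#'
#' @param g a connected `vessel_graph`.
#' @return The graph restricted to the `|B| - 1` tree edges, `is_tree = TRUE`.
#' @export
max_radius_spanning_tree <- function(g) {
  n <- nrow(g$nodes)
  if (!graph_connected(g)) stop("input graph is not connected")
  if (g$is_tree || nrow(g$edges) == n - 1) {
    g$is_tree <- TRUE
    return(g)
  }
  e <- g$edges[!duplicated(g$edges[, c("i", "j")]), , drop = FALSE]
  ord <- order(-e$weight, e$i, e$j)
  e <- e[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- logical(nrow(e))
  taken <- 0L
  for (k in seq_len(nrow(e))) {
    ri <- find(e$i[k]); rj <- find(e$j[k])
    if (ri != rj) { parent[ri] <- rj; keep[k] <- TRUE; taken <- taken + 1L }
    if (taken == n - 1L) break
  }
  tree <- e[keep, , drop = FALSE]
  tree <- tree[order(tree$i, tree$j), , drop = FALSE]
  rownames(tree) <- NULL
  new_vessel_graph(g$nodes, tree, is_tree = TRUE)
}

#' Nearest vessel segment to a point
#'
#' Distance from a point to a segment is the Euclidean distance to its
#' `sl`--`el` centerline minus the radius `r`, floored at 0 (a point inside
#' the cylinder has distance 0). Ties are broken by the lower segment id.
#'
#' @param g a `vessel_graph`.
#' @param p world point (length-3, mm).
#' @return segment id (integer), with the surface distance in attribute
#'   `"distance"`.
#' @export
nearest_vessel <- function(g, p) {
  d <- vessel_surface_distances(g, p)
  id <- which.min(d) # first minimum = lowest id
  structure(as.integer(id), distance = d[id])
}

vessel_surface_distances <- function(g, p) {
  nd <- g$nodes
  n <- nrow(nd)
  d <- numeric(n)
  pm <- matrix(p, ncol = 3)
  for (i in seq_len(n)) {
    d[i] <- point_segment_distance(pm,
                                   c(nd$slx[i], nd$sly[i], nd$slz[i]),
                                   c(nd$elx[i], nd$ely[i], nd$elz[i]))
  }
  pmax(d - nd$r, 0)
}

#' Enumerate flow paths shorter than a length bound
#'
#' All simple paths from `S` to `T` of length strictly less than `nu`, found
#' by breadth-first expansion with pruning: a partial path is discarded as
#' soon as its accumulated length reaches `nu`. The length of a path is the
#' sum of the traversed segments' heights `h` plus the inter-endpoint gaps
#' stored on its edges; the single-node path (`S == T`) has length 0. On a
#' spanning tree there is at most one such path.
#'
#' @param g a `vessel_graph`.
#' @param S,T segment ids.
#' @param nu length bound (mm); may be `Inf`.
#' @return list of integer id vectors (possibly empty = extinction before
#'   arrival), in breadth-first order.
#' @export
enumerate_paths <- function(g, S, T, nu = Inf) {
  n <- nrow(g$nodes)
  stopifnot(S >= 1, S <= n, T >= 1, T <= n, nu > 0)
  if (S == T) return(list(as.integer(S)))
  adj <- adjacency_list(g)
  gap <- gap_lookup(g)
  h <- g$nodes$h
  out <- list()
  # queue of partial paths with accumulated length (h of all nodes + gaps)
  queue <- list(list(path = as.integer(S), len = h[S]))
  while (length(queue)) {
    nxt <- list()
    for (q in queue) {
      tip <- q$path[length(q$path)]
      for (nb in adj[[tip]]) {
        if (nb %in% q$path) next
        len2 <- q$len + gap[[edge_key(tip, nb)]] + h[nb]
        if (len2 >= nu) next
        p2 <- c(q$path, nb)
        if (nb == T) out[[length(out) + 1L]] <- p2
        else nxt[[length(nxt) + 1L]] <- list(path = p2, len = len2)
      }
    }
    queue <- nxt
  }
  out
}

edge_key <- function(i, j) paste0(min(i, j), "-", max(i, j))

gap_lookup <- function(g) {
  e <- g$edges
  keys <- paste0(e$i, "-", e$j)
  gl <- as.list(e$gap)
  names(gl) <- keys
  # keep the smallest gap if parallel edges exist
  if (anyDuplicated(keys)) gl <- tapply(e$gap, keys, min, simplify = FALSE)
  gl
}

# Unique path between S and all nodes on a tree: BFS parent pointers.
# Returns list(parent, order) with parent[S] = 0.
tree_parents <- function(g, S) {
  n <- nrow(g$nodes)
  adj <- adjacency_list(g)
  parent <- integer(n)
  parent[] <- -1L
  parent[S] <- 0L
  frontier <- as.integer(S)
  visit <- frontier
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (nb in adj[[v]]) if (parent[nb] < 0L) {
        parent[nb] <- v
        nxt <- c(nxt, nb)
      }
    }
    visit <- c(visit, nxt)
    frontier <- nxt
  }
  list(parent = parent, order = visit)
}

tree_path <- function(parents, S, T) {
  if (parents$parent[T] < 0L) return(NULL) # unreachable
  path <- integer(0)
  v <- as.integer(T)
  while (v != 0L) {
    path <- c(v, path)
    v <- parents$parent[v]
    if (length(path) > length(parents$parent)) stop("cycle in tree parents")
  }
  if (path[1] != S) return(NULL)
  path
}
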