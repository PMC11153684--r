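#' Biophysical model parameters
#'
#' Parameters of the three-layer colonization model. The shedding rate `d`,
#' extinction threshold `xi`, and stop time `T` are the model's core
#' quantities; the remaining parameters configure the stand-in sub-models
#' (Gompertz growth, Poiseuille network flow, saturating colonization) and
#' are documented in the methods vignette. All semantics are expected-value
#' (deterministic): the probabilistic extravasation step is realized as an
#' expected settled count.
#'
#' @param d shedding rate once the tumor reaches a vessel (cells/hour).
#' @param lambda_decay exponential death rate of circulating cells (1/hour).
#' @param xi extinction threshold (cells): a population below `xi` at arrival
#'   is set to zero. Implicitly bounds the survivable path length.
#' @param T stop time of the simulation (hours).
#' @param growth_a Gompertz growth rate (1/hour).
#' @param growth_K Gompertz carrying capacity (cells).
#' @param cells_per_mm3 tissue cell density used to convert tumor volume to
#'   cell count (cells/mm^3).
#' @param p_extravasate per-arrival extravasation probability scale, in
#'   (0, 1].
#' @param colonization_capacity saturation level of local settlement (cells).
#' @param colonize_radius radius of the tissue ball used for the local
#'   healthy-tissue fraction (mm).
#' @param root_velocity mean blood velocity assigned to the tree's inlet
#'   (mm/s); fixes the otherwise arbitrary pressure scale of the steady flow
#'   solve.
#' @return validated parameter list of class `model_params`.
#' @export
model_params <- function(d = 1e6, lambda_decay = 2, xi = 100, T = 720,
                         growth_a = 0.005, growth_K = 1e12,
                         cells_per_mm3 = 1e6,
                         p_extravasate = 1e-3,
                         colonization_capacity = 1e7,
                         colonize_radius = 5,
                         root_velocity = 100) {
  stopifnot(d >= 0, lambda_decay >= 0, xi >= 1, T > 0,
            growth_a >= 0, growth_K > 0, cells_per_mm3 > 0,
            p_extravasate > 0, p_extravasate <= 1,
            colonization_capacity > 0, colonize_radius > 0,
            root_velocity > 0)
  structure(list(d = d, lambda_decay = lambda_decay, xi = xi, T = T,
                 growth_a = growth_a, growth_K = growth_K,
                 cells_per_mm3 = cells_per_mm3,
                 p_extravasate = p_extravasate,
                 colonization_capacity = colonization_capacity,
                 colonize_radius = colonize_radius,
                 root_velocity = root_velocity),
            class = "model_params")
}

tumor_cells_from_radius <- function(radius, params)
  params$cells_per_mm3 * 4 / 3 * pi * radius^3

tumor_radius_from_cells <- function(cells, params)
  (3 * cells / (4 * pi * params$cells_per_mm3))^(1 / 3)

#' Gompertz growth of the primary tumor
#'
#' Closed-form Gompertz law `N(t) = K * exp(log(N0/K) * exp(-a*t))`, the
#' solution of `dN/dt = a * N * log(K/N)`, with the initial cell count
#' derived from the tumor's radius via the tissue cell density.
#'
#' @param tumor a [tumor_spec()].
#' @param params a [model_params()].
#' @param t time (hours), >= 0; vectorized.
#' @return list with `cells` and the equivalent spherical `radius` (mm).
#' @export
grow_tumor <- function(tumor, params, t) {
  stopifnot(all(t >= 0))
  n0 <- tumor_cells_from_radius(tumor$size, params)
  if (n0 >= params$growth_K)
    stop("initial tumor cell count exceeds carrying capacity growth_K")
  cells <- params$growth_K * exp(log(n0 / params$growth_K) * exp(-params$growth_a * t))
  list(cells = cells, radius = tumor_radius_from_cells(cells, params))
}

#' Time until the growing tumor reaches a blood vessel
#'
#' Smallest `t` at which the tumor's equivalent radius reaches the distance
#' from its center to the nearest vessel surface, solved by bisection to
#' 1e-6 h. Returns 0 if already in contact and `Inf` (a "never reaches"
#' sentinel) if even the carrying-capacity radius is too small — downstream
#' this makes the settled count 0.
#'
#' @param tumor a [tumor_spec()].
#' @param g a `vessel_graph`.
#' @param params a [model_params()].
#' @return contact time in hours (possibly 0 or `Inf`).
#' @export
time_to_vessel_contact <- function(tumor, g, params) {
  if (nrow(g$nodes) == 0) stop("empty vessel graph")
  D <- min(vessel_surface_distances(g, tumor$location))
  if (tumor$size >= D) return(0)
  r_max <- tumor_radius_from_cells(params$growth_K, params)
  if (r_max < D || params$growth_a <= 0) return(Inf)
  lo <- 0; hi <- 1
  while (grow_tumor(tumor, params, hi)$radius < D) {
    hi <- hi * 2
    if (hi > 1e9) return(Inf)
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (grow_tumor(tumor, params, mid)$radius >= D) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Steady Poiseuille flow on the vessel spanning tree
#'
#' Solves a linear pressure network with Hagen-Poiseuille edge conductance
#' `g = r^4 / L` (`r` = the limiting incident radius, `L` = mean incident
#' height plus the endpoint gap), unit pressure at the inlet and zero at the
#' leaves, then derives per-edge volumetric flows `q = g * dp` and mean
#' velocities `v = q / (pi r^2)`. All flows are rescaled so the inlet's mean
#' velocity equals `params$root_velocity` (the Dirichlet pressures are in
#' arbitrary units, so the scale is otherwise free). Mass is conserved at
#' every interior node.
#'
#' @param tree a spanning-tree `vessel_graph`.
#' @param inlet inlet segment id; defaults to the largest-radius segment.
#' @param params a [model_params()] (only `root_velocity` is used).
#' @return object of class `flow_field`: list with `pressure` (per node),
#'   `edges` (data.frame `i, j, r, L, conductance, flow, velocity`; flow
#'   oriented from `i` to `j` when positive) and `inlet`.
#' @export
solve_flow <- function(tree, inlet = NULL, params = model_params()) {
  if (!tree$is_tree) stop("solve_flow expects the spanning tree")
  n <- nrow(tree$nodes)
  if (is.null(inlet)) inlet <- which.max(tree$nodes$r)
  e <- tree$edges
  if (n == 1 || nrow(e) == 0) {
    edges0 <- data.frame(i = integer(0), j = integer(0), gap = numeric(0),
                         weight = numeric(0), r = numeric(0), L = numeric(0),
                         conductance = numeric(0), flow = numeric(0),
                         velocity = numeric(0))
    return(structure(list(pressure = rep(1, n), edges = edges0, inlet = inlet),
                     class = "flow_field"))
  }
  h <- tree$nodes$h
  e$r <- pmin(tree$nodes$r[e$i], tree$nodes$r[e$j])
  e$L <- (h[e$i] + h[e$j]) / 2 + e$gap
  e$conductance <- e$r^4 / e$L

  deg <- tabulate(c(e$i, e$j), nbins = n)
  if (any(deg == 0)) stop("isolated node in flow network")
  leaves <- setdiff(which(deg == 1), inlet)
  fixed <- c(inlet, leaves)
  p_fix <- setNames(c(1, rep(0, length(leaves))), fixed)

  free <- setdiff(seq_len(n), fixed)
  pressure <- numeric(n)
  pressure[fixed] <- p_fix[as.character(fixed)]
  if (length(free)) {
    lap <- matrix(0, n, n)
    for (k in seq_len(nrow(e))) {
      i <- e$i[k]; j <- e$j[k]; gk <- e$conductance[k]
      lap[i, i] <- lap[i, i] + gk; lap[j, j] <- lap[j, j] + gk
      lap[i, j] <- lap[i, j] - gk; lap[j, i] <- lap[j, i] - gk
    }
    A <- lap[free, free, drop = FALSE]
    b <- -lap[free, fixed, drop = FALSE] %*% pressure[fixed]
    pressure[free] <- solve(A, b)
  }
  e$flow <- e$conductance * (pressure[e$i] - pressure[e$j])
  e$velocity <- abs(e$flow) / (pi * e$r^2)

  # pin the physical scale: inlet mean velocity = root_velocity (mm/s)
  inlet_edges <- which(e$i == inlet | e$j == inlet)
  q_in <- sum(abs(e$flow[inlet_edges]))
  v_in <- q_in / (pi * tree$nodes$r[inlet]^2)
  if (v_in > 0) {
    s <- params$root_velocity / v_in
    e$flow <- e$flow * s
    e$velocity <- e$velocity * s
    pressure <- pressure * s
  }
  structure(list(pressure = pressure, edges = e, inlet = inlet),
            class = "flow_field")
}

#' Bloodstream transit survival with extinction threshold
#'
#' Cells released onto a path decay exponentially over the transit time
#' `t = sum(edge length / edge velocity)`: `N_out = N_in * exp(-lambda * t)`.
#' If the surviving count falls below the extinction threshold `xi` it is set
#' to zero — this rule implicitly defines the maximal survivable path length
#' (`nu_t = log(N_in / xi) / lambda` in transit-time units). An edge with
#' zero velocity gives infinite transit and extinction.
#'
#' @param path integer vector of segment ids (a path in the tree).
#' @param flow a `flow_field` from [solve_flow()].
#' @param N_in cells entering the bloodstream, >= 0.
#' @param params a [model_params()].
#' @return list with `n_out` (surviving cells, 0 if extinct) and
#'   `transit_time` (hours; 0 for a single-node path, `Inf` when stalled).
#' @export
transit_survival <- function(path, flow, N_in, params) {
  stopifnot(N_in >= 0)
  t_h <- path_transit_hours(path, flow)
  if (!is.finite(t_h)) return(list(n_out = 0, transit_time = Inf))
  n_out <- N_in * exp(-params$lambda_decay * t_h)
  if (n_out < params$xi) n_out <- 0
  list(n_out = n_out, transit_time = t_h)
}

path_transit_hours <- function(path, flow) {
  if (length(path) <= 1) return(0)
  e <- flow$edges
  key_e <- paste0(e$i, "-", e$j)
  t_h <- 0
  for (k in seq_len(length(path) - 1)) {
    key <- edge_key(path[k], path[k + 1])
    m <- match(key, key_e)
    if (is.na(m)) stop("path edge ", key, " not in flow field")
    v <- e$velocity[m]
    if (v <= 0) return(Inf)
    t_h <- t_h + e$L[m] / v / 3600
  }
  t_h
}

#' Colonization of tissue around the arrival site
#'
#' Saturating settlement law: with `f` the healthy-tissue fraction of a ball
#' of radius `colonize_radius` around the site (0 if the site itself is not
#' lung tissue), the expected settled count is
#' `round(capacity * f * (1 - exp(-p * arrived / capacity)))` — monotone in
#' arrivals, saturating at `capacity * f`, and zero without tissue.
#'
#' @param arrived cells surviving transit, >= 0.
#' @param site world coordinates of the evaluation point (mm).
#' @param lung lung mask (array or `lung_mask`), with `spacing` attribute or
#'   accompanying `spacing` argument.
#' @param params a [model_params()].
#' @param spacing voxel spacing (mm) of the lung mask.
#' @return settled cell count (non-negative integer-valued numeric).
#' @export
colonize <- function(arrived, site, lung, params, spacing = c(1, 1, 1)) {
  stopifnot(arrived >= 0)
  if (arrived == 0) return(0)
  f <- tissue_fraction(site, lung, params$colonize_radius, spacing)
  cap <- params$colonization_capacity
  round(cap * f * (1 - exp(-params$p_extravasate * arrived / cap)))
}

tissue_fraction <- function(site, lung, radius, spacing) {
  mask <- lung_mask_array(lung)
  shape <- dim(mask)
  ctr <- world_to_vox(site, spacing, shape)
  # outside-volume or non-tissue site settles nothing
  site_idx <- round(site / spacing) + 1
  if (any(site_idx < 1) || any(site_idx > shape)) return(0)
  if (mask[ctr[1], ctr[2], ctr[3]] == 0) return(0)
  off <- ball_offsets(radius, spacing)
  nb <- sweep(off, 2, as.numeric(ctr), `+`)
  ok <- in_bounds(nb, shape)
  nb <- nb[ok, , drop = FALSE]
  lin <- nb[, 1] + (nb[, 2] - 1) * shape[1] + (nb[, 3] - 1) * shape[1] * shape[2]
  sum(mask[lin] > 0) / nrow(off) # out-of-volume ball voxels count as non-tissue
}

#' Predicted settled cell count at a location
#'
#' Composes the model chain for one query location `tau`: tumor growth to
#' vessel contact, shedding `d * max(0, T - t_contact)`, transport along the
#' unique spanning-tree path from the vessel nearest the tumor to the vessel
#' nearest `tau` (with exponential decay and extinction), and colonization at
#' `tau`. Deterministic.
#'
#' @param tree spanning-tree `vessel_graph`.
#' @param tumor a [tumor_spec()].
#' @param lung lung mask array (or `lung_mask`).
#' @param tau world coordinates of the query location (mm).
#' @param params a [model_params()].
#' @param spacing voxel spacing of the lung mask (mm).
#' @param cache optional precomputed state from [heatmap_cache()]; must
#'   describe the same tree/tumor/params.
#' @return list of class `cell_count_result`: `c` (settled cells), `path`,
#'   `transit_time` (h), `arrived`, `shed`, `t_contact`.
#' @export
predict_cell_count <- function(tree, tumor, lung, tau, params,
                               spacing = c(1, 1, 1), cache = NULL) {
  if (is.null(cache)) cache <- heatmap_cache(tree, tumor, params)
  res0 <- list(c = 0, path = NULL, transit_time = NA_real_,
               arrived = 0, shed = cache$shed, t_contact = cache$t_contact)
  class(res0) <- "cell_count_result"
  if (cache$shed <= 0) return(res0)
  Tn <- nearest_vessel(tree, tau)
  path <- tree_path(cache$parents, cache$S, Tn)
  if (is.null(path)) return(res0)
  t_h <- cache$transit_h[Tn]
  if (!is.finite(t_h)) return(res0)
  arrived <- cache$shed * exp(-params$lambda_decay * t_h)
  if (arrived < params$xi) arrived <- 0
  settled <- colonize(arrived, tau, lung, params, spacing)
  structure(list(c = settled, path = path, transit_time = t_h,
                 arrived = arrived, shed = cache$shed,
                 t_contact = cache$t_contact),
            class = "cell_count_result")
}

#' Precomputed state for repeated model evaluations
#'
#' Computes, once per (tree, tumor, params): the flow field, the
#' vessel-contact time and shed count, the source vessel `S`, BFS parent
#' pointers from `S`, and cumulative transit times from `S` to every node
#' (summed edge by edge outward, so they equal the per-path left-to-right
#' sums exactly).
#'
#' @inheritParams predict_cell_count
#' @return list used as the `cache` argument of [predict_cell_count()].
#' @export
heatmap_cache <- function(tree, tumor, params) {
  flow <- solve_flow(tree, params = params)
  t_contact <- time_to_vessel_contact(tumor, tree, params)
  shed <- if (is.finite(t_contact)) params$d * max(0, params$T - t_contact) else 0
  S <- as.integer(nearest_vessel(tree, tumor$location))
  parents <- tree_parents(tree, S)
  n <- nrow(tree$nodes)
  transit_h <- rep(NA_real_, n)
  transit_h[S] <- 0
  e <- flow$edges
  key_e <- if (nrow(e)) paste0(e$i, "-", e$j) else character(0)
  for (v in parents$order) {
    p <- parents$parent[v]
    if (p == 0L) next
    m <- match(edge_key(p, v), key_e)
    vel <- e$velocity[m]
    step <- if (is.na(m) || vel <= 0) Inf else e$L[m] / vel / 3600
    transit_h[v] <- transit_h[p] + step
  }
  list(flow = flow, t_contact = t_contact, shed = shed, S = S,
       parents = parents, transit_h = transit_h)
}
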