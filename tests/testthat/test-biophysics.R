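test_that("Gompertz growth honors boundary, asymptote, and closed-form values", {
  p <- model_params(growth_a = 1, growth_K = 1e10, cells_per_mm3 = 1e6)
  tum <- tumor_spec(c(0, 0, 0), 2)
  n0 <- p$cells_per_mm3 * 4 / 3 * pi * 2^3
  expect_equal(grow_tumor(tum, p, 0)$cells, n0)
  expect_equal(grow_tumor(tum, p, 50)$cells, p$growth_K, tolerance = 1e-6)

  # N0 = K/e, a = 1, t = 1 gives N = K * exp(-1/e)
  K <- 1e9
  r0 <- (3 * (K / exp(1)) / (4 * pi * 1e6))^(1 / 3)
  pe <- model_params(growth_a = 1, growth_K = K, cells_per_mm3 = 1e6)
  expect_equal(grow_tumor(tumor_spec(c(0, 0, 0), r0), pe, 1)$cells,
               K * exp(-exp(-1)), tolerance = 1e-12)
})

test_that("Gompertz closed form agrees with numerical ODE integration", {
  p <- model_params(growth_a = 0.03, growth_K = 5e9, cells_per_mm3 = 1e6)
  tum <- tumor_spec(c(0, 0, 0), 1.5)
  n0 <- lungmetmap:::tumor_cells_from_radius(1.5, p)
  times <- seq(0, 100, by = 5)
  ode <- deSolve::ode(y = c(N = n0), times = times,
                      func = function(t, y, parms)
                        list(parms$a * y * log(parms$K / y)),
                      parms = list(a = p$growth_a, K = p$growth_K),
                      rtol = 1e-10, atol = 1e-4)
  closed <- grow_tumor(tum, p, times)$cells
  expect_equal(closed, unname(ode[, "N"]), tolerance = 1e-6)
})

test_that("time to vessel contact inverts the growth curve", {
  segs <- chain_segments(2)
  g <- as_tree(build_vessel_graph(segs))
  p <- model_params(growth_a = 0.01, growth_K = 1e12, cells_per_mm3 = 1e6)

  # already touching: tumor centered on a vessel
  tum_on <- tumor_spec(c(0, chain_segments(1)$cy[1], 0), 2)
  expect_equal(time_to_vessel_contact(tum_on, g, p), 0)

  # unreachable: required radius above the carrying-capacity radius
  far <- tumor_spec(c(1e5, 0, 0), 0.1)
  expect_identical(time_to_vessel_contact(far, g, p), Inf)

  # construct distance = radius at exactly t = 10 via the closed form:
  # the chain starts at sl = (0,0,0) with r = 1, so a tumor at
  # (0, -(r_t + 1), 0) has surface distance exactly r_t
  t_star <- 10
  r_t <- grow_tumor(tumor_spec(c(0, 0, 0), 3), p, t_star)$radius
  tum <- tumor_spec(c(0, -(r_t + 1), 0), 3)
  d_now <- min(lungmetmap:::vessel_surface_distances(g, tum$location))
  expect_equal(d_now, r_t, tolerance = 1e-9)
  expect_equal(time_to_vessel_contact(tum, g, p), t_star, tolerance = 1e-5)
})

test_that("Poiseuille solve conserves mass, splits symmetric junctions evenly, and matches circuit reduction", {
  # single edge: velocity = flow / (pi r^2)
  g2 <- as_tree(build_vessel_graph(chain_segments(2, r = 1.5)))
  f2 <- solve_flow(g2, params = model_params(root_velocity = 80))
  expect_equal(nrow(f2$edges), 1)
  expect_equal(f2$edges$velocity, abs(f2$edges$flow) / (pi * f2$edges$r^2))
  expect_equal(abs(f2$edges$flow) / (pi * g2$nodes$r[f2$inlet]^2), 80)

  # symmetric Y: parent + two identical children
  segsY <- rbind(seg_row(c(0, 0, 0), pi / 2, pi / 2, 10, 2),
                 seg_row(c(3, 7, 0), pi / 4, pi / 2, 8, 1.2),
                 seg_row(c(-3, 7, 0), 3 * pi / 4, pi / 2, 8, 1.2))
  gY <- make_graph(segsY, data.frame(i = c(1, 1), j = c(2, 3), gap = 1))
  fY <- solve_flow(as_tree(gY))
  expect_equal(abs(fY$edges$flow[1]), abs(fY$edges$flow[2]), tolerance = 1e-12)
  q_parent <- sum(abs(fY$edges$flow))
  expect_equal(abs(fY$edges$flow[1]), q_parent / 2)

  # series path: two resistors in series carry the same flow as the reduced circuit
  segs3 <- chain_segments(3, r = 1.5)
  segs3$r <- c(2, 1.5, 1) # distinct conductances
  g3 <- as_tree(build_vessel_graph(segs3))
  f3 <- solve_flow(g3, params = model_params(root_velocity = 50))
  e <- f3$edges
  expect_equal(abs(e$flow[1]), abs(e$flow[2]), tolerance = 1e-9) # series: equal flow
  # oracle: total conductance of two series conductances
  g_series <- 1 / (1 / e$conductance[1] + 1 / e$conductance[2])
  dp <- abs(f3$pressure[f3$inlet] - 0)
  expect_equal(abs(e$flow[1]), g_series * dp, tolerance = 1e-9)

  # random 10-node trees: interior mass balance < 1e-9 relative
  withr::with_seed(13, {
    for (rep in 1:5) {
      g10 <- random_connected_graph(10, extra = 0)
      f10 <- solve_flow(as_tree(g10))
      deg <- tabulate(c(f10$edges$i, f10$edges$j), nbins = 10)
      interior <- setdiff(which(deg > 1), f10$inlet)
      for (v in interior) {
        net <- sum(f10$edges$flow[f10$edges$i == v]) -
               sum(f10$edges$flow[f10$edges$j == v])
        expect_lt(abs(net) / max(abs(f10$edges$flow)), 1e-9)
      }
    }
  })
})

test_that("transit survival is exact exponential decay with extinction threshold", {
  # worked case: 1000 cells, t = 10 h, lambda = 0.1/h -> 367.88; xi = 400 zeroes it
  segs <- chain_segments(2)
  g <- as_tree(build_vessel_graph(segs))
  f <- solve_flow(g, params = model_params(root_velocity = 10))
  t_h <- lungmetmap:::path_transit_hours(c(1L, 2L), f)
  p0 <- model_params(lambda_decay = 0, xi = 1)
  expect_equal(transit_survival(c(1L, 2L), f, 1234, p0)$n_out, 1234)

  # direct closed-form check at machine precision using the computed t
  lam <- 0.37
  pl <- model_params(lambda_decay = lam, xi = 1)
  expect_equal(transit_survival(c(1L, 2L), f, 1e6, pl)$n_out,
               1e6 * exp(-lam * t_h), tolerance = 1e-12)

  # threshold: construct lambda so survivors = 367.88 < xi = 400
  lam2 <- log(1000 / 367.879441) / t_h
  p2 <- model_params(lambda_decay = lam2, xi = 400)
  expect_equal(transit_survival(c(1L, 2L), f, 1000, p2)$n_out, 0)
  p3 <- model_params(lambda_decay = lam2, xi = 300)
  expect_gt(transit_survival(c(1L, 2L), f, 1000, p3)$n_out, 0)

  # entering below threshold dies on any path
  expect_equal(transit_survival(c(1L, 2L), f, 50, model_params(xi = 100))$n_out, 0)
})

test_that("the extinction rule defines the survivable transit-time bound", {
  # nu_t = log(N_in / xi) / lambda: survival iff transit time < nu_t
  segs <- chain_segments(8, h = 10, gap = 0.5)
  g <- as_tree(build_vessel_graph(segs, graph_build_params(R0 = 2)))
  f <- solve_flow(g, params = model_params(root_velocity = 0.02)) # slow flow: hours-scale transit
  N_in <- 1e6; lam <- 15
  p <- model_params(lambda_decay = lam, xi = 500)
  nu_t <- log(N_in / p$xi) / lam
  times <- vapply(2:8, function(k)
    lungmetmap:::path_transit_hours(seq_len(k), f), numeric(1))
  surv <- vapply(2:8, function(k)
    transit_survival(seq_len(k), f, N_in, p)$n_out, numeric(1))
  expect_true(any(times < nu_t) && any(times >= nu_t)) # the bound is straddled
  expect_true(all(surv[times < nu_t] > 0))
  expect_true(all(surv[times >= nu_t] == 0))
})

test_that("colonization saturates, needs tissue, and needs arrivals", {
  lung <- array(1L, c(20, 20, 20))
  p <- model_params(p_extravasate = 0.5, colonization_capacity = 1e4,
                    colonize_radius = 3)
  expect_equal(colonize(0, c(10, 10, 10), lung, p), 0)
  # site outside the lung mask
  lung0 <- array(0L, c(20, 20, 20))
  expect_equal(colonize(1e9, c(10, 10, 10), lung0, p), 0)
  # saturation with full tissue
  expect_equal(colonize(1e12, c(10, 10, 10), lung, p), p$colonization_capacity)
  # monotone in arrivals
  vals <- vapply(10^(2:8), function(a) colonize(a, c(10, 10, 10), lung, p),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("predicted cell count composes the chain and matches a hand-stepped oracle", {
  # fully specified 3-segment system: root + two leaves
  segsY <- rbind(seg_row(c(0, 0, 0), pi / 2, pi / 2, 10, 2),
                 seg_row(c(3, 7, 0), pi / 4, pi / 2, 8, 1.2),
                 seg_row(c(-3, 7, 0), 3 * pi / 4, pi / 2, 8, 1.2))
  tree <- as_tree(make_graph(segsY, data.frame(i = c(1, 1), j = c(2, 3), gap = 1)))
  lung <- array(1L, c(40, 40, 40))
  p <- model_params(d = 1e5, lambda_decay = 0.5, xi = 10, T = 100,
                    root_velocity = 0.05, p_extravasate = 0.01,
                    colonization_capacity = 1e6, colonize_radius = 3)
  tum <- tumor_spec(c(0, 0, 0), 3) # on segment 1: contact at t = 0
  ep2 <- segment_endpoints(segsY[2, ])
  tau <- as.vector(ep2$el) + c(1, 1, 0) # near segment 2's end, inside volume

  res <- predict_cell_count(tree, tum, lung, tau, p)

  # hand-stepped oracle, independent arithmetic:
  flow <- solve_flow(tree, params = p)
  shed_o <- p$d * p$T # contact at t=0
  eo <- flow$edges
  k12 <- which(eo$i == 1 & eo$j == 2)
  t_o <- eo$L[k12] / eo$velocity[k12] / 3600
  arr_o <- shed_o * exp(-p$lambda_decay * t_o)
  if (arr_o < p$xi) arr_o <- 0
  f_o <- lungmetmap:::tissue_fraction(tau, lung, p$colonize_radius, c(1, 1, 1))
  set_o <- round(p$colonization_capacity * f_o *
                   (1 - exp(-p$p_extravasate * arr_o / p$colonization_capacity)))
  expect_equal(res$path, c(1L, 2L))
  expect_equal(res$arrived, arr_o, tolerance = 1e-12)
  expect_equal(res$c, set_o)
  expect_lte(res$c, res$arrived)
  expect_lte(res$arrived, res$shed)

  # degenerate path: tau on the tumor's own nearest vessel
  tau0 <- c(0, 0.1, 0)
  res0 <- predict_cell_count(tree, tum, lung, tau0, p)
  expect_equal(res0$path, 1L)
  expect_equal(res0$arrived, shed_o)

  # no shedding window: T earlier than contact time
  tum_far <- tumor_spec(c(20, 20, 20), 0.5)
  p_short <- model_params(d = 1e5, T = 1e-9, growth_a = 1e-4)
  res_ns <- predict_cell_count(tree, tum_far, lung, tau, p_short)
  expect_equal(res_ns$c, 0)
})

test_that("settled counts are monotone in decay, stop time, and shedding rate", {
  segsY <- rbind(seg_row(c(0, 0, 0), pi / 2, pi / 2, 10, 2),
                 seg_row(c(3, 7, 0), pi / 4, pi / 2, 8, 1.2))
  tree <- as_tree(make_graph(segsY, data.frame(i = 1, j = 2, gap = 1)))
  lung <- array(1L, c(40, 40, 40))
  tum <- tumor_spec(c(0, 0, 0), 3)
  tau <- c(6, 11, 1)
  base <- list(d = 1e5, lambda_decay = 0.5, xi = 10, T = 100,
               root_velocity = 0.05, p_extravasate = 0.01,
               colonization_capacity = 1e6, colonize_radius = 3)
  run <- function(over) {
    p <- do.call(model_params, utils::modifyList(base, over))
    predict_cell_count(tree, tum, lung, tau, p)$c
  }
  c_lam <- vapply(c(0.1, 0.5, 1, 2, 5), function(l) run(list(lambda_decay = l)), numeric(1))
  expect_true(all(diff(c_lam) <= 0))
  c_T <- vapply(c(10, 50, 100, 500), function(Tt) run(list(T = Tt)), numeric(1))
  expect_true(all(diff(c_T) >= 0))
  c_d <- vapply(c(1e3, 1e4, 1e5, 1e6), function(dd) run(list(d = dd)), numeric(1))
  expect_true(all(diff(c_d) >= 0))
})
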