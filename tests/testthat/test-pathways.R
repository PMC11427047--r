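test_that("nucleus sampling is uniform, contained and deterministic", {
  expect_equal(nrow(sample_points_in_nucleus(nucleus_volume("GPi", c(0, 0, 0),
                                                            c(1, 1, 1)), 0)), 0)
  ball <- nucleus_volume("GPi", c(0, 0, 0), c(1, 1, 1))
  p <- sample_points_in_nucleus(ball, 2000, rng_seed = 9)
  expect_true(all(inside_nucleus(ball, p)))
  # mean radius of uniform sampling in a ball is 3/4
  expect_lt(abs(mean(sqrt(rowSums(p^2))) - 0.75), 0.02)
  expect_identical(p, sample_points_in_nucleus(ball, 2000, rng_seed = 9))
})

test_that("modified-Akima slopes match an independent reference", {
  # reference slopes computed with SciPy's Akima1DInterpolator(method="makima")
  # for knots (0, 1, 2.5, 3, 4.2, 6), values (0, 2, 1, 3, 2.5, 4)
  ref <- c(2.7407407407, 0.7027027027, 0.9636098981, 0.4099821747,
           0.4536604361, 1.1698717949)
  got <- pallidopath:::makima_slopes(c(0, 1, 2.5, 3, 4.2, 6),
                                     c(0, 2, 1, 3, 2.5, 4))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("trajectory interpolation preserves lines and hits waypoints", {
  # two waypoints: straight segment, zero turning
  tr <- build_trajectory(rbind(c(0, 0, 0), c(5, 0, 0)), 0.1)
  expect_equal(max_turning(tr), 0, tolerance = 1e-9)

  # collinear data stays on the line
  wp <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  tr <- build_trajectory(wp, 0.1)
  expect_lt(max(abs(tr[, 2])), 1e-9)
  expect_lt(max(abs(tr[, 3])), 1e-9)

  # the interpolating curve passes through every waypoint exactly
  wp <- rbind(c(0, 0, 0), c(4, 2, 1), c(7, 1, 3), c(12, 0, 5))
  crv <- makima_curve(wp)
  knots <- attr(crv, "knots")
  expect_equal(crv(knots), wp, tolerance = 1e-9)

  # uniform chord spacing of the resampled polyline
  tr <- build_trajectory(wp, 0.1)
  d <- sqrt(rowSums((tr[-1, ] - tr[-nrow(tr), ])^2))
  expect_lt(max(abs(d - 0.1)), 1e-6)

  expect_error(build_trajectory(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "duplicate")
  expect_error(build_trajectory(rbind(c(0, 0, 0))), "two waypoints")
})

test_that("configured route shares follow the population counts", {
  sh <- route_shares(population_config())
  expect_equal(sh$pallidosubthalamic_trans_gpi, 750 / 2000)
  expect_equal(sh$striatofugal_trans_gpi, 980 / 2000)
  expect_equal(sh$gpi_efferent_dorsal, 0.5)
})

test_that("populated pathways honour counts, routes and containment", {
  sc <- build_default_scene(1)
  cfg <- small_config(n = 12)
  pops <- populate_pathways(cfg, sc, seed = 5)

  expect_setequal(names(pops), c("GPi_efferent", "GPe_GPi_STN", "GPe_STN",
                                 "Put_GPe_GPi", "Put_GPe", "IC_M1", "IC_PM",
                                 "IC_SMA"))
  for (pw in names(pops))
    expect_equal(pops[[pw]]$n_configured, unname(cfg$counts[pw]))

  # GPi efferents alternate routes with even ids dorsal; exact 50:50
  routes <- vapply(pops$GPi_efferent$trajectories, `[[`, "", "route")
  ids <- vapply(pops$GPi_efferent$trajectories, `[[`, 0L, "id")
  expect_equal(sum(routes == "dorsal_exit"), 6)
  expect_true(all(routes[ids %% 2 == 0] == "dorsal_exit"))

  # trans-GPi pallidosubthalamic axons touch GPe, GPi and end in STN
  for (ax in pops$GPe_GPi_STN$trajectories) {
    expect_true(any(inside_nucleus(sc$nuclei$GPe, ax$points)))
    expect_true(any(inside_nucleus(sc$nuclei$GPi, ax$points)))
    expect_true(inside_nucleus(sc$nuclei$STN, ax$points[nrow(ax$points), ]))
  }
  # striatofugal axons start in the putamen
  for (ax in pops$Put_GPe$trajectories)
    expect_true(inside_nucleus(sc$nuclei$Putamen, ax$points[1, ]))

  # fiber diameters: 2 um pallidal, 5.7 um capsular
  expect_true(all(vapply(pops$GPi_efferent$trajectories, `[[`, 0, "fiber_diameter") == 2.0))
  expect_true(all(vapply(pops$IC_M1$trajectories, `[[`, 0, "fiber_diameter") == 5.7))

  # turning bound holds for every axon of every pathway
  bound <- cfg$max_turning_angle * cfg$arc_spacing / cfg$reference_step
  for (pop in pops)
    for (ax in pop$trajectories)
      expect_lte(max_turning(ax$points), bound + 1e-9)

  # determinism
  pops2 <- populate_pathways(cfg, sc, seed = 5)
  expect_identical(pops, pops2)
  expect_false(identical(pops, populate_pathways(cfg, sc, seed = 6)))

  # missing nucleus is reported by name
  sc_broken <- sc
  sc_broken$nuclei$STN <- NULL
  expect_error(populate_pathways(cfg, sc_broken, seed = 1), "STN")
})

test_that("encapsulation removal flags exactly the colliding axons", {
  lead <- lead_model("medtronic_3389", c(0, 0, 0), c(0, 0, 1))
  lim <- lead$shaft_diameter / 2 + 0.25
  spacing <- 0.05
  offsets <- seq(0, 2, by = 0.1)
  mk <- function(off) {
    pts <- cbind(seq(-5, 5, by = spacing), off, 5)   # crosses at height 5
    structure(list(id = 1L, pathway = "GPi_efferent", route = "none",
                   points = pts, fiber_diameter = 2, removed = FALSE),
              class = "axon_trajectory")
  }
  pop <- structure(list(label = "GPi_efferent",
                        trajectories = lapply(offsets, mk),
                        n_configured = length(offsets), n_removed = 0L,
                        seed = 1L),
                   class = "pathway_population")
  out <- remove_encapsulation_collisions(pop, lead, 0.25)
  removed <- vapply(out$trajectories, `[[`, FALSE, "removed")

  # brute-force oracle: point-to-segment distance per trajectory
  a <- lead$tip_position; b <- lead$tip_position + lead$length * lead$axis
  oracle <- vapply(out$trajectories, function(ax)
    min(pallidopath:::point_segment_distance(ax$points, a, b)) <= lim,
    logical(1))
  expect_identical(removed, oracle)

  # boundary sits at shaft radius + thickness (within one lateral step)
  edge <- max(offsets[removed])
  expect_lt(abs(edge - lim), 0.1 + 1e-9)

  # audit trail: counts conserved, flags only
  expect_equal(out$n_configured, length(offsets))
  expect_equal(out$n_removed, sum(removed))

  # a trajectory through the axis is removed; a distant one is not
  expect_true(removed[1])
  expect_false(removed[length(offsets)])
})
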