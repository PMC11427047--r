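test_that("ellipsoid inside-test respects the closed-boundary convention", {
  nu <- nucleus_volume("GPi", c(1, -2, 3), c(4, 6, 4),
                       rotation_xyz(10, -20, 30))
  expect_true(inside_nucleus(nu, nu$center))
  # points at twice a semi-axis from the centre are outside
  M <- nu$orientation %*% diag(nu$semi_axes)
  for (k in 1:3) {
    expect_false(inside_nucleus(nu, nu$center + 2 * M[, k]))
    # exact surface points count as inside and have implicit value 1
    p <- nu$center + M[, k]
    expect_true(inside_nucleus(nu, p))
    expect_equal(pallidopath:::ellipsoid_value(nu, p)[1], 1, tolerance = 1e-9)
  }
})

test_that("inside-test volume agrees with Monte-Carlo sampling within 2%", {
  nu <- nucleus_volume("GPe", c(2, 1, -1), c(3, 5, 2.5),
                       rotation_xyz(25, 40, -15))
  set.seed(11)
  n <- 200000
  box <- cbind(runif(n, -6, 6), runif(n, -6, 6), runif(n, -6, 6))
  pts <- sweep(box, 2, nu$center, "+")
  frac <- mean(inside_nucleus(nu, pts))
  vol_mc <- frac * 12^3
  vol_true <- 4 / 3 * pi * prod(nu$semi_axes)
  expect_lt(abs(vol_mc - vol_true) / vol_true, 0.02)
})

test_that("ventral extreme matches closed form, brute force and equivariance", {
  nu <- nucleus_volume("STN", c(0, 0, 0), c(3, 2, 5))
  expect_equal(ventral_extreme(nu), c(0, 0, -5), tolerance = 1e-12)

  rot <- nucleus_volume("STN", c(0, 0, 0), c(3, 2, 5), rotation_xyz(x = 90))
  expect_equal(ventral_extreme(rot)[3], -2, tolerance = 1e-9)

  # translation equivariance
  sh <- nucleus_volume("STN", c(1, 2, 3), c(3, 2, 5), rotation_xyz(x = 90))
  expect_equal(ventral_extreme(sh), ventral_extreme(rot) + c(1, 2, 3),
               tolerance = 1e-9)

  # brute-force surface minimisation
  gen <- nucleus_volume("SN", c(1, -1, 2), c(2, 4, 3), rotation_xyz(33, 12, -57))
  set.seed(3)
  u <- matrix(rnorm(3 * 200000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  surf <- sweep(u %*% t(gen$orientation %*% diag(gen$semi_axes)), 2,
                gen$center, "+")
  expect_lt(abs(min(surf[, 3]) - ventral_extreme(gen)[3]), 1e-3)
  expect_lte(ventral_extreme(gen)[3], min(surf[, 3]) + 1e-6)
})

test_that("default scene is deterministic with the required geometry", {
  sc1 <- build_default_scene(1)
  sc2 <- build_default_scene(1)
  expect_identical(sc1, sc2)
  expect_false(identical(sc1, build_default_scene(2)))

  expect_setequal(names(sc1$nuclei), c("GPe", "GPi", "STN", "Putamen", "SN"))
  expect_true(inside_nucleus(sc1$nuclei$GPi, sc1$nuclei$GPi$center))

  # at least two contacts inside GPi (point-in-ellipsoid oracle per contact)
  inside <- inside_nucleus(sc1$nuclei$GPi,
                           as.matrix(sc1$lead$contacts[, c("x", "y", "z")]))
  expect_gte(sum(inside), 2)

  # tip inside or ventral to the GPi
  tip <- sc1$lead$tip_position
  expect_true(inside_nucleus(sc1$nuclei$GPi, tip) ||
                tip[3] < sc1$nuclei$GPi$center[3])

  # GPe and GPi do not overlap (sampled interior points of each are outside
  # the other)
  for (seed in 1:3) {
    sc <- build_default_scene(seed)
    pts_i <- sample_points_in_nucleus(sc$nuclei$GPi, 2000, rng_seed = 5)
    pts_e <- sample_points_in_nucleus(sc$nuclei$GPe, 2000, rng_seed = 5)
    expect_equal(sum(inside_nucleus(sc$nuclei$GPe, pts_i)), 0)
    expect_equal(sum(inside_nucleus(sc$nuclei$GPi, pts_e)), 0)
  }
})

test_that("lead contact geometry matches the manufacturer tables", {
  ld <- lead_model("medtronic_3389", c(0, 0, 0), c(0, 0, 1))
  ct <- ld$contacts
  expect_equal(nrow(ct), 4)
  expect_true(all(is.na(ct$segment)))
  # centres: tip offset 1.5 + half contact 0.75, then 2.0 mm pitch
  expect_equal(ct$z, c(2.25, 4.25, 6.25, 8.25), tolerance = 1e-12)
  expect_equal(unique(diff(ct$z)), 2.0, tolerance = 1e-12)
  expect_equal(ct$surface_area, rep(pi * 1.27 * 1.5, 4), tolerance = 1e-12)

  ld87 <- lead_model("medtronic_3387", c(0, 0, 0), c(0, 0, 1))
  expect_equal(unique(diff(ld87$contacts$z)), 3.0, tolerance = 1e-12)

  ab <- lead_model("abbott_6172", c(0, 0, 0), c(0, 0, 1))
  expect_equal(as.integer(table(ab$contacts$level)), c(1L, 3L, 3L, 1L))
  segs <- ab$contacts[ab$contacts$level == 2, ]
  expect_equal(segs$segment, c("a", "b", "c"))
  # segments of one level share the same axial span and a third of the area
  expect_equal(segs$surface_area, rep(pi * 1.29 * 1.5 / 3, 3), tolerance = 1e-12)

  # containment: total contact span shorter than the lead
  for (l in list(ld, ld87, ab)) {
    span <- sum(l$contacts$axial_span[!duplicated(l$contacts$level)])
    expect_lt(span, l$length)
  }
  # strict ventral-to-dorsal ordering along the axis
  proj <- as.matrix(ab$contacts[, c("x", "y", "z")]) %*% ab$axis
  lev_proj <- tapply(proj, ab$contacts$level, mean)
  expect_true(all(diff(lev_proj) > 0))

  expect_error(lead_model("boston_xyz"), "unknown lead model")
})

test_that("scene YAML round-trips", {
  sc <- build_default_scene(4)
  path <- tempfile(fileext = ".yaml")
  write_scene_yaml(sc, path)
  sc2 <- read_scene_yaml(path)
  expect_equal(sc2$nuclei$GPi$center, sc$nuclei$GPi$center, tolerance = 1e-6)
  expect_equal(sc2$lead$tip_position, sc$lead$tip_position, tolerance = 1e-6)
  expect_equal(sc2$lead$contacts$z, sc$lead$contacts$z, tolerance = 1e-6)
  expect_equal(sc2$encapsulation_thickness, sc$encapsulation_thickness)
})
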