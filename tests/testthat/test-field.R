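make_point_scene <- function(sigma_other = 0.3) {
  # a lead far from any nucleus so the conductivity is the `other` value
  nuclei <- list(nucleus_volume("GPi", c(100, 100, 100), c(1, 1, 1)),
                 nucleus_volume("GPe", c(110, 100, 100), c(1, 1, 1)),
                 nucleus_volume("STN", c(100, 110, 100), c(1, 1, 1)),
                 nucleus_volume("Putamen", c(120, 100, 100), c(1, 1, 1)),
                 nucleus_volume("SN", c(100, 120, 100), c(1, 1, 1)))
  lead <- lead_model("medtronic_3389", c(0, 0, 0), c(0, 0, 1))
  anatomy_scene(nuclei, lead, tissue_model(sigma_other = sigma_other), seed = 1)
}

test_that("unit potential of a single cathode matches the point-source form", {
  sc <- make_point_scene()
  st <- stim_setting("clinical", "0", "case", 1, "current", 60, 130)
  fs <- solve_unit_field(sc, st)
  ctr <- unlist(sc$lead$contacts[1, c("x", "y", "z")])
  # 3 mm radially from the contact centre: phi = -1e-3/(4 pi 0.3 0.003) V/mA
  got <- unname(fs$unit_potential_at(matrix(ctr + c(3, 0, 0), 1)))
  # a short line source reads slightly below the ideal point source
  expect_equal(got, -1e-3 / (4 * pi * 0.3 * 3e-3), tolerance = 0.02)
  expect_equal(fs$solve_frequency, 3049)

  # symmetry about the contact's equatorial plane
  p_up <- fs$unit_potential_at(matrix(ctr + c(2, 0, 1.3), 1))
  p_dn <- fs$unit_potential_at(matrix(ctr + c(2, 0, -1.3), 1))
  expect_equal(p_up, p_dn, tolerance = 1e-9)

  # monotone decay along a ray beyond the contact span
  rr <- seq(2, 12, by = 0.5)
  vals <- fs$unit_potential_at(cbind(ctr[1] + rr, ctr[2], ctr[3]))
  expect_true(all(diff(abs(vals)) < 0))
})

test_that("two equal cathodes superpose as half-strength sources", {
  sc <- make_point_scene()
  st2 <- stim_setting("clinical", c("0", "1"), "case", 1, "current", 60, 130)
  st0 <- stim_setting("clinical", "0", "case", 1, "current", 60, 130)
  st1 <- stim_setting("clinical", "1", "case", 1, "current", 60, 130)
  f2 <- solve_unit_field(sc, st2)
  f0 <- solve_unit_field(sc, st0)
  f1 <- solve_unit_field(sc, st1)
  set.seed(2)
  pts <- matrix(rnorm(30, sd = 6), ncol = 3)
  pts <- pts[sqrt(rowSums(pts^2)) > 2, , drop = FALSE]
  expect_equal(f2$unit_potential_at(pts),
               (f0$unit_potential_at(pts) + f1$unit_potential_at(pts)) / 2,
               tolerance = 1e-9)
})

test_that("off setting yields a zero field and bad settings error", {
  sc <- make_point_scene()
  off <- stim_setting("off", character(), "case", 0, "current", 60, 130)
  f <- solve_unit_field(sc, off)
  expect_equal(f$unit_potential_at(matrix(c(3, 0, 0), 1)), 0)
  expect_error(stim_setting("clinical", character(), "case", 2, "current"),
               "cathode")
  expect_error(stim_setting("off", character(), "case", 2, "current"),
               "amplitude 0")
})

test_that("anisotropic mode with an isotropic tensor matches isotropic", {
  sc_iso <- make_point_scene()
  sc_tens <- sc_iso
  sc_tens$tissue <- tissue_model("tensor_field", sigma_other = 0.3,
                                 tensor_at = function(p) diag(3) * 0.3)
  st <- stim_setting("clinical", "0", "case", 1, "current", 60, 130)
  f_iso <- solve_unit_field(sc_iso, st)
  f_ten <- solve_unit_field(sc_tens, st)
  set.seed(4)
  pts <- matrix(rnorm(30, sd = 5), ncol = 3)
  pts <- pts[sqrt(rowSums(pts^2)) > 2.5, , drop = FALSE]
  expect_equal(f_ten$unit_potential_at(pts), f_iso$unit_potential_at(pts),
               tolerance = 1e-9)
})

test_that("sampling along positions preserves order and guards the shaft", {
  sc <- make_point_scene()
  st <- stim_setting("clinical", "0", "case", 1, "current", 60, 130)
  fs <- solve_unit_field(sc, st)
  ctr <- unlist(sc$lead$contacts[1, c("x", "y", "z")])
  # equal radii give equal potentials
  ring <- t(vapply(seq(0, 2 * pi, length.out = 7)[-7],
                   function(a) ctr + 3 * c(cos(a), sin(a), 0), numeric(3)))
  v <- sample_along(fs, ring)
  expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
  # doubling the radius halves the magnitude (far field)
  v1 <- sample_along(fs, matrix(ctr + c(6, 0, 0), 1))
  v2 <- sample_along(fs, matrix(ctr + c(12, 0, 0), 1))
  expect_equal(unname(v1 / v2), 2, tolerance = 0.02)
  expect_identical(sample_along(fs, matrix(numeric(0), 0, 3)), numeric(0))
  expect_error(sample_along(fs, matrix(ctr + c(0.1, 0, 0), 1), lead = sc$lead),
               "shaft")
})

test_that("voltage mode normalizes the mean contact-surface potential", {
  sc <- make_point_scene()
  st <- stim_setting("clinical", "0", "case", 1, "voltage", 60, 130)
  fs <- solve_unit_field(sc, st)
  expect_equal(fs$solve_frequency, 4294)
  ct <- sc$lead$contacts[1, ]
  # potential magnitude on the contact surface is of order 1 V per volt
  basis <- pallidopath:::orthonormal_basis(sc$lead$axis)
  surf <- t(vapply(seq(0, 2 * pi, length.out = 13)[-13], function(a)
    c(ct$x, ct$y, ct$z) + (sc$lead$shaft_diameter / 2) *
      (cos(a) * basis$u + sin(a) * basis$v), numeric(3)))
  vals <- fs$unit_potential_at(surf)
  expect_lt(abs(mean(vals) - (-1)), 0.45)
  # linearity in drive is inherited downstream: unit field independent of
  # amplitude by construction
  st2 <- stim_setting("clinical", "0", "case", 3, "voltage", 60, 130)
  fs2 <- solve_unit_field(sc, st2)
  p <- matrix(c(3, 1, 2), 1)
  expect_equal(fs$unit_potential_at(p), fs2$unit_potential_at(p))
})

test_that("waveforms have the right pulse train structure", {
  st <- test_setting(pulse_width = 60, frequency = 130)
  wf <- make_waveform(st, n_pulses = 10, dt = 5)
  expect_equal(length(wf$pulse_times), 10)
  expect_equal(wf$pulse_times, (0:9) / 130 * 1e6, tolerance = 1e-9)
  expect_true(all(wf$samples >= -1 & wf$samples <= 0))
  # total cathodic charge: 10 pulses x 60 us at amplitude -1
  expect_equal(sum(wf$samples) * wf$dt, -10 * 60, tolerance = 1e-9)

  # filtering preserves charge
  wff <- make_waveform(st, n_pulses = 10, dt = 5, filtered = TRUE)
  expect_equal(sum(wff$samples) * wff$dt, sum(wf$samples) * wf$dt,
               tolerance = 1e-6)

  # zero pulses: all-zero waveform
  wf0 <- make_waveform(st, n_pulses = 0)
  expect_true(all(wf0$samples == 0))

  expect_error(make_waveform(st, dt = 30), "dt too coarse")
})

test_that("settings parse from the shipped table", {
  path <- system.file("extdata", "dbs_settings.csv", package = "pallidopath")
  settings <- read_stim_settings(path)
  expect_equal(length(settings), 51)
  labels <- vapply(settings, `[[`, "", "label")
  expect_equal(sum(labels == "clinical"), 17)
  expect_equal(sum(labels == "dorsal"), 17)
  expect_equal(sum(labels == "ventral"), 17)
  # segmented example: three active segments, current controlled
  seg <- settings[[which(vapply(settings, function(s)
    attr(s, "id") == 3 && s$label == "clinical", logical(1)))[1]]]
  expect_equal(seg$cathodes, c("2a", "2b", "2c"))
  expect_equal(seg$control, "current")
  expect_equal(seg$amplitude, 4)
  # experimental settings hold 120 Hz / 60 us
  exper <- settings[labels != "clinical"]
  expect_true(all(vapply(exper, `[[`, 0, "frequency") == 120))
  expect_true(all(vapply(exper, `[[`, 0, "pulse_width") == 60))
})
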