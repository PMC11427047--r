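# Shared fixtures: small cables, analytic point-source fields and compact
# stimulation settings used across the suite.

straight_cable <- function(fiber_diameter, length_mm = 10.5, n_pts = 105) {
  build_cable(cbind(seq(-length_mm / 2, length_mm / 2, length.out = n_pts), 0, 0),
              fiber_diameter)
}

# Unit cathodic point-source field (V per mA) at distance z above the cable.
point_source_ve <- function(cable, src = c(0, 0, 2), sigma = 0.3) {
  r <- sqrt(rowSums(sweep(cable$positions, 2, src)^2))
  -1e-3 / (4 * pi * sigma * (r * 1e-3))
}

test_setting <- function(amplitude = 2, pulse_width = 60, frequency = 130) {
  stim_setting("clinical", cathodes = "0", anodes = "case",
               amplitude = amplitude, control = "current",
               pulse_width = pulse_width, frequency = frequency)
}

# Small pathway configuration for fast population tests.
small_config <- function(n = 12) {
  population_config(counts = c(GPi_efferent = n, GPe_GPi_STN = n, GPe_STN = n,
                               Put_GPe_GPi = n, Put_GPe = n, IC_M1 = 4,
                               IC_PM = 4, IC_SMA = 4))
}

max_turning <- function(points) {
  a <- pallidopath:::turning_angles(points)
  if (length(a)) max(a) else 0
}

# All permutations of 1..n (tiny n only).
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1))
    for (k in 0:(n - 1))
      out[[length(out) + 1]] <- append(p, n, after = k)
  out
}

# Brute-force signed-rank oracle: exact two-sided p by enumerating all 2^n
# sign assignments of the midranked absolute differences.
enumerate_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_low <- mean(w_all <= w_obs + 1e-12)
  p_high <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_low, p_high))
}
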