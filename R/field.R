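# Extracellular field of a stimulation setting.  The finite-element volume
# conductor is replaced by an analytic multi-point-source surrogate behind a
# pluggable solver contract: anything that maps (scene, setting) to a
# unit-potential function can be swapped in, and downstream modules depend
# only on that contract.

#' Stimulation setting
#'
#' @param label `"clinical"`, `"dorsal"`, `"ventral"` or `"off"`.
#' @param cathodes character vector of contact labels (e.g. `c("2a","2b")`),
#'   resolved against the lead's contact table.
#' @param anodes contact labels, or `"case"` for monopolar stimulation.
#' @param amplitude pulse amplitude (mA in current mode, V in voltage mode);
#'   non-negative.
#' @param control `"current"` or `"voltage"`.
#' @param pulse_width pulse width, microseconds.
#' @param frequency pulse rate, Hz.
#' @return an object of class `stim_setting`.
#' @export
stim_setting <- function(label = c("clinical", "dorsal", "ventral", "off"),
                         cathodes = character(), anodes = "case",
                         amplitude = 0, control = c("current", "voltage"),
                         pulse_width = 60, frequency = 120) {
  label <- match.arg(label)
  control <- match.arg(control)
  stopifnot(amplitude >= 0, pulse_width > 0, frequency > 0)
  if (label == "off" && amplitude != 0) stop("off setting must have amplitude 0")
  if (label != "off" && length(cathodes) < 1) stop("setting needs at least one cathode")
  structure(list(label = label, cathodes = cathodes, anodes = anodes,
                 amplitude = amplitude, control = control,
                 pulse_width = pulse_width, frequency = frequency),
            class = "stim_setting")
}

#' @export
print.stim_setting <- function(x, ...) {
  cat(sprintf("<stim_setting> %s: %s- %s+ %.2f %s, %g us, %g Hz\n", x$label,
              paste(x$cathodes, collapse = ","), paste(x$anodes, collapse = ","),
              x$amplitude, if (x$control == "current") "mA" else "V",
              x$pulse_width, x$frequency))
  invisible(x)
}

#' Read stimulation settings from CSV
#'
#' Expected columns: `label`, `cathodes` (comma-separated contact labels),
#' `anodes` (labels or `case`), `amplitude`, `unit` (`mA` or `V`),
#' `pulse_width_us`, `frequency_hz`. Extra columns (ids, lead model, side)
#' are carried through as attributes on each setting.
#'
#' @param path CSV file path.
#' @return list of [stim_setting()] objects.
#' @export
read_stim_settings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  split_labels <- function(s) {
    s <- trimws(s)
    if (is.na(s) || s == "") character() else trimws(strsplit(s, ",")[[1]])
  }
  lapply(seq_len(nrow(df)), function(i) {
    st <- stim_setting(df$label[i], split_labels(df$cathodes[i]),
                       split_labels(df$anodes[i]), df$amplitude[i],
                       if (toupper(df$unit[i]) == "V") "voltage" else "current",
                       df$pulse_width_us[i], df$frequency_hz[i])
    for (extra in setdiff(names(df), c("label", "cathodes", "anodes", "amplitude",
                                       "unit", "pulse_width_us", "frequency_hz")))
      attr(st, extra) <- df[[extra]][i]
    st
  })
}

# Resolve contact labels against a lead's contact table.
resolve_contacts <- function(lead, labels) {
  idx <- match(labels, lead$contacts$label)
  if (anyNA(idx)) stop("unknown contact label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' Solve the unit-amplitude extracellular field of a setting
#'
#' Analytic surrogate honouring the conventions of the original
#' finite-element formulation. Current mode: each active contact is a short
#' line of point sources along its axial span carrying its surface-area share
#' of +/-1 mA (cathodes negative, contact anodes positive, case at infinity);
#' the potential is the superposition phi(r) = sum I_i / (4 pi sigma |r-r_i|)
#' with sigma evaluated at the cathode midpoint. Voltage mode: identical
#' geometry, with the source strength normalized so the mean potential over
#' the active cathode surface equals -1 V (sphere-equivalent access
#' resistance). The solve frequency (3049 Hz current / 4294 Hz voltage) is
#' recorded as metadata only; the surrogate is quasi-static.
#'
#' @param scene an [anatomy_scene()].
#' @param setting a [stim_setting()].
#' @param n_sources point sources per contact span.
#' @param encapsulation_attenuation optional scalar multiplier (default 1)
#'   folding the encapsulation layer's electrical effect into the field.
#' @return an object of class `field_solution` with element
#'   `unit_potential_at(points)` returning volts per unit drive (per mA in
#'   current mode, per V in voltage mode).
#' @export
solve_unit_field <- function(scene, setting, n_sources = 5,
                             encapsulation_attenuation = 1) {
  lead <- scene$lead
  solve_frequency <- if (setting$control == "current") 3049 else 4294

  if (setting$label == "off") {
    f <- function(points) rep(0, nrow(matrix(points, ncol = 3)))
    return(structure(list(setting = setting, unit_potential_at = f,
                          solve_frequency = solve_frequency,
                          sources = data.frame()),
                     class = "field_solution"))
  }
  if (length(setting$cathodes) == 0)
    stop("setting with nonzero amplitude needs a cathode")

  cat_idx <- resolve_contacts(lead, setting$cathodes)
  an_idx <- if (identical(setting$anodes, "case") || length(setting$anodes) == 0)
    integer(0) else resolve_contacts(lead, setting$anodes)

  # point sources along each active contact's axial span; segmented contacts
  # are already offset radially in the contact table
  source_points <- function(rows, sign) {
    ct <- lead$contacts[rows, , drop = FALSE]
    share <- ct$surface_area / sum(ct$surface_area)
    out <- list()
    for (i in seq_len(nrow(ct))) {
      offs <- seq(-ct$axial_span[i] / 2, ct$axial_span[i] / 2,
                  length.out = n_sources)
      ctr <- c(ct$x[i], ct$y[i], ct$z[i])
      pts <- t(vapply(offs, function(o) ctr + o * lead$axis, numeric(3)))
      out[[i]] <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                             current = sign * share[i] / n_sources)
    }
    do.call(rbind, out)
  }
  src <- source_points(cat_idx, -1)
  if (length(an_idx)) src <- rbind(src, source_points(an_idx, +1))

  mid <- colMeans(lead$contacts[cat_idx, c("x", "y", "z")])
  sigma <- tissue_sigma_at(scene, as.numeric(mid))   # S/m

  # voltage-mode normalization: sphere-equivalent access resistance of the
  # combined cathode surface; drive scaled so the mean cathode-surface
  # potential is -1 V per unit (1 V) programmed amplitude
  scale <- if (setting$control == "voltage") {
    a_eq <- sqrt(sum(lead$contacts$surface_area[cat_idx]) / (4 * pi)) * 1e-3  # m
    4 * pi * sigma * a_eq * 1e3    # mA per V through the access resistance
  } else 1

  srcm <- as.matrix(src[, c("x", "y", "z")])
  cur <- src$current * scale * encapsulation_attenuation   # mA per unit drive
  min_r <- lead$shaft_diameter / 2 * 0.999

  unit_potential_at <- function(points) {
    points <- matrix(points, ncol = 3)
    if (nrow(points) == 0) return(numeric(0))
    out <- numeric(nrow(points))
    for (i in seq_len(nrow(srcm))) {
      r <- sqrt((points[, 1] - srcm[i, 1])^2 + (points[, 2] - srcm[i, 2])^2 +
                (points[, 3] - srcm[i, 3])^2)
      r <- pmax(r, min_r)                      # clamp at the shaft surface
      out <- out + cur[i] * 1e-3 / (4 * pi * sigma * r * 1e-3)
    }
    out                                         # volts per unit drive
  }

  structure(list(setting = setting, unit_potential_at = unit_potential_at,
                 solve_frequency = solve_frequency, sigma = sigma,
                 sources = cbind(src, scaled_current = cur)),
            class = "field_solution")
}

#' Sample a field solution along positions
#'
#' @param field a `field_solution`.
#' @param positions n x 3 matrix of points, mm; positions inside the lead
#'   shaft are an error (axons there must have been removed).
#' @param lead optional [lead_model()] used for the shaft check.
#' @return numeric vector of unit potentials (V per unit drive), same order.
#' @export
sample_along <- function(field, positions, lead = NULL) {
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0) return(numeric(0))
  if (!is.null(lead)) {
    d <- point_segment_distance(positions, lead$tip_position,
                                lead$tip_position + lead$length * lead$axis)
    if (any(d < lead$shaft_diameter / 2))
      stop("position(s) inside the lead shaft; remove colliding axons first")
  }
  field$unit_potential_at(positions)
}

#' Build a stimulation pulse-train waveform
#'
#' Rectangular monophasic cathodic pulses (amplitude -1, width
#' `pulse_width`) at the setting's frequency. With `filtered = TRUE` the
#' train is convolved with a first-order low-pass (time constant `tau_f`,
#' default 10 us) normalized to preserve pulse charge, standing in for the
#' filtering that tissue applies to stimulus pulses.
#'
#' @param setting a [stim_setting()].
#' @param n_pulses number of pulses (default 10).
#' @param dt sample interval, microseconds (must satisfy
#'   `dt <= pulse_width / 6`).
#' @param filtered apply the low-pass?
#' @param tau_f filter time constant, microseconds.
#' @param tail_us extra time simulated after the last pulse, microseconds.
#' @return object of class `stim_waveform`: samples in `[-1, 0]`, `dt`,
#'   pulse onset times (us), pulse width, frequency.
#' @export
make_waveform <- function(setting, n_pulses = 10, dt = 5, filtered = FALSE,
                          tau_f = 10, tail_us = 10000) {
  if (dt > setting$pulse_width / 6)
    stop("dt too coarse: must be <= pulse_width / 6")
  period_us <- 1e6 / setting$frequency
  onsets <- (seq_len(n_pulses) - 1) * period_us
  total <- if (n_pulses > 0) onsets[n_pulses] + tail_us else tail_us
  tt <- seq(0, total, by = dt)
  samples <- rep(0, length(tt))
  for (on in onsets)
    samples[tt >= on & tt < on + setting$pulse_width] <- -1
  if (filtered && n_pulses > 0) {
    # exact exponential-smoothing discretization of a single-pole low-pass
    alpha <- 1 - exp(-dt / tau_f)
    y <- numeric(length(samples))
    acc <- 0
    for (i in seq_along(samples)) {
      acc <- acc + alpha * (samples[i] - acc)
      y[i] <- acc
    }
    # renormalize to preserve charge per train
    q0 <- sum(samples) * dt
    q1 <- sum(y) * dt
    if (q1 != 0) y <- y * (q0 / q1)
    samples <- y
  }
  structure(list(samples = samples, dt = dt, pulse_times = onsets,
                 pulse_width = setting$pulse_width,
                 frequency = setting$frequency, filtered = filtered),
            class = "stim_waveform")
}
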