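# Multicompartment myelinated axon cables: geometry tables, construction
# along a trajectory, stimulation, activation detection and threshold search.

# Published MRG geometry sets by fiber diameter (um).  deltax = internodal
# (node-to-node) length, node_diam = node/MYSA axolemma diameter, axon_diam =
# FLUT/STIN axolemma diameter, flut_len = paranode-main length, n_lamella =
# myelin lamellae.  Node length 1 um and MYSA length 3 um for all diameters.
MRG_GEOM_TABLE <- data.frame(
  fiber_diam = c(5.7, 7.3, 8.7, 10, 11.5, 12.8, 14, 15, 16),
  deltax     = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
  node_diam  = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
  axon_diam  = c(3.4, 4.6, 5.8, 6.9, 8.1, 9.2, 10.4, 11.5, 12.7),
  flut_len   = c(35, 38, 40, 46, 50, 54, 56, 58, 60),
  n_lamella  = c(80, 100, 110, 120, 130, 135, 140, 145, 150))

# Power-law (log-log least-squares over the table above) coefficients used to
# extend the geometry below the smallest published diameter; a straight-line
# fit goes negative at 2 um, a power law stays positive and reproduces the
# classic ~100 x diameter internodal-length rule.  value = a * fiber_diam^b.
MRG_GEOM_FIT <- list(
  deltax    = c(a = 99.296757, b = 1.012988),
  node_diam = c(a = 0.313542, b = 1.022468),
  axon_diam = c(a = 0.376738, b = 1.260782),
  flut_len  = c(a = 12.634039, b = 0.561541),
  n_lamella = c(a = 30.745652, b = 0.579433))

#' MRG cable geometry for a fiber diameter
#'
#' Published parameter sets are used at their exact diameters; other
#' diameters (notably the 2.0-um pallidal fibers) use a power-law fit of the
#' published diameter scaling, shipped as an explicit coefficient table.
#'
#' @param fiber_diameter outer fiber diameter, um.
#' @return list of section lengths/diameters (um), lamella count and
#'   periaxonal-space widths.
#' @export
mrg_geometry <- function(fiber_diameter) {
  stopifnot(fiber_diameter > 0)
  hit <- which(abs(MRG_GEOM_TABLE$fiber_diam - fiber_diameter) < 1e-9)
  g <- if (length(hit) == 1) {
    as.list(MRG_GEOM_TABLE[hit, ])
  } else {
    out <- lapply(MRG_GEOM_FIT, function(cf)
      unname(cf["a"] * fiber_diameter^cf["b"]))
    out$fiber_diam <- fiber_diameter
    out
  }
  flut <- g$flut_len
  stin <- (g$deltax - 1 - 2 * 3 - 2 * flut) / 6
  if (stin <= 0) stop("degenerate geometry: non-positive STIN length")
  list(fiber_diam = g$fiber_diam, deltax = g$deltax,
       node_len = 1, mysa_len = 3, flut_len = flut, stin_len = stin,
       node_diam = g$node_diam, mysa_diam = g$node_diam,
       flut_diam = g$axon_diam, stin_diam = g$axon_diam,
       n_lamella = g$n_lamella,
       # periaxonal space widths (um): node/MYSA narrow, FLUT/STIN wider
       peri_node = 0.002, peri_mysa = 0.002, peri_flut = 0.004,
       peri_stin = 0.004)
}

#' Build a cable along an axon trajectory
#'
#' Compartments follow the repeating section sequence
#' node-(MYSA-FLUT-STIN x6-FLUT-MYSA)-node. The cable is centred on the
#' trajectory: leftover arc length is split between both ends. Compartment
#' centre positions are interpolated on the polyline by arc length.
#'
#' @param trajectory n x 3 matrix of polyline points (mm) or an
#'   `axon_trajectory`.
#' @param fiber_diameter um; defaults to the trajectory's diameter if given
#'   an `axon_trajectory`.
#' @return object of class `axon_cable`: per-compartment `type`
#'   (node/MYSA/FLUT/STIN), lengths, diameters, positions (mm), `n_nodes`,
#'   `node_index` (compartment index of each node).
#' @export
build_cable <- function(trajectory, fiber_diameter = NULL) {
  if (inherits(trajectory, "axon_trajectory")) {
    if (is.null(fiber_diameter)) fiber_diameter <- trajectory$fiber_diameter
    trajectory <- trajectory$points
  }
  stopifnot(!is.null(fiber_diameter))
  g <- mrg_geometry(fiber_diameter)
  pts <- matrix(trajectory, ncol = 3)
  arc_mm <- polyline_arclength(pts)
  L_um <- arc_mm[length(arc_mm)] * 1000
  if (L_um < 2 * g$deltax)
    stop("trajectory too short: needs at least two internodal lengths")
  n_nodes <- floor(L_um / g$deltax) + 1

  seq_types <- c("MYSA", "FLUT", rep("STIN", 6), "FLUT", "MYSA")
  type <- c("node", rep(c(seq_types, "node"), n_nodes - 1))
  lens <- c(node = g$node_len, MYSA = g$mysa_len, FLUT = g$flut_len,
            STIN = g$stin_len)
  diams <- c(node = g$node_diam, MYSA = g$mysa_diam, FLUT = g$flut_diam,
             STIN = g$stin_diam)
  peri <- c(node = g$peri_node, MYSA = g$peri_mysa, FLUT = g$peri_flut,
            STIN = g$peri_stin)
  len_um <- unname(lens[type])
  cable_len <- sum(len_um)
  offset <- (L_um - cable_len) / 2
  centers_um <- offset + cumsum(len_um) - len_um / 2
  positions <- polyline_point_at(pts, centers_um / 1000)

  structure(list(
    fiber_diameter = fiber_diameter, geometry = g,
    type = type, len_um = len_um, diam_um = unname(diams[type]),
    peri_w_um = unname(peri[type]),
    positions = positions, arc_um = centers_um,
    n_nodes = n_nodes, node_index = which(type == "node"),
    n_compartments = length(type)),
    class = "axon_cable")
}

#' @export
print.axon_cable <- function(x, ...) {
  cat(sprintf("<axon_cable> D = %.1f um, %d nodes, %d compartments, internodal %.0f um\n",
              x$fiber_diameter, x$n_nodes, x$n_compartments, x$geometry$deltax))
  invisible(x)
}

type_code <- function(type) {
  match(type, c("node", "MYSA", "FLUT", "STIN")) - 1L
}

# Detection node: second node in from the cable end farther from the
# extracellular field maximum, so a detected spike reflects propagation
# rather than local stimulus artifact.
detection_node <- function(cable, ve_unit) {
  peak <- which.max(abs(ve_unit))
  nidx <- cable$node_index
  far_end_first <- abs(peak - nidx[length(nidx)]) < abs(peak - nidx[1])
  if (far_end_first) nidx[3] else nidx[length(nidx) - 2]
}

#' Simulate extracellular stimulation of a cable
#'
#' The extracellular potential applied to every compartment is
#' amplitude x envelope(t) x Ve_unit(compartment), where the envelope is the
#' (sign-flipped) stimulus waveform so that the cathodic phase imposes the
#' cathode-negative unit field. Spikes are upward crossings of -20 mV with a
#' 1-ms refractory period, detected at the second node from the cable end
#' farther from the field maximum; an axon is activated if a spike follows at
#' least 80% of the pulses within 10 ms of the pulse onset.
#'
#' @param cable an [build_cable()] result.
#' @param ve_unit per-compartment unit potentials, V per unit drive.
#' @param amplitude stimulation amplitude (mA or V).
#' @param waveform a [make_waveform()] result.
#' @param duration simulated time, ms; defaults to last pulse onset + 10 ms.
#' @param dt time step, ms (must be <= 0.005).
#' @param record_trace also return the voltage trace at recorded nodes.
#' @param record_extra extra compartment indices to monitor for spikes
#'   (e.g. terminal nodes).
#' @param early_stop stop integrating as soon as the activation outcome is
#'   settled (a spike reached the detection node, or every compartment has
#'   decayed subthreshold after the last pulse); only meaningful for
#'   single-pulse activation tests.
#' @param early_stop_train stop integrating a multi-pulse train once the
#'   80%-of-pulses criterion is already decided either way (enough pulse
#'   windows hit, or too many closed without a spike). The truncated spike
#'   list still yields the same activation decision.
#' @return list with elements `activation` (an `activation_result`),
#'   `spike_times`, `max_deviation_mV`, and optionally `trace`.
#' @export
simulate_cable <- function(cable, ve_unit, amplitude, waveform,
                           duration = NULL, dt = 0.002,
                           record_trace = FALSE, record_extra = integer(),
                           early_stop = FALSE, early_stop_train = FALSE) {
  stopifnot(length(ve_unit) == cable$n_compartments)
  if (dt > 0.005) stop("dt must be <= 0.005 ms")
  if (any(!is.finite(ve_unit))) stop("non-finite extracellular potentials")
  onsets_ms <- waveform$pulse_times / 1000
  if (is.null(duration))
    duration <- if (length(onsets_ms)) max(onsets_ms) + 10 else 10
  if (length(onsets_ms) && duration < max(onsets_ms) + 10)
    stop("duration must cover the last pulse onset + 10 ms")
  det <- detection_node(cable, ve_unit)
  rec <- unique(c(det, as.integer(record_extra)))
  env <- -waveform$samples                   # cathodic envelope in [0, 1]
  pulse_end_ms <- if (length(onsets_ms))
    max(onsets_ms) + waveform$pulse_width / 1000 else 0
  res <- .mrg_simulate_cpp(type_code(cable$type), cable$len_um, cable$diam_um,
                           cable$fiber_diameter, cable$geometry$n_lamella,
                           cable$peri_w_um, as.numeric(ve_unit),
                           amplitude, env, waveform$dt, dt, duration,
                           rec - 1L, -20, record_trace, early_stop,
                           pulse_end_ms, onsets_ms, early_stop_train)
  spikes <- setNames(res$spike_times, paste0("c", rec))
  act <- activation_result(spikes[[1]], onsets_ms)
  out <- list(activation = act, spike_times = spikes,
              detection_compartment = det,
              max_deviation_mV = res$max_deviation_mV,
              vm_final = res$vm_final)
  if (record_trace) {
    out$trace <- res$trace
    out$trace_time_ms <- seq(0, by = dt, length.out = nrow(res$trace))
    colnames(out$trace) <- paste0("c", rec)
  }
  out
}

#' Activation criterion from spike times
#'
#' Flag k is true iff a spike occurs in (onset_k, onset_k + 10 ms]; the axon
#' counts as activated when at least 80% of pulses are followed by a spike.
#'
#' @param spike_times spike times at the detection node, ms.
#' @param pulse_onsets_ms pulse onset times, ms.
#' @return object of class `activation_result`: `flags`, `activated`.
#' @export
activation_result <- function(spike_times, pulse_onsets_ms) {
  flags <- vapply(pulse_onsets_ms, function(on)
    any(spike_times > on & spike_times <= on + 10), logical(1))
  structure(list(flags = flags,
                 activated = length(flags) > 0 && mean(flags) >= 0.8),
            class = "activation_result")
}

#' Is the axon activated at a given amplitude?
#'
#' @inheritParams simulate_cable
#' @return logical.
#' @export
activated_at <- function(cable, ve_unit, amplitude, waveform, dt = 0.002,
                         duration = NULL, early_stop_train = TRUE) {
  simulate_cable(cable, ve_unit, amplitude, waveform, duration = duration,
                 dt = dt, early_stop_train = early_stop_train)$activation$activated
}

#' Binary-search activation threshold
#'
#' bisection on the interval 0..cap: if the axon is not activated at the cap it is
#' flagged `capped`; otherwise the bracket (highest non-activating, lowest
#' activating) is shrunk until its width is at most `tol` and the threshold
#' is reported as the bracket midpoint. Deterministic.
#'
#' @inheritParams simulate_cable
#' @param setting a [stim_setting()]; supplies the waveform unless one is
#'   given explicitly.
#' @param cap amplitude cap (mA or V), > 0.
#' @param tol bracket width tolerance (default 0.1 mA or V).
#' @param n_pulses pulses in the test waveform.
#' @param waveform optional pre-built waveform (overrides `setting`).
#' @param activation_fn optional predicate `amplitude -> logical` replacing
#'   the cable simulation (used to verify the bisection contract against
#'   synthetic oracles).
#' @return object of class `threshold_result`: `threshold`, `bracket`,
#'   `converged`, `capped`.
#' @export
find_threshold <- function(cable, ve_unit, setting, cap = 10, tol = 0.1,
                           dt = 0.002, n_pulses = 10, waveform = NULL,
                           activation_fn = NULL) {
  stopifnot(cap > 0)
  if (is.null(waveform)) waveform <- make_waveform(setting, n_pulses = n_pulses)
  if (is.null(activation_fn))
    activation_fn <- function(a) activated_at(cable, ve_unit, a, waveform, dt = dt)
  if (!activation_fn(cap))
    return(structure(list(threshold = NA_real_, bracket = c(cap, NA_real_),
                          converged = FALSE, capped = TRUE),
                     class = "threshold_result"))
  lo <- 0; hi <- cap
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (activation_fn(mid)) hi <- mid else lo <- mid
  }
  structure(list(threshold = (lo + hi) / 2, bracket = c(lo, hi),
                 converged = TRUE, capped = FALSE),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$capped) cat("<threshold_result> not activated at cap", x$bracket[1], "\n")
  else cat(sprintf("<threshold_result> %.3f (bracket %.3f - %.3f)\n",
                   x$threshold, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Thresholds (or direct activation) for whole populations
#'
#' Runs the threshold-then-compare workflow over every surviving axon of the
#' given populations for one stimulation setting. `mode = "direct"` skips the
#' threshold search and tests activation at the setting amplitude only (one
#' simulation per axon), which is what percent-activation summaries need; it
#' is used for large scaled-down pipeline runs.
#'
#' @param populations named list of `pathway_population` (removal flags set).
#' @param scene the [anatomy_scene()].
#' @param setting a [stim_setting()].
#' @param mode `"threshold"` or `"direct"`.
#' @param cap amplitude cap for threshold search.
#' @param dt integration step, ms.
#' @param n_pulses pulses per waveform (10 for the full criterion; 1 in fast
#'   scaled-down runs where per-pulse responses are identical).
#' @param field optional precomputed `field_solution`.
#' @param max_cable_mm optional cap on cable length: the trajectory is
#'   truncated to a window of this arc length centred on its closest approach
#'   to the lead before the cable is built (activation is governed by the
#'   field near the electrode; distal compartments contribute negligibly).
#' @return data frame: axon_id, pathway, threshold, capped, activated.
#' @export
compute_thresholds <- function(populations, scene, setting,
                               mode = c("threshold", "direct"),
                               cap = 10, dt = 0.002, n_pulses = 10,
                               field = NULL, max_cable_mm = Inf) {
  mode <- match.arg(mode)
  if (is.null(field)) field <- solve_unit_field(scene, setting)
  waveform <- make_waveform(setting, n_pulses = n_pulses)
  rows <- list()
  for (pop in populations) {
    for (ax in pop$trajectories) {
      if (ax$removed) next
      pts <- if (is.finite(max_cable_mm))
        truncate_near_lead(ax$points, scene$lead, max_cable_mm) else ax$points
      cab <- build_cable(pts, ax$fiber_diameter)
      ve <- field$unit_potential_at(cab$positions)
      if (mode == "threshold") {
        th <- find_threshold(cab, ve, setting, cap = cap, dt = dt,
                             waveform = waveform)
        rows[[length(rows) + 1]] <- data.frame(
          axon_id = ax$id, pathway = ax$pathway,
          threshold = th$threshold, capped = th$capped,
          activated = !th$capped && th$threshold <= setting$amplitude)
      } else {
        act <- simulate_cable(cab, ve, setting$amplitude, waveform, dt = dt,
                              early_stop = TRUE)$activation$activated
        rows[[length(rows) + 1]] <- data.frame(
          axon_id = ax$id, pathway = ax$pathway,
          threshold = NA_real_, capped = NA, activated = act)
      }
    }
  }
  do.call(rbind, rows)
}

# Contiguous trajectory window of arc length `window_mm` centred on the
# point of closest approach to the lead axis.
truncate_near_lead <- function(points, lead, window_mm) {
  d <- point_segment_distance(points, lead$tip_position,
                              lead$tip_position + lead$length * lead$axis)
  arc <- polyline_arclength(points)
  s0 <- arc[which.min(d)]
  keep <- arc >= s0 - window_mm / 2 & arc <= s0 + window_mm / 2
  if (sum(keep) < 2) keep[seq_len(min(2, length(keep)))] <- TRUE
  points[keep, , drop = FALSE]
}
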