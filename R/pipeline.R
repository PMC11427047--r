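# End-to-end scaled pipeline: synthetic hemispheres -> pathway populations ->
# field -> cable activation -> per-setting activated-axon counts.  This is
# the geometry/biophysics front end of the linkage analysis; its output is a
# design matrix of activated-axon counts per hemisphere x setting.

#' Default per-hemisphere experimental settings for pipeline runs
#'
#' A clinically-styled monopolar triplet on a 4-ring lead: a higher-amplitude
#' setting on a middle contact plus lower-amplitude settings biased to the
#' ventral and dorsal contacts.
#'
#' @param amplitudes named amplitudes (mA) for clinical/ventral/dorsal.
#' @return list of [stim_setting()] objects.
#' @export
pipeline_settings <- function(amplitudes = c(clinical = 4, ventral = 2.5, dorsal = 2.5)) {
  list(
    stim_setting("clinical", cathodes = "1", anodes = "case",
                 amplitude = amplitudes[["clinical"]], control = "current",
                 pulse_width = 60, frequency = 130),
    stim_setting("ventral", cathodes = "0", anodes = "case",
                 amplitude = amplitudes[["ventral"]], control = "current",
                 pulse_width = 60, frequency = 120),
    stim_setting("dorsal", cathodes = "2", anodes = "case",
                 amplitude = amplitudes[["dorsal"]], control = "current",
                 pulse_width = 60, frequency = 120))
}

#' Activated-axon design matrix from the scaled biophysical pipeline
#'
#' For each synthetic hemisphere: build a scene (lead depth varies across
#' hemispheres), populate the five pallidal/striatofugal pathways, remove
#' encapsulation collisions, solve the field of each setting and count the
#' axons activated at the setting amplitude with single-pulse cable
#' simulations (per-pulse responses of a regular train are identical, so a
#' one-pulse activation test decides the 80%-of-pulses criterion).
#'
#' @param n_hemispheres number of synthetic hemispheres.
#' @param axons_per_pathway axon count used for every pallidal pathway.
#' @param seed integer seed.
#' @param settings list of [stim_setting()] per hemisphere (default
#'   [pipeline_settings()]).
#' @param dt integration step, ms.
#' @param max_cable_mm cable-window truncation (see [compute_thresholds()]).
#' @return data frame: hemisphere, setting, activated-axon count per pathway
#'   column, plus `n_total` per pathway as attributes.
#' @export
pipeline_activation_design <- function(n_hemispheres = 17,
                                       axons_per_pathway = 100,
                                       seed = 1,
                                       settings = pipeline_settings(),
                                       dt = 0.005, max_cable_mm = 8) {
  depth_shift <- seq(-1.5, 1.5, length.out = n_hemispheres)
  counts <- setNames(rep(0L, length(PATHWAY_LABELS)), PATHWAY_LABELS)
  counts[LINKAGE_PATHWAYS] <- axons_per_pathway
  config <- population_config(counts = counts)
  rows <- list()
  for (h in seq_len(n_hemispheres)) {
    scene <- build_default_scene(seed + h)
    lead <- scene$lead
    scene$lead <- lead_model(lead$model,
                             lead$tip_position + depth_shift[h] * lead$axis,
                             lead$axis, lead$roll_angle)
    pops <- populate_pathways(config, scene, seed = seed + 1000 + h)
    pops <- remove_collisions_all(pops, scene)
    pops <- pops[LINKAGE_PATHWAYS]
    for (st in settings) {
      thr <- compute_thresholds(pops, scene, st, mode = "direct",
                                dt = dt, n_pulses = 1,
                                max_cable_mm = max_cable_mm)
      summ <- summarize_activation(thr, st, pops)
      row <- data.frame(hemisphere = h, setting = st$label)
      for (pw in LINKAGE_PATHWAYS)
        row[[pw]] <- summ$n_activated[summ$pathway == pw]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_total") <- axons_per_pathway
  out
}
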