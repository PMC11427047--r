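# Per-pathway activation summaries and electrode-location analyses.

#' Summarize percent pathway activation for a setting
#'
#' An axon counts as activated when its threshold is at or below the setting
#' amplitude (and not capped); removed axons are excluded from the
#' denominator. Percent activation is 100 x activated / surviving.
#'
#' @param thresholds data frame from [compute_thresholds()] (columns
#'   axon_id, pathway, threshold, capped; `activated` is recomputed from the
#'   amplitude unless thresholds are absent, as in direct mode).
#' @param setting the [stim_setting()] the thresholds were computed for.
#' @param populations the populations the thresholds cover (for totals and
#'   missing-axon checks).
#' @return data frame: pathway, setting, n_total, n_activated, percent.
#' @export
summarize_activation <- function(thresholds, setting, populations) {
  rows <- list()
  for (pop in populations) {
    ids <- vapply(pop$trajectories, `[[`, 0L, "id")
    surv <- !vapply(pop$trajectories, `[[`, FALSE, "removed")
    ids <- ids[surv]
    n_total <- length(ids)
    if (setting$label == "off" || setting$amplitude == 0) {
      n_act <- 0L
    } else {
      sub <- thresholds[thresholds$pathway == pop$label, , drop = FALSE]
      missing <- setdiff(ids, sub$axon_id)
      if (length(missing))
        stop("missing thresholds for axon ids: ",
             paste(head(missing, 10), collapse = ", "))
      sub <- sub[sub$axon_id %in% ids, , drop = FALSE]
      n_act <- if (all(is.na(sub$threshold))) sum(sub$activated) else
        sum(!sub$capped & sub$threshold <= setting$amplitude, na.rm = TRUE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      pathway = pop$label, setting = setting$label, n_total = n_total,
      n_activated = as.integer(n_act),
      percent = if (n_total > 0) 100 * n_act / n_total else NA_real_)
  }
  do.call(rbind, rows)
}

#' Dorsoventral distance from active cathode(s) to the ventral GPi border
#'
#' The z-axis (dorsoventral) difference between the mean centre of the active
#' cathodes and the most ventral point of the GPi. Anodes and the case are
#' excluded.
#'
#' @param scene an [anatomy_scene()].
#' @param setting a [stim_setting()] with at least one cathode.
#' @return distance in mm (positive when the cathode is dorsal to the ventral
#'   border).
#' @export
contact_distance <- function(scene, setting) {
  if (length(setting$cathodes) < 1) stop("setting needs at least one cathode")
  idx <- resolve_contacts(scene$lead, setting$cathodes)
  zc <- mean(scene$lead$contacts$z[idx])
  zv <- ventral_extreme(scene$nuclei$GPi)[3]
  zc - zv
}

#' Regression of percent activation on cathode-to-ventral-GPi distance
#'
#' Ordinary least squares of percent on distance across leads/settings, with
#' the Pearson correlation and the two-sided p-value of the slope.
#'
#' @param distance,percent numeric vectors (one row per lead x setting),
#'   length >= 3.
#' @return list: slope, intercept, r, p_value, n.
#' @export
distance_activation_regression <- function(distance, percent) {
  stopifnot(length(distance) == length(percent), length(distance) >= 3)
  if (var(distance) == 0) stop("zero variance in distance")
  fit <- lm(percent ~ distance)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(sign(coef(fit)[2]) * sqrt(sm$r.squared)),
       p_value = sm$coefficients[2, 4], n = length(distance))
}

#' Paired dorsal-versus-ventral activation comparison
#'
#' For each pathway, a two-sided paired Wilcoxon signed-rank test (exact
#' distribution for small n) between percent activation under the dorsal and
#' ventral settings, paired by lead.
#'
#' @param dorsal,ventral data frames with columns `lead`, `pathway`,
#'   `percent` (one row per lead x pathway).
#' @return data frame: pathway, n, statistic, p_value.
#' @export
compare_dorsal_ventral <- function(dorsal, ventral) {
  pathways <- sort(unique(dorsal$pathway))
  rows <- lapply(pathways, function(pw) {
    d <- dorsal[dorsal$pathway == pw, ]
    v <- ventral[ventral$pathway == pw, ]
    mer <- merge(d[, c("lead", "percent")], v[, c("lead", "percent")],
                 by = "lead", suffixes = c("_dorsal", "_ventral"))
    if (nrow(mer) < nrow(d) || nrow(mer) < nrow(v))
      stop("unpaired lead(s) for pathway ", pw)
    if (all(mer$percent_dorsal == mer$percent_ventral))
      return(data.frame(pathway = pw, n = nrow(mer), statistic = NA_real_,
                        p_value = 1))
    wt <- wilcoxon_signed_rank(mer$percent_dorsal, mer$percent_ventral)
    data.frame(pathway = pw, n = wt$n, statistic = wt$statistic,
               p_value = wt$p_value)
  })
  do.call(rbind, rows)
}
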