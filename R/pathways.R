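# Axon pathway populations.  Eight pathways are modelled: five pallidal /
# striatofugal routes and three internal-capsule bundles.  Waypoints are
# joined with a modified-Akima (makima) interpolant parameterized by
# cumulative chord length and resampled to uniform spacing, mirroring the
# fiber-construction procedure used for single-axon reconstructions.

PATHWAY_LABELS <- c("GPi_efferent", "GPe_GPi_STN", "GPe_STN",
                    "Put_GPe_GPi", "Put_GPe", "IC_M1", "IC_PM", "IC_SMA")

# Default axon counts per pathway (full-scale model).
DEFAULT_PATHWAY_COUNTS <- c(
  GPi_efferent = 1000L, GPe_GPi_STN = 750L, GPe_STN = 1250L,
  Put_GPe_GPi = 980L, Put_GPe = 1020L,
  IC_M1 = 500L, IC_PM = 250L, IC_SMA = 250L)

#' Pathway population configuration
#'
#' Defaults are the full-scale populations: 1000 GPi efferents (half exiting
#' dorsally via the lenticular-fasciculus route, half ventrally via the ansa
#' lenticularis), 750 + 1250 pallidosubthalamic axons (37.5% passing through
#' GPi versus 62.5% direct to STN), 980 + 1020 striatofugal axons, and
#' 500/250/250 internal-capsule axons projecting to M1/PM/SMA.
#'
#' @param counts named integer vector over the eight pathway labels.
#' @param gpi_efferent_dorsal_fraction share of GPi efferents taking the
#'   dorsal exit (default 0.5; assignment alternates by id so the split is
#'   exact for even counts).
#' @param max_turning_angle maximum discrete turning angle, degrees per
#'   `reference_step` of arc.
#' @param reference_step arc step (mm) at which `max_turning_angle` is quoted.
#' @param arc_spacing uniform resampling spacing of trajectories, mm.
#' @param waypoint_jitter_sd s.d. (mm) of waypoint jitter producing curvature
#'   diversity between axons of one pathway.
#' @return an object of class `population_config`.
#' @export
population_config <- function(counts = DEFAULT_PATHWAY_COUNTS,
                              gpi_efferent_dorsal_fraction = 0.5,
                              max_turning_angle = 25, reference_step = 0.5,
                              arc_spacing = 0.1, waypoint_jitter_sd = 0.3) {
  counts_full <- DEFAULT_PATHWAY_COUNTS
  counts_full[names(counts)] <- as.integer(counts)
  stopifnot(all(counts_full >= 0), all(names(counts) %in% PATHWAY_LABELS),
            gpi_efferent_dorsal_fraction >= 0, gpi_efferent_dorsal_fraction <= 1,
            arc_spacing > 0, max_turning_angle > 0)
  structure(list(counts = counts_full,
                 gpi_efferent_dorsal_fraction = gpi_efferent_dorsal_fraction,
                 max_turning_angle = max_turning_angle,
                 reference_step = reference_step,
                 arc_spacing = arc_spacing,
                 waypoint_jitter_sd = waypoint_jitter_sd),
            class = "population_config")
}

#' Route shares implied by a configuration
#'
#' @param config a [population_config()].
#' @return named list: trans-GPi share of pallidosubthalamic projections,
#'   trans-GPi share of striatofugal projections, dorsal-exit share of GPi
#'   efferents.
#' @export
route_shares <- function(config = population_config()) {
  ct <- config$counts
  list(
    pallidosubthalamic_trans_gpi = unname(ct["GPe_GPi_STN"] /
                                            (ct["GPe_GPi_STN"] + ct["GPe_STN"])),
    striatofugal_trans_gpi = unname(ct["Put_GPe_GPi"] /
                                      (ct["Put_GPe_GPi"] + ct["Put_GPe"])),
    gpi_efferent_dorsal = config$gpi_efferent_dorsal_fraction)
}

#' Uniform random points inside a nucleus
#'
#' Rejection sampling in the oriented bounding box; deterministic per seed.
#'
#' @param nucleus a [nucleus_volume()].
#' @param n number of points (>= 0).
#' @param rng_seed integer seed.
#' @return an n x 3 matrix of points (mm), all inside the nucleus.
#' @export
sample_points_in_nucleus <- function(nucleus, n, rng_seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  with_seed(rng_seed, {
    out <- matrix(NA_real_, 0, 3)
    M <- nucleus$orientation
    a <- nucleus$semi_axes
    while (nrow(out) < n) {
      m <- max(2 * (n - nrow(out)), 16)
      q <- cbind(runif(m, -a[1], a[1]), runif(m, -a[2], a[2]), runif(m, -a[3], a[3]))
      keep <- rowSums(sweep(q, 2, a, "/")^2) <= 1
      if (any(keep)) {
        p <- sweep(q[keep, , drop = FALSE] %*% t(M), 2, nucleus$center, "+")
        out <- rbind(out, p)
      }
    }
    out[seq_len(n), , drop = FALSE]
  })
}

## ---- modified-Akima interpolation ------------------------------------------

# Slopes of the modified-Akima (makima) piecewise-cubic Hermite interpolant.
# Weights w1 = |d[i+1]-d[i]| + |d[i+1]+d[i]|/2 (and symmetrically w2) damp the
# overshoot of the classic Akima scheme while still preserving linear data
# exactly.  End slopes use quadratically extrapolated ghost secants.
makima_slopes <- function(t, y) {
  n <- length(t)
  h <- diff(t)
  delta <- diff(y) / h
  d2 <- c(2 * delta[1] - if (n > 2) delta[2] else delta[1], delta)
  d1 <- c(2 * d2[1] - d2[2], d2)
  dn1 <- 2 * d1[length(d1)] - d1[length(d1) - 1]
  dn2 <- 2 * dn1 - d1[length(d1)]
  dd <- c(d1, dn1, dn2)          # secants with two ghosts on each side
  slopes <- numeric(n)
  for (i in seq_len(n)) {
    dm2 <- dd[i]; dm1 <- dd[i + 1]; dp1 <- dd[i + 2]; dp2 <- dd[i + 3]
    w1 <- abs(dp2 - dp1) + abs(dp2 + dp1) / 2
    w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
    slopes[i] <- if (w1 + w2 == 0) 0 else (w1 * dm1 + w2 * dp1) / (w1 + w2)
  }
  slopes
}

# Evaluate the cubic Hermite interpolant defined by knots (t, y) and slopes m
# at query points tq.
hermite_eval <- function(t, y, m, tq) {
  idx <- pmin(pmax(findInterval(tq, t), 1), length(t) - 1)
  h <- t[idx + 1] - t[idx]
  s <- (tq - t[idx]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[idx] + h10 * h * m[idx] + h01 * y[idx + 1] + h11 * h * m[idx + 1]
}

#' Modified-Akima space curve through waypoints
#'
#' Returns the interpolating curve itself (before resampling): a function of
#' the cumulative-chord-length parameter returning points on the curve. The
#' curve passes through waypoint i exactly at parameter `knots[i]`.
#'
#' @param waypoints k x 3 matrix (k >= 2), mm.
#' @return function(s) -> n x 3 matrix, with attribute `knots` (the chord
#'   parameters of the waypoints).
#' @export
makima_curve <- function(waypoints) {
  waypoints <- matrix(waypoints, ncol = 3)
  if (nrow(waypoints) < 2) stop("need at least two waypoints")
  seglen <- sqrt(rowSums((waypoints[-1, , drop = FALSE] -
                            waypoints[-nrow(waypoints), , drop = FALSE])^2))
  if (any(seglen < 1e-9)) stop("duplicate consecutive waypoints")
  t <- c(0, cumsum(seglen))
  ms <- lapply(1:3, function(k) makima_slopes(t, waypoints[, k]))
  f <- function(s) {
    out <- sapply(1:3, function(k)
      hermite_eval(t, waypoints[, k], ms[[k]], s))
    matrix(out, ncol = 3)
  }
  attr(f, "knots") <- t
  f
}

#' Build an axon trajectory polyline through waypoints
#'
#' Each coordinate is interpolated with a modified-Akima piecewise cubic
#' parameterized by cumulative chord length, then the curve is resampled so
#' that consecutive points are exactly `arc_spacing` apart (Euclidean
#' "sphere-marching" along a dense evaluation of the interpolant). The
#' trajectory passes through every waypoint to within 1e-6 mm.
#'
#' @param waypoints k x 3 matrix of waypoints (k >= 2), mm; no two consecutive
#'   waypoints may coincide.
#' @param arc_spacing resampling spacing, mm.
#' @return an n x 3 matrix of uniformly spaced points.
#' @export
build_trajectory <- function(waypoints, arc_spacing = 0.1) {
  waypoints <- matrix(waypoints, ncol = 3)
  if (nrow(waypoints) < 2) stop("need at least two waypoints")
  seglen <- sqrt(rowSums((waypoints[-1, , drop = FALSE] -
                            waypoints[-nrow(waypoints), , drop = FALSE])^2))
  if (any(seglen < 1e-9)) stop("duplicate consecutive waypoints")
  t <- c(0, cumsum(seglen))
  # dense evaluation (>= 50 samples per shortest interval)
  nd <- max(200L, as.integer(ceiling(50 * t[length(t)] / min(seglen))))
  nd <- min(nd, 200000L)
  tq <- seq(0, t[length(t)], length.out = nd)
  dense <- sapply(1:3, function(k) {
    y <- waypoints[, k]
    hermite_eval(t, y, makima_slopes(t, y), tq)
  })
  resample_polyline_chord(dense, arc_spacing)
}

# Walk along a dense polyline placing points at exact Euclidean spacing.
resample_polyline_chord <- function(pts, spacing) {
  .resample_chord_cpp(matrix(pts, ncol = 3), spacing)
}

## ---- population generation -------------------------------------------------

new_axon <- function(id, pathway, route, points, fiber_diameter) {
  structure(list(id = id, pathway = pathway, route = route, points = points,
                 fiber_diameter = fiber_diameter, removed = FALSE),
            class = "axon_trajectory")
}

new_population <- function(label, trajectories, seed) {
  structure(list(label = label, trajectories = trajectories,
                 n_configured = length(trajectories),
                 n_removed = sum(vapply(trajectories, `[[`, FALSE, "removed")),
                 seed = seed),
            class = "pathway_population")
}

#' @export
print.pathway_population <- function(x, ...) {
  cat(sprintf("<pathway_population> %s: %d axons configured, %d removed\n",
              x$label, x$n_configured, x$n_removed))
  invisible(x)
}

# Drop interior waypoints closer than `min_seg` to their predecessor
# (always keeping first and last), so chord-length interpolation cannot kink.
filter_waypoints <- function(wp, min_seg = 0.5) {
  keep <- 1L
  for (i in 2:nrow(wp)) {
    if (sqrt(sum((wp[i, ] - wp[keep[length(keep)], ])^2)) >= min_seg ||
        i == nrow(wp))
      keep <- c(keep, i)
  }
  if (length(keep) >= 2 &&
      sqrt(sum((wp[keep[length(keep)], ] - wp[keep[length(keep) - 1], ])^2)) < 1e-6)
    keep <- keep[-(length(keep) - 1)]
  wp[keep, , drop = FALSE]
}

# Build a trajectory from a waypoint chain and accept it only if the
# per-step turning bound holds; NULL otherwise (the caller redraws the
# chain's random waypoints -- the same rejection against abnormally sharp
# turns that constrains fiber curvature).
curved_trajectory <- function(waypoints, config) {
  bound <- config$max_turning_angle * config$arc_spacing / config$reference_step
  wp <- filter_waypoints(waypoints, min_seg = 0.05)
  if (nrow(wp) < 2) return(NULL)
  traj <- build_trajectory(wp, config$arc_spacing)
  ang <- turning_angles(traj)
  if (length(ang) == 0 || max(ang) <= bound) traj else NULL
}

# Build one axon trajectory from a chain-generating closure, redrawing the
# chain's random waypoints while the turning bound cannot be met.  The final
# fallback smooths the unjittered chain's polyline (local averaging, which
# only reduces curvature and converges to a straight line) until the bound
# holds, keeping the trajectory close to its required interior waypoints.
sample_trajectory <- function(make_chain, config, max_redraws = 20) {
  for (k in seq_len(max_redraws)) {
    traj <- curved_trajectory(make_chain(), config)
    if (!is.null(traj)) return(traj)
  }
  bound <- config$max_turning_angle * config$arc_spacing / config$reference_step
  traj <- build_trajectory(filter_waypoints(make_chain()), config$arc_spacing)
  for (round in 1:30) {
    ang <- turning_angles(traj)
    if (length(ang) == 0 || max(ang) <= bound) break
    for (it in 1:10) {
      n <- nrow(traj)
      traj[2:(n - 1), ] <- (traj[1:(n - 2), ] + 2 * traj[2:(n - 1), ] +
                              traj[3:n, ]) / 4
    }
    traj <- resample_polyline_chord(traj, config$arc_spacing)
  }
  traj
}

# Replace every interior corner of a waypoint chain by points sampled along
# an inscribed circular arc, so the interpolant turns with near-uniform
# curvature at a controlled radius instead of kinking at the corner.  The
# corner point itself is dropped; the arc passes within its sagitta
# (~0.1-0.4 mm for typical radii), preserving nucleus containment when the
# corner was sampled with an interior margin.
round_chain <- function(wp, radius = 2.0, max_step_deg = 6) {
  k <- nrow(wp)
  if (k <= 2) return(wp)
  out <- list(wp[1, ])
  for (i in 2:(k - 1)) {
    a <- out[[length(out)]]
    cc <- wp[i, ]
    b <- wp[i + 1, ]
    v1 <- cc - a; l1 <- sqrt(sum(v1^2)); u1 <- v1 / l1
    v2 <- b - cc; l2 <- sqrt(sum(v2^2)); u2 <- v2 / l2
    cosang <- max(-1, min(1, sum(u1 * u2)))
    theta <- acos(cosang)                      # turn angle at the corner
    if (theta < 8 * pi / 180) { out[[length(out) + 1]] <- cc; next }
    d2max <- if (i == k - 1) 0.8 * l2 else 0.45 * l2
    d <- min(radius * tan(theta / 2), 0.8 * l1, d2max)
    reff <- d / tan(theta / 2)
    p1 <- cc - d * u1
    p2 <- cc + d * u2
    # arc center: along the internal bisector, distance reff/cos(theta/2)
    m <- u2 - u1; m <- m / sqrt(sum(m^2))
    O <- cc + (reff / cos(theta / 2)) * m
    w1 <- p1 - O; w2 <- p2 - O
    narc <- max(2L, as.integer(ceiling(theta / (max_step_deg * pi / 180))))
    for (ss in seq(0, 1, length.out = narc + 1)) {
      pt <- as.numeric(O + (sin((1 - ss) * theta) * w1 + sin(ss * theta) * w2) /
                         sin(theta))
      out[[length(out) + 1]] <- pt
    }
  }
  out[[length(out) + 1]] <- wp[k, ]
  filter_waypoints(do.call(rbind, out), min_seg = 0.05)
}

# Sample nucleus interior points with a fractional margin from the surface,
# guaranteeing that resampled trajectory endpoints stay inside.
sample_interior <- function(nucleus, n, margin = 0.85) {
  shrunk <- nucleus
  shrunk$semi_axes <- nucleus$semi_axes * margin
  sample_points_in_nucleus(shrunk, n)
}

#' Populate all eight axon pathways
#'
#' Pallidal populations originate at uniformly sampled points within their
#' nucleus of origin. GPi efferents alternate between a dorsal
#' (lenticular-fasciculus surrogate) and a ventral-anterior (ansa
#' lenticularis surrogate) exit contour by id (even ids dorsal), so the
#' configured dorsal fraction is realized exactly for even counts.
#' Pallidosubthalamic and striatofugal route memberships are fixed by the two
#' per-route counts. Internal-capsule axons form three parallel curved
#' bundles, ordered premotor / supplementary-motor / primary-motor from
#' anterior to posterior (overlap permitted), descending from a synthetic
#' cortical disc through a capsular corridor posteromedial to the pallidum.
#'
#' @param config a [population_config()].
#' @param scene an [anatomy_scene()] containing all required nuclei.
#' @param seed integer seed; populations are deterministic per
#'   (config, scene, seed).
#' @return named list of `pathway_population` objects, one per label.
#' @export
populate_pathways <- function(config = population_config(),
                              scene = build_default_scene(1), seed = 1) {
  for (need in c("GPi", "GPe", "STN", "Putamen"))
    if (is.null(scene$nuclei[[need]]))
      stop("scene is missing required nucleus: ", need)
  gpi <- scene$nuclei$GPi; gpe <- scene$nuclei$GPe
  stn <- scene$nuclei$STN; put <- scene$nuclei$Putamen

  with_seed(seed, {
    pops <- list()
    id0 <- 0L
    jit <- function(sd = config$waypoint_jitter_sd) rnorm(3, 0, sd)

    ## GPi efferents: origin in GPi, dorsal (lenticular-fasciculus) or
    ## ventral (ansa lenticularis) exit contour, common thalamic target.
    n <- config$counts[["GPi_efferent"]]
    dorsal_exit <- gpi$center + c(0, 1, 1) * gpi$semi_axes + c(0, 0, 1.5)
    ventral_exit <- gpi$center + c(0, 1, -1) * gpi$semi_axes + c(0, 1.5, -1.5)
    over_gpi <- gpi$center + c(-6, 2, gpi$semi_axes[3] + 2)
    under_gpi <- gpi$center + c(-6, 2, -(gpi$semi_axes[3] + 2))
    thal_center <- gpi$center + c(-10, 3, 3)   # medial-dorsal target region
    # deterministic quota assignment: dorsal iff the cumulative dorsal quota
    # increments at id i (for a 0.5 fraction this is "even ids dorsal" and the
    # split is exact for even counts)
    f_dorsal <- config$gpi_efferent_dorsal_fraction
    axons <- vector("list", n)
    for (i in seq_len(n)) {
      dorsal <- floor(i * f_dorsal) > floor((i - 1) * f_dorsal)
      chain <- function() {
        origin <- sample_points_in_nucleus(gpi, 1)[1, ]
        target <- thal_center + runif(3, -1.5, 1.5)
        via <- (if (dorsal) over_gpi else under_gpi) + jit()
        exitp <- (if (dorsal) dorsal_exit else ventral_exit) + jit()
        round_chain(rbind(origin, exitp, via, target))
      }
      axons[[i]] <- new_axon(id0 + i, "GPi_efferent",
                             if (dorsal) "dorsal_exit" else "ventral_exit",
                             sample_trajectory(chain, config), 2.0)
    }
    pops$GPi_efferent <- new_population("GPi_efferent", axons, seed)
    id0 <- id0 + n

    ## Pallidosubthalamic: GPe -> (GPi ->) STN.
    make_pallidosubthalamic <- function(label, n, via_gpi) {
      axons <- vector("list", n)
      for (i in seq_len(n)) {
        chain <- function() {
          start <- sample_points_in_nucleus(gpe, 1)[1, ]
          end <- sample_interior(stn, 1)[1, ]
          if (via_gpi) {
            mid <- sample_interior(gpi, 1)[1, ]
            round_chain(rbind(start, mid, end))
          } else {
            # direct route hugging the ventral GPi border
            mid <- start + 0.45 * (end - start)
            bypass <- c(mid[1], mid[2],
                        gpi$center[3] - gpi$semi_axes[3] - 0.8) + jit()
            round_chain(rbind(start, bypass, end), radius = 2.5)
          }
        }
        axons[[i]] <- new_axon(id0 + i, label,
                               if (via_gpi) "trans_gpi" else "direct",
                               sample_trajectory(chain, config), 2.0)
      }
      new_population(label, axons, seed)
    }
    pops$GPe_GPi_STN <- make_pallidosubthalamic("GPe_GPi_STN",
                                                config$counts[["GPe_GPi_STN"]], TRUE)
    id0 <- id0 + config$counts[["GPe_GPi_STN"]]
    pops$GPe_STN <- make_pallidosubthalamic("GPe_STN",
                                            config$counts[["GPe_STN"]], FALSE)
    id0 <- id0 + config$counts[["GPe_STN"]]

    ## Striatofugal: Putamen -> GPe (-> GPi).
    make_striatofugal <- function(label, n, via_gpi) {
      axons <- vector("list", n)
      for (i in seq_len(n)) {
        chain <- function() {
          start <- sample_points_in_nucleus(put, 1)[1, ]
          if (via_gpi) {
            mid <- sample_interior(gpe, 1)[1, ]
            end <- sample_interior(gpi, 1)[1, ]
            round_chain(rbind(start, mid, end))
          } else {
            end <- sample_interior(gpe, 1)[1, ]
            rbind(start, start + 0.5 * (end - start) + jit(), end)
          }
        }
        axons[[i]] <- new_axon(id0 + i, label,
                               if (via_gpi) "trans_gpi" else "direct",
                               sample_trajectory(chain, config), 2.0)
      }
      new_population(label, axons, seed)
    }
    pops$Put_GPe_GPi <- make_striatofugal("Put_GPe_GPi",
                                          config$counts[["Put_GPe_GPi"]], TRUE)
    id0 <- id0 + config$counts[["Put_GPe_GPi"]]
    pops$Put_GPe <- make_striatofugal("Put_GPe", config$counts[["Put_GPe"]], FALSE)
    id0 <- id0 + config$counts[["Put_GPe"]]

    ## Internal capsule: three bundles anterior -> posterior (PM, SMA, M1),
    ## descending posteromedial to the pallidum toward the cerebral peduncle.
    ic_ref <- gpi$center
    bundle_y <- c(IC_PM = -5, IC_SMA = -7.5, IC_M1 = -10)
    for (label in c("IC_PM", "IC_SMA", "IC_M1")) {
      n <- config$counts[[label]]
      axons <- vector("list", n)
      for (i in seq_len(n)) {
        chain <- function() {
          yc <- ic_ref[2] + bundle_y[[label]] + rnorm(1, 0, 1.2)
          xc <- ic_ref[1] - 2 + rnorm(1, 0, 1.0)
          round_chain(rbind(
            c(xc + rnorm(1, 0, 2), yc + rnorm(1, 0, 2), ic_ref[3] + 30),
            c(xc, yc, ic_ref[3] + 8),
            c(xc - 1, yc - 1, ic_ref[3] - 8),
            c(xc - 2, yc - 2, ic_ref[3] - 18)), radius = 4)
        }
        axons[[i]] <- new_axon(id0 + i, label, "none",
                               sample_trajectory(chain, config), 5.7)
      }
      pops[[label]] <- new_population(label, axons, seed)
      id0 <- id0 + n
    }
    pops[PATHWAY_LABELS]
  })
}

#' Flag axons colliding with the lead encapsulation layer
#'
#' An axon is marked removed iff any of its polyline points lies within
#' (shaft radius + `thickness`) of the lead's axis segment (finite cylinder
#' with a hemispherical tip cap). Removed axons stay in the population as an
#' audit trail; only their `removed` flag and the population's `n_removed`
#' change.
#'
#' @param pop a `pathway_population`.
#' @param lead a [lead_model()].
#' @param thickness encapsulation thickness, mm (>= 0).
#' @return the population with updated removal flags.
#' @export
remove_encapsulation_collisions <- function(pop, lead, thickness = 0.25) {
  stopifnot(thickness >= 0)
  a <- lead$tip_position
  b <- lead$tip_position + lead$length * lead$axis
  lim <- lead$shaft_diameter / 2 + thickness
  pop$trajectories <- lapply(pop$trajectories, function(ax) {
    ax$removed <- any(point_segment_distance(ax$points, a, b) <= lim)
    ax
  })
  pop$n_removed <- sum(vapply(pop$trajectories, `[[`, FALSE, "removed"))
  pop
}

#' Apply encapsulation removal to every population in a scene
#'
#' @param populations named list from [populate_pathways()].
#' @param scene the [anatomy_scene()] providing lead and encapsulation.
#' @return the list with removal flags set.
#' @export
remove_collisions_all <- function(populations, scene) {
  lapply(populations, remove_encapsulation_collisions,
         lead = scene$lead, thickness = scene$encapsulation_thickness)
}

#' Serialize populations to JSON lines
#'
#' One axon per line: pathway, route, id, fiber diameter, removed flag and
#' the polyline points.
#'
#' @param populations named list of `pathway_population`.
#' @param path output file.
#' @export
write_populations_jsonl <- function(populations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pop in populations) for (ax in pop$trajectories) {
    pts <- apply(ax$points, 1, function(p)
      sprintf("[%.4f,%.4f,%.4f]", p[1], p[2], p[3]))
    writeLines(sprintf(
      '{"id":%d,"pathway":"%s","route":"%s","diameter":%.1f,"removed":%s,"points":[%s]}',
      ax$id, ax$pathway, ax$route, ax$fiber_diameter,
      if (ax$removed) "true" else "false", paste(pts, collapse = ",")), con)
  }
  invisible(path)
}
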