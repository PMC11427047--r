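# Synthetic anatomy: ellipsoidal basal-ganglia nuclei, a DBS lead with its
# contact geometry, and a tissue conductivity model.  The scene stands in for
# segmented imaging: only the geometric relations that matter downstream
# (adjacency, dorsoventral extent, lead containment) are reproduced.

NUCLEUS_NAMES <- c("GPe", "GPi", "STN", "Putamen", "SN")

#' Ellipsoidal nucleus volume
#'
#' An idealized basal-ganglia nucleus: an ellipsoid with an arbitrary
#' orientation. Coordinates are mm, +x lateral, +y anterior, +z dorsal.
#'
#' @param name one of `"GPe"`, `"GPi"`, `"STN"`, `"Putamen"`, `"SN"`.
#' @param center ellipsoid centre, length-3 numeric (mm).
#' @param semi_axes three positive semi-axis lengths (mm).
#' @param orientation 3x3 rotation matrix (columns = body axes in world frame).
#' @return an object of class `nucleus_volume`.
#' @export
nucleus_volume <- function(name, center, semi_axes, orientation = diag(3)) {
  name <- match.arg(name, NUCLEUS_NAMES)
  center <- vec3(center)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-8 ||
      abs(det(orientation) - 1) > 1e-8)
    stop("orientation must be a proper rotation matrix")
  structure(list(name = name, center = center, semi_axes = semi_axes,
                 orientation = orientation),
            class = "nucleus_volume")
}

# Implicit value: <= 1 inside, 1 on the surface.
ellipsoid_value <- function(nucleus, p) {
  p <- matrix(p, ncol = 3)
  rel <- sweep(p, 2, nucleus$center)
  q <- rel %*% nucleus$orientation          # body-frame coordinates
  rowSums(sweep(q, 2, nucleus$semi_axes, "/")^2)
}

#' Point-in-nucleus test
#'
#' Boundary points count as inside (closed volume), so downstream removal and
#' containment rules are unambiguous.
#'
#' @param nucleus a [nucleus_volume()].
#' @param p a point (length 3) or an n x 3 matrix of points, mm.
#' @return logical vector.
#' @export
inside_nucleus <- function(nucleus, p) {
  ellipsoid_value(nucleus, p) <= 1 + 1e-9
}

#' Most ventral surface point of a nucleus
#'
#' Closed form: for the ellipsoid x = c + R diag(a) u with |u| = 1, the
#' dorsoventral (z) coordinate is minimized at u = -v/|v| where v is the third
#' row of R diag(a).
#'
#' @param nucleus a [nucleus_volume()].
#' @return the surface point (length 3) with minimal z.
#' @export
ventral_extreme <- function(nucleus) {
  M <- nucleus$orientation %*% diag(nucleus$semi_axes)
  v <- M[3, ]
  u <- -v / vnorm(v)
  as.numeric(nucleus$center + M %*% u)
}

#' @export
print.nucleus_volume <- function(x, ...) {
  cat(sprintf("<nucleus_volume> %s  centre (%.1f, %.1f, %.1f) mm  semi-axes (%.1f, %.1f, %.1f) mm\n",
              x$name, x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

## ---- DBS lead geometry -----------------------------------------------------

# Manufacturer contact dimensions (mm).  The three supported leads:
#   medtronic_3389: 4 rings, 1.5 mm contacts, 0.5 mm gaps
#   medtronic_3387: 4 rings, 1.5 mm contacts, 1.5 mm gaps
#   abbott_6172:    1-3-3-1 directional (levels 2 and 3 split into three
#                   120-degree arc segments a/b/c), 1.5 mm contacts, 0.5 mm gaps
LEAD_SPECS <- list(
  medtronic_3389 = list(diameter = 1.27, contact_length = 1.5, spacing = 0.5,
                        tip_offset = 1.5, levels = c(1, 1, 1, 1),
                        level_labels = c("0", "1", "2", "3"), length = 40),
  medtronic_3387 = list(diameter = 1.27, contact_length = 1.5, spacing = 1.5,
                        tip_offset = 1.5, levels = c(1, 1, 1, 1),
                        level_labels = c("0", "1", "2", "3"), length = 40),
  abbott_6172    = list(diameter = 1.29, contact_length = 1.5, spacing = 0.5,
                        tip_offset = 1.0, levels = c(1, 3, 3, 1),
                        level_labels = c("1", "2", "3", "4"), length = 40)
)

#' DBS lead model
#'
#' @param model `"medtronic_3389"`, `"medtronic_3387"` or `"abbott_6172"`.
#' @param tip_position position of the distal lead tip, mm.
#' @param axis lead axis direction (tip to shaft); normalized internally.
#' @param roll_angle rotation (degrees) of segment "a" about the axis, measured
#'   from the first basis vector perpendicular to the axis.
#' @return an object of class `dbs_lead` with a `contacts` data frame.
#' @export
lead_model <- function(model = c("medtronic_3389", "medtronic_3387", "abbott_6172"),
                       tip_position = c(0, 0, 0), axis = c(0, 0, 1),
                       roll_angle = 0) {
  if (!is.character(model) || !model[1] %in% names(LEAD_SPECS))
    stop("unknown lead model")
  model <- model[1]
  lead <- structure(list(model = model,
                         shaft_diameter = LEAD_SPECS[[model]]$diameter,
                         length = LEAD_SPECS[[model]]$length,
                         tip_position = vec3(tip_position),
                         axis = unitize(vec3(axis)),
                         roll_angle = as.numeric(roll_angle)),
                    class = "dbs_lead")
  lead$contacts <- contact_geometry(lead)
  lead
}

#' Contact centres, spans and areas for a lead
#'
#' Contacts are ordered ventral to dorsal along the axis (0-based `index`).
#' Segmented levels yield three 120-degree arc segments whose centres are
#' offset radially by the shaft radius in the arc direction.
#'
#' @param lead a [lead_model()].
#' @return data frame: index, level, segment, label, x, y, z, axial_span,
#'   surface_area.
#' @export
contact_geometry <- function(lead) {
  if (!inherits(lead, "dbs_lead")) stop("unknown lead model")
  spec <- LEAD_SPECS[[lead$model]]
  basis <- orthonormal_basis(lead$axis)
  ring_area <- pi * spec$diameter * spec$contact_length
  rows <- list()
  idx <- 0L
  for (lv in seq_along(spec$levels)) {
    d_axial <- spec$tip_offset + (lv - 1) * (spec$contact_length + spec$spacing) +
      spec$contact_length / 2
    axial_center <- lead$tip_position + d_axial * lead$axis
    nseg <- spec$levels[lv]
    if (nseg == 1) {
      rows[[length(rows) + 1]] <- data.frame(
        index = idx, level = lv, segment = NA_character_,
        label = spec$level_labels[lv],
        x = axial_center[1], y = axial_center[2], z = axial_center[3],
        axial_span = spec$contact_length, surface_area = ring_area,
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    } else {
      for (s in seq_len(nseg)) {
        ang <- (lead$roll_angle + (s - 1) * 360 / nseg) * pi / 180
        radial <- cos(ang) * basis$u + sin(ang) * basis$v
        ctr <- axial_center + (spec$diameter / 2) * radial
        rows[[length(rows) + 1]] <- data.frame(
          index = idx, level = lv, segment = letters[s],
          label = paste0(spec$level_labels[lv], letters[s]),
          x = ctr[1], y = ctr[2], z = ctr[3],
          axial_span = spec$contact_length, surface_area = ring_area / nseg,
          stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.dbs_lead <- function(x, ...) {
  cat(sprintf("<dbs_lead> %s  tip (%.1f, %.1f, %.1f) mm, %d contacts\n",
              x$model, x$tip_position[1], x$tip_position[2], x$tip_position[3],
              nrow(x$contacts)))
  invisible(x)
}

## ---- tissue conductivity ---------------------------------------------------

#' Tissue conductivity model
#'
#' Isotropic conductivities follow the standard assignment: 0.11 S/m grey
#' matter, 0.065 S/m white matter, 0.3 S/m other tissue. In `tensor_field`
#' mode a user-supplied function returns a symmetric positive-definite 3x3
#' tensor (S/m) at a point; with an isotropic tensor this reproduces the
#' isotropic solution.
#'
#' @param mode `"isotropic"` or `"tensor_field"`.
#' @param sigma_gray,sigma_white,sigma_other conductivities, S/m.
#' @param tensor_at function `point -> 3x3 SPD matrix` (required in
#'   `tensor_field` mode).
#' @return an object of class `tissue_model`.
#' @export
tissue_model <- function(mode = c("isotropic", "tensor_field"),
                         sigma_gray = 0.11, sigma_white = 0.065,
                         sigma_other = 0.3, tensor_at = NULL) {
  mode <- match.arg(mode)
  if (mode == "tensor_field") {
    if (!is.function(tensor_at)) stop("tensor_field mode needs a tensor_at function")
    Tm <- tensor_at(c(0, 0, 0))
    ev <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("tensor_at must return positive-definite tensors")
  }
  structure(list(mode = mode, sigma_gray = sigma_gray,
                 sigma_white = sigma_white, sigma_other = sigma_other,
                 tensor_at = tensor_at),
            class = "tissue_model")
}

# Scalar conductivity at a point: grey inside any nucleus, otherwise "other".
tissue_sigma_at <- function(scene, p) {
  for (nu in scene$nuclei) if (inside_nucleus(nu, p)) return(scene$tissue$sigma_gray)
  scene$tissue$sigma_other
}

## ---- scene -----------------------------------------------------------------

#' Assemble an anatomy scene
#'
#' @param nuclei named list of [nucleus_volume()] objects.
#' @param lead a [lead_model()].
#' @param tissue a [tissue_model()].
#' @param encapsulation_thickness thickness (mm) of the glial sheath around the
#'   lead; axon trajectories intersecting it are removed downstream.
#' @param seed integer seed recorded with the scene.
#' @return an object of class `anatomy_scene`.
#' @export
anatomy_scene <- function(nuclei, lead, tissue = tissue_model(),
                          encapsulation_thickness = 0.25, seed = NA_integer_) {
  stopifnot(encapsulation_thickness >= 0)
  if (!all(vapply(nuclei, inherits, TRUE, "nucleus_volume")))
    stop("nuclei must be nucleus_volume objects")
  names(nuclei) <- vapply(nuclei, `[[`, "", "name")
  structure(list(nuclei = nuclei, lead = lead, tissue = tissue,
                 encapsulation_thickness = encapsulation_thickness,
                 seed = seed),
            class = "anatomy_scene")
}

#' Default synthetic pallidal scene
#'
#' Five ellipsoidal nuclei at human pallidal scale with a DBS lead placed in
#' the posterolateral GPi, passing dorsally with at least two contacts inside
#' the nucleus. The seed jitters nucleus centres (within 0.3 mm) and the lead
#' tip (within 0.2 mm); identical seeds give identical scenes.
#'
#' @param seed integer seed.
#' @param lead_model_name which lead to implant.
#' @return an [anatomy_scene()].
#' @export
build_default_scene <- function(seed = 1, lead_model_name = "medtronic_3389") {
  with_seed(seed, {
    j <- function(s) runif(3, -s, s)
    nuclei <- list(
      nucleus_volume("GPi",     c(0, 0, 0) + j(0.3),    c(4.0, 6.0, 4.0)),
      nucleus_volume("GPe",     c(7.4, 0, 1) + j(0.3),  c(3.2, 7.0, 5.5)),
      nucleus_volume("Putamen", c(15.5, 0, 0) + j(0.3), c(4.0, 9.0, 6.0)),
      nucleus_volume("STN",     c(-4, -6, -7) + j(0.3), c(2.5, 3.5, 2.5)),
      nucleus_volume("SN",      c(-4.5, -7, -10.5) + j(0.3), c(2.5, 4.0, 2.5))
    )
    tip <- c(2.0, -2.8, -4.8) + runif(3, -0.2, 0.2)
    axis <- unitize(c(0.08, 0.15, 1))
    lead <- lead_model(lead_model_name, tip_position = tip, axis = axis)
    anatomy_scene(nuclei, lead, tissue_model(), seed = seed)
  })
}

#' @export
print.anatomy_scene <- function(x, ...) {
  cat("<anatomy_scene>\n")
  for (nu in x$nuclei) print(nu)
  print(x$lead)
  cat(sprintf("  tissue: %s (gray %.3f, white %.3f, other %.3f S/m); encapsulation %.2f mm\n",
              x$tissue$mode, x$tissue$sigma_gray, x$tissue$sigma_white,
              x$tissue$sigma_other, x$encapsulation_thickness))
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

# Decompose a rotation matrix into extrinsic x-y-z Euler angles (degrees).
rotation_to_euler <- function(R) {
  sy <- sqrt(R[1, 1]^2 + R[2, 1]^2)
  if (sy > 1e-9) {
    x <- atan2(R[3, 2], R[3, 3]); y <- atan2(-R[3, 1], sy); z <- atan2(R[2, 1], R[1, 1])
  } else {
    x <- atan2(-R[2, 3], R[2, 2]); y <- atan2(-R[3, 1], sy); z <- 0
  }
  c(x, y, z) * 180 / pi
}

#' Write / read a scene as YAML
#'
#' Nuclei are stored as centre / semi-axes / Euler angles (degrees); the lead
#' as model, tip, axis and roll.
#'
#' @param scene an [anatomy_scene()].
#' @param path file path.
#' @return `read_scene_yaml` returns an [anatomy_scene()].
#' @export
write_scene_yaml <- function(scene, path) {
  obj <- list(
    seed = scene$seed,
    encapsulation_thickness = scene$encapsulation_thickness,
    tissue = list(mode = scene$tissue$mode, sigma_gray = scene$tissue$sigma_gray,
                  sigma_white = scene$tissue$sigma_white,
                  sigma_other = scene$tissue$sigma_other),
    lead = list(model = scene$lead$model,
                tip = as.numeric(scene$lead$tip_position),
                axis = as.numeric(scene$lead$axis),
                roll = scene$lead$roll_angle),
    nuclei = lapply(scene$nuclei, function(nu)
      list(name = nu$name, center = as.numeric(nu$center),
           semi_axes = as.numeric(nu$semi_axes),
           euler_deg = as.numeric(rotation_to_euler(nu$orientation))))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  nuclei <- lapply(obj$nuclei, function(nu)
    nucleus_volume(nu$name, unlist(nu$center), unlist(nu$semi_axes),
                   rotation_xyz(nu$euler_deg[[1]], nu$euler_deg[[2]], nu$euler_deg[[3]])))
  lead <- lead_model(obj$lead$model, unlist(obj$lead$tip), unlist(obj$lead$axis),
                     obj$lead$roll)
  tis <- tissue_model("isotropic", obj$tissue$sigma_gray, obj$tissue$sigma_white,
                      obj$tissue$sigma_other)
  anatomy_scene(nuclei, lead, tis, obj$encapsulation_thickness,
                if (is.null(obj$seed)) NA_integer_ else obj$seed)
}
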