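# Small 3-D geometry helpers shared across modules.  Coordinates are
# millimetres in an RAS-like frame: +x lateral (toward the implanted
# hemisphere), +y anterior, +z dorsal.

vec3 <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  stopifnot(length(v) == 3, all(is.finite(v)))
  v
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix from extrinsic x-y-z Euler angles
#'
#' Angles are in degrees, applied as Rz(z) %*% Ry(y) %*% Rx(x).
#'
#' @param x,y,z rotation angles about the +x, +y, +z axes, degrees.
#' @return a 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
rotation_xyz <- function(x = 0, y = 0, z = 0) {
  r <- pi / 180
  cx <- cos(x * r); sx <- sin(x * r)
  cy <- cos(y * r); sy <- sin(y * r)
  cz <- cos(z * r); sz <- sin(z * r)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Two unit vectors completing `axis` to a right-handed orthonormal frame.
orthonormal_basis <- function(axis) {
  a <- unitize(axis)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(ref - sum(ref * a) * a)
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  list(u = u, v = v)
}

# Distance from each row of `pts` (n x 3) to the segment [a, b].
point_segment_distance <- function(pts, a, b) {
  pts <- matrix(pts, ncol = 3)
  ab <- b - a
  L2 <- sum(ab^2)
  rel <- sweep(pts, 2, a)
  t <- if (L2 < 1e-15) rep(0, nrow(pts)) else
    pmin(1, pmax(0, as.numeric(rel %*% ab) / L2))
  proj <- outer(t, ab)
  sqrt(rowSums((rel - proj)^2))
}

# Cumulative arc length of a polyline (n x 3 matrix).
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Interpolate positions at arc-length values `s` along a polyline.
polyline_point_at <- function(pts, s) {
  cs <- polyline_arclength(pts)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  out <- matrix(NA_real_, length(s), 3)
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1), nrow(pts) - 1)
  seg <- cs[idx + 1] - cs[idx]
  w <- ifelse(seg > 0, (s - cs[idx]) / seg, 0)
  for (k in 1:3) out[, k] <- pts[idx, k] + w * (pts[idx + 1, k] - pts[idx, k])
  out
}

# Interior turning angles (degrees) of a polyline.
turning_angles <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(numeric(0))
  a <- pts[2:(n - 1), , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  b <- pts[3:n, , drop = FALSE] - pts[2:(n - 1), , drop = FALSE]
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  cosang <- rowSums(a * b) / pmax(na * nb, 1e-300)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
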