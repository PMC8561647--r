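#' Construct a coil object
#'
#' A coil is a cloud of magnetic dipoles (position + moment per unit
#' current), the standard CCD-style representation. In the local frame the
#' winding plane is z = 0, `normal_axis` (+z, the coil centerline) points
#' away from the head, and `handle_axis` points along the dominant induced
#' electric field under the coil center.
#'
#' @param dipole_positions n x 3 matrix, METERS, local frame.
#' @param dipole_moments n x 3 matrix, A m^2 per unit current.
#' @param handle_axis,normal_axis local unit vectors (orthogonal).
#' @param bounding_idx indices of dipoles used for scalp-clearance tests
#'   (defaults to all).
#' @param casing_depth distance (mm) from the winding plane down to the
#'   bottom of the plastic casing; the placement standoff is measured from
#'   the casing bottom, while the scalp-clearance constraint applies to
#'   the windings (the metal conductor) only.
#' @param units `"m"` (local frame) or `"mm"` (head frame after
#'   [transform_coil()]).
#' @return object of class `coil`.
#' @export
coil <- function(dipole_positions, dipole_moments,
                 handle_axis = c(0, 1, 0), normal_axis = c(0, 0, 1),
                 bounding_idx = NULL, units = "m", casing_depth = 0) {
  dipole_positions <- as.matrix(dipole_positions)
  dipole_moments <- as.matrix(dipole_moments)
  stopifnot(nrow(dipole_positions) >= 1,
            all(dim(dipole_positions) == dim(dipole_moments)),
            all(is.finite(dipole_moments)))
  if (abs(sum(handle_axis * normal_axis)) > 1e-8)
    stop("handle_axis must be perpendicular to normal_axis")
  if (is.null(bounding_idx)) bounding_idx <- seq_len(nrow(dipole_positions))
  structure(list(dipole_positions = dipole_positions,
                 dipole_moments = dipole_moments,
                 handle_axis = handle_axis / sqrt(sum(handle_axis^2)),
                 normal_axis = normal_axis / sqrt(sum(normal_axis^2)),
                 bounding_idx = bounding_idx,
                 units = units, casing_depth = casing_depth),
            class = "coil")
}

#' @export
print.coil <- function(x, ...) {
  cat(sprintf("coil: %d dipoles (%s frame), |total moment| %.4g A m^2\n",
              nrow(x$dipole_positions), x$units,
              sqrt(sum(colSums(x$dipole_moments)^2))))
  invisible(x)
}

#' Parametric figure-8 coil (two counter-wound spiral wings)
#'
#' Each wing is a flat spiral winding from `inner_radius` to `outer_radius`
#' with `turns` turns; it is discretized as a polar grid of magnetic
#' dipoles whose moment density equals the number of turns enclosing the
#' grid cell (the enclosed-area increment representation). The wings lie
#' side by side along local x and carry opposite moments, so the dominant
#' induced field under the center — the handle direction — is local +y,
#' perpendicular to the line of wing centers.
#'
#' @param outer_radius,inner_radius wing radii in mm.
#' @param turns turns per wing.
#' @param elements_per_turn angular discretization (>= 8).
#' @param wing_gap gap between the two wings in mm.
#' @param radial_cells radial discretization of each wing.
#' @param casing_depth winding-plane-to-casing-bottom distance, mm.
#' @return a `coil` in the local frame (meters).
#' @export
make_figure8_coil <- function(outer_radius = 45, inner_radius = 15,
                              turns = 10L, elements_per_turn = 24L,
                              wing_gap = 2, radial_cells = 12L,
                              casing_depth = 6) {
  if (inner_radius >= outer_radius) stop("inner_radius must be < outer_radius")
  if (elements_per_turn < 8L) stop("elements_per_turn must be >= 8")
  Ro <- outer_radius / 1000; Ri <- inner_radius / 1000
  cx <- (outer_radius + wing_gap / 2) / 1000
  re <- seq(0, Ro, length.out = radial_cells + 1L)
  rc <- (re[-1] + re[-length(re)]) / 2
  dr <- diff(re)
  th <- seq(0, 2 * pi, length.out = elements_per_turn + 1L)[-(elements_per_turn + 1L)] +
    pi / elements_per_turn
  turns_enclosing <- function(r) turns * pmin(1, pmax(0, (Ro - r) / (Ro - Ri)))
  pos <- NULL; mom <- NULL
  for (sgn in c(1, -1)) {
    for (j in seq_along(rc)) {
      cell_area <- rc[j] * dr[j] * (2 * pi / elements_per_turn)
      mz <- sgn * turns_enclosing(rc[j]) * cell_area
      p <- cbind(sgn * cx + rc[j] * cos(th), rc[j] * sin(th), 0)
      pos <- rbind(pos, p)
      mom <- rbind(mom, cbind(0, 0, rep(mz, length(th))))
    }
  }
  keep <- abs(mom[, 3]) > 0
  pos <- pos[keep, , drop = FALSE]; mom <- mom[keep, , drop = FALSE]
  r_local <- sqrt((abs(pos[, 1]) - cx)^2 + pos[, 2]^2)
  bnd <- which(r_local > 0.85 * Ro)
  coil(pos, mom, handle_axis = c(0, 1, 0), normal_axis = c(0, 0, 1),
       bounding_idx = bnd, casing_depth = casing_depth)
}

#' Single circular loop coil (validation geometry)
#'
#' Dipole-sheet representation of a flat circular loop; total moment is
#' `turns * pi * radius^2` per unit current.
#' @param radius loop radius in mm.
#' @param turns number of turns.
#' @param elements_per_turn,radial_cells discretization.
#' @return a `coil`.
#' @export
make_loop_coil <- function(radius = 25, turns = 1L, elements_per_turn = 24L,
                           radial_cells = 12L) {
  R <- radius / 1000
  re <- seq(0, R, length.out = radial_cells + 1L)
  rc <- (re[-1] + re[-length(re)]) / 2
  dr <- diff(re)
  th <- seq(0, 2 * pi, length.out = elements_per_turn + 1L)[-(elements_per_turn + 1L)]
  pos <- NULL; mom <- NULL
  for (j in seq_along(rc)) {
    cell_area <- rc[j] * dr[j] * (2 * pi / elements_per_turn)
    p <- cbind(rc[j] * cos(th), rc[j] * sin(th), 0)
    pos <- rbind(pos, p)
    mom <- rbind(mom, cbind(0, 0, rep(turns * cell_area, length(th))))
  }
  coil(pos, mom)
}

#' Shipped coil presets
#'
#' `"large"` and `"small"` figure-8 coils whose handle-direction dimensions
#' differ by a factor of approximately two, standing in for a large
#' elliptical and a small focal commercial coil.
#' @param preset `"large"` or `"small"`.
#' @param elements_per_turn angular discretization.
#' @return a `coil`.
#' @export
coil_preset <- function(preset = c("large", "small"), elements_per_turn = 24L) {
  preset <- match.arg(preset)
  if (preset == "large")
    make_figure8_coil(outer_radius = 45, inner_radius = 15, turns = 10L,
                      elements_per_turn = elements_per_turn)
  else
    make_figure8_coil(outer_radius = 22, inner_radius = 8, turns = 10L,
                      elements_per_turn = elements_per_turn)
}

#' Read / write CCD coil files
#'
#' Dialect: one comment line, a count line, then rows `x y z mx my mz`
#' (meters, A m^2 per unit current).
#' @param path file path.
#' @return a `coil` (local frame; handle/normal axes take their
#'   conventional local values, which the CCD format does not store).
#' @export
load_ccd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("CCD parse error: second line must be the dipole count")
  rows <- lines[-(1:2)]
  if (length(rows) != n)
    stop(sprintf("CCD parse error: count line says %d dipoles but %d rows follow",
                 n, length(rows)))
  tab <- matrix(scan(text = rows, quiet = TRUE), ncol = 6, byrow = TRUE)
  coil(tab[, 1:3, drop = FALSE], tab[, 4:6, drop = FALSE])
}

#' @rdname load_ccd
#' @param coil a `coil` in the local frame.
#' @export
save_ccd <- function(coil, path) {
  if (coil$units != "m") stop("save_ccd expects a local-frame coil (meters)")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# tmsfocal CCD dipole cloud: x y z mx my mz (m, A m^2)", con)
  writeLines(sprintf("%d", nrow(coil$dipole_positions)), con)
  writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                     coil$dipole_positions[, 1], coil$dipole_positions[, 2],
                     coil$dipole_positions[, 3], coil$dipole_moments[, 1],
                     coil$dipole_moments[, 2], coil$dipole_moments[, 3]), con)
  invisible(path)
}

#' Six-parameter coil pose
#'
#' Maps the local coil frame rigidly into the head frame:
#' `p_head = R_y(roll) R_x(pitch) R_z(yaw) p_local + center`, i.e. yaw
#' about the coil normal is applied first in the local frame, then pitch
#' about local x, then roll about local y. Angles are radians, unwrapped.
#'
#' @param center 3-vector, mm, head frame.
#' @param pitch,roll,yaw rotation angles (rad).
#' @return object of class `coil_pose`.
#' @export
coil_pose <- function(center = c(0, 0, 0), pitch = 0, roll = 0, yaw = 0) {
  structure(list(center = as.numeric(center), pitch = pitch, roll = roll,
                 yaw = yaw), class = "coil_pose")
}

#' @export
print.coil_pose <- function(x, ...) {
  cat(sprintf("coil_pose: center (%.1f, %.1f, %.1f) mm  pitch %.3f  roll %.3f  yaw %.3f rad\n",
              x$center[1], x$center[2], x$center[3], x$pitch, x$roll, x$yaw))
  invisible(x)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

pose_rotation <- function(pose) rot_y(pose$roll) %*% rot_x(pose$pitch) %*% rot_z(pose$yaw)

#' Apply a pose to a coil
#'
#' Rigid transform of dipole positions and moments into the head frame.
#' Positions come out in millimetres (the head-frame unit); moments are
#' rotated only.
#' @param coil a local-frame `coil` (meters).
#' @param pose a `coil_pose`.
#' @return a head-frame `coil` (mm).
#' @export
transform_coil <- function(coil, pose) {
  if (coil$units != "m") stop("transform_coil expects a local-frame coil")
  R <- pose_rotation(pose)
  pos <- coil$dipole_positions %*% t(R) * 1000
  pos <- sweep(pos, 2, pose$center, "+")
  out <- coil
  out$dipole_positions <- pos
  out$dipole_moments <- coil$dipole_moments %*% t(R)
  out$handle_axis <- as.numeric(R %*% coil$handle_axis)
  out$normal_axis <- as.numeric(R %*% coil$normal_axis)
  out$units <- "mm"
  out
}

#' Primary (incident) electric field of a coil
#'
#' The free-space field `E_p(r) = -(mu0/4pi) dIdt sum_k m_k x (r - p_k) /
#' |r - p_k|^3`, exactly linear in `dIdt` and in the dipole moments.
#'
#' @param coil a head-frame `coil` (from [transform_coil()]) or a
#'   local-frame coil evaluated in its own frame.
#' @param points n x 3 matrix, mm (same frame as the coil).
#' @param dIdt coil current slew rate, A/s. The default `9.4e7` is a
#'   typical pulse strength at motor-threshold intensities.
#' @return n x 3 matrix of E vectors, V/m.
#' @export
primary_field <- function(coil, points, dIdt = 9.4e7) {
  points <- matrix(as.numeric(points), ncol = 3)
  pos_m <- if (coil$units == "mm") coil$dipole_positions / 1000 else coil$dipole_positions
  pts_m <- points / 1000
  dmin <- cpp_nearest_point(pts_m, pos_m)$dist
  if (any(dmin < 1e-9)) stop("field point coincides with a coil dipole")
  cpp_dipole_field(pos_m, coil$dipole_moments, pts_m, dIdt)
}

#' Minimum coil-scalp clearance
#'
#' Smallest point-to-triangle distance from any coil bounding point to the
#' skin mesh, in mm; negative (penetration depth) when the nearest bounding
#' point lies inside the skin. The pose search rejects poses with clearance
#' below the 10 mm safety constraint.
#'
#' @param coil a head-frame `coil` (mm).
#' @param skin the skin `surface_mesh`.
#' @return signed distance in mm.
#' @export
coil_scalp_clearance <- function(coil, skin) {
  if (coil$units != "mm") stop("coil_scalp_clearance expects a head-frame coil")
  pts <- coil$dipole_positions[coil$bounding_idx, , drop = FALSE]
  fc <- facet_corners(skin)
  d <- cpp_point_tri_dist(pts, fc$v1, fc$v2, fc$v3)
  inside <- rowSums((pts - d$closest) * skin$normals[d$tri, , drop = FALSE]) < 0
  sd <- d$dist * ifelse(inside, -1, 1)
  min(sd)
}
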