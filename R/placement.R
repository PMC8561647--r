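#' Nearest-facet outward normal at a point
#' @param mesh a `surface_mesh`.
#' @param point 3-vector, mm.
#' @return list with `normal`, `facet`, `closest`, `dist`.
#' @export
surface_normal_at <- function(mesh, point) {
  fc <- facet_corners(mesh)
  d <- cpp_point_tri_dist(matrix(point, 1, 3), fc$v1, fc$v2, fc$v3)
  list(normal = mesh$normals[d$tri[1], ], facet = d$tri[1],
       closest = d$closest[1, ], dist = d$dist[1])
}

# first hit of ray origin + t*dir (t > 0) against a triangle soup;
# returns NULL when the ray misses
ray_mesh_intersect <- function(mesh, origin, dir) {
  fc <- facet_corners(mesh)
  e1 <- fc$v2 - fc$v1
  e2 <- fc$v3 - fc$v1
  dmat <- matrix(dir, nrow(e1), 3, byrow = TRUE)
  pvec <- cbind(dmat[, 2] * e2[, 3] - dmat[, 3] * e2[, 2],
                dmat[, 3] * e2[, 1] - dmat[, 1] * e2[, 3],
                dmat[, 1] * e2[, 2] - dmat[, 2] * e2[, 1])
  det <- rowSums(e1 * pvec)
  tvec <- sweep(-fc$v1, 2, origin, "+")
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
                tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
                tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  v <- rowSums(dmat * qvec) / det
  t <- rowSums(e2 * qvec) / det
  hit <- which(abs(det) > 1e-12 & u >= -1e-9 & v >= -1e-9 &
                 (u + v) <= 1 + 1e-9 & t > 1e-9)
  if (length(hit) == 0) return(NULL)
  h <- hit[which.min(t[hit])]
  list(facet = h, t = t[h], point = origin + t[h] * dir,
       normal = mesh$normals[h, ])
}

# distance (mm) from the coil-frame origin to the coil bottom (lowest
# winding point plus the casing depth) along the centerline
coil_bottom_offset <- function(coil) {
  -min(coil$dipole_positions %*% coil$normal_axis) * 1000 + coil$casing_depth
}

# pose whose centerline direction is u (outward) and whose handle maps to
# h_des (projected to the coil plane), center at `center`
pose_from_axes <- function(center, u, h_des = NULL, handle_local = c(0, 1, 0)) {
  u <- u / sqrt(sum(u^2))
  pitch <- asin(max(-1, min(1, -u[2])))
  roll <- atan2(u[1], u[3])
  yaw <- 0
  if (!is.null(h_des)) {
    h <- h_des - sum(h_des * u) * u
    hn <- sqrt(sum(h^2))
    if (hn > 1e-8) {
      h <- h / hn
      M <- rot_y(roll) %*% rot_x(pitch)
      v <- as.numeric(t(M) %*% h)
      # R_z(yaw) handle_local = (cos*hx - sin*hy, sin*hx + cos*hy); solve for
      # the standard local handle +y
      yaw <- atan2(-v[1] * handle_local[2] + v[2] * handle_local[1],
                   v[1] * handle_local[1] + v[2] * handle_local[2])
    }
  }
  coil_pose(center, pitch = pitch, roll = roll, yaw = yaw)
}

#' Sulcus-aligned initial coil placement
#'
#' The three-step projection construction used as the optimization's
#' initial guess: (1) the coil centerline passes through the target;
#' (2) the centerline is perpendicular to the skin at the skin-centerline
#' intersection, with the coil bottom at `standoff` (10 +/- 0.25 mm) from
#' the skin along the centerline; (3) the coil handle (dominant induced
#' field direction) is rotated about the centerline to be perpendicular to
#' the nearest sulcal wall.
#'
#' The skin intersection is sought along the outward gray-matter normal at
#' the target; if that ray misses, the nearest skin point is used (with a
#' message). On rotationally symmetric heads with no wall information the
#' yaw is degenerate; it is left at zero and flagged via the
#' `degenerate_yaw` attribute rather than silently resolved.
#'
#' @param head a `head_model` with skin and GM shells.
#' @param target 3-vector on/near the GM surface, mm.
#' @param coil local-frame `coil`.
#' @param wall_normal unit 3-vector of the nearest sulcal wall, or
#'   `"auto"` to use the gyrus phantom's analytic wall normal (flagged
#'   degenerate when unavailable).
#' @param standoff coil-bottom-to-skin distance, mm.
#' @param standoff_tol placement tolerance, mm (recorded, used by tests).
#' @return a `coil_pose` with attributes `skin_point`, `centerline` and
#'   `degenerate_yaw`.
#' @export
sulcus_aligned_pose <- function(head, target, coil, wall_normal = "auto",
                                standoff = 10, standoff_tol = 0.25) {
  skin <- head_shell(head, names(head$shells)[1])
  gm <- head_shell(head, "GM")
  gn <- surface_normal_at(gm, target)
  hit <- ray_mesh_intersect(skin, target, gn$normal)
  if (is.null(hit)) {
    message("sulcus_aligned_pose: outward-normal ray misses the skin; using nearest skin point")
    sn <- surface_normal_at(skin, target)
    hit <- list(point = sn$closest, normal = sn$normal)
  }
  u <- hit$normal
  degenerate <- FALSE
  if (identical(wall_normal, "auto")) {
    if (!is.null(attr(head, "gyrus"))) {
      wall_normal <- gyrus_wall_normal(head, target)
    } else {
      message("sulcus_aligned_pose: no sulcal wall available; yaw is degenerate")
      wall_normal <- NULL
      degenerate <- TRUE
    }
  }
  center <- hit$point + (standoff + coil_bottom_offset(coil)) * u
  pose <- pose_from_axes(center, u, h_des = wall_normal,
                         handle_local = coil$handle_axis)
  attr(pose, "skin_point") <- hit$point
  attr(pose, "centerline") <- u
  attr(pose, "degenerate_yaw") <- degenerate
  attr(pose, "standoff") <- standoff
  attr(pose, "standoff_tol") <- standoff_tol
  pose
}
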