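#' Assemble and factorize the surface-charge forward operator
#'
#' Direct collocation BEM for the quasistatic problem, formulated in the
#' induced surface charge density on the conductivity interfaces. With
#' `g = rho / eps0` (so eps0 never enters the system), facet `m` with
#' conductivities `sig_in` / `sig_out` satisfies
#'
#' `g_m (sig_in + sig_out) / (2 (sig_in - sig_out))
#'    - n_m . sum_{k != m} g_k K_k(c_m) = n_m . E_p(c_m)`
#'
#' where `K_k` is the field of facet `k` per unit charge: the centroid
#' point kernel `A_k (r - c_k) / (4 pi |r - c_k|^3)` for well-separated
#' pairs, and the exact closed-form field of a uniformly charged flat
#' triangle (solid-angle plus edge-log terms) for pairs closer than
#' `near_mult * sqrt(A_k)`. The testing functional is averaged over six
#' barycentric subcentroids of each facet (`test_avg = TRUE`), which
#' substantially improves accuracy for thin, closely spaced shells at no
#' memory cost. The operator is assembled and LU-factorized once per head;
#' every coil pose then costs a single right-hand-side solve.
#'
#' Interfaces with no conductivity contrast carry no charge and are
#' excluded (with a message).
#'
#' @param head a `head_model` with closed, outward-oriented shells.
#' @param near_mult near-field cutoff in units of `sqrt(facet area)`
#'   (4.5 is about three edge lengths).
#' @param test_avg average the collocation test over six subcentroids per
#'   facet instead of using the centroid only.
#' @return object of class `forward_system` containing the facet data
#'   (meters), the dense operator and its LU factorization, and solve
#'   counters.
#' @export
assemble_system <- function(head, near_mult = 4.5, test_avg = TRUE) {
  cen <- NULL; nrm <- NULL; area <- NULL
  v1 <- NULL; v2 <- NULL; v3 <- NULL
  dg <- NULL; shell_of <- integer(0)
  for (i in seq_along(head$shells)) {
    s <- head$shells[[i]]
    if (abs(s$sigma_in - s$sigma_out) < 1e-12) {
      message(sprintf("assemble_system: shell '%s' has no conductivity contrast; excluded",
                      s$name))
      next
    }
    m <- s$mesh
    fc <- facet_corners(m)
    cen <- rbind(cen, m$centroids / 1000)
    nrm <- rbind(nrm, m$normals)
    area <- c(area, m$areas / 1e6)
    v1 <- rbind(v1, fc$v1 / 1000); v2 <- rbind(v2, fc$v2 / 1000)
    v3 <- rbind(v3, fc$v3 / 1000)
    dg <- c(dg, rep((s$sigma_in + s$sigma_out) /
                      (2 * (s$sigma_in - s$sigma_out)), nrow(m$triangles)))
    shell_of <- c(shell_of, rep(i, nrow(m$triangles)))
  }
  counters <- new.env(parent = emptyenv())
  counters$factorizations <- 0L
  counters$solves <- 0L
  cache <- new.env(parent = emptyenv())
  sys <- list(head = head, cen = cen, nrm = nrm, area = area,
              v1 = v1, v2 = v2, v3 = v3, diag = dg, shell_of = shell_of,
              near_mult = near_mult, counters = counters, cache = cache)
  if (is.null(cen) || nrow(cen) == 0L) {
    sys$empty <- TRUE
    class(sys) <- "forward_system"
    return(sys)
  }
  if (test_avg) {
    tpl <- facet_test_points(v1, v2, v3)
    tp <- tpl$points
    tidx <- tpl$tidx
  } else {
    tp <- cen
    tidx <- seq_len(nrow(cen)) - 1L
  }
  A <- cpp_assemble(v1, v2, v3, cen, nrm, area, dg, near_mult, tp, tidx)
  lu <- tryCatch(Matrix::lu(A), error = function(e)
    stop(sprintf("forward operator is singular (n = %d, rcond ~ %.2e): %s",
                 nrow(A), rcond(A), conditionMessage(e))))
  counters$factorizations <- 1L
  sys$A <- A
  sys$lu <- lu
  sys$empty <- FALSE
  class(sys) <- "forward_system"
  sys
}

# six barycentric subcentroids per facet (flat, in the facet plane)
facet_test_points <- function(v1, v2, v3) {
  m12 <- (v1 + v2) / 2; m23 <- (v2 + v3) / 2; m31 <- (v3 + v1) / 2
  cc <- (v1 + v2 + v3) / 3
  pts <- rbind((v1 + m12 + cc) / 3, (m12 + v2 + cc) / 3,
               (v2 + m23 + cc) / 3, (m23 + v3 + cc) / 3,
               (v3 + m31 + cc) / 3, (m31 + v1 + cc) / 3)
  list(points = pts, tidx = rep(seq_len(nrow(v1)) - 1L, 6L))
}

#' @export
print.forward_system <- function(x, ...) {
  cat(sprintf("forward_system: %d facets, %d factorization(s), %d solve(s)\n",
              if (x$empty) 0L else nrow(x$cen),
              x$counters$factorizations, x$counters$solves))
  invisible(x)
}

#' Solve for the induced surface charges of one coil pose
#'
#' Right-hand-side solve against the factorized operator; the solution is
#' exactly linear in `dIdt`.
#'
#' @param system a `forward_system`.
#' @param coil local-frame `coil`.
#' @param pose `coil_pose`.
#' @param dIdt pulse strength, A/s.
#' @return object of class `charge_solution` with `scaled_charge`
#'   (`g = rho/eps0` per facet), the relative residual, and references to
#'   the head and pose.
#' @export
solve_charges <- function(system, coil, pose, dIdt = 9.4e7) {
  ch <- transform_coil(coil, pose)
  if (system$empty) {
    g <- numeric(0); res <- 0
  } else {
    Ep <- cpp_dipole_field(ch$dipole_positions / 1000, ch$dipole_moments,
                           system$cen, dIdt)
    rhs <- rowSums(system$nrm * Ep)
    g <- as.numeric(Matrix::solve(system$lu, rhs))
    system$counters$solves <- system$counters$solves + 1L
    rn <- sqrt(sum(rhs^2))
    res <- if (rn > 0) sqrt(sum((as.numeric(system$A %*% g) - rhs)^2)) / rn else 0
    if (res > 1e-8)
      stop(sprintf("charge solve residual %.2e exceeds 1e-8", res))
  }
  structure(list(scaled_charge = g, residual = res, pose_ref = pose,
                 dIdt = dIdt), class = "charge_solution")
}

#' Total electric field at interior observation points
#'
#' `E(r) = E_p(r) + sum_k g_k K_k(r)` with the same far/near charge kernel
#' as the assembly; observation points within the near cutoff of a facet
#' automatically receive the exact triangle integral.
#'
#' @param system a `forward_system`.
#' @param charges the matching `charge_solution`.
#' @param coil local-frame `coil`.
#' @param pose `coil_pose` (must match the one used for the charges).
#' @param points n x 3 matrix of observation points, mm, strictly inside
#'   the conductor.
#' @return object of class `field_map`: `points`, `E` (V/m), `magnitude`,
#'   `pose_ref`.
#' @export
total_field <- function(system, charges, coil, pose, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  ch <- transform_coil(coil, pose)
  E <- primary_field(ch, points, charges$dIdt)
  if (!system$empty && length(charges$scaled_charge))
    E <- E + cpp_charge_field(system$v1, system$v2, system$v3, system$cen,
                              system$nrm, system$area, charges$scaled_charge,
                              points / 1000, system$near_mult)
  field_map(points, E, pose)
}

field_map <- function(points, E, pose = NULL) {
  structure(list(points = points, E = E, magnitude = sqrt(rowSums(E^2)),
                 pose_ref = pose), class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field_map: %d points, |E| in [%.3g, %.3g] V/m\n",
              nrow(x$points), min(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Export a field map as CSV (point_id,x,y,z,Ex,Ey,Ez,mag)
#' @param field a `field_map`.
#' @param path output path.
#' @export
write_field_csv <- function(field, path) {
  df <- data.frame(point_id = seq_len(nrow(field$points)),
                   x = field$points[, 1], y = field$points[, 2],
                   z = field$points[, 3], Ex = field$E[, 1],
                   Ey = field$E[, 2], Ez = field$E[, 3],
                   mag = field$magnitude)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Closed-form field inside a spherically symmetric conductor
#'
#' Total electric field induced at interior points by an external magnetic
#' dipole, for ANY spherically symmetric conductivity profile: the induced
#' field is purely tangential and independent of the radial profile, which
#' makes this the reference oracle for the multi-shell sphere phantom. The
#' expression is the reciprocal form of the classical
#' magnetically-silent-sphere result.
#'
#' @param dipole_position 3-vector, mm, outside the sphere.
#' @param dipole_moment 3-vector, A m^2 per unit current.
#' @param dIdt pulse strength, A/s.
#' @param sphere_center 3-vector, mm.
#' @param points n x 3 matrix of interior points, mm.
#' @param sphere_radius optional radius (mm) used to validate that points
#'   are interior; when missing, points are only required to be closer to
#'   the center than the dipole.
#' @return a `field_map`.
#' @export
sphere_analytic_field <- function(dipole_position, dipole_moment, dIdt,
                                  sphere_center, points,
                                  sphere_radius = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  a <- (dipole_position - sphere_center) / 1000
  rr <- sweep(points, 2, sphere_center) / 1000
  an <- sqrt(sum(a^2))
  rn <- sqrt(rowSums(rr^2))
  if (!is.null(sphere_radius)) {
    if (an * 1000 <= sphere_radius) stop("dipole must lie outside the sphere")
    if (any(rn * 1000 > sphere_radius + 1e-9)) stop("points must lie inside the sphere")
  } else if (any(rn >= an)) stop("points must lie inside the dipole radius")
  m <- as.numeric(dipole_moment)
  d <- sweep(-rr, 2, a, "+")               # a - r
  dn <- sqrt(rowSums(d^2))
  FF <- dn * (dn * an + an^2 - rowSums(rr * matrix(a, nrow(rr), 3, byrow = TRUE)))
  ra <- rowSums(rr * matrix(a, nrow(rr), 3, byrow = TRUE))
  cf1 <- dn^2 / an + rowSums(d * matrix(a, nrow(rr), 3, byrow = TRUE)) / dn + 2 * dn + 2 * an
  cf2 <- dn + 2 * an + rowSums(d * matrix(a, nrow(rr), 3, byrow = TRUE)) / dn
  gradF <- outer(cf1, a) - cf2 * rr
  rxm <- cbind(rr[, 2] * m[3] - rr[, 3] * m[2],
               rr[, 3] * m[1] - rr[, 1] * m[3],
               rr[, 1] * m[2] - rr[, 2] * m[1])
  rxa <- cbind(rr[, 2] * a[3] - rr[, 3] * a[2],
               rr[, 3] * a[1] - rr[, 1] * a[3],
               rr[, 1] * a[2] - rr[, 2] * a[1])
  mdF <- gradF %*% m
  E <- -dIdt * 1e-7 / FF^2 * (FF * rxm - as.numeric(mdF) * rxa)
  field_map(points, E)
}

#' Sphere-oracle field of a whole coil
#'
#' Sums [sphere_analytic_field()] over every dipole of a head-frame coil.
#' @param coil head-frame `coil` (mm).
#' @param sphere_center 3-vector, mm.
#' @param points interior points, mm.
#' @param dIdt pulse strength, A/s.
#' @param sphere_radius optional radius for interior validation.
#' @return a `field_map`.
#' @export
sphere_analytic_field_coil <- function(coil, sphere_center, points,
                                       dIdt = 9.4e7, sphere_radius = NULL) {
  if (coil$units != "mm") stop("expecting a head-frame coil")
  points <- matrix(as.numeric(points), ncol = 3)
  E <- matrix(0, nrow(points), 3)
  for (k in seq_len(nrow(coil$dipole_positions))) {
    E <- E + sphere_analytic_field(coil$dipole_positions[k, ],
                                   coil$dipole_moments[k, ], dIdt,
                                   sphere_center, points, sphere_radius)$E
  }
  field_map(points, E)
}
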