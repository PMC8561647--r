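#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` is a closed, consistently oriented triangulated tissue
#' boundary with outward normals. Coordinates are millimetres throughout the
#' package; only the forward solver converts to SI internally.
#'
#' Zero-area facets are dropped with a warning (the only mesh repair this
#' package performs). Open meshes are tolerated — phantoms such as flat
#' plates are legitimate test geometry — but are flagged via `is_closed()`,
#' and production head shells are expected to be closed.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `normals` (per-facet outward unit vectors), `centroids`
#'   (mm) and `areas` (mm^2).
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  m <- list(vertices = vertices, triangles = triangles)
  m <- recompute_facets(m)
  zero <- m$areas < 1e-12
  if (any(zero)) {
    warning(sprintf("dropping %d zero-area facet(s)", sum(zero)))
    m$triangles <- m$triangles[!zero, , drop = FALSE]
    m <- recompute_facets(m)
  }
  if (nrow(m$triangles) == 0L) stop("mesh has no facets with nonzero area")
  class(m) <- "surface_mesh"
  m
}

recompute_facets <- function(m) {
  v1 <- m$vertices[m$triangles[, 1], , drop = FALSE]
  v2 <- m$vertices[m$triangles[, 2], , drop = FALSE]
  v3 <- m$vertices[m$triangles[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(cr^2))
  m$normals <- cr / ifelse(a2 > 0, a2, 1)
  m$areas <- a2 / 2
  m$centroids <- (v1 + v2 + v3) / 3
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d facets, area %.1f mm^2, %s\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas),
              if (is_closed(x)) "closed" else "open"))
  invisible(x)
}

facet_corners <- function(m) {
  list(v1 = m$vertices[m$triangles[, 1], , drop = FALSE],
       v2 = m$vertices[m$triangles[, 2], , drop = FALSE],
       v3 = m$vertices[m$triangles[, 3], , drop = FALSE])
}

#' Signed volume enclosed by a mesh
#'
#' Positive for a closed shell whose normals point outward.
#' @param mesh a `surface_mesh`.
#' @return volume in mm^3 (divergence-theorem sum; meaningless for open
#'   meshes).
#' @export
mesh_volume <- function(mesh) {
  fc <- facet_corners(mesh)
  sum(fc$v1[, 1] * (fc$v2[, 2] * fc$v3[, 3] - fc$v2[, 3] * fc$v3[, 2]) -
      fc$v1[, 2] * (fc$v2[, 1] * fc$v3[, 3] - fc$v2[, 3] * fc$v3[, 1]) +
      fc$v1[, 3] * (fc$v2[, 1] * fc$v3[, 2] - fc$v2[, 2] * fc$v3[, 1])) / 6
}

#' Is a mesh closed (watertight)?
#'
#' Every undirected edge must be shared by exactly two facets.
#' @param mesh a `surface_mesh`.
#' @return logical scalar.
#' @export
is_closed <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

mean_edge_length <- function(mesh) {
  fc <- facet_corners(mesh)
  mean(c(sqrt(rowSums((fc$v2 - fc$v1)^2)),
         sqrt(rowSums((fc$v3 - fc$v2)^2)),
         sqrt(rowSums((fc$v1 - fc$v3)^2))))
}

#' Barycentric subdivision of a triangulated surface
#'
#' Each facet is split into 6 subtriangles about its centroid and edge
#' midpoints; `levels = 2` yields the 1:36 refinement used when measuring
#' inter-shell distances. Subdivision is flat: subfacet centroids stay in the
#' plane of the parent and total area is conserved.
#'
#' @param mesh a `surface_mesh`.
#' @param levels number of 1:6 passes (>= 1).
#' @return a `surface_mesh` with `6^levels` times the facet count.
#' @export
barycentric_subdivide <- function(mesh, levels = 1L) {
  stopifnot(levels >= 1L)
  v <- mesh$vertices
  tr <- mesh$triangles
  for (l in seq_len(levels)) {
    nv <- nrow(v)
    nt <- nrow(tr)
    # shared edge midpoints
    ea <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    lo <- pmin(ea[, 1], ea[, 2])
    hi <- pmax(ea[, 1], ea[, 2])
    key <- paste0(lo, "_", hi)
    uk <- !duplicated(key)
    mid_of <- match(key, key[uk])
    mids <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
    cents <- (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
              v[tr[, 3], , drop = FALSE]) / 3
    m12 <- nv + mid_of[seq_len(nt)]
    m23 <- nv + mid_of[nt + seq_len(nt)]
    m31 <- nv + mid_of[2L * nt + seq_len(nt)]
    cc <- nv + sum(uk) + seq_len(nt)
    v <- rbind(v, mids, cents)
    tr <- rbind(cbind(tr[, 1], m12, cc), cbind(m12, tr[, 2], cc),
                cbind(tr[, 2], m23, cc), cbind(m23, tr[, 3], cc),
                cbind(tr[, 3], m31, cc), cbind(m31, tr[, 1], cc))
  }
  surface_mesh(v, tr)
}

#' Mean shortest inter-shell distance
#'
#' Mean over all facet centroids of `a` of the distance to the nearest facet
#' centroid of `b`, after `b` has been barycentrically refined (two 1:6
#' passes by default, i.e. the 1:36 ratio). One-directional by construction;
#' set `symmetric = TRUE` to average both directions.
#'
#' @param a,b `surface_mesh` objects.
#' @param refine_levels barycentric refinement passes applied to the target
#'   shell before the centroid-to-centroid search.
#' @param symmetric average `a -> b` and `b -> a`?
#' @return distance in mm.
#' @export
shell_distance <- function(a, b, refine_levels = 2L, symmetric = FALSE) {
  if (nrow(a$triangles) == 0L || nrow(b$triangles) == 0L)
    stop("shell_distance: empty mesh")
  one_way <- function(src, dst) {
    dstr <- if (refine_levels > 0L) barycentric_subdivide(dst, refine_levels) else dst
    mean(cpp_nearest_point(src$centroids, dstr$centroids)$dist)
  }
  if (symmetric) (one_way(a, b) + one_way(b, a)) / 2 else one_way(a, b)
}

#' Build an intracortical observation surface between gray and white matter
#'
#' For every gray-matter facet centroid `c`, the shortest vector `v` to the
#' barycentrically refined white-matter centroid cloud is found; the
#' observation node is `c + f v`, with `f = 0.5` for the 1:1 mid-surface
#' (approximately cortical layer 2/3) and `f = 0.8` for the 4:1 surface
#' shifted toward the white-matter boundary (approximately the bottom of
#' layer 5). Points whose gray-to-white distance exceeds
#' `max_thickness` are excluded as segmentation artifacts.
#'
#' When the pose search probes the cost with millimetre steps, the
#' suprathreshold node set must be able to change membership at that
#' resolution; `focus_center`/`focus_radius`/`focus_levels` barycentrically
#' subdivide the gray-matter facets around the region of interest before
#' the nodes are built, refining the observation sampling there without
#' touching the forward discretization.
#'
#' @param gm,wm gray- and white-matter `surface_mesh` shells of one head.
#' @param ratio `"1:1"` or `"4:1"` separation from the gray-matter side.
#' @param refine_levels refinement passes for the white-matter target cloud.
#' @param max_thickness cortical-thickness cap in mm.
#' @param focus_center optional 3-vector (mm): GM facets within
#'   `focus_radius` of it are subdivided `focus_levels` times before node
#'   construction.
#' @param focus_radius radius of the refined region, mm (45 mm covers
#'   the hot-spot ring of the poses the search visits around one target).
#' @param focus_levels subdivision passes inside the refined region.
#' @return An object of class `observation_surface`: `points` (n x 3 mm),
#'   `source_facet` (index into the gm facets), `ratio`, `gm_wm_vector`
#'   (n x 3 mm) and `excluded` (indices of gm facets dropped by the cap).
#' @export
build_observation_surface <- function(gm, wm, ratio = c("1:1", "4:1"),
                                      refine_levels = 2L, max_thickness = 6,
                                      focus_center = NULL, focus_radius = 35,
                                      focus_levels = 2L) {
  ratio <- match.arg(ratio)
  if (nrow(wm$triangles) == 0L) stop("white-matter mesh is empty")
  f <- if (ratio == "1:1") 0.5 else 0.8
  if (!is.null(focus_center) && focus_levels > 0L) {
    d <- sqrt(rowSums((gm$centroids - matrix(focus_center, nrow(gm$centroids),
                                             3, byrow = TRUE))^2))
    near <- d <= focus_radius
    if (any(near)) {
      fine <- barycentric_subdivide(
        surface_mesh(gm$vertices, gm$triangles[near, , drop = FALSE]),
        focus_levels)
      nvc <- nrow(gm$vertices)
      gm <- surface_mesh(rbind(gm$vertices, fine$vertices),
                         rbind(gm$triangles[!near, , drop = FALSE],
                               fine$triangles + nvc))
    }
  }
  wmr <- if (refine_levels > 0L) barycentric_subdivide(wm, refine_levels) else wm
  nn <- cpp_nearest_point(gm$centroids, wmr$centroids)
  v <- wmr$centroids[nn$idx, , drop = FALSE] - gm$centroids
  keep <- nn$dist <= max_thickness
  if (!all(keep))
    message(sprintf("observation surface: excluding %d point(s) beyond the %g mm thickness cap",
                    sum(!keep), max_thickness))
  pts <- gm$centroids[keep, , drop = FALSE] + f * v[keep, , drop = FALSE]
  obs <- list(points = pts,
              source_facet = which(keep),
              ratio = ratio,
              fraction = f,
              gm_wm_vector = v[keep, , drop = FALSE],
              excluded = which(!keep),
              id = sprintf("%d_%.6f", nrow(pts), sum(pts)))
  class(obs) <- "observation_surface"
  obs
}

#' @export
print.observation_surface <- function(x, ...) {
  cat(sprintf("observation_surface (%s, f = %.1f): %d nodes\n",
              x$ratio, x$fraction, nrow(x$points)))
  invisible(x)
}

#' Export an observation surface as CSV
#'
#' Columns: `point_id,x,y,z,source_facet,ratio`.
#' @param obs an `observation_surface`.
#' @param path output file path.
#' @export
write_observation_csv <- function(obs, path) {
  df <- data.frame(point_id = seq_len(nrow(obs$points)),
                   x = obs$points[, 1], y = obs$points[, 2],
                   z = obs$points[, 3],
                   source_facet = obs$source_facet,
                   ratio = obs$ratio)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a multi-shell head model
#'
#' Shells are ordered outermost to innermost. Conductivities must nest:
#' each shell's outside conductivity equals the inside conductivity of the
#' shell enclosing it, and the outermost shell sees air (0 S/m) outside.
#'
#' @param shells named list of `surface_mesh` objects, outermost first,
#'   names drawn from skin, skull, CSF, GM, WM, ventricles.
#' @param conductivities numeric vector, one inside-conductivity (S/m) per
#'   shell, same order.
#' @return An object of class `head_model` with per-shell `sigma_in` /
#'   `sigma_out`.
#' @export
head_model <- function(shells, conductivities) {
  stopifnot(length(shells) >= 1, length(conductivities) == length(shells))
  nm <- names(shells)
  if (is.null(nm) || any(!nzchar(nm))) stop("shells must be named")
  sigma_out <- c(0, conductivities[-length(conductivities)])
  hm <- list(shells = lapply(seq_along(shells), function(i) {
    list(name = nm[i], mesh = shells[[i]],
         sigma_in = conductivities[i], sigma_out = sigma_out[i])
  }))
  names(hm$shells) <- nm
  class(hm) <- "head_model"
  hm
}

#' @export
print.head_model <- function(x, ...) {
  cat("head_model:\n")
  for (s in x$shells)
    cat(sprintf("  %-10s %6d facets  sigma_in %.3f  sigma_out %.3f S/m\n",
                s$name, nrow(s$mesh$triangles), s$sigma_in, s$sigma_out))
  invisible(x)
}

#' Extract a shell mesh from a head model
#' @param head a `head_model`.
#' @param name shell name (e.g. `"GM"`).
#' @return the shell's `surface_mesh`.
#' @export
head_shell <- function(head, name) {
  s <- head$shells[[name]]
  if (is.null(s)) stop(sprintf("head model has no '%s' shell", name))
  s$mesh
}
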