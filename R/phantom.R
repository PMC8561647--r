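#' Default tissue conductivities (S/m)
#'
#' SimNIBS-style literature defaults for the standard compartments. These
#' are configuration defaults, not subject-specific ground truth.
#' @return named numeric vector.
#' @export
default_conductivities <- function() {
  c(skin = 0.465, skull = 0.010, CSF = 1.654, GM = 0.276, WM = 0.126,
    ventricles = 1.654, surface = 1.0)
}

#' Phantom specification
#'
#' Defines a synthetic head: nested spheres emulating the skin, skull, CSF,
#' gray-matter and white-matter shells of an adult head (GM-WM gap about
#' 2.5 mm), optionally with a gyral crown flanked by two sulcal trenches.
#' The seed drives subject-like variability: a global size factor, a jitter
#' of the GM-WM gap, and a random crown orientation.
#'
#' @param kind `"sphere"` or `"gyrus"`.
#' @param shell_radii named radii in mm, outermost first, strictly
#'   decreasing.
#' @param conductivities inside conductivities (S/m), same order.
#' @param mesh_density target edge length in mm for the CSF, GM and WM
#'   shells; the skin shell is kept one subdivision level finer (its
#'   induced charge dominates the operator accuracy) and the skull one
#'   level coarser.
#' @param sulcus_depth,sulcus_width trench depth / width in mm (gyrus only).
#' @param ridge_length length of the gyral crown in mm (gyrus only).
#' @param seed integer seed for the subject-variability draws.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("sphere", "gyrus"),
                         shell_radii = c(skin = 92, skull = 86, CSF = 82,
                                         GM = 80, WM = 77.5),
                         conductivities = default_conductivities()[names(shell_radii)],
                         mesh_density = 10,
                         sulcus_depth = 10, sulcus_width = 12,
                         ridge_length = 70, seed = 1L) {
  kind <- match.arg(kind)
  if (any(diff(shell_radii) >= 0)) stop("shell radii must be strictly decreasing")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  structure(list(kind = kind, shell_radii = shell_radii,
                 conductivities = conductivities,
                 mesh_density = mesh_density,
                 sulcus_depth = sulcus_depth, sulcus_width = sulcus_width,
                 ridge_length = ridge_length, seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Unit icosphere mesh
#'
#' Icosahedron refined by `level` midpoint-subdivision passes, vertices
#' projected to the given radius. Deterministic.
#' @param radius sphere radius (mm).
#' @param level subdivision level (0 = icosahedron, each level quadruples
#'   the facet count).
#' @param center 3-vector center (mm).
#' @return a `surface_mesh` with outward normals.
#' @export
icosphere <- function(radius = 1, level = 3L, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    nv <- nrow(v)
    nt <- nrow(f)
    ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    lo <- pmin(ea[, 1], ea[, 2]); hi <- pmax(ea[, 1], ea[, 2])
    key <- paste0(lo, "_", hi)
    uk <- !duplicated(key)
    mid_of <- nv + match(key, key[uk])
    v <- rbind(v, (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2)
    m12 <- mid_of[seq_len(nt)]
    m23 <- mid_of[nt + seq_len(nt)]
    m31 <- mid_of[2L * nt + seq_len(nt)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(m12, f[, 2], m23),
               cbind(m31, m23, f[, 3]), cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

# subdivision level that brings the icosphere edge length near the target
density_level <- function(radius, density) {
  max(1L, min(6L, as.integer(round(log2(1.05 * radius / density)))))
}

#' Generate a nested-sphere head phantom
#'
#' Five closed icosphere shells (skin, skull, CSF, GM, WM by default) at the
#' spec radii. The seed perturbs the overall size by ~2% and the GM-WM gap
#' by ~10% to emulate inter-subject variability; the same seed always yields
#' bit-identical meshes.
#'
#' @param spec a [phantom_spec()] with `kind = "sphere"` (a gyrus spec is
#'   accepted by the gyrus generator, which calls this internally).
#' @return a `head_model`.
#' @export
make_sphere_head <- function(spec = phantom_spec()) {
  radii <- spec$shell_radii
  with_seed(spec$seed, {
    scale <- 1 + stats::runif(1, -0.02, 0.02)
    gap_jit <- 1 + stats::runif(1, -0.1, 0.1)
  })
  radii <- radii * scale
  if (all(c("GM", "WM") %in% names(radii))) {
    gap <- radii[["GM"]] - radii[["WM"]]
    radii[["WM"]] <- radii[["GM"]] - gap * gap_jit
  }
  if (any(diff(radii) >= 0)) stop("shell radii must remain strictly decreasing")
  # per-shell subdivision: the skin boundary carries the largest induced
  # charge density (insulating interface) and drives the accuracy of the
  # charge operator, so it is kept one level finer; the smooth resistive
  # skull tolerates one level coarser
  shells <- lapply(seq_along(radii), function(i) {
    lev <- density_level(radii[i], spec$mesh_density)
    if (names(radii)[i] == "skin") lev <- min(6L, lev + 1L)
    if (names(radii)[i] == "skull") lev <- max(1L, lev - 1L)
    icosphere(radii[i], lev)
  })
  names(shells) <- names(radii)
  head <- head_model(shells, unname(spec$conductivities))
  attr(head, "phantom") <- list(kind = "sphere", radii = radii, spec = spec)
  head
}

#' Generate a gyrus head phantom
#'
#' Starts from the nested-sphere head and carves two Gaussian-profile sulcal
#' trenches into the GM and WM shells, leaving a gyral crown (ridge) between
#' them. The crown direction is seeded at random around the head's top. The
#' smooth analytic trench profile makes the sulcal wall normals available in
#' closed form (see [gyrus_wall_normal()]), which anchors the sulcus-aligned
#' placement tests.
#'
#' @param spec a [phantom_spec()]; `sulcus_depth = 0` reproduces the sphere
#'   head exactly.
#' @return a `head_model` with attributes `crown` (ridge-apex polyline,
#'   n x 3 mm) and `gyrus` (frame and trench parameters).
#' @export
make_gyrus_head <- function(spec = phantom_spec(kind = "gyrus")) {
  head <- make_sphere_head(spec)
  radii <- attr(head, "phantom")$radii
  # seeded crown frame: e3 near +z, e1 = crown direction, e2 across
  with_seed(spec$seed + 1000L, {
    az <- stats::runif(1, 0, 2 * pi)
    tilt <- stats::runif(1, 0, 0.25)
    rot <- stats::runif(1, 0, 2 * pi)
  })
  e3 <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
  ref <- if (abs(e3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a <- ref - sum(ref * e3) * e3; a <- a / sqrt(sum(a^2))
  b <- c(e3[2] * a[3] - e3[3] * a[2], e3[3] * a[1] - e3[1] * a[3],
         e3[1] * a[2] - e3[2] * a[1])
  e1 <- cos(rot) * a + sin(rot) * b
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  gy <- list(e1 = e1, e2 = e2, e3 = e3,
             depth = spec$sulcus_depth,
             width = spec$sulcus_width,
             sigma = spec$sulcus_width / 3,
             offset = spec$sulcus_width,       # trench centers at t = +/- offset
             ridge_length = spec$ridge_length,
             taper = 8)
  if (spec$sulcus_depth > 0) {
    for (nm in c("GM", "WM")) {
      if (is.null(head$shells[[nm]])) next
      m <- head$shells[[nm]]$mesh
      v <- m$vertices
      d <- gyrus_trench_depth(v, gy)
      r <- sqrt(rowSums(v^2))
      if (any(r - d <= 0)) stop("sulcus_depth too large: carved shell collapses")
      v2 <- v * (1 - d / r)
      m2 <- surface_mesh(v2, m$triangles)
      if (mesh_volume(m2) <= 0 || !is_closed(m2))
        stop("sulcus deformation produced an invalid shell (check sulcus_depth/sulcus_width)")
      head$shells[[nm]]$mesh <- m2
    }
  }
  # ridge apex polyline at t = 0, sampled along s
  rg <- radii[["GM"]]
  s <- seq(-spec$ridge_length / 2, spec$ridge_length / 2, by = 1)
  u <- s / rg
  dirs <- outer(sin(u), e1) + outer(cos(u), e3)
  d0 <- gyrus_trench_depth(dirs * rg, gy)
  crown <- dirs * (rg - d0)
  attr(head, "phantom") <- list(kind = "gyrus", radii = radii, spec = spec)
  attr(head, "gyrus") <- gy
  attr(head, "crown") <- crown
  head
}

# trench depth at arbitrary points (rows of v, mm, head frame)
gyrus_trench_depth <- function(v, gy) {
  r <- sqrt(rowSums(v^2))
  vh <- v / r
  t_ang <- asin(pmin(1, pmax(-1, as.numeric(vh %*% gy$e2))))
  s_ang <- as.numeric(atan2(vh %*% gy$e1, vh %*% gy$e3))
  tt <- as.numeric(t_ang) * r       # transverse arc coordinate, mm
  ss <- as.numeric(s_ang) * r       # along-ridge arc coordinate, mm
  env <- ifelse(abs(ss) <= gy$ridge_length / 2, 1,
                exp(-((abs(ss) - gy$ridge_length / 2) / gy$taper)^2))
  # suppress the carve on the far side of the head
  env <- env * (abs(s_ang) < pi / 2)
  g <- function(x) exp(-x^2 / (2 * gy$sigma^2))
  gy$depth * env * (g(tt - gy$offset) + g(tt + gy$offset))
}

#' Analytic sulcal-wall normal of the gyrus phantom
#'
#' Outward surface normal of the carved GM shell evaluated from the smooth
#' trench profile at the wall nearest to `point`; used by the
#' sulcus-aligned placement and as the oracle in its tests.
#'
#' @param head a gyrus `head_model`.
#' @param point 3-vector (mm) near the crown.
#' @return unit 3-vector.
#' @export
gyrus_wall_normal <- function(head, point) {
  gy <- attr(head, "gyrus")
  if (is.null(gy)) stop("head model has no gyrus attributes")
  v <- matrix(point, ncol = 3)
  r <- sqrt(sum(point^2))
  vh <- point / r
  tt <- asin(min(1, max(-1, sum(vh * gy$e2)))) * r
  # nearest trench wall: inner wall of the trench on this side of the crown
  tw <- if (tt >= 0) gy$offset else -gy$offset
  g <- function(x) exp(-x^2 / (2 * gy$sigma^2))
  dg <- function(x) -x / gy$sigma^2 * g(x)
  # wall midpoint between crown and trench center
  t_wall <- tw / 2 + tt * 0   # evaluate at half-way down the inner wall
  ddt <- gy$depth * (dg(t_wall - gy$offset) + dg(t_wall + gy$offset))
  # surface r(t) = R - delta(t): outward normal ~ rhat + d(delta)/dt * that
  that <- gy$e2 - sum(gy$e2 * vh) * vh
  that <- that / sqrt(sum(that^2))
  n <- vh + ddt * that
  n / sqrt(sum(n^2))
}

#' Place targets along a gyral crown
#'
#' Steps along the crown polyline so that consecutive targets are separated
#' by exactly `spacing` mm in the straight-line (chord) sense, centered on
#' the crown midpoint. Each target records its immediate neighbours (the
#' adjacent targets) and, when an observation surface is supplied, the
#' indices of its `n_avg_nodes` nearest observation nodes.
#'
#' @param head a `head_model` (used only for reporting).
#' @param crown n x 3 polyline (mm); defaults to the head's crown attribute.
#' @param n_targets number of targets.
#' @param spacing consecutive straight-line spacing in mm.
#' @param obs optional `observation_surface` for node assignment.
#' @param n_avg_nodes number of nearest observation nodes per target.
#' @return object of class `target_placement`: `targets` (n x 3),
#'   `spacings`, `mean_spacing`, `sd_spacing`, and `sets` — one
#'   `target_set` per target with fields `target`, `neighbors`,
#'   `nearest_obs_nodes`.
#' @export
place_targets <- function(head, crown = attr(head, "crown"), n_targets = 3L,
                          spacing = 10, obs = NULL, n_avg_nodes = 4L) {
  if (is.null(crown)) stop("no crown polyline available; supply one")
  # resample the polyline densely for accurate chord stepping
  seg <- sqrt(rowSums(diff(crown)^2))
  arc <- c(0, cumsum(seg))
  if (max(arc) < (n_targets - 1) * spacing)
    stop(sprintf("crown too short: %.1f mm for %d targets at %g mm spacing",
                 max(arc), n_targets, spacing))
  dense_s <- seq(0, max(arc), by = 0.02)
  dense <- apply(crown, 2, function(col) stats::approx(arc, col, xout = dense_s)$y)
  mid_i <- which.min(abs(dense_s - max(arc) / 2))
  # start roughly half the chain before the midpoint (arc ~ chord on a crown)
  start_s <- max(0, dense_s[mid_i] - (n_targets - 1) * spacing / 2)
  i <- which.min(abs(dense_s - start_s))
  targets <- matrix(NA_real_, n_targets, 3)
  targets[1, ] <- dense[i, ]
  for (k in seq_len(n_targets - 1L)) {
    d <- sqrt(rowSums((dense - matrix(targets[k, ], nrow(dense), 3, byrow = TRUE))^2))
    ahead <- seq_len(nrow(dense)) > i
    cross <- which(ahead & d >= spacing)
    if (length(cross) == 0) stop("crown too short while stepping targets")
    j <- cross[1]
    # linear interpolation to the exact chord length
    d0 <- d[j - 1]; d1 <- d[j]
    f <- if (d1 > d0) (spacing - d0) / (d1 - d0) else 1
    targets[k + 1L, ] <- dense[j - 1, ] + f * (dense[j, ] - dense[j - 1, ])
    i <- j
  }
  spacings <- if (n_targets > 1L)
    sqrt(rowSums(diff(targets)^2)) else numeric(0)
  sets <- lapply(seq_len(n_targets), function(k) {
    nb <- targets[setdiff(c(k - 1L, k + 1L), c(0L, n_targets + 1L)), , drop = FALSE]
    nodes <- NULL
    if (!is.null(obs)) {
      d <- sqrt(rowSums((obs$points - matrix(targets[k, ], nrow(obs$points), 3,
                                             byrow = TRUE))^2))
      nodes <- order(d)[seq_len(n_avg_nodes)]
    }
    structure(list(target = targets[k, ], neighbors = nb,
                   nearest_obs_nodes = nodes), class = "target_set")
  })
  structure(list(targets = targets, spacings = spacings,
                 mean_spacing = if (length(spacings)) mean(spacings) else NA_real_,
                 sd_spacing = if (length(spacings) > 1) stats::sd(spacings) else 0,
                 sets = sets),
            class = "target_placement")
}

#' Export targets as CSV (id,x,y,z,neighbor_ids)
#' @param placement a `target_placement`.
#' @param path output path.
#' @export
write_targets_csv <- function(placement, path) {
  n <- nrow(placement$targets)
  nb <- vapply(seq_len(n), function(k)
    paste(setdiff(c(k - 1L, k + 1L), c(0L, n + 1L)), collapse = ";"), "")
  df <- data.frame(id = seq_len(n), x = placement$targets[, 1],
                   y = placement$targets[, 2], z = placement$targets[, 3],
                   neighbor_ids = nb)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
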