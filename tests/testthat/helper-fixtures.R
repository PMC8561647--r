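# Shared fixtures and independent oracles built in code.

# flat square plate in the z = z0 plane, n x n quads split into triangles,
# normals pointing +z
plate_mesh <- function(z0 = 0, half = 20, n = 8) {
  s <- seq(-half, half, length.out = n + 1)
  g <- expand.grid(x = s, y = s)
  verts <- cbind(g$x, g$y, z0)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  tris <- NULL
  for (j in seq_len(n)) for (i in seq_len(n)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    tris <- rbind(tris, c(a, b, c), c(a, c, d))
  }
  surface_mesh(verts, tris)
}

# unit tetrahedron with outward orientation
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  surface_mesh(v, f)
}

# brute-force nearest neighbour in plain R (independent of the C++ kernel)
r_nearest <- function(a, b) {
  t(apply(a, 1, function(p) {
    d2 <- colSums((t(b) - p)^2)
    k <- which.min(d2)
    c(dist = sqrt(d2[k]), idx = k)
  }))
}

# brute-force point-to-triangle distance in plain R
r_point_tri_dist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

# dense barycentric-grid quadrature of int_T (r - r')/|r - r'|^3 dA'
# (independent oracle for the analytic triangle kernel)
r_tri_kernel_quadrature <- function(q1, q2, q3, r, L = 120) {
  e1 <- q2 - q1; e2 <- q3 - q1
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  area <- sqrt(sum(cr^2)) / 2
  acc <- c(0, 0, 0); cnt <- 0L
  for (i in 0:(L - 1)) for (j in 0:(L - 1 - i)) {
    u <- (i + 1 / 3) / L; v <- (j + 1 / 3) / L
    p <- q1 + e1 * u + e2 * v
    d <- r - p
    acc <- acc + d / sum(d^2)^1.5
    cnt <- cnt + 1L
    if (i + j < L - 1) {
      u <- (i + 2 / 3) / L; v <- (j + 2 / 3) / L
      p <- q1 + e1 * u + e2 * v
      d <- r - p
      acc <- acc + d / sum(d^2)^1.5
      cnt <- cnt + 1L
    }
  }
  acc * area / cnt
}

# filament Biot-Savart oracle: E_p of a closed/open polyline carrying unit
# current, via straight-segment midpoint integration
r_filament_field <- function(path_pts, pts, dIdt) {
  seg <- diff(path_pts)
  mid <- (path_pts[-1, , drop = FALSE] + path_pts[-nrow(path_pts), , drop = FALSE]) / 2
  E <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) {
    d <- t(pts[i, ] - t(mid))
    w <- 1 / sqrt(rowSums(d^2))
    E[i, ] <- -1e-7 * dIdt * colSums(seg * w)
  }
  E
}

# small sphere head for fast solver tests: one homogeneous shell
tiny_sphere_head <- function(radius = 92, level = 2L, sigma = 0.276) {
  head_model(list(skin = icosphere(radius, level)), c(skin = sigma))
}

# coarse five-shell head (fast; accuracy tests use the default density)
coarse_head <- function() {
  head_model(list(skin = icosphere(92, 2L), skull = icosphere(86, 2L),
                  CSF = icosphere(82, 2L), GM = icosphere(80, 2L),
                  WM = icosphere(77.5, 2L)),
             unname(default_conductivities()[c("skin", "skull", "CSF", "GM", "WM")]))
}
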