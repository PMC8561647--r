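test_that("mesh construction computes facet data and flags closedness", {
  m <- tetra_mesh()
  expect_s3_class(m, "surface_mesh")
  expect_true(is_closed(m))
  expect_gt(mesh_volume(m), 0)
  expect_equal(sum(m$areas), 1.5 + sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(sqrt(rowSums(m$normals^2)), rep(1, 4), tolerance = 1e-12)
  p <- plate_mesh()
  expect_false(is_closed(p))
})

test_that("mesh round trips through MSH, STL and PLY", {
  m <- tetra_mesh()
  for (fmt in c("msh", "stl", "ply")) {
    path <- file.path(tempdir(), paste0("tetra.", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$vertices), 4, info = fmt)
    expect_equal(nrow(m2$triangles), 4, info = fmt)
    # same facet soup up to vertex reordering: compare sorted centroids
    expect_equal(m2$centroids[order(m2$centroids[, 1], m2$centroids[, 2],
                                    m2$centroids[, 3]), ],
                 m$centroids[order(m$centroids[, 1], m$centroids[, 2],
                                   m$centroids[, 3]), ],
                 tolerance = 1e-7, info = fmt)
  }
  ico <- icosphere(80, 3L)   # 642 vertices
  expect_equal(nrow(ico$vertices), 642)
  path <- file.path(tempdir(), "ico.msh")
  write_mesh(ico, path)
  ico2 <- read_mesh(path)
  expect_equal(ico2$triangles, ico$triangles)
  expect_lt(max(abs(ico2$vertices - ico$vertices)), 1e-9)
  # binary STL round trip (float32 storage)
  pb <- file.path(tempdir(), "ico_bin.stl")
  write_mesh(ico, pb, format = "stl", binary = TRUE)
  ico3 <- read_mesh(pb)
  expect_equal(nrow(ico3$triangles), nrow(ico$triangles))
  expect_lt(max(abs(sort(ico3$vertices[, 1]) - sort(ico$vertices[, 1]))), 1e-4)
})

test_that("zero-area STL facets are dropped with a warning", {
  lines <- c("solid t",
             "facet normal 0 0 1", "  outer loop",
             "    vertex 0 0 0", "    vertex 1 0 0", "    vertex 0 1 0",
             "  endloop", "endfacet",
             "facet normal 0 0 1", "  outer loop",
             "    vertex 2 0 0", "    vertex 3 0 0", "    vertex 2.5 0 0",
             "  endloop", "endfacet",
             "endsolid t")
  path <- file.path(tempdir(), "degen.stl")
  writeLines(lines, path)
  expect_warning(m <- read_mesh(path), "zero-area")
  expect_equal(nrow(m$triangles), 1)
})

test_that("malformed mesh files raise parse errors naming the problem", {
  p <- file.path(tempdir(), "bad.msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes", "2",
               "1 0 0 0"), p)
  expect_error(read_mesh(p), "MSH parse error")
  p2 <- file.path(tempdir(), "bad.ply")
  writeLines(c("not-ply"), p2)
  expect_error(read_mesh(p2), "PLY parse error")
})

test_that("barycentric subdivision is 1:6 per level and conserves area", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0.3, 1.7, 0.5)),
                      rbind(c(1, 2, 3)))
  s1 <- barycentric_subdivide(tri, 1L)
  expect_equal(nrow(s1$triangles), 6)
  expect_equal(sum(s1$areas), sum(tri$areas), tolerance = 1e-12)
  s2 <- barycentric_subdivide(tri, 2L)
  expect_equal(nrow(s2$triangles), 36)
  expect_equal(sum(s2$areas), sum(tri$areas), tolerance = 1e-12)
  # subfacet centroids stay in the parent plane
  n <- tri$normals[1, ]
  offs <- (s2$centroids - matrix(tri$vertices[1, ], 36, 3, byrow = TRUE)) %*% n
  expect_lt(max(abs(offs)), 1e-12)
  ico <- icosphere(10, 1L)
  si <- barycentric_subdivide(ico, 1L)
  expect_equal(nrow(si$triangles), 6 * nrow(ico$triangles))
  expect_equal(sum(si$areas) / sum(ico$areas), 1, tolerance = 1e-10)
  # original vertices are a subset of the subdivided vertex set
  key <- function(v) paste(round(v[, 1], 9), round(v[, 2], 9), round(v[, 3], 9))
  expect_true(all(key(ico$vertices) %in% key(si$vertices)))
})

test_that("shell_distance matches analytic plate and sphere oracles", {
  a <- plate_mesh(z0 = 0, half = 20, n = 10)
  b <- plate_mesh(z0 = 2, half = 30, n = 16)
  expect_equal(shell_distance(a, b), 2, tolerance = 0.02)
  # the centroid-to-centroid measure carries a positive facet-size bias,
  # so the 5% check against the radial gap needs a tessellation that
  # resolves the curvature
  s78 <- icosphere(78, 4L)
  s80 <- icosphere(80, 4L)
  expect_equal(shell_distance(s80, s78), 2, tolerance = 0.05 * 2)
  # self distance below one refined edge length
  s78c <- icosphere(78, 2L)
  ref_edge <- tmsfocal:::mean_edge_length(barycentric_subdivide(s78c, 2L))
  expect_lt(shell_distance(s78c, s78c), ref_edge)
  # refining the target shell cannot increase the distance on curved shells
  s80c <- icosphere(80, 2L)
  d1 <- shell_distance(s80c, s78c, refine_levels = 1L)
  d2 <- shell_distance(s80c, s78c, refine_levels = 2L)
  expect_lte(d2, d1 + 1e-9)
})

test_that("nearest-point kernel agrees with an R brute-force oracle", {
  set.seed(5)
  a <- matrix(rnorm(60), 20, 3)
  b <- matrix(rnorm(90), 30, 3)
  got <- tmsfocal:::cpp_nearest_point(a, b)
  ref <- r_nearest(a, b)
  expect_equal(as.numeric(got$dist), unname(ref[, "dist"]), tolerance = 1e-12)
  expect_equal(as.integer(got$idx), as.integer(ref[, "idx"]))
})

test_that("observation surfaces sit at the stated fraction between GM and WM", {
  gm <- plate_mesh(z0 = 3, half = 15, n = 6)
  wm <- plate_mesh(z0 = 0, half = 25, n = 20)
  mid <- build_observation_surface(gm, wm, "1:1")
  expect_equal(unname(mid$points[, 3]), rep(1.5, nrow(mid$points)), tolerance = 0.02)
  l5 <- build_observation_surface(gm, wm, "4:1")
  expect_equal(unname(l5$points[, 3]), rep(0.6, nrow(l5$points)), tolerance = 0.02)
  # 4:1 means the point has covered 80% of the thickness from the GM side
  d_gm <- 3 - l5$points[, 3]
  d_wm <- l5$points[, 3]
  expect_equal(mean(d_gm / d_wm), 4, tolerance = 0.1)
  # per-point fraction |p - c| / |v| is exact
  f <- sqrt(rowSums((l5$points - gm$centroids[l5$source_facet, ])^2)) /
    sqrt(rowSums(l5$gm_wm_vector^2))
  expect_equal(f, rep(0.8, length(f)), tolerance = 1e-12)

  sg <- icosphere(80, 2L)
  sw <- icosphere(77, 2L)
  obs <- build_observation_surface(sg, sw, "1:1")
  expect_equal(mean(sqrt(rowSums(obs$points^2))), 78.5, tolerance = 78.5 * 0.01)
})

test_that("observation points beyond the thickness cap are excluded", {
  gm <- plate_mesh(z0 = 8, half = 10, n = 4)
  wm <- plate_mesh(z0 = 0, half = 10, n = 4)
  expect_message(obs <- build_observation_surface(gm, wm, "1:1", max_thickness = 6),
                 "excluding")
  expect_equal(nrow(obs$points), 0)
})

test_that("head models enforce nested conductivities", {
  h <- coarse_head()
  expect_equal(h$shells$skin$sigma_out, 0)
  expect_equal(h$shells$skull$sigma_out, h$shells$skin$sigma_in)
  expect_equal(h$shells$WM$sigma_out, h$shells$GM$sigma_in)
  expect_error(head_model(list(icosphere(10, 1L)), 0.3), "named")
})

test_that("multi-shell head MSH files round trip with shell identity", {
  h <- coarse_head()
  p <- file.path(tempdir(), "head.msh")
  write_head_msh(h, p)
  h2 <- read_head_msh(p)
  expect_equal(names(h2$shells), names(h$shells))
  for (nm in names(h$shells)) {
    expect_equal(nrow(h2$shells[[nm]]$mesh$triangles),
                 nrow(h$shells[[nm]]$mesh$triangles), info = nm)
    expect_equal(h2$shells[[nm]]$sigma_in, h$shells[[nm]]$sigma_in, info = nm)
  }
  expect_lt(abs(mesh_volume(head_shell(h2, "GM")) - mesh_volume(head_shell(h, "GM"))), 1e-6)
})
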