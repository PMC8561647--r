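#' Read a surface mesh from MSH, STL or PLY
#'
#' Supported dialects: Gmsh MSH v2 ASCII (surface elements of all physical
#' groups are merged; use [read_head_msh()] to keep shells apart), STL
#' (ASCII or standard binary, vertices deduplicated exactly), and ASCII PLY.
#'
#' @param path file path.
#' @param format one of `"msh"`, `"stl"`, `"ply"`; guessed from the file
#'   extension when missing.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "msh", "stl", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format,
         msh = read_msh_merged(path),
         stl = read_stl(path),
         ply = read_ply(path),
         stop(sprintf("unsupported mesh format '%s'", format)))
}

#' Write a surface mesh to MSH, STL or PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format one of `"msh"`, `"stl"`, `"ply"` (default from extension).
#' @param binary write binary STL instead of ASCII (STL only).
#' @export
write_mesh <- function(mesh, path, format = c("auto", "msh", "stl", "ply"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  switch(format,
         msh = write_head_msh(list(surface = mesh), path),
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", format)))
  invisible(path)
}

# ---- Gmsh MSH v2 ASCII ----------------------------------------------------

msh_sections <- function(lines) {
  starts <- grep("^\\$(?!End)", lines, perl = TRUE)
  out <- list()
  for (s in starts) {
    name <- sub("^\\$", "", lines[s])
    end <- match(paste0("$End", name), lines)
    if (is.na(end)) stop(sprintf("MSH parse error: unterminated section %s (line %d)", name, s))
    out[[name]] <- lines[(s + 1):(end - 1)]
  }
  out
}

parse_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- msh_sections(lines)
  if (is.null(sec$MeshFormat) || !startsWith(sec$MeshFormat[1], "2"))
    stop("MSH parse error: only Gmsh v2 ASCII is supported")
  if (is.null(sec$Nodes) || is.null(sec$Elements))
    stop("MSH parse error: missing $Nodes or $Elements section")
  nn <- as.integer(sec$Nodes[1])
  ntab <- matrix(scan(text = sec$Nodes[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (nrow(ntab) != nn) stop("MSH parse error: node count mismatch in $Nodes")
  verts <- ntab[, 2:4, drop = FALSE]
  id_map <- integer(max(ntab[, 1]))
  id_map[ntab[, 1]] <- seq_len(nn)
  el <- sec$Elements[-1]
  tok <- strsplit(el, "[ \t]+")
  tris <- list(); tags <- integer(0)
  for (i in seq_along(tok)) {
    v <- as.integer(tok[[i]])
    if (length(v) < 2) stop(sprintf("MSH parse error: bad element record %d", i))
    if (v[2] != 2L) next  # keep 3-node triangles only
    ntags <- v[3]
    conn <- v[(4 + ntags):(6 + ntags)]
    tris[[length(tris) + 1L]] <- conn
    tags <- c(tags, if (ntags >= 1) v[4] else 0L)
  }
  if (length(tris) == 0L) stop("MSH parse error: no triangle elements")
  tris <- matrix(id_map[do.call(rbind, tris)], ncol = 3)
  phys <- NULL
  if (!is.null(sec$PhysicalNames)) {
    pn <- sec$PhysicalNames[-1]
    pm <- regmatches(pn, regexec('^\\s*\\d+\\s+(\\d+)\\s+"(.*)"', pn))
    keep <- lengths(pm) == 3
    phys <- stats::setNames(vapply(pm[keep], function(x) as.integer(x[2]), 1L),
                            vapply(pm[keep], function(x) x[3], ""))
  }
  list(vertices = verts, triangles = tris, tags = tags, phys = phys)
}

read_msh_merged <- function(path) {
  p <- parse_msh(path)
  used <- sort(unique(as.vector(p$triangles)))
  remap <- integer(nrow(p$vertices)); remap[used] <- seq_along(used)
  surface_mesh(p$vertices[used, , drop = FALSE],
               matrix(remap[p$triangles], ncol = 3))
}

#' Read a multi-shell head MSH file
#'
#' Each physical surface group becomes one shell; group names are the shell
#' names. Conductivities are supplied by the caller (they are not part of
#' the MSH format).
#'
#' @param path MSH v2 ASCII file with one physical group per shell.
#' @param conductivities named vector of inside conductivities (S/m); names
#'   must cover the group names. Defaults to [default_conductivities()] for
#'   the standard shells.
#' @return a `head_model`, shells ordered as stored in the file.
#' @export
read_head_msh <- function(path, conductivities = default_conductivities()) {
  p <- parse_msh(path)
  if (is.null(p$phys)) stop("MSH file has no $PhysicalNames; cannot identify shells")
  shells <- list()
  for (nm in names(p$phys)) {
    sel <- p$tags == p$phys[[nm]]
    if (!any(sel)) next
    tri <- p$triangles[sel, , drop = FALSE]
    used <- sort(unique(as.vector(tri)))
    remap <- integer(nrow(p$vertices)); remap[used] <- seq_along(used)
    shells[[nm]] <- surface_mesh(p$vertices[used, , drop = FALSE],
                                 matrix(remap[tri], ncol = 3))
  }
  if (!all(names(shells) %in% names(conductivities)))
    stop("conductivities missing for shell(s): ",
         paste(setdiff(names(shells), names(conductivities)), collapse = ", "))
  head_model(shells, unname(conductivities[names(shells)]))
}

#' Write a head model (or named mesh list) as multi-shell MSH v2 ASCII
#'
#' One physical surface group per shell, numbered in order (SimNIBS-style
#' sequential numbering; the README documents the convention).
#'
#' @param head a `head_model` or a named list of `surface_mesh` objects.
#' @param path output path.
#' @export
write_head_msh <- function(head, path) {
  meshes <- if (inherits(head, "head_model"))
    stats::setNames(lapply(head$shells, `[[`, "mesh"), names(head$shells))
  else head
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("$MeshFormat"); wl("2.2 0 8"); wl("$EndMeshFormat")
  wl("$PhysicalNames"); wl("%d", length(meshes))
  for (i in seq_along(meshes)) wl('2 %d "%s"', i, names(meshes)[i])
  wl("$EndPhysicalNames")
  offs <- cumsum(c(0, vapply(meshes, function(m) nrow(m$vertices), 1)))
  nv <- offs[length(offs)]
  wl("$Nodes"); wl("%d", nv)
  id <- 0L
  for (m in meshes) {
    v <- m$vertices
    writeLines(sprintf("%d %.12g %.12g %.12g",
                       id + seq_len(nrow(v)), v[, 1], v[, 2], v[, 3]), con)
    id <- id + nrow(v)
  }
  wl("$EndNodes")
  nt <- sum(vapply(meshes, function(m) nrow(m$triangles), 1))
  wl("$Elements"); wl("%d", nt)
  eid <- 0L
  for (i in seq_along(meshes)) {
    tr <- meshes[[i]]$triangles + offs[i]
    writeLines(sprintf("%d 2 2 %d %d %d %d %d",
                       eid + seq_len(nrow(tr)), i, i,
                       tr[, 1], tr[, 2], tr[, 3]), con)
    eid <- eid + nrow(tr)
  }
  wl("$EndElements")
  invisible(path)
}

# ---- STL ------------------------------------------------------------------

stl_is_binary <- function(path) {
  head5 <- readBin(path, "raw", n = 5)
  if (!identical(rawToChar(head5), "solid")) return(TRUE)
  # "solid" prefix can legally start a binary header; check size consistency
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  identical(sz, 84 + 50 * as.numeric(n))
}

read_stl <- function(path) {
  if (stl_is_binary(path)) {
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", n = 50 * n)
    tri <- matrix(NA_real_, nrow = 3 * n, ncol = 3)
    for (i in seq_len(n)) {
      rec <- raw[(50 * (i - 1) + 1):(50 * i)]
      f <- readBin(rec[1:48], "numeric", n = 12, size = 4, endian = "little")
      tri[(3 * i - 2):(3 * i), ] <- matrix(f[4:12], ncol = 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop(sprintf("STL parse error: vertex record count %d is not a multiple of 3", length(vl)))
    tri <- matrix(scan(text = sub("^\\s*vertex\\s+", "", lines[vl]), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  }
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "_")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  surface_mesh(tri[uk, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}

write_stl <- function(mesh, path, binary = FALSE) {
  fc <- facet_corners(mesh)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(c(charToRaw("tmsfocal binary STL"), raw(80))[1:80], con)
    writeBin(as.integer(nrow(mesh$triangles)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(mesh$triangles))) {
      writeBin(as.numeric(c(mesh$normals[i, ], fc$v1[i, ], fc$v2[i, ], fc$v3[i, ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0L), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid tmsfocal", con)
    for (i in seq_len(nrow(mesh$triangles))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g",
                         mesh$normals[i, 1], mesh$normals[i, 2], mesh$normals[i, 3]), con)
      writeLines("  outer loop", con)
      writeLines(sprintf("    vertex %.9g %.9g %.9g",
                         c(fc$v1[i, 1], fc$v2[i, 1], fc$v3[i, 1]),
                         c(fc$v1[i, 2], fc$v2[i, 2], fc$v3[i, 2]),
                         c(fc$v1[i, 3], fc$v2[i, 3], fc$v3[i, 3])), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid tmsfocal", con)
  }
  invisible(path)
}

# ---- PLY (ASCII) ----------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("PLY parse error: missing 'ply' magic (line 1)")
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("PLY parse error: missing end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY parse error: missing element counts")
  vlines <- lines[(hdr_end + 1):(hdr_end + nv)]
  verts <- matrix(scan(text = vlines, quiet = TRUE), ncol = 3, byrow = TRUE)
  flines <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  ftab <- lapply(strsplit(flines, "[ \t]+"), as.integer)
  if (any(vapply(ftab, function(x) x[1], 1L) != 3L))
    stop("PLY parse error: non-triangular face present")
  tris <- do.call(rbind, lapply(ftab, function(x) x[2:4] + 1L))
  surface_mesh(verts, tris)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}
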