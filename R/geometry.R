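# Test-object geometry: triangulated surface meshes, canonical primitives,
# rigid posing relative to the phantom, and STL input/output.

new_to_geometry <- function(vertices, faces, canonical = vertices,
                            orientation = NA_character_, center = c(0, 0, 0),
                            shape = "mesh") {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3L,
            is.matrix(faces), ncol(faces) == 3L)
  structure(list(vertices = vertices,
                 faces = matrix(as.integer(faces), ncol = 3L),
                 canonical = canonical,
                 orientation = orientation,
                 center = as.numeric(center),
                 shape = shape),
            class = "to_geometry")
}

#' Construct a test-object geometry from raw vertices and faces
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices; triangles
#'   must wind consistently so that face normals point outward (enclosed
#'   volume positive).
#' @return A `to_geometry` object.
#' @export
mesh_geometry <- function(vertices, faces) {
  g <- new_to_geometry(vertices, faces)
  if (mesh_volume(g) < 0) {
    g$faces <- g$faces[, c(1L, 3L, 2L)]
    g$canonical <- g$vertices
  }
  g
}

#' @export
print.to_geometry <- function(x, ...) {
  cat(sprintf("<to_geometry> %s: %d vertices, %d faces, volume %.3f mm^3",
              x$shape, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  if (!is.na(x$orientation)) cat(sprintf(", orientation %s", x$orientation))
  cat("\n")
  invisible(x)
}

#' Closed cylinder surface mesh
#'
#' Builds a watertight triangulated cylinder with its axis along +z,
#' centered at the origin.  Used for the 3 mm x 15 mm rod test objects.
#'
#' @param diameter Cylinder diameter in mm, > 0.
#' @param length Cylinder length in mm, > 0.
#' @param n_segments Number of circumferential segments, >= 8.  The enclosed
#'   volume converges to `pi * (diameter/2)^2 * length` as `n_segments`
#'   grows.
#' @return A `to_geometry` object (watertight, outward normals).
#' @examples
#' rod <- make_cylinder_mesh(3, 15, 64)
#' mesh_volume(rod)  # ~106.03 mm^3
#' @export
make_cylinder_mesh <- function(diameter, length, n_segments = 64L) {
  if (!is.numeric(diameter) || diameter <= 0 || !is.numeric(length) || length <= 0) {
    stop("invalid geometry: 'diameter' and 'length' must be > 0")
  }
  n <- as.integer(n_segments)
  if (n < 8L) stop("'n_segments' must be >= 8")
  r <- diameter / 2
  h <- length / 2
  th <- 2 * pi * (seq_len(n) - 1L) / n
  ring <- cbind(r * cos(th), r * sin(th))
  v <- rbind(cbind(ring, -h),          # 1..n     bottom ring
             cbind(ring, +h),          # n+1..2n  top ring
             c(0, 0, -h),              # 2n+1     bottom center
             c(0, 0, +h))              # 2n+2     top center
  i <- seq_len(n)
  j <- c(seq_len(n - 1L) + 1L, 1L)     # next index around the ring
  faces <- rbind(
    cbind(i, j, n + i),                # side, lower triangles
    cbind(j, n + j, n + i),            # side, upper triangles
    cbind(2L * n + 1L, j, i),          # bottom cap (normal -z)
    cbind(2L * n + 2L, n + i, n + j))  # top cap (normal +z)
  g <- new_to_geometry(v, faces, shape = sprintf("cylinder d=%g L=%g", diameter, length))
  stopifnot(mesh_volume(g) > 0)
  g
}

#' Enclosed volume of a closed triangulated mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin).  Positive for consistently outward-wound watertight meshes.
#'
#' @param geometry A `to_geometry` object.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(geometry) {
  v <- geometry$vertices
  f <- geometry$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  # triple product a . (b x c) / 6 per face
  cx <- b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]
  cy <- b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]
  cz <- b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L]
  sum(a[, 1L] * cx + a[, 2L] * cy + a[, 3L] * cz) / 6
}

#' Check that a mesh is watertight
#'
#' Deduplicates vertices and verifies that every undirected edge is shared
#' by exactly two faces with opposite orientation.
#'
#' @param geometry A `to_geometry` object.
#' @param tol Coordinate rounding tolerance used to merge duplicated
#'   vertices (mm).
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(geometry, tol = 1e-9) {
  v <- round(geometry$vertices / tol) * tol
  key <- paste(v[, 1L], v[, 2L], v[, 3L], sep = "/")
  id <- match(key, unique(key))
  f <- matrix(id[geometry$faces], ncol = 3L)
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  fwd <- paste(edges[, 1L], edges[, 2L])
  rev <- paste(edges[, 2L], edges[, 1L])
  if (anyDuplicated(fwd)) return(FALSE)
  all(fwd %in% rev)
}

rotation_for_orientation <- function(orientation, transverse_axis = "x") {
  switch(orientation,
         parallel = diag(3),
         perpendicular = {
           if (transverse_axis == "x") {
             # rotate +z onto +x (about y)
             matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
           } else if (transverse_axis == "y") {
             matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE)
           } else stop("config error: 'transverse_axis' must be \"x\" or \"y\"")
         },
         stop(sprintf("config error: unknown orientation '%s'", orientation)))
}

#' Pose a test object parallel or perpendicular to the static field
#'
#' The static field axis is the grid z-axis.  `parallel` aligns the object's
#' canonical long axis (+z) with z; `perpendicular` aligns it with a
#' transverse axis (x by default, the frequency-encode default axis).  The
#' object is centered at the phantom center.  The operation is idempotent:
#' it always poses the stored canonical geometry.
#'
#' @param geometry A `to_geometry` object.
#' @param orientation `"parallel"` or `"perpendicular"` (w.r.t. the B0 axis).
#' @param transverse_axis Which transverse axis the long axis takes for
#'   `"perpendicular"`: `"x"` (default) or `"y"`.
#' @param center Object center in phantom coordinates (mm).
#' @return The posed `to_geometry`.
#' @export
orient_object <- function(geometry, orientation = c("parallel", "perpendicular"),
                          transverse_axis = "x", center = c(0, 0, 0)) {
  orientation <- match.arg(orientation)
  R <- rotation_for_orientation(orientation, transverse_axis)
  g <- geometry
  g$vertices <- sweep(g$canonical %*% t(R), 2L, as.numeric(center), "+")
  g$orientation <- orientation
  g$center <- as.numeric(center)
  g
}

#' Read a surface mesh from an STL file
#'
#' Supports both binary and ASCII STL.  Vertices are taken as written
#' (duplicated per facet); downstream operations deduplicate as needed.
#'
#' @param path Path to an `.stl` file.
#' @return A `to_geometry` object.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 80L)
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop("invalid geometry: malformed ASCII STL")
    }
    vals <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(p) as.numeric(p[2:4]), numeric(3)))
    verts <- vals
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", n = ntri * 50L)
    if (length(rec) != ntri * 50L) stop("invalid geometry: truncated binary STL")
    m <- matrix(rec, nrow = 50L)
    fl <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric", size = 4L,
                  n = 12L * ntri, endian = "little")
    fl <- matrix(fl, nrow = 12L)        # per-facet: normal + 3 vertices
    verts <- matrix(as.vector(fl[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  mesh_geometry(verts, faces)
}

#' Write a surface mesh to an ASCII STL file
#'
#' @param geometry A `to_geometry` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stl <- function(geometry, path) {
  v <- geometry$vertices
  f <- geometry$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid artifactsim", con)
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid artifactsim", con)
  invisible(path)
}

#' Centered voxel-grid coordinates
#'
#' Voxel centers along one axis of an n-voxel grid with isotropic edge
#' `voxel_size`, centered on the grid midpoint (for even n the grid center
#' falls on a voxel corner, so the layout is exactly symmetric).
#'
#' @param n Number of voxels.
#' @param voxel_size Voxel edge length (mm).
#' @return Numeric vector of n center coordinates (mm).
#' @export
grid_axis <- function(n, voxel_size) (seq_len(n) - (n + 1) / 2) * voxel_size

#' Voxelize a watertight mesh on a centered grid
#'
#' Marks voxels whose centers lie inside the closed surface, by even-odd
#' ray parity along the z-axis.  No partial-volume weighting at this stage:
#' sub-voxel structure enters the simulation later through the isochromat
#' sampling.
#'
#' @param geometry A `to_geometry` object; must be watertight.
#' @param grid_shape Integer vector of 3 (nx, ny, nz).
#' @param voxel_size Isotropic voxel edge length (mm).
#' @return Logical array of dimension `grid_shape`.
#' @export
voxelize_mesh <- function(geometry, grid_shape, voxel_size) {
  stopifnot(length(grid_shape) == 3L, voxel_size > 0)
  if (!mesh_is_watertight(geometry)) {
    stop("invalid geometry: mesh is not watertight")
  }
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  xs <- grid_axis(nx, voxel_size)
  ys <- grid_axis(ny, voxel_size)
  zs <- grid_axis(nz, voxel_size)
  v <- geometry$vertices
  lo <- apply(v, 2L, min); hi <- apply(v, 2L, max)
  ext <- voxel_size / 2
  if (lo[1] < xs[1] - ext || hi[1] > xs[nx] + ext ||
      lo[2] < ys[1] - ext || hi[2] > ys[ny] + ext ||
      lo[3] < zs[1] - ext || hi[3] > zs[nz] + ext) {
    stop("out of bounds: mesh extends beyond the voxel grid")
  }
  # deterministic sub-voxel ray offset so rays never graze mesh edges
  jx <- voxel_size * 2.718281828e-7
  jy <- voxel_size * 3.141592653e-7
  f <- geometry$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  cols <- integer(0)
  zhit <- numeric(0)
  for (t in seq_len(nrow(f))) {
    a <- p1[t, ]; b <- p2[t, ]; c_ <- p3[t, ]
    txlo <- min(a[1], b[1], c_[1]); txhi <- max(a[1], b[1], c_[1])
    tylo <- min(a[2], b[2], c_[2]); tyhi <- max(a[2], b[2], c_[2])
    ix <- which(xs + jx >= txlo & xs + jx <= txhi)
    iy <- which(ys + jy >= tylo & ys + jy <= tyhi)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix] + jx, times = length(iy))
    py <- rep(ys[iy] + jy, each = length(ix))
    # 2D barycentric test in the xy projection
    d <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    if (abs(d) < .Machine$double.eps * 100) next  # facet vertical in z: no crossing
    l1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / d
    l2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(inside)) next
    zc <- l1[inside] * a[3] + l2[inside] * b[3] + l3[inside] * c_[3]
    ci <- (rep(ix, times = length(iy)))[inside] +
      (rep(iy, each = length(ix))[inside] - 1L) * nx
    cols <- c(cols, ci)
    zhit <- c(zhit, zc)
  }
  out <- array(FALSE, dim = grid_shape)
  if (!length(cols)) return(out)
  ord <- order(cols, zhit)
  cols <- cols[ord]; zhit <- zhit[ord]
  split_idx <- split(zhit, cols)
  for (key in names(split_idx)) {
    zc <- split_idx[[key]]
    if (length(zc) %% 2L != 0L) {
      stop("invalid geometry: odd ray-crossing parity (mesh degenerate along a ray)")
    }
    col <- as.integer(key)
    below <- findInterval(zs, zc)
    insz <- which(below %% 2L == 1L)
    if (length(insz)) out[col + (insz - 1L) * (nx * ny)] <- TRUE
  }
  out
}
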