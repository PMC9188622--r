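# Mesh and phantom builders shared across tests.  All fixtures are built
# in code; nothing is read from disk.

# UV (latitude-longitude) sphere mesh with outward-wound triangles.
uv_sphere <- function(R, nth = 32L, nph = 64L) {
  th <- seq(0, pi, length.out = nth + 1L)
  verts <- matrix(c(0, 0, R), 1L)
  for (i in 2:nth) {
    ph <- 2 * pi * (0:(nph - 1L)) / nph
    verts <- rbind(verts, cbind(R * sin(th[i]) * cos(ph),
                                R * sin(th[i]) * sin(ph),
                                R * cos(th[i])))
  }
  verts <- rbind(verts, c(0, 0, -R))
  ring <- function(i) 2L + (i - 2L) * nph        # first vertex of ring i (2..nth)
  faces <- list()
  for (j in 0:(nph - 1L)) {                      # north cap
    faces[[length(faces) + 1L]] <- c(1L, ring(2L) + j, ring(2L) + (j + 1L) %% nph)
  }
  if (nth > 2L) for (i in 2:(nth - 1L)) for (j in 0:(nph - 1L)) {
    a <- ring(i) + j                   # upper ring
    b <- ring(i) + (j + 1L) %% nph
    cc <- ring(i + 1L) + j             # lower ring
    d <- ring(i + 1L) + (j + 1L) %% nph
    faces[[length(faces) + 1L]] <- c(cc, d, b)
    faces[[length(faces) + 1L]] <- c(cc, b, a)
  }
  south <- nrow(verts)
  for (j in 0:(nph - 1L)) {                      # south cap
    faces[[length(faces) + 1L]] <- c(south, ring(nth) + (j + 1L) %% nph, ring(nth) + j)
  }
  mesh_geometry(verts, do.call(rbind, faces))
}

# Axis-aligned box mesh [x0,x1] x [y0,y1] x [z0,z1].
box_mesh <- function(x0, x1, y0, y1, z0, z1) {
  v <- as.matrix(expand.grid(x = c(x0, x1), y = c(y0, y1), z = c(z0, z1)))
  # vertex order: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0) 5=(0,0,1) ...
  f <- rbind(c(1, 3, 4), c(1, 4, 2),    # bottom (z0), normal -z
             c(5, 6, 8), c(5, 8, 7),    # top (z1), normal +z
             c(1, 2, 6), c(1, 6, 5),    # y0 face
             c(3, 7, 8), c(3, 8, 4),    # y1 face
             c(1, 5, 7), c(1, 7, 3),    # x0 face
             c(2, 4, 8), c(2, 8, 6))    # x1 face
  mesh_geometry(v, f)
}

# Small uniform-slab isochromat set: in-plane square of oil at df = df0.
slab_isochromats <- function(half_mm, spacing = 0.5, df0 = 0, amp = 1) {
  ax <- seq(-half_mm, half_mm, by = spacing)
  list(u = rep(ax, times = length(ax)),
       v = rep(ax, each = length(ax)),
       df = rep(df0, length(ax)^2),
       amp = rep(amp, length(ax)^2))
}

# Coordinate arrays of a centered grid.
coord_arrays <- function(n, h) {
  ax <- grid_axis(n, h)
  list(x = array(rep(ax, times = n * n), c(n, n, n)),
       y = array(rep(rep(ax, each = n), times = n), c(n, n, n)),
       z = array(rep(ax, each = n * n), c(n, n, n)),
       ax = ax)
}
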