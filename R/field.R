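# Susceptibility-induced off-resonance: forward field computation with the
# k-space dipole kernel, plus closed-form sphere/cylinder oracles.

#' Gyromagnetic ratio over 2 pi for protons, in Hz per tesla
#' @export
GAMMA_BAR_HZ_PER_T <- 42.577e6

fft_freq <- function(n, d = 1) {
  i <- 0:(n - 1L)
  ifelse(i <= n %/% 2, i, i - n) / (n * d)
}

# next integer >= n whose prime factors are all in {2, 3, 5} (fast mixed-radix FFT)
next_smooth <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

#' k-space dipole kernel
#'
#' The unitless multiplier `D(k) = 1/3 - kz^2 / (kx^2 + ky^2 + kz^2)` on the
#' discrete frequency grid of an FFT of shape `grid_shape`, converting a
#' susceptibility distribution into its induced relative field shift.
#' `D(0)` is set to 0: the mean field offset is fixed instead by
#' demodulation over the background (see [compute_offresonance()]).
#'
#' @param grid_shape Integer vector of 3, all >= 2.
#' @param voxel_size Isotropic voxel edge (mm); only enters through ratios,
#'   so the kernel is scale-invariant.
#' @return 3D numeric array of kernel values.
#' @export
dipole_kernel <- function(grid_shape, voxel_size = 1) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  kx <- fft_freq(grid_shape[1L], voxel_size)
  ky <- fft_freq(grid_shape[2L], voxel_size)
  kz <- fft_freq(grid_shape[3L], voxel_size)
  kx2ky2 <- outer(kx^2, ky^2, `+`)
  out <- array(0, dim = grid_shape)
  for (iz in seq_along(kz)) {
    k2 <- kx2ky2 + kz[iz]^2
    d <- 1 / 3 - kz[iz]^2 / k2
    if (kz[iz] == 0) d[kx2ky2 == 0] <- 0
    out[, , iz] <- d
  }
  out
}

#' Off-resonance field of a susceptibility distribution
#'
#' Computes `delta_f = gamma_bar * B0 * 1e-6 * IFT[D(k) * FT(chi)]` in Hz,
#' then removes the mean over background voxels (modelling the scanner's
#' center-frequency adjustment on the bulk medium).  The grid is
#' zero-padded (in susceptibility contrast relative to `pad_value`) to
#' suppress circular-convolution wrap-around.
#'
#' @param chi_map 3D array of susceptibility in ppm; all finite.
#' @param B0 Field strength in tesla.
#' @param voxel_size Isotropic voxel edge (mm).
#' @param background Optional logical array marking background voxels for
#'   the demodulation; defaults to voxels whose chi equals `pad_value`.
#' @param pad_factor Per-axis padding factor (scalar or length 3); each
#'   padded dimension is the next 2-3-5-smooth integer >=
#'   `pad_factor * n`.  `1` disables padding (periodic boundary), which is
#'   also how translation-invariant geometries such as infinite cylinders
#'   are modelled.
#' @param pad_value Susceptibility assigned to the padded region (ppm);
#'   defaults to the corner voxel of `chi_map` (the far background).
#' @param gamma_bar Gyromagnetic ratio / 2 pi in Hz/T.
#' @return An object of class `field_map`: list with `delta_f` (Hz, same
#'   grid as `chi_map`), `B0`, `voxel_size`, `gamma_bar`.
#' @export
compute_offresonance <- function(chi_map, B0, voxel_size = 1,
                                 background = NULL, pad_factor = 4 / 3,
                                 pad_value = NULL,
                                 gamma_bar = GAMMA_BAR_HZ_PER_T) {
  dm <- dim(chi_map)
  stopifnot(length(dm) == 3L, all(dm >= 2L))
  if (anyNA(chi_map) || any(!is.finite(chi_map))) {
    stop("value error: 'chi_map' must be finite everywhere")
  }
  if (length(pad_factor) == 1L) pad_factor <- rep(pad_factor, 3L)
  if (is.null(pad_value)) pad_value <- chi_map[1L, 1L, 1L]
  pd <- vapply(seq_len(3L),
               function(a) next_smooth(as.integer(ceiling(dm[a] * pad_factor[a]))),
               integer(1))
  work <- array(0, dim = pd)
  work[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- chi_map - pad_value
  work <- stats::fft(work)
  kx <- fft_freq(pd[1L], voxel_size)
  ky <- fft_freq(pd[2L], voxel_size)
  kz <- fft_freq(pd[3L], voxel_size)
  kx2ky2 <- outer(kx^2, ky^2, `+`)
  for (iz in seq_along(kz)) {
    k2 <- kx2ky2 + kz[iz]^2
    d <- 1 / 3 - kz[iz]^2 / k2
    if (kz[iz] == 0) d[kx2ky2 == 0] <- 0
    work[, , iz] <- work[, , iz] * d
  }
  work <- stats::fft(work, inverse = TRUE)
  shift <- Re(work[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])]) / prod(pd)
  rm(work); gc(FALSE)
  delta_f <- gamma_bar * B0 * 1e-6 * shift
  if (is.null(background)) background <- (chi_map == pad_value)
  if (any(background)) delta_f <- delta_f - mean(delta_f[background])
  structure(list(delta_f = delta_f, B0 = B0, voxel_size = voxel_size,
                 gamma_bar = gamma_bar),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %s voxels at %.4g mm, B0 = %g T, range [%.3g, %.3g] Hz\n",
              paste(dim(x$delta_f), collapse = " x "), x$voxel_size, x$B0,
              min(x$delta_f), max(x$delta_f)))
  invisible(x)
}

#' Export a field map as NIfTI-1 (Hz)
#'
#' @param field A `field_map`.
#' @param path Output path.
#' @export
write_field_nifti <- function(field, path) {
  write_volume_nifti(field$delta_f, field$voxel_size, path)
}

#' Closed-form external field of a uniformly magnetized sphere
#'
#' Analytic oracle: `gamma_bar * B0 * (delta_chi * 1e-6 / 3) * (R/r)^3 *
#' (3 cos^2 theta - 1)` at points outside the sphere, with theta the angle
#' to the B0 (z) axis.
#'
#' @param R Sphere radius (mm).
#' @param delta_chi Susceptibility contrast vs background (ppm).
#' @param B0 Field strength (T).
#' @param points n x 3 matrix of coordinates (mm), sphere centered at the
#'   origin; all points must lie strictly outside the sphere.
#' @param gamma_bar Gyromagnetic ratio / 2 pi in Hz/T.
#' @return Numeric vector of off-resonance values (Hz).
#' @export
analytic_sphere_field <- function(R, delta_chi, B0, points,
                                  gamma_bar = GAMMA_BAR_HZ_PER_T) {
  points <- rbind(points)
  r <- sqrt(rowSums(points^2))
  if (any(r <= R)) stop("domain error: all points must lie outside the sphere")
  cos2 <- (points[, 3L] / r)^2
  gamma_bar * B0 * (delta_chi * 1e-6 / 3) * (R / r)^3 * (3 * cos2 - 1)
}

#' Closed-form field of an infinite circular cylinder
#'
#' Analytic oracle matching the k-space kernel convention.  The cylinder
#' axis lies in the x-z plane at `axis_angle` degrees from the B0 (z)
#' axis.  Inside: `gamma_bar * B0 * delta_chi * 1e-6 * (3 cos^2 theta - 1) / 6`
#' (so +1/3 of the contrast for a parallel cylinder, -1/6 for a
#' perpendicular one).  Outside:
#' `gamma_bar * B0 * delta_chi * 1e-6 / 2 * (R/rho)^2 * cos(2 phi) * sin^2 theta`,
#' with `rho`, `phi` polar coordinates in the plane perpendicular to the
#' axis and `phi` measured from the projection of B0 into that plane.  A
#' parallel cylinder has no external field.
#'
#' @param R Cylinder radius (mm).
#' @param delta_chi Susceptibility contrast vs background (ppm).
#' @param B0 Field strength (T).
#' @param axis_angle Angle between cylinder axis and B0, in degrees within
#'   [0, 90].
#' @param points n x 3 matrix of coordinates (mm), axis through the origin.
#' @param gamma_bar Gyromagnetic ratio / 2 pi in Hz/T.
#' @return Numeric vector of off-resonance values (Hz).
#' @export
analytic_cylinder_field <- function(R, delta_chi, B0, axis_angle, points,
                                    gamma_bar = GAMMA_BAR_HZ_PER_T) {
  if (axis_angle < 0 || axis_angle > 90) {
    stop("domain error: 'axis_angle' must lie in [0, 90] degrees")
  }
  points <- rbind(points)
  th <- axis_angle * pi / 180
  axis <- c(sin(th), 0, cos(th))
  along <- drop(points %*% axis)
  perp <- points - outer(along, axis)
  rho <- sqrt(rowSums(perp^2))
  scale <- gamma_bar * B0 * delta_chi * 1e-6
  out <- numeric(nrow(points))
  inside <- rho <= R
  out[inside] <- scale * (3 * cos(th)^2 - 1) / 6
  if (any(!inside)) {
    # in-plane basis: e1 = projection of z (B0) into the perpendicular plane
    e1 <- c(0, 0, 1) - cos(th) * axis
    n1 <- sqrt(sum(e1^2))
    if (n1 < 1e-12) {
      out[!inside] <- 0                       # parallel: no external field
    } else {
      e1 <- e1 / n1
      e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
              axis[3] * e1[1] - axis[1] * e1[3],
              axis[1] * e1[2] - axis[2] * e1[1])
      c1 <- drop(perp %*% e1)[!inside]
      c2 <- drop(perp %*% e2)[!inside]
      phi <- atan2(c2, c1)
      out[!inside] <- scale / 2 * (R / rho[!inside])^2 * cos(2 * phi) * sin(th)^2
    }
  }
  out
}
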