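# 2D spin-echo / gradient-echo acquisition of one phantom slice:
# distorted slice selection, steady-state contrast, k-space synthesis from
# isochromats, and magnitude reconstruction.

#' Acquisition parameters for the ASTM artifact sequences
#'
#' Spin-echo defaults: TE 20 ms, flip 90 deg.  Gradient-echo defaults:
#' TE 15 ms, flip 30 deg.  Shared defaults: TR 500 ms, 256 x 256 matrix,
#' 3 mm slice, 130 Hz/px pixel bandwidth, 200 mm square FOV.
#'
#' @param kind `"SE"` or `"GRE"`.
#' @param te_ms Echo time (ms); default by `kind`.
#' @param tr_ms Repetition time (ms).
#' @param flip_deg Flip angle (deg); default by `kind`.
#' @param matrix_size Integer vector (N_freq, N_phase), entries >= 8.
#' @param slice_mm Slice thickness (mm).
#' @param px_bw_hz Pixel bandwidth along the frequency axis (Hz/px).
#' @param fov_mm Square field of view (mm).
#' @param phase_dir `"FH"` or `"AP"`: which in-plane grid axis is
#'   phase-encoded (a labeling convention; the other axis is
#'   frequency-encoded and carries the off-resonance displacement).
#' @param slice_orientation `"tra"` (normal z), `"cor"` (normal y) or
#'   `"sag"` (normal x).  The B0 axis is z.
#' @return An object of class `sequence_params`.
#' @examples
#' sequence_params("SE")
#' sequence_params("GRE", te_ms = 10)
#' @export
sequence_params <- function(kind = c("SE", "GRE"), te_ms = NULL, tr_ms = 500,
                            flip_deg = NULL, matrix_size = c(256L, 256L),
                            slice_mm = 3, px_bw_hz = 130, fov_mm = 200,
                            phase_dir = c("FH", "AP"),
                            slice_orientation = c("tra", "cor", "sag")) {
  kind <- match.arg(kind)
  phase_dir <- match.arg(phase_dir)
  slice_orientation <- match.arg(slice_orientation)
  if (is.null(te_ms)) te_ms <- if (kind == "SE") 20 else 15
  if (is.null(flip_deg)) flip_deg <- if (kind == "SE") 90 else 30
  matrix_size <- as.integer(rep_len(matrix_size, 2L))
  if (!(te_ms > 0 && te_ms < tr_ms)) stop("invalid sequence: need 0 < TE < TR")
  if (any(matrix_size < 8L)) stop("invalid sequence: matrix entries must be >= 8")
  if (px_bw_hz <= 0) stop("invalid sequence: 'px_bw_hz' must be > 0")
  if (fov_mm <= 0) stop("invalid sequence: 'fov_mm' must be > 0")
  if (slice_mm <= 0) stop("invalid sequence: 'slice_mm' must be > 0")
  structure(list(kind = kind, te_ms = te_ms, tr_ms = tr_ms,
                 flip_deg = flip_deg, matrix_size = matrix_size,
                 slice_mm = slice_mm, px_bw_hz = px_bw_hz, fov_mm = fov_mm,
                 phase_dir = phase_dir, slice_orientation = slice_orientation),
            class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf(paste0("<sequence_params> %s: TE %g ms, TR %g ms, flip %g deg, ",
                     "%d x %d, slice %g mm, %g Hz/px, FOV %g mm, %s/%s\n"),
              x$kind, x$te_ms, x$tr_ms, x$flip_deg, x$matrix_size[1],
              x$matrix_size[2], x$slice_mm, x$px_bw_hz, x$fov_mm,
              x$slice_orientation, x$phase_dir))
  invisible(x)
}

#' Image-axis assignment for a slice orientation
#'
#' Maps a slice orientation and phase-encode toggle to phantom grid axes
#' (1 = x, 2 = y, 3 = z; B0 along z).  `"FH"` phase-encodes the
#' higher-index in-plane axis (z when it lies in plane, else y), `"AP"` the
#' lower-index one; the remaining in-plane axis is frequency-encoded.
#'
#' @param slice_orientation `"tra"`, `"cor"` or `"sag"`.
#' @param phase_dir `"FH"` or `"AP"`.
#' @return List with integer axes `normal`, `freq`, `phase`.
#' @export
slice_axes <- function(slice_orientation, phase_dir = "FH") {
  normal <- switch(slice_orientation, tra = 3L, cor = 2L, sag = 1L,
                   stop("config error: unknown slice orientation"))
  inplane <- setdiff(1:3, normal)
  if (identical(phase_dir, "FH")) {
    list(normal = normal, freq = inplane[1L], phase = inplane[2L])
  } else if (identical(phase_dir, "AP")) {
    list(normal = normal, freq = inplane[2L], phase = inplane[1L])
  } else stop("config error: unknown phase direction")
}

#' Steady-state signal weight of a material
#'
#' Relaxation-weighted signal magnitude per unit proton density entering
#' the k-space synthesis.  Spin echo (ideal 90/180):
#' `M0 (1 - exp(-TR/T1)) exp(-TE/T2)`.  Spoiled gradient echo:
#' `M0 sin(a) (1 - E1) / (1 - cos(a) E1) exp(-TE/T2)` with
#' `E1 = exp(-TR/T1)`.  Off-resonance effects are handled explicitly in the
#' k-space model, not here.
#'
#' @param props A [material_props()].
#' @param params A [sequence_params()].
#' @return Unitless signal weight.
#' @examples
#' steady_state_signal(oil_material(), sequence_params("SE"))  # ~0.7976
#' @export
steady_state_signal <- function(props, params) {
  if (props$M0 == 0) return(0)
  E1 <- exp(-params$tr_ms / props$T1)
  e2 <- exp(-params$te_ms / props$T2)
  if (params$kind == "SE") {
    props$M0 * (1 - E1) * e2
  } else {
    a <- params$flip_deg * pi / 180
    props$M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1) * e2
  }
}

axis_field <- function(grid_shape, values, axis) {
  n1 <- grid_shape[1L]; n2 <- grid_shape[2L]; n3 <- grid_shape[3L]
  if (axis == 1L) array(rep(values, times = n2 * n3), dim = grid_shape)
  else if (axis == 2L) array(rep(rep(values, each = n1), times = n3), dim = grid_shape)
  else array(rep(values, each = n1 * n2), dim = grid_shape)
}

#' Distorted slice-selection weights
#'
#' An isochromat at position `s` along the slice normal with off-resonance
#' `delta_f` is excited iff
#' `|gamma_bar Gs (s - s0) + delta_f| < gamma_bar Gs thickness/2`
#' (ideal rectangular RF profile, strict inequality at the edge);
#' equivalently it behaves as if located at `s + delta_f / (gamma_bar Gs)`.
#' Off-resonance therefore bends and shifts the excited slab.
#'
#' @param phantom A [build_phantom()] object supplying grid and voxel size.
#' @param params A [sequence_params()].
#' @param field Optional [compute_offresonance()] result (or `NULL` for an
#'   on-resonance slab).
#' @param Gs Slice-select gradient in mT/m, > 0.
#' @param slice_center Slice center along the normal (mm).
#' @param gamma_bar Gyromagnetic ratio / 2 pi in Hz/T.
#' @return Logical array of excitation weights on the phantom grid.
#' @export
select_slice <- function(phantom, params, field = NULL, Gs = 10,
                         slice_center = 0, gamma_bar = GAMMA_BAR_HZ_PER_T) {
  if (!is.numeric(Gs) || Gs <= 0) stop("config error: 'Gs' must be > 0 (mT/m)")
  ax <- slice_axes(params$slice_orientation, params$phase_dir)
  gshz <- gamma_bar * Gs * 1e-6                 # Hz per mm
  half <- gshz * params$slice_mm / 2
  s <- grid_axis(phantom$grid_shape[ax$normal], phantom$voxel_size) - slice_center
  if (is.null(field)) {
    axis_field(phantom$grid_shape, abs(gshz * s) < half, ax$normal)
  } else {
    stopifnot(identical(dim(field$delta_f), as.integer(phantom$grid_shape)))
    S <- axis_field(phantom$grid_shape, gshz * s, ax$normal)
    abs(S + field$delta_f) < half
  }
}

#' Synthesize k-space from excited isochromats
#'
#' Each excited isochromat at in-plane position (u, v) with static
#' off-resonance `df` contributes
#' `amp * exp(-i 2 pi (k_n u + k_m v)) * exp(-i phi(t_n))` with
#' `phi(t) = 2 pi df t` for GRE (time from excitation) and
#' `phi(t) = 2 pi df (t - TE)` for SE (refocused at the echo center).
#' Because `df` is constant during the readout, the readout phase is
#' exactly linear in the sample index and is identical to shifting the
#' isochromat to `u + df / px_bw * pixel` along the frequency axis; GRE
#' additionally carries the static phase `exp(-i 2 pi df TE)`.  The
#' synthesis is therefore closed-form.  Isochromats displaced outside the
#' readout band (|u_eff| > FOV/2) are removed, modelling the anti-alias
#' readout filter.  Phase encoding is ideal (no distortion along v).
#'
#' @param iso List or data frame with numeric `u`, `v` (mm, frequency and
#'   phase-axis positions), `df` (Hz) and `amp` (real or complex).
#' @param params A [sequence_params()].
#' @param method `"grid"` (oversampled linear-interpolation gridding with
#'   sinc^2 roll-off correction; default) or `"exact"` (direct DFT; slow,
#'   used to verify the gridding accuracy contract).
#' @param oversample Gridding oversampling factors (frequency, phase).
#' @return An object of class `kspace_data` (complex N_freq x N_phase
#'   matrix plus the integer k indices).
#' @export
simulate_kspace <- function(iso, params, method = c("grid", "exact"),
                            oversample = c(8L, 4L)) {
  method <- match.arg(method)
  n <- length(iso$u)
  if (length(iso$v) != n || length(iso$df) != n || length(iso$amp) != n) {
    stop("dimension error: isochromat fields must share one length")
  }
  Nf <- params$matrix_size[1L]; Np <- params$matrix_size[2L]
  fov <- params$fov_mm
  px <- fov / Nf
  amp <- as.complex(iso$amp)
  if (params$kind == "GRE") amp <- amp * exp(-2i * pi * iso$df * params$te_ms * 1e-3)
  u <- iso$u + iso$df / params$px_bw_hz * px
  v <- iso$v
  keep <- abs(u) <= fov / 2 & abs(v) <= fov / 2
  u <- u[keep]; v <- v[keep]; amp <- amp[keep]
  kn <- seq.int(-(Nf %/% 2), Nf %/% 2 - 1L)
  km <- seq.int(-(Np %/% 2), Np %/% 2 - 1L)
  if (method == "exact") {
    S <- matrix(0 + 0i, Nf, Np)
    for (a in seq_along(kn)) {
      w <- amp * exp(-2i * pi * kn[a] * u / fov)
      for (b in seq_along(km)) S[a, b] <- sum(w * exp(-2i * pi * km[b] * v / fov))
    }
  } else {
    Mx <- next_smooth(as.integer(oversample[1L]) * Nf)
    My <- next_smooth(as.integer(oversample[2L]) * Np)
    S <- grid_synthesis(u, v, amp, kn, km, fov, Mx, My)
  }
  structure(list(kspace = S, kn = kn, km = km, params = params),
            class = "kspace_data")
}

# Gridding of point sources onto an oversampled grid with a cubic
# B-spline deposition kernel, FFT, crop to the sampled k lines, undo the
# bin-origin phase and the kernel's sinc^4 roll-off.  At 8x / 4x
# oversampling the residual aliasing of the B-spline spectrum stays below
# 0.1% of the image peak (verified against the exact per-isochromat DFT).
grid_synthesis <- function(u, v, amp, kn, km, fov, Mx, My) {
  dx <- fov / Mx; dy <- fov / My
  x1 <- -(Mx - 1) / 2 * dx; y1 <- -(My - 1) / 2 * dy
  bspline3 <- function(t) {
    # weights for taps at distances t+1, t, 1-t, 2-t (t in [0,1))
    cbind((1 - t)^3 / 6,
          2 / 3 - t^2 + t^3 / 2,
          2 / 3 - (1 - t)^2 + (1 - t)^3 / 2,
          t^3 / 6)
  }
  tx <- (u - x1) / dx
  ty <- (v - y1) / dy
  jx <- pmin(pmax(floor(tx), 1), Mx - 3); fx <- tx - jx
  jy <- pmin(pmax(floor(ty), 1), My - 3); fy <- ty - jy
  wxm <- bspline3(fx)
  wym <- bspline3(fy)
  gacc <- complex(Mx * My)
  for (cx in 0:3) for (cy in 0:3) {
    w <- wxm[, cx + 1L] * wym[, cy + 1L]
    id <- as.integer(jx + cx + (jy + cy - 1L) * Mx)
    val <- amp * w
    # duplicate-safe accumulation: radix sort then run-wise cumsum
    o <- sort.int(id, method = "radix", index.return = TRUE)
    cs <- cumsum(val[o$ix])
    ends <- c(which(diff(o$x) != 0L), length(o$x))
    at <- o$x[ends]
    gacc[at] <- gacc[at] + diff(c(0 + 0i, cs[ends]))
  }
  g <- matrix(gacc, Mx, My)
  G <- stats::fft(g)
  ix <- (kn %% Mx) + 1L
  iy <- (km %% My) + 1L
  S <- G[ix, iy, drop = FALSE]
  phx <- exp(-2i * pi * kn * x1 / fov)
  phy <- exp(-2i * pi * km * y1 / fov)
  sx <- pi * kn / Mx; wx <- ifelse(kn == 0, 1, (sin(sx) / sx)^4)
  sy <- pi * km / My; wy <- ifelse(km == 0, 1, (sin(sy) / sy)^4)
  S <- S * outer(phx / wx, phy / wy)
  S
}

#' Reconstruct a magnitude image from full rectangular k-space
#'
#' Inverse 2D discrete Fourier transform evaluated at the image pixel
#' centers; no distortion correction or acceleration.
#'
#' @param kspace A `kspace_data` object.
#' @param provenance Optional list recorded on the image.
#' @return An object of class `simulated_image`: complex matrix `data`
#'   (N_freq x N_phase), `pixel_mm`, `params`, `provenance`.  Use
#'   [magnitude()] for the magnitude view.
#' @export
reconstruct <- function(kspace, provenance = list()) {
  if (!inherits(kspace, "kspace_data")) {
    if (is.matrix(kspace) && is.complex(kspace)) {
      Nf <- nrow(kspace); Np <- ncol(kspace)
      kspace <- structure(list(kspace = kspace,
                               kn = seq.int(-(Nf %/% 2), Nf %/% 2 - 1L),
                               km = seq.int(-(Np %/% 2), Np %/% 2 - 1L),
                               params = sequence_params("SE", matrix_size = c(Nf, Np))),
                          class = "kspace_data")
    } else stop("dimension error: need a kspace_data object or complex matrix")
  }
  p <- kspace$params
  Nf <- p$matrix_size[1L]; Np <- p$matrix_size[2L]; fov <- p$fov_mm
  if (!identical(dim(kspace$kspace), c(Nf, Np))) {
    stop("dimension error: non-rectangular k-space")
  }
  xp <- grid_axis(Nf, fov / Nf)
  yq <- grid_axis(Np, fov / Np)
  A <- exp(2i * pi * outer(kspace$kn, xp) / fov)
  B <- exp(2i * pi * outer(kspace$km, yq) / fov)
  img <- (t(A) %*% kspace$kspace %*% B) / (Nf * Np)
  structure(list(data = img, pixel_mm = c(fov / Nf, fov / Np), params = p,
                 provenance = provenance),
            class = "simulated_image")
}

#' Magnitude view of a simulated image
#' @param image A `simulated_image`.
#' @return Numeric matrix of magnitudes.
#' @export
magnitude <- function(image) Mod(image$data)

#' @export
print.simulated_image <- function(x, ...) {
  cat(sprintf("<simulated_image> %d x %d px (%.4g x %.4g mm), %s%s\n",
              nrow(x$data), ncol(x$data), x$pixel_mm[1], x$pixel_mm[2],
              x$params$kind,
              if (length(x$provenance)) paste0(", B0 = ", x$provenance$B0, " T") else ""))
  invisible(x)
}

# Collect excited, signal-bearing isochromats for one slice.
# Returns physical coordinates along all three grid axes plus df and amp.
extract_isochromats <- function(phantom, normal_axis, slice_mm, df_arr = NULL,
                                Gs = 10, slice_center = 0, amp_bg = 1,
                                amp_obj = 0, gamma_bar = GAMMA_BAR_HZ_PER_T) {
  gs <- phantom$grid_shape
  h <- phantom$voxel_size
  gshz <- gamma_bar * Gs * 1e-6
  half <- gshz * slice_mm / 2
  s <- grid_axis(gs[normal_axis], h) - slice_center
  label <- phantom$label
  if (is.null(df_arr)) {
    exc <- axis_field(gs, abs(gshz * s) < half, normal_axis)
  } else {
    exc <- abs(axis_field(gs, gshz * s, normal_axis) + df_arr) < half
  }
  if (!is.null(label) && amp_obj == 0) exc <- exc & !label
  idx <- which(exc)
  ijk <- arrayInd(idx, gs)
  amp <- rep(amp_bg, length(idx))
  if (!is.null(label) && amp_obj != 0) amp[label[idx]] <- amp_obj
  list(coord = lapply(1:3, function(a) grid_axis(gs[a], h)[ijk[, a]]),
       df = if (is.null(df_arr)) numeric(length(idx)) else df_arr[idx],
       amp = amp)
}

#' Simulate one 2D acquisition of the phantom
#'
#' Orchestrates the full chain: off-resonance field (for the with-object
#' image), distorted slice selection, steady-state contrast, k-space
#' synthesis and reconstruction.  With `with_object = FALSE` the object is
#' removed entirely (the ASTM reference image) on the identical grid and
#' demodulation.  Isochromats are the native phantom voxels (at the
#' default 2 voxels/mm this gives 6 sub-samples across a 3 mm slice).
#'
#' @param phantom A [build_phantom()] object.
#' @param params A [sequence_params()].
#' @param B0 Field strength (T).
#' @param with_object Simulate with the test object (`TRUE`) or the
#'   reference without it (`FALSE`).
#' @param field Optional precomputed [compute_offresonance()] result for
#'   this phantom and B0 (the field is expensive; callers running many
#'   sequences reuse it).
#' @param Gs Slice-select gradient (mT/m).
#' @param slice_center Slice center along the normal (mm); 0 is the center
#'   slice through the test object.
#' @param method k-space synthesis method, see [simulate_kspace()].
#' @param noise_sd Standard deviation of optional complex Gaussian k-space
#'   noise relative to the k-space center magnitude; 0 (default) is
#'   noiseless and fully deterministic.
#' @param noise_seed RNG seed used iff `noise_sd > 0`.
#' @param gamma_bar Gyromagnetic ratio / 2 pi in Hz/T.
#' @return A `simulated_image`.
#' @export
simulate_image <- function(phantom, params, B0, with_object = TRUE,
                           field = NULL, Gs = 10, slice_center = 0,
                           method = "grid", noise_sd = 0, noise_seed = NULL,
                           gamma_bar = GAMMA_BAR_HZ_PER_T) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(params, "sequence_params"))
  if (!is.numeric(B0) || B0 <= 0) stop("'B0' must be > 0 (tesla)")
  ax <- slice_axes(params$slice_orientation, params$phase_dir)
  has_object <- with_object && !is.null(phantom$label) && any(phantom$label)
  df_arr <- NULL
  if (has_object) {
    if (is.null(field)) {
      field <- compute_offresonance(phantom_map(phantom, "chi"), B0,
                                    phantom$voxel_size,
                                    background = !phantom_labels(phantom),
                                    gamma_bar = gamma_bar)
    }
    stopifnot(inherits(field, "field_map"),
              identical(dim(field$delta_f), as.integer(phantom$grid_shape)))
    df_arr <- field$delta_f
  }
  amp_bg <- steady_state_signal(phantom$background, params)
  amp_obj <- if (has_object) steady_state_signal(phantom$object, params) else 0
  iso <- extract_isochromats(
    if (has_object) phantom else build_phantom_like(phantom),
    ax$normal, params$slice_mm, df_arr, Gs, slice_center, amp_bg, amp_obj,
    gamma_bar)
  ks <- simulate_kspace(list(u = iso$coord[[ax$freq]], v = iso$coord[[ax$phase]],
                             df = iso$df, amp = iso$amp),
                        params, method = method)
  if (noise_sd > 0) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    s0 <- Mod(ks$kspace[ks$kn == 0, ks$km == 0])
    nmat <- matrix(complex(real = stats::rnorm(length(ks$kspace)),
                           imaginary = stats::rnorm(length(ks$kspace))),
                   nrow(ks$kspace))
    ks$kspace <- ks$kspace + noise_sd * s0 * nmat
  }
  reconstruct(ks, provenance = list(
    B0 = B0, with_object = with_object, Gs = Gs, slice_center = slice_center,
    phantom = list(grid_shape = phantom$grid_shape, voxel_size = phantom$voxel_size,
                   background = phantom$background$name,
                   object = if (has_object) phantom$object$name else NA_character_)))
}

# background-only copy of a phantom (for reference acquisitions)
build_phantom_like <- function(phantom) {
  p <- phantom
  p$label <- NULL
  p$object <- NULL
  p
}

#' Export a simulated image
#'
#' `write_image_nifti()` writes the magnitude as NIfTI-1;
#' `write_image_png()` writes a window-normalized 8-bit PNG quick-look;
#' `write_image_tiff()` writes a window-normalized 16-bit TIFF.
#'
#' @param image A `simulated_image` (or numeric matrix for the PNG/TIFF
#'   writers).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image_nifti <- function(image, path) {
  write_volume_nifti(magnitude(image), image$pixel_mm[1L], path)
}

#' @rdname write_image_nifti
#' @export
write_image_png <- function(image, path) {
  m <- if (inherits(image, "simulated_image")) magnitude(image) else image
  rng <- range(m)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  png::writePNG(t(m - rng[1]) / diff(rng), path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
write_image_tiff <- function(image, path) {
  m <- if (inherits(image, "simulated_image")) magnitude(image) else image
  rng <- range(m)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  tiff::writeTIFF(t(m - rng[1]) / diff(rng), path, bits.per.sample = 16L)
  invisible(path)
}
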