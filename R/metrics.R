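# ASTM F2119 artifact quantification: relative signal-change image, 30%
# mask, areas, one-pixel erosion/dilation bounds, centroid overlay and the
# intersection-over-union similarity factor.

#' Relative signal-change image
#'
#' Elementwise `(S_TO - S_ref) / S_ref`.  Pixels whose reference signal
#' falls below a floor `eps = eps_rel * max(S_ref)` are flagged as infinite
#' relative change (they threshold as artifact: an unbounded change is
#' "more than 30%").
#'
#' @param s_to Magnitude image with the test object (matrix).
#' @param s_ref Reference magnitude image without it; same shape, values
#'   >= 0.
#' @param eps_rel Relative reference floor.
#' @return Matrix of relative changes (possibly `Inf` at floored pixels).
#' @export
artifact_image <- function(s_to, s_ref, eps_rel = 1e-6) {
  if (!identical(dim(s_to), dim(s_ref))) {
    stop("dimension error: images must share one shape")
  }
  if (any(s_ref < 0)) stop("'s_ref' must be non-negative")
  eps <- eps_rel * max(s_ref)
  out <- (s_to - s_ref) / s_ref
  out[s_ref < eps] <- Inf
  out
}

#' Threshold a signal-change map into an artifact mask
#'
#' A pixel is artifact iff its absolute relative change is strictly
#' greater than the threshold ("more than 30%": a change of exactly 0.30
#' is not artifact).
#'
#' @param change_map Matrix from [artifact_image()].
#' @param threshold Fraction in (0, 1]; default 0.30 per ASTM F2119.
#' @param pixel_mm Pixel edge length (mm), recorded on the mask.
#' @return Logical matrix of class `artifact_mask` with attribute
#'   `pixel_mm`.
#' @export
threshold_mask <- function(change_map, threshold = 0.30, pixel_mm = NA_real_) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("config error: 'threshold' must lie in (0, 1]")
  }
  m <- abs(change_map) > threshold
  m[is.na(m)] <- TRUE                   # 0/0 pixels count as artifact
  structure(m, pixel_mm = pixel_mm, class = c("artifact_mask", "matrix"))
}

as_artifact_mask <- function(m, pixel_mm = NA_real_) {
  structure(as.matrix(m) & TRUE, pixel_mm = pixel_mm,
            class = c("artifact_mask", "matrix"))
}

#' Artifact area in pixels and mm^2
#'
#' @param mask An `artifact_mask` (or logical matrix plus `pixel_mm`).
#' @param pixel_mm Pixel edge (mm); taken from the mask attribute when
#'   missing.
#' @return List with `area_px` and `area_mm2`.
#' @export
artifact_area <- function(mask, pixel_mm = NULL) {
  if (is.null(pixel_mm)) pixel_mm <- attr(mask, "pixel_mm")
  n <- sum(mask)
  list(area_px = as.integer(n),
       area_mm2 = if (is.null(pixel_mm) || is.na(pixel_mm)) NA_real_ else n * pixel_mm^2)
}

shift_mask <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  oki <- si >= 1 & si <= nrow(m)
  okj <- sj >= 1 & sj <= ncol(m)
  out[oki, okj] <- m[si[oki], sj[okj], drop = FALSE]
  out
}

morph_offsets <- function(connectivity) {
  if (connectivity == 8L) expand.grid(di = -1:1, dj = -1:1)
  else if (connectivity == 4L) data.frame(di = c(0, -1, 0, 1, 0), dj = c(0, 0, -1, 0, 1))
  else stop("config error: connectivity must be 4 or 8")
}

#' One-pixel artifact-size uncertainty bounds
#'
#' Binary erosion and dilation by one pixel "in every direction" (3 x 3
#' square structuring element by default, i.e. including diagonals; a
#' 4-connected cross is available).  Dilation is clipped at the image edge;
#' erosion treats outside pixels as background.  The eroded count is the
#' lower and the dilated count the upper bound of the artifact size.
#'
#' @param mask An `artifact_mask` or logical matrix.
#' @param connectivity 8 (3 x 3 square, default) or 4 (cross).
#' @return List with `area_eroded_px` and `area_dilated_px`.
#' @export
one_pixel_bounds <- function(mask, connectivity = 8L) {
  off <- morph_offsets(as.integer(connectivity))
  m <- unclass(mask) & TRUE
  ero <- Reduce(`&`, Map(function(di, dj) shift_mask(m, di, dj), off$di, off$dj))
  dil <- Reduce(`|`, Map(function(di, dj) shift_mask(m, di, dj), off$di, off$dj))
  list(area_eroded_px = as.integer(sum(ero)),
       area_dilated_px = as.integer(sum(dil)))
}

#' @rdname one_pixel_bounds
#' @param what `"erode"` or `"dilate"`: return the morphed mask itself.
#' @export
morph_mask <- function(mask, what = c("erode", "dilate"), connectivity = 8L) {
  what <- match.arg(what)
  off <- morph_offsets(as.integer(connectivity))
  m <- unclass(mask) & TRUE
  op <- if (what == "erode") `&` else `|`
  out <- Reduce(op, Map(function(di, dj) shift_mask(m, di, dj), off$di, off$dj))
  as_artifact_mask(out, attr(mask, "pixel_mm"))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

mask_centroid <- function(mask) {
  idx <- which(unclass(mask) & TRUE, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("alignment error: mask is empty")
  colMeans(idx)
}

#' Translate one mask onto another by artifact centroid
#'
#' Shifts `mask_b` by the rounded (half away from zero) integer difference
#' of the two center-of-mass positions, superimposing the artifact
#' centers.  Pixels shifted off-grid are dropped.
#'
#' @param mask_a,mask_b Non-empty logical matrices of one shape.
#' @return The shifted `mask_b` as an `artifact_mask`.
#' @export
align_by_centroid <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("dimension error: masks must share one shape")
  }
  d <- mask_centroid(mask_a) - mask_centroid(mask_b)
  s <- round_half_away(d)
  as_artifact_mask(shift_mask(unclass(mask_b) & TRUE, s[1L], s[2L]),
                   attr(mask_b, "pixel_mm"))
}

#' Similarity factor of two artifact masks
#'
#' Number of overlapping pixels divided by the number of pixels belonging
#' to either artifact (intersection over union), after centroid
#' superimposition by default.
#'
#' @param mask_a,mask_b Logical matrices of one shape; not both empty.
#' @param align Superimpose `mask_b` on `mask_a` by centroid first
#'   (default); disable for masks already on a common grid.
#' @return Fraction in [0, 1]; 1 iff the (aligned) masks are identical.
#' @export
similarity_factor <- function(mask_a, mask_b, align = TRUE) {
  a <- unclass(mask_a) & TRUE
  b <- unclass(mask_b) & TRUE
  if (!identical(dim(a), dim(b))) stop("dimension error: masks must share one shape")
  if (!any(a) && !any(b)) stop("similarity undefined: both masks are empty")
  if (align && any(a) && any(b)) b <- unclass(align_by_centroid(a, b)) & TRUE
  sum(a & b) / sum(a | b)
}

#' Three-class overlay of two artifact masks
#'
#' Partitions the union of two (aligned) masks into congruent pixels and
#' pixels unique to either mask, as in overlay figures (red = both,
#' yellow = only A, blue = only B).
#'
#' @param mask_a,mask_b Logical matrices of one shape.
#' @return Integer matrix with levels 0 = neither, 1 = both, 2 = only_a,
#'   3 = only_b, plus a `counts` attribute.
#' @export
overlay_classes <- function(mask_a, mask_b) {
  a <- unclass(mask_a) & TRUE
  b <- unclass(mask_b) & TRUE
  if (!identical(dim(a), dim(b))) stop("dimension error: masks must share one shape")
  out <- matrix(0L, nrow(a), ncol(a))
  out[a & b] <- 1L
  out[a & !b] <- 2L
  out[!a & b] <- 3L
  attr(out, "counts") <- c(both = sum(a & b), only_a = sum(a & !b),
                           only_b = sum(!a & b))
  out
}

#' Evaluate an acquisition pair into an ASTM artifact result
#'
#' Computes the relative-change image, thresholds it at 30%, and attaches
#' areas and one-pixel bounds.  The mask is evaluated on the reference
#' signal support (pixels with at least `support_frac` of the maximum
#' reference magnitude): outside the phantom both images are essentially
#' zero and their ratio is meaningless, exactly as noise-floor pixels are
#' excluded when evaluating measured images.
#'
#' @param img_to,img_ref `simulated_image` objects (or magnitude matrices)
#'   on one grid.
#' @param threshold Signal-change threshold (default 0.30).
#' @param support_frac Reference-support fraction (default 0.1).
#' @param pixel_mm Pixel size override (mm).
#' @return Object of class `artifact_result`: `mask`, `area_px`,
#'   `area_mm2`, `area_eroded_px`, `area_dilated_px`, `change_map`.
#' @export
evaluate_artifact <- function(img_to, img_ref, threshold = 0.30,
                              support_frac = 0.1, pixel_mm = NULL) {
  s_to <- if (inherits(img_to, "simulated_image")) magnitude(img_to) else img_to
  s_ref <- if (inherits(img_ref, "simulated_image")) magnitude(img_ref) else img_ref
  if (is.null(pixel_mm)) {
    pixel_mm <- if (inherits(img_to, "simulated_image")) img_to$pixel_mm[1L] else NA_real_
  }
  change <- artifact_image(s_to, s_ref)
  mask <- threshold_mask(change, threshold, pixel_mm)
  support <- s_ref >= support_frac * max(s_ref)
  mask[!support] <- FALSE
  ar <- artifact_area(mask)
  b <- one_pixel_bounds(mask)
  structure(list(mask = mask, area_px = ar$area_px, area_mm2 = ar$area_mm2,
                 area_eroded_px = b$area_eroded_px,
                 area_dilated_px = b$area_dilated_px,
                 change_map = change),
            class = "artifact_result")
}

#' @export
print.artifact_result <- function(x, ...) {
  cat(sprintf("<artifact_result> %d px (%.2f mm^2), one-pixel bounds [%d, %d] px\n",
              x$area_px, x$area_mm2, x$area_eroded_px, x$area_dilated_px))
  invisible(x)
}

#' Export masks and overlays
#'
#' `write_mask_png()` writes a binary mask; `write_overlay_png()` colors an
#' [overlay_classes()] map red (both), yellow (only A) and blue (only B);
#' `write_mask_nifti()` writes the mask as NIfTI-1.
#'
#' @param mask An `artifact_mask`.
#' @param overlay An [overlay_classes()] matrix.
#' @param path Output path.
#' @param pixel_mm Pixel size for the NIfTI header.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(t(matrix(as.numeric(mask), nrow(mask))), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
write_overlay_png <- function(overlay, path) {
  cols <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 1))
  arr <- array(0, dim = c(ncol(overlay), nrow(overlay), 3L))
  for (ch in 1:3) arr[, , ch] <- t(matrix(cols[overlay + 1L, ch], nrow(overlay)))
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
write_mask_nifti <- function(mask, path, pixel_mm = attr(mask, "pixel_mm")) {
  write_volume_nifti(matrix(as.numeric(mask), nrow(mask)),
                     if (is.null(pixel_mm) || is.na(pixel_mm)) 1 else pixel_mm,
                     path)
}
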