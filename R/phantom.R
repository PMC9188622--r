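# Voxelized numerical phantom: a homogeneous background medium with one
# posed test object, on an isotropic centered grid.

#' Build a voxelized phantom with a posed test object
#'
#' Fills a cubic grid with the background material and overwrites the
#' voxels of `object_mask` with the object material.  Property maps are
#' stored compactly (label mask + the two property sets); use
#' [phantom_map()] to materialize a full 3D scalar field.
#'
#' @param phantom_edge Cube edge length in mm (default 150).
#' @param resolution Spatial resolution in voxels per mm (default 2, i.e.
#'   0.5 mm voxels).
#' @param background A [material_props()] for the background medium.
#' @param object_mask Optional logical array (grid occupancy of the test
#'   object); `NULL` for an empty phantom.
#' @param object_props [material_props()] of the test object (required when
#'   `object_mask` is given).
#' @return An object of class `voxel_phantom` with fields `grid_shape`,
#'   `voxel_size` (mm), `background`, `object`, `label` (logical array or
#'   `NULL`).
#' @examples
#' ph <- build_phantom(20, 2, oil_material())
#' dim(phantom_map(ph, "chi"))
#' @export
build_phantom <- function(phantom_edge = 150, resolution = 2,
                          background = oil_material(),
                          object_mask = NULL, object_props = NULL) {
  if (!is.numeric(resolution) || resolution <= 0) stop("'resolution' must be > 0")
  if (!is.numeric(phantom_edge) || phantom_edge <= 0) stop("'phantom_edge' must be > 0")
  stopifnot(inherits(background, "material_props"))
  n <- as.integer(round(phantom_edge * resolution))
  grid_shape <- c(n, n, n)
  if (!is.null(object_mask)) {
    if (!identical(dim(object_mask), as.integer(grid_shape))) {
      stop("dimension error: 'object_mask' does not match the phantom grid")
    }
    if (is.null(object_props)) stop("'object_props' required with 'object_mask'")
    stopifnot(inherits(object_props, "material_props"))
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size = 1 / resolution,
                 phantom_edge = phantom_edge,
                 background = background,
                 object = object_props,
                 label = object_mask),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels at %.4g mm, background '%s'",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size, x$background$name))
  if (!is.null(x$object)) {
    cat(sprintf(", object '%s' (%d voxels)", x$object$name, sum(x$label)))
  }
  cat("\n")
  invisible(x)
}

#' Materialize a phantom property map
#'
#' @param phantom A `voxel_phantom`.
#' @param what One of `"chi"`, `"T1"`, `"T2"`, `"M0"`.
#' @return A 3D numeric array on the phantom grid.
#' @export
phantom_map <- function(phantom, what = c("chi", "T1", "T2", "M0")) {
  what <- match.arg(what)
  out <- array(phantom$background[[what]], dim = phantom$grid_shape)
  if (!is.null(phantom$label)) out[phantom$label] <- phantom$object[[what]]
  out
}

#' Phantom label map (TRUE = object voxel)
#'
#' @param phantom A `voxel_phantom`.
#' @return Logical array on the phantom grid.
#' @export
phantom_labels <- function(phantom) {
  if (is.null(phantom$label)) array(FALSE, dim = phantom$grid_shape) else phantom$label
}

#' Export phantom property maps as NIfTI-1 volumes
#'
#' Writes one file per property (`<prefix>_chi.nii.gz`, etc.) with the
#' voxel size recorded in the header.
#'
#' @param phantom A `voxel_phantom`.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  paths <- character(0)
  for (what in c("chi", "T1", "T2", "M0")) {
    p <- paste0(prefix, "_", what, ".nii.gz")
    write_volume_nifti(phantom_map(phantom, what), phantom$voxel_size, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

write_volume_nifti <- function(arr, voxel_size, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size, length(dim(arr)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
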