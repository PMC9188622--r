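#' Material properties for phantom and test objects
#'
#' Bundle the MR-relevant bulk properties of a material: magnetic
#' susceptibility `chi` (ppm), longitudinal and transverse relaxation times
#' `T1` and `T2` (ms), and relative proton density `M0`.
#'
#' @param name Material name (single string).
#' @param chi Magnetic susceptibility in ppm (dimensionless x 1e-6). Must be
#'   finite.
#' @param T1 Longitudinal relaxation time in ms, > 0.
#' @param T2 Transverse relaxation time in ms, > 0.
#' @param M0 Relative proton density, >= 0. Metals carry `M0 = 0`: they give
#'   no MR signal, only a susceptibility source.
#' @return An object of class `material_props`.
#' @examples
#' oil <- material_props("oil", chi = -8.8, T1 = 90, T2 = 90, M0 = 1)
#' @export
material_props <- function(name, chi, T1, T2, M0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(chi) || length(chi) != 1L || !is.finite(chi)) {
    stop("'chi' must be a finite number (ppm)")
  }
  if (!is.numeric(T1) || T1 <= 0) stop("'T1' must be > 0 (ms)")
  if (!is.numeric(T2) || T2 <= 0) stop("'T2' must be > 0 (ms)")
  if (!is.numeric(M0) || M0 < 0) stop("'M0' must be >= 0")
  structure(list(name = name, chi = chi, T1 = T1, T2 = T2, M0 = M0),
            class = "material_props")
}

#' @export
print.material_props <- function(x, ...) {
  cat(sprintf("<material_props> %s: chi = %g ppm, T1 = %g ms, T2 = %g ms, M0 = %g\n",
              x$name, x$chi, x$T1, x$T2, x$M0))
  invisible(x)
}

#' Reference materials for the rod-in-oil experiment
#'
#' The study conditions use a vegetable-oil background (chi = -8.8 ppm,
#' T1 = T2 = 90 ms, M0 = 1) and cylindrical rods of grade-2 titanium
#' (chi = 182 ppm) or austenitic stainless steel (chi = 3500 ppm).  The
#' metals are modelled as signal-free (`M0 = 0`); their T1/T2 are set to the
#' background values and never enter the signal model.
#'
#' @return A `material_props` object.
#' @export
oil_material <- function() material_props("oil", chi = -8.8, T1 = 90, T2 = 90, M0 = 1)

#' @rdname oil_material
#' @export
titanium_material <- function() material_props("titanium", chi = 182, T1 = 90, T2 = 90, M0 = 0)

#' @rdname oil_material
#' @export
steel_material <- function() material_props("stainless_steel", chi = 3500, T1 = 90, T2 = 90, M0 = 0)
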