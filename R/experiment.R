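# Experiment orchestration: configuration files, fixture generation, the
# full acquisition grid and the cross-field scaling report.

fixture_material_by_name <- function(name) {
  switch(name,
         oil = oil_material(),
         titanium = titanium_material(),
         stainless_steel = ,
         steel = steel_material(),
         plastic = material_props("plastic", chi = -8.8, T1 = 90, T2 = 90, M0 = 0),
         stop(sprintf("config error: unknown material '%s'", name)))
}

config_schema <- c("material", "b0", "sequence", "te_ms", "tr_ms", "flip_deg",
                   "matrix", "slice_mm", "px_bw_hz", "fov_mm", "phase_dir",
                   "slice_orientation", "to_orientation", "gs_mt_m",
                   "phantom_edge_mm", "resolution_px_mm", "rod_diameter_mm",
                   "rod_length_mm", "chi_ppm", "t1_ms", "t2_ms", "m0")

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration, rejects unknown keys, and fills defaults:
#' the ASTM sequence parameter set (SE: TE 20 ms, flip 90; GRE: TE 15 ms,
#' flip 30; TR 500 ms, 256 matrix, 3 mm slice, 130 Hz/px, 200 mm FOV), the
#' 150 mm / 2 px-per-mm phantom, and the named fixture materials.
#'
#' @param path Path to a YAML file (or a named list already in memory).
#' @return A validated list with elements `material` ([material_props()]),
#'   `b0`, `params` ([sequence_params()]), `to_orientation`, `gs_mt_m`,
#'   `phantom_edge_mm`, `resolution_px_mm`, `rod_diameter_mm`,
#'   `rod_length_mm`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop(sprintf("config error: no such file '%s'", path))
    yaml::read_yaml(path)
  } else as.list(path)
  bad <- setdiff(names(cfg), config_schema)
  if (length(bad)) {
    stop(sprintf("config error: unknown key%s: %s",
                 if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")))
  }
  need <- setdiff(c("material", "b0", "sequence"), names(cfg))
  if (length(need)) {
    stop(sprintf("config error: missing key%s: %s",
                 if (length(need) > 1) "s" else "", paste(need, collapse = ", ")))
  }
  if (!cfg$sequence %in% c("SE", "GRE")) {
    stop(sprintf("config error: unknown sequence kind '%s'", cfg$sequence))
  }
  material <- if (!is.null(cfg$chi_ppm)) {
    material_props(cfg$material, cfg$chi_ppm,
                   cfg$t1_ms %||% 90, cfg$t2_ms %||% 90, cfg$m0 %||% 0)
  } else fixture_material_by_name(cfg$material)
  params <- sequence_params(
    kind = cfg$sequence,
    te_ms = cfg$te_ms %||% NULL,
    tr_ms = cfg$tr_ms %||% 500,
    flip_deg = cfg$flip_deg %||% NULL,
    matrix_size = cfg$matrix %||% c(256L, 256L),
    slice_mm = cfg$slice_mm %||% 3,
    px_bw_hz = cfg$px_bw_hz %||% 130,
    fov_mm = cfg$fov_mm %||% 200,
    phase_dir = cfg$phase_dir %||% "FH",
    slice_orientation = cfg$slice_orientation %||% "tra")
  list(material = material,
       b0 = as.numeric(cfg$b0),
       params = params,
       to_orientation = cfg$to_orientation %||% "parallel",
       gs_mt_m = cfg$gs_mt_m %||% 10,
       phantom_edge_mm = cfg$phantom_edge_mm %||% 150,
       resolution_px_mm = cfg$resolution_px_mm %||% 2,
       rod_diameter_mm = cfg$rod_diameter_mm %||% 3,
       rod_length_mm = cfg$rod_length_mm %||% 15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The experiment grid of the rod study
#'
#' Per test object and field strength: 2 sequences x 2 rod orientations x
#' 2 slice orientations x 2 phase-encode directions = 16 configurations.
#' Slice orientations depend on the rod orientation (one of the three
#' planes is redundant under the rod's rotational symmetry): a parallel
#' rod (axis along B0/z) uses transverse and coronal slices, a
#' perpendicular rod (axis along x) uses sagittal (rod cross-section) and
#' coronal (plane containing rod axis and B0) slices.
#'
#' @param materials List of test-object [material_props()].
#' @param field_strengths Field strengths in tesla.
#' @param sequences Sequence kinds.
#' @param orientations Rod orientations w.r.t. B0.
#' @param phase_dirs Phase-encode directions.
#' @param slice_orientations Named list mapping rod orientation to its two
#'   slice orientations.
#' @return Object of class `experiment_grid`.
#' @export
default_experiment_grid <- function(materials = list(titanium_material(), steel_material()),
                                    field_strengths = c(1.5, 3, 7),
                                    sequences = c("SE", "GRE"),
                                    orientations = c("parallel", "perpendicular"),
                                    phase_dirs = c("FH", "AP"),
                                    slice_orientations = list(
                                      parallel = c("tra", "cor"),
                                      perpendicular = c("sag", "cor"))) {
  structure(list(materials = materials, field_strengths = field_strengths,
                 sequences = sequences, orientations = orientations,
                 phase_dirs = phase_dirs, slice_orientations = slice_orientations),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  npo <- length(x$sequences) * length(x$phase_dirs) *
    sum(lengths(x$slice_orientations[x$orientations]))
  cat(sprintf("<experiment_grid> %d material(s) x %d field(s) x %d configs = %d runs\n",
              length(x$materials), length(x$field_strengths), npo,
              length(x$materials) * length(x$field_strengths) * npo))
  invisible(x)
}

#' Write the fixture set to disk
#'
#' Generates the rod meshes (ASCII STL), a materials YAML and one YAML
#' configuration per grid cell (16 per test object per field strength),
#' plus a null-control configuration (a signal-free rod with zero
#' susceptibility contrast to the oil).
#'
#' @param out_dir Writable output directory (created if missing).
#' @param grid An [default_experiment_grid()].
#' @return Character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, grid = default_experiment_grid()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  rod <- make_cylinder_mesh(3, 15, 64)
  for (orient in grid$orientations) {
    p <- file.path(out_dir, sprintf("rod_%s.stl", orient))
    write_stl(orient_object(rod, orient), p)
    paths <- c(paths, p)
  }
  mats <- c(list(oil_material()), grid$materials)
  mp <- file.path(out_dir, "materials.yaml")
  yaml::write_yaml(lapply(mats, function(m) m[c("name", "chi", "T1", "T2", "M0")]), mp)
  paths <- c(paths, mp)
  for (m in grid$materials) for (b0 in grid$field_strengths) {
    for (orient in grid$orientations) {
      for (so in grid$slice_orientations[[orient]]) {
        for (seq_kind in grid$sequences) for (pd in grid$phase_dirs) {
          cfg <- list(material = m$name, b0 = b0, sequence = seq_kind,
                      to_orientation = orient, slice_orientation = so,
                      phase_dir = pd)
          p <- file.path(out_dir, sprintf("config_%s_%gT_%s_%s_%s_%s.yaml",
                                          m$name, b0, seq_kind, orient, so, pd))
          yaml::write_yaml(cfg, p)
          paths <- c(paths, p)
        }
      }
    }
  }
  p <- file.path(out_dir, "config_null_control.yaml")
  yaml::write_yaml(list(material = "plastic", b0 = 1.5, sequence = "SE",
                        to_orientation = "parallel", slice_orientation = "tra",
                        phase_dir = "FH"), p)
  paths <- c(paths, p)
  invisible(paths)
}

# Voxelize the posed rod on the phantom grid (shared by grid runs and
# one-shot simulations).
rod_mask_for_orientation <- function(orientation, grid_shape, voxel_size,
                                     diameter = 3, length = 15, n_segments = 64L) {
  rod <- make_cylinder_mesh(diameter, length, n_segments)
  voxelize_mesh(orient_object(rod, orientation), grid_shape, voxel_size)
}

#' Run the full acquisition grid and tabulate artifact sizes
#'
#' For every grid configuration this simulates the center-slice image with
#' the test object and its reference without it, evaluates the ASTM
#' artifact mask and appends one result row.  The expensive susceptibility
#' field is computed once per rod orientation as a unit field (per ppm of
#' contrast per tesla) and rescaled per material and field strength, which
#' is exact because the forward field model is linear in both; reference
#' images are cached per sequence/geometry.  The run is noiseless and
#' fully deterministic with a fixed row order.
#'
#' @param grid An [default_experiment_grid()].
#' @param phantom_edge Phantom cube edge (mm).
#' @param resolution Voxels per mm.
#' @param Gs Slice-select gradient (mT/m).
#' @param params_fun Function `(kind, slice_orientation, phase_dir)`
#'   returning the [sequence_params()] for one cell; the default applies
#'   the ASTM parameter set.
#' @param pad_factor Field-solver padding factor, see
#'   [compute_offresonance()].
#' @param verbose Emit progress messages.
#' @return A data frame with columns material, b0, sequence,
#'   to_orientation, slice_orientation, phase_dir, area_px, area_mm2,
#'   area_lo_px, area_hi_px.
#' @export
run_experiment_grid <- function(grid = default_experiment_grid(),
                                phantom_edge = 150, resolution = 2, Gs = 10,
                                params_fun = NULL, pad_factor = 4 / 3,
                                verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(params_fun)) {
    params_fun <- function(kind, so, pd) {
      sequence_params(kind, slice_orientation = so, phase_dir = pd)
    }
  }
  background <- oil_material()
  n <- as.integer(round(phantom_edge * resolution))
  gs3 <- c(n, n, n)
  h <- 1 / resolution
  ref_cache <- new.env(parent = emptyenv())
  reference_image <- function(kind, so, pd) {
    key <- paste(kind, so, pd, sep = "_")
    if (is.null(ref_cache[[key]])) {
      ph <- build_phantom(phantom_edge, resolution, background)
      ref_cache[[key]] <- simulate_image(ph, params_fun(kind, so, pd),
                                         B0 = 1.5, with_object = FALSE, Gs = Gs)
    }
    ref_cache[[key]]
  }
  rows <- list()
  for (orient in grid$orientations) {
    say("voxelizing %s rod ...", orient)
    mask <- rod_mask_for_orientation(orient, gs3, h)
    say("computing unit off-resonance field (%s) ...", orient)
    unit <- compute_offresonance(array(as.numeric(mask), dim = gs3), B0 = 1,
                                 voxel_size = h, background = !mask,
                                 pad_factor = pad_factor)
    for (mat in grid$materials) {
      contrast <- mat$chi - background$chi
      phantom <- build_phantom(phantom_edge, resolution, background, mask, mat)
      for (b0 in grid$field_strengths) {
        df_arr <- unit$delta_f * (contrast * b0)
        for (so in grid$slice_orientations[[orient]]) {
          # excitation geometry is shared by both sequences and both
          # phase-encode directions; extract the isochromats once
          normal_axis <- slice_axes(so)$normal
          iso <- extract_isochromats(phantom, normal_axis,
                                     params_fun(grid$sequences[1L], so,
                                                grid$phase_dirs[1L])$slice_mm,
                                     df_arr, Gs, 0, amp_bg = 1, amp_obj = 0)
          for (seq_kind in grid$sequences) for (pd in grid$phase_dirs) {
            params <- params_fun(seq_kind, so, pd)
            ax <- slice_axes(so, pd)
            w_bg <- steady_state_signal(background, params)
            ks <- simulate_kspace(list(u = iso$coord[[ax$freq]],
                                       v = iso$coord[[ax$phase]],
                                       df = iso$df, amp = w_bg * iso$amp),
                                  params)
            img <- reconstruct(ks, provenance = list(B0 = b0, with_object = TRUE))
            ref <- reference_image(seq_kind, so, pd)
            res <- evaluate_artifact(img, ref)
            rows[[length(rows) + 1L]] <- data.frame(
              material = mat$name, b0 = b0, sequence = seq_kind,
              to_orientation = orient, slice_orientation = so,
              phase_dir = pd, area_px = res$area_px, area_mm2 = res$area_mm2,
              area_lo_px = res$area_eroded_px, area_hi_px = res$area_dilated_px)
            say("  %s %gT %s %s/%s/%s: %d px (%.1f mm^2)",
                mat$name, b0, seq_kind, orient, so, pd,
                res$area_px, res$area_mm2)
          }
        }
      }
    }
    rm(mask, unit); gc(FALSE)
  }
  do.call(rbind, rows)
}

#' Pair artifact areas of the same configuration across two fields
#'
#' @param results A [run_experiment_grid()] data frame.
#' @param B_low,B_high The two field strengths (present in `results`).
#' @param unit `"mm2"` or `"px"`.
#' @return Data frame with `area_low`, `area_high` and the configuration
#'   keys, one row per configuration.
#' @export
pair_field_strengths <- function(results, B_low, B_high, unit = c("mm2", "px")) {
  unit <- match.arg(unit)
  col <- if (unit == "mm2") "area_mm2" else "area_px"
  keys <- c("material", "sequence", "to_orientation", "slice_orientation", "phase_dir")
  lo <- results[results$b0 == B_low, c(keys, col)]
  hi <- results[results$b0 == B_high, c(keys, col)]
  if (!nrow(lo) || !nrow(hi)) {
    stop(sprintf("insufficient data: no results at %g T and/or %g T", B_low, B_high))
  }
  names(lo)[length(lo)] <- "area_low"
  names(hi)[length(hi)] <- "area_high"
  merge(lo, hi, by = keys, sort = TRUE)
}

#' Cross-field scaling report
#'
#' Fits the through-origin trend line for each field-strength pair and
#' tabulates the fitted slope with its 95% CI and R^2 next to the
#' theoretical `sqrt(B_high / B_low)` factor and their percent difference.
#'
#' @param results A [run_experiment_grid()] data frame covering all fields.
#' @param pairs List of `c(B_low, B_high)` pairs.
#' @param unit Area unit used for the fits.
#' @return Object of class `scaling_report`: data frame `table` (one row
#'   per pair) and the underlying `fits`.
#' @export
field_scaling_report <- function(results,
                                 pairs = list(c(1.5, 3), c(3, 7), c(1.5, 7)),
                                 unit = "mm2") {
  fits <- list()
  tab <- list()
  for (p in pairs) {
    d <- pair_field_strengths(results, p[1L], p[2L], unit)
    fit <- fit_trend(d$area_low, d$area_high)
    m_theo <- theoretical_slope(p[1L], p[2L])
    key <- sprintf("%gT vs %gT", p[2L], p[1L])
    fits[[key]] <- fit
    tab[[key]] <- data.frame(
      pair = key, b_low = p[1L], b_high = p[2L],
      slope = fit$slope, ci_lo = fit$ci95[1L], ci_hi = fit$ci95[2L],
      r_squared = fit$r_squared, n = fit$n,
      theoretical = m_theo,
      pct_diff = 100 * (fit$slope - m_theo) / m_theo)
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits,
                 max_abs_pct_diff = max(abs(tab$pct_diff)),
                 mean_r_squared = mean(tab$r_squared)),
            class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat("Cross-field artifact-area scaling\n")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-12s slope %.3f (%.3f - %.3f), R^2 %.3f, theory %.3f, diff %+.2f%%\n",
                t$pair[i], t$slope[i], t$ci_lo[i], t$ci_hi[i],
                t$r_squared[i], t$theoretical[i], t$pct_diff[i]))
  }
  cat(sprintf("  mean R^2 %.4f; max |slope - theory| %.2f%%\n",
              x$mean_r_squared, x$max_abs_pct_diff))
  invisible(x)
}
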