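test_that("sequence defaults follow the ASTM parameter set", {
  se <- sequence_params("SE")
  expect_equal(se$te_ms, 20); expect_equal(se$flip_deg, 90)
  gre <- sequence_params("GRE")
  expect_equal(gre$te_ms, 15); expect_equal(gre$flip_deg, 30)
  for (p in list(se, gre)) {
    expect_equal(p$tr_ms, 500)
    expect_identical(p$matrix_size, c(256L, 256L))
    expect_equal(p$slice_mm, 3); expect_equal(p$px_bw_hz, 130)
    expect_equal(p$fov_mm, 200)
  }
  expect_error(sequence_params("SE", te_ms = 600), "TE")
  expect_error(sequence_params("SE", matrix_size = 4), "matrix")
  expect_error(sequence_params("SE", px_bw_hz = 0), "px_bw")
})

test_that("slice orientation maps to orthogonal image axes", {
  for (so in c("tra", "cor", "sag")) for (pd in c("FH", "AP")) {
    ax <- slice_axes(so, pd)
    expect_setequal(c(ax$normal, ax$freq, ax$phase), 1:3)
  }
  expect_equal(slice_axes("tra")$normal, 3L)
  expect_equal(slice_axes("cor")$normal, 2L)
  expect_equal(slice_axes("sag")$normal, 1L)
  # the phase toggle swaps frequency and phase axes
  a <- slice_axes("tra", "FH"); b <- slice_axes("tra", "AP")
  expect_equal(a$freq, b$phase); expect_equal(a$phase, b$freq)
  expect_error(slice_axes("oblique"), "config")
})

test_that("steady-state signal weights follow the SE and spoiled-GRE forms", {
  oil <- oil_material()
  expect_equal(steady_state_signal(oil, sequence_params("SE")),
               (1 - exp(-500 / 90)) * exp(-20 / 90), tolerance = 1e-12)
  expect_equal(round(steady_state_signal(oil, sequence_params("SE")), 4), 0.7976)
  # no protons, no signal
  expect_equal(steady_state_signal(titanium_material(), sequence_params("GRE")), 0)
  # TR >> T1 at 90 degrees: GRE and SE both reduce to M0 exp(-TE/T2)
  se_inf <- sequence_params("SE", te_ms = 20, tr_ms = 1e6)
  gre_inf <- sequence_params("GRE", te_ms = 20, tr_ms = 1e6, flip_deg = 90)
  expect_equal(steady_state_signal(oil, se_inf), exp(-20 / 90), tolerance = 1e-9)
  expect_equal(steady_state_signal(oil, gre_inf), exp(-20 / 90), tolerance = 1e-9)
})

test_that("slice selection excites the nominal slab on resonance", {
  ph <- build_phantom(20, 2, oil_material())          # 40^3, 0.5 mm
  params <- sequence_params("SE", matrix_size = c(16L, 16L), fov_mm = 20)
  w <- select_slice(ph, params)
  zax <- grid_axis(40, 0.5)
  in_slab <- abs(zax) < 1.5
  expect_equal(sum(in_slab), 6L)                      # 6 sub-samples across 3 mm
  expect_identical(w[1, 1, ], in_slab)
  expect_error(select_slice(ph, params, Gs = 0), "config")
})

test_that("uniform off-resonance shifts the excited slab by df/(gamma_bar Gs)", {
  ph <- build_phantom(20, 2, oil_material())
  params <- sequence_params("SE", matrix_size = c(16L, 16L), fov_mm = 20)
  gshz <- GAMMA_BAR_HZ_PER_T * 10 * 1e-6              # Hz/mm at Gs = 10 mT/m
  mkfield <- function(df0) {
    structure(list(delta_f = array(df0, c(40L, 40L, 40L)), B0 = 1.5,
                   voxel_size = 0.5, gamma_bar = GAMMA_BAR_HZ_PER_T),
              class = "field_map")
  }
  # df = gamma_bar Gs * 3 mm shifts by one slice thickness: s0 excluded
  w <- select_slice(ph, params, mkfield(gshz * 3))
  zax <- grid_axis(40, 0.5)
  expect_identical(w[1, 1, ], abs(zax + 3) < 1.5)
  expect_false(any(w[, , which.min(abs(zax))]))
  # exactly at the slab edge: strict inequality excludes the isochromat
  w_edge <- select_slice(ph, params, mkfield(gshz * 1.5))
  expect_identical(w_edge[1, 1, ], (zax + 1.5) > -1.5 & (zax + 1.5) < 1.5)
})

test_that("uniform off-resonance of one pixel bandwidth shifts the image 1 px", {
  for (kind in c("SE", "GRE")) {
    params <- sequence_params(kind, matrix_size = c(64L, 64L), fov_mm = 64,
                              px_bw_hz = 130)
    iso0 <- slab_isochromats(16)
    iso1 <- slab_isochromats(16, df0 = 130)
    m0 <- magnitude(reconstruct(simulate_kspace(iso0, params)))
    m1 <- magnitude(reconstruct(simulate_kspace(iso1, params)))
    expect_lt(max(abs(m1[2:64, ] - m0[1:63, ])), 1e-10 * max(m0))
  }
})

test_that("SE magnitude is invariant to uniform off-resonance (refocusing)", {
  params <- sequence_params("SE", matrix_size = c(64L, 64L), fov_mm = 64,
                            px_bw_hz = 130)
  m0 <- magnitude(reconstruct(simulate_kspace(slab_isochromats(16), params)))
  m1 <- magnitude(reconstruct(simulate_kspace(slab_isochromats(16, df0 = 3 * 130),
                                              params)))
  expect_lt(max(abs(m1[4:64, ] - m0[1:61, ])), 1e-10 * max(m0))
})

test_that("GRE signal decays monotonically with intravoxel spread", {
  # very high pixel bandwidth makes the in-plane displacement negligible,
  # isolating the static-phase dephasing that distinguishes GRE from SE
  params <- sequence_params("GRE", matrix_size = c(32L, 32L), fov_mm = 32,
                            px_bw_hz = 1e6)
  quarter <- 1 / (4 * params$te_ms * 1e-3)            # first zero crossing / 2
  spreads <- seq(0, quarter, length.out = 8)
  toy <- function(p, s) {
    iso <- list(u = c(0, 0), v = c(0, 0), df = c(-s, s), amp = c(0.5, 0.5))
    max(magnitude(reconstruct(simulate_kspace(iso, p))))
  }
  peaks <- vapply(spreads, function(s) toy(params, s), numeric(1))
  expect_true(all(diff(peaks) < 0))
  # the refocused spin echo suffers no such loss
  paramsSE <- sequence_params("SE", matrix_size = c(32L, 32L), fov_mm = 32,
                              px_bw_hz = 1e6)
  pk_se <- vapply(spreads, function(s) toy(paramsSE, s), numeric(1))
  expect_lt(diff(range(pk_se)) / pk_se[1], 1e-6)
})

test_that("gridded synthesis matches the exact DFT to within 0.1% of peak", {
  set.seed(19)
  n <- 2000
  iso <- list(u = runif(n, -25, 25), v = runif(n, -25, 25),
              df = runif(n, -500, 500), amp = runif(n))
  for (kind in c("SE", "GRE")) {
    params <- sequence_params(kind, matrix_size = c(64L, 64L), fov_mm = 64)
    mg <- magnitude(reconstruct(simulate_kspace(iso, params, method = "grid")))
    me <- magnitude(reconstruct(simulate_kspace(iso, params, method = "exact")))
    expect_lt(max(abs(mg - me)) / max(me), 1e-3)
  }
})

test_that("isochromats displaced outside the readout band are filtered out", {
  params <- sequence_params("GRE", matrix_size = c(32L, 32L), fov_mm = 32,
                            px_bw_hz = 130)
  iso <- list(u = 0, v = 0, df = 130 * 32, amp = 1)   # displaced a full FOV
  m <- magnitude(reconstruct(simulate_kspace(iso, params)))
  expect_lt(max(m), 1e-12)
})

test_that("reconstruction obeys the Fourier identities", {
  Nf <- 32L
  params <- sequence_params("SE", matrix_size = c(Nf, Nf), fov_mm = 32)
  kn <- seq.int(-16L, 15L)
  # delta at k-space center -> uniform image
  S <- matrix(0 + 0i, Nf, Nf); S[kn == 0, kn == 0] <- 1
  ks <- structure(list(kspace = S, kn = kn, km = kn, params = params),
                  class = "kspace_data")
  img <- reconstruct(ks)
  expect_lt(diff(range(magnitude(img))), 1e-12)
  # linear phase ramp -> shifted image (shift theorem); 2 px = 2 mm here
  iso <- slab_isochromats(8)
  ks1 <- simulate_kspace(iso, params)
  ks2 <- ks1
  ks2$kspace <- ks2$kspace * exp(-2i * pi * outer(ks1$kn, rep(1, Nf)) * 2 / 32)
  m1 <- magnitude(reconstruct(ks1)); m2 <- magnitude(reconstruct(ks2))
  expect_lt(max(abs(m2[3:32, ] - m1[1:30, ])), 1e-9 * max(m1))
  # Parseval with the unitary convention: image energy = k-space energy / N
  expect_equal(sum(magnitude(reconstruct(ks1))^2),
               sum(Mod(ks1$kspace)^2) / (Nf * Nf), tolerance = 1e-10)
})

test_that("simulate_image is deterministic and self-referencing gives no artifact", {
  ph <- build_phantom(24, 2, oil_material())          # uniform oil, no object
  params <- sequence_params("SE", matrix_size = c(32L, 32L), fov_mm = 32)
  img1 <- simulate_image(ph, params, 1.5, with_object = TRUE)
  img2 <- simulate_image(ph, params, 1.5, with_object = TRUE)
  ref <- simulate_image(ph, params, 1.5, with_object = FALSE)
  expect_identical(img1$data, img2$data)              # bit-identical, no RNG
  res <- evaluate_artifact(img1, ref)
  expect_equal(res$area_px, 0L)
})

test_that("a signal-void rod without susceptibility contrast images as a disk", {
  # null control: chi equal to oil, M0 = 0, slice perpendicular to the rod
  gs <- c(48L, 48L, 48L)
  mask <- voxelize_mesh(orient_object(make_cylinder_mesh(3, 15, 64), "parallel"),
                        gs, 0.5)
  plastic <- material_props("plastic", -8.8, 90, 90, 0)
  ph <- build_phantom(24, 2, oil_material(), mask, plastic)
  params <- sequence_params("SE", matrix_size = c(64L, 64L), fov_mm = 32)
  img <- simulate_image(ph, params, 1.5)
  ref <- simulate_image(ph, params, 1.5, with_object = FALSE)
  res <- evaluate_artifact(img, ref)
  # area must fall between the one-pixel bounds of the ideal rasterized disk
  px <- 32 / 64
  pc <- grid_axis(64L, px)
  disk <- outer(pc^2, pc^2, `+`) < 1.5^2
  b <- one_pixel_bounds(disk)
  expect_gte(res$area_px, b$area_eroded_px)
  expect_lte(res$area_px, b$area_dilated_px)
})
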