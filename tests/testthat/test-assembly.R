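test_that("a 1x1 grid stitches to the single tile", {
  f <- field_of_view(matrix(runif(48 * 48, 0, 100), 48, 48), "DAPI", 1,
                     c(0, 0), 50, c(0, 0))
  expect_equal(stitch(list(f), c(1, 1), 0.1), f$pixels)
})

test_that("zero overlap stitches to the exact block concatenation", {
  spec <- degenerate_spec(overlap_fraction = 0, seed = 2)
  ph <- tiny_phantom(spec, seed = 2)
  rc <- render_cycle(ph, spec, 1)
  tiles <- Filter(function(f) f$channel == "Cy5", rc$fovs)
  mosaic <- stitch(tiles, spec$grid_shape, 0)
  for (f in tiles) {
    ys <- f$stage_offset_px[1] + 1:48; xs <- f$stage_offset_px[2] + 1:48
    expect_identical(mosaic[ys, xs], f$pixels)
  }
})

test_that("cut-and-reassemble with overlap reproduces the scene within one grey level", {
  spec <- degenerate_spec(seed = 3)
  ph <- tiny_phantom(spec, seed = 3)
  rc <- render_cycle(ph, spec, 1)
  tiles <- Filter(function(f) f$channel == "TRITC", rc$fovs)
  mosaic <- stitch(tiles, spec$grid_shape, spec$overlap_fraction)
  scene <- quantize16(seqifr:::channel_scene(ph, spec, "TRITC", 1))
  expect_lt(max(abs(mosaic - scene)), 1)
})

test_that("an incomplete grid is reported with the missing positions", {
  spec <- tiny_spec(seed = 2)
  ph <- tiny_phantom(spec, seed = 2)
  tiles <- Filter(function(f) f$channel == "DAPI",
                  render_cycle(ph, spec, 1)$fovs)
  expect_error(stitch(tiles[-5], spec$grid_shape, spec$overlap_fraction),
               "missing positions \\(1, 0\\)")
  mixed <- c(tiles, Filter(function(f) f$channel == "Cy5",
                           render_cycle(ph, spec, 1)$fovs)[1])
  expect_error(stitch(mixed, spec$grid_shape, 0.1), "single cycle and channel")
})

test_that("a full-scale 17x21 acquisition consumes exactly 357 tiles", {
  fovs <- lapply(0:(17 * 21 - 1), function(i)
    field_of_view(matrix(i %% 7, 8, 8), "DAPI", 1,
                  c(i %/% 21, i %% 21), 50, c(0, 0)))
  expect_length(fovs, 357)
  mosaic <- stitch(fovs, c(17, 21), 0)
  expect_identical(dim(mosaic), c(17L * 8L, 21L * 8L))
  # one tile fewer is no longer a complete grid
  expect_error(stitch(fovs[-1], c(17, 21), 0), "missing positions")
})

test_that("registering an image against itself yields the identity", {
  m <- dapi_mosaic_for(2)
  tf <- estimate_transform(m, m)
  expect_lt(abs(tf$rotation_deg), 1e-3)
  expect_lt(max(abs(tf$translation_px)), 1e-3)
})

test_that("featureless images raise a registration-failure error, never a silent identity", {
  m <- dapi_mosaic_for(2)
  blank <- matrix(5, nrow(m), ncol(m))
  expect_error(estimate_transform(m, blank), "registration failed")
  expect_error(estimate_transform(blank, m), "registration failed")
})

test_that("a known sub-pixel shift and rotation is recovered within tolerance", {
  scene <- dapi_mosaic_for(3)
  drift <- rigid_transform(0.3, c(5.25, -3.5), center = (dim(scene) - 1) / 2)
  moving <- bare(resample(scene, drift))
  tf <- estimate_transform(scene, moving)
  truth <- invert_rigid(drift)
  expect_lt(abs(tf$rotation_deg - truth$rotation_deg), 0.05)
  expect_lt(max(abs(tf$translation_px - truth$translation_px)), 0.5)
})

test_that("autofluorescence subtraction follows its contract", {
  layer <- matrix(runif(100, 0, 500), 10, 10)
  expect_identical(subtract_autofluorescence(layer, matrix(0, 10, 10)), layer)
  af <- matrix(100, 10, 10)
  out <- subtract_autofluorescence(layer, af, exposure_ratio = 2)
  expect_equal(out, pmax(layer - 200, 0))
  expect_true(all(out >= 0))
  expect_error(subtract_autofluorescence(layer, matrix(0, 5, 5)), "shape")
})

test_that("AF-only layers vanish after baseline subtraction up to noise", {
  spec <- tiny_spec(cycle_drift = NULL, seed = 5)
  ph <- tiny_phantom(spec, seed = 5)
  fovs1 <- render_autofluorescence_baseline(ph, spec)
  spec2 <- spec; spec2$seed <- spec$seed + 1L # fresh noise draw
  fovs2 <- render_autofluorescence_baseline(ph, spec2)
  vigref <- build_flatfield_reference(
    simulate_calibration_fovs(spec, "TRITC"), "TRITC")
  mos <- function(fovs) stitch(lapply(
    Filter(function(f) f$channel == "TRITC", fovs),
    function(f) apply_flatfield(f, vigref)), spec$grid_shape,
    spec$overlap_fraction)
  out <- subtract_autofluorescence(mos(fovs2), mos(fovs1))
  # clipped-at-zero noise residue: mean stays below the read+shot noise scale
  expect_lt(mean(out), 15)
})

test_that("assemble_run produces the contracted layer set in the reference frame", {
  spec <- tiny_spec(seed = 6)
  run <- simulate_run(spec)
  stk <- assemble_run(run, flatfield = FALSE, subtract_af = TRUE,
                      keep_af_layers = TRUE)
  md <- stk$metadata
  expect_equal(sum(md$is_reference), 1)
  expect_identical(md$name[md$is_reference], "DAPI")
  # 2 cycles x 2 markers + DAPI + 2 AF layers
  expect_length(stk$layers, 2 * 2 + 1 + 2)
  expect_setequal(md$name[md$cycle > 0 & !md$is_reference],
                  run$phantom$panel$marker)
  dims <- vapply(stk$layers, dim, integer(2))
  expect_true(all(dims == dims[, 1]))
})

test_that("assembled marker layers are aligned to ground truth within half a pixel", {
  spec <- tiny_spec(seed = 7, n_cycles = 2)
  run <- simulate_run(spec)
  stk <- assemble_run(run, flatfield = FALSE)
  est <- stk$transforms[[2]]
  truth <- run$ground_truth$per_cycle_transforms[[2]]
  corners <- rbind(c(0, 0), c(0, 176), c(133, 0), c(133, 176))
  err <- max(abs(transform_points(est, corners) -
                 transform_points(truth, corners)))
  expect_lt(err, 0.5)
})

test_that("stitch-then-transform commutes with transform-then-stitch on noise-free data", {
  spec <- degenerate_spec(seed = 9, n_cycles = 2,
                          cycle_drift = matrix(c(0, 0, 0, 0.2, 3.5, -2.25),
                                               2, 3, byrow = TRUE))
  ph <- tiny_phantom(spec, seed = 9)
  # route A: drifted render, stitched
  mos_drifted <- stitch(Filter(function(f) f$channel == "DAPI",
                               render_cycle(ph, spec, 2)$fovs),
                        spec$grid_shape, spec$overlap_fraction)
  # route B: stitch undrifted cycle, then transform the mosaic
  spec_nd <- spec; spec_nd$cycle_drift <- NULL
  mos_plain <- stitch(Filter(function(f) f$channel == "DAPI",
                             render_cycle(ph, spec_nd, 2)$fovs),
                      spec$grid_shape, spec$overlap_fraction)
  drift <- seqifr:::cycle_drift_transforms(spec)[[2]]
  mos_b <- resample(mos_plain, drift)
  v <- attr(mos_b, "valid")
  inner <- which(v, arr.ind = TRUE)
  keep <- inner[, 1] > 8 & inner[, 1] < 126 & inner[, 2] > 8 & inner[, 2] < 169
  expect_lt(mean(abs(mos_drifted[inner[keep, ]] - mos_b[inner[keep, ]])), 1)
})
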