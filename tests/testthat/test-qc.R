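# --- Otsu -------------------------------------------------------------

test_that("otsu matches exhaustive between-class-variance maximization on varied images", {
  set.seed(42)
  imgs <- list()
  for (i in 1:6) { # bimodal mixtures with varying separation and balance
    n0 <- 150 * i
    imgs[[length(imgs) + 1]] <- matrix(
      c(rnorm(n0, 100, 15), rnorm(1200 - n0, 100 + 60 * i, 25)), 30, 40)
  }
  for (i in 1:4) # uniform random
    imgs[[length(imgs) + 1]] <- matrix(runif(1200, 0, 10^i), 30, 40)
  imgs[[length(imgs) + 1]] <- matrix(rep(c(10, 200), each = 50), 10, 10)
  # 8-bit style integer image
  imgs[[length(imgs) + 1]] <- matrix(sample.int(256, 2000, TRUE) - 1, 40, 50)
  for (img in imgs)
    expect_identical(otsu_threshold(img), otsu_bruteforce(img))
})

test_that("otsu separates well-separated classes and rejects constants", {
  img <- matrix(c(rep(10, 500), rep(200, 500)), 25, 40)
  th <- otsu_threshold(img)
  expect_gt(th, 10); expect_lt(th, 200)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "constant image")
})

test_that("otsu agrees with an independent library implementation on 8-bit data", {
  set.seed(7)
  img <- matrix(sample(c(rpois(600, 20), rpois(600, 150)), 1200), 30, 40)
  th <- otsu_threshold(img, n_bins = 256)
  # EBImage works on [0,1] with its own binning; agree on the class split
  th_eb <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1),
                         levels = 256) * 255
  expect_equal(mean(img > th), mean(img > th_eb), tolerance = 0.01)
})

# --- ROI detection ----------------------------------------------------

test_that("ROIs exactly tile a canvas that holds exactly n of them", {
  mask <- matrix(TRUE, 20, 30) # 2x3 ROIs of 10 px at 100 um/px = 1 mm
  rois <- detect_rois(mask, n_rois = 6, roi_size_mm = 1, pixel_size_um = 100)
  expect_equal(nrow(rois), 6)
  expect_setequal(paste(rois$y0, rois$x0),
                  paste(rep(c(0, 10), 3), rep(c(0, 10, 20), each = 2)))
})

test_that("detected ROIs are non-overlapping and inside the tissue", {
  set.seed(5)
  mask <- matrix(FALSE, 120, 150)
  mask[15:110, 20:140] <- TRUE
  mask[40:60, 50:80] <- FALSE # a hole
  rois <- detect_rois(mask, n_rois = 6, roi_size_mm = 0.25,
                      pixel_size_um = 10) # 25 px ROIs
  expect_equal(nrow(rois), 6)
  for (i in seq_len(6)) {
    sub <- mask[rois$y0[i] + 1:25, rois$x0[i] + 1:25]
    expect_true(all(sub))
    for (j in seq_len(6)) if (j != i)
      expect_false(abs(rois$y0[i] - rois$y0[j]) < 25 &&
                   abs(rois$x0[i] - rois$x0[j]) < 25)
  }
  # determinism
  expect_identical(rois, detect_rois(mask, 6, 0.25, pixel_size_um = 10))
})

test_that("insufficient tissue reports the feasible maximum", {
  mask <- matrix(FALSE, 50, 50)
  mask[1:20, 1:20] <- TRUE
  expect_error(detect_rois(mask, n_rois = 6, roi_size_mm = 0.1,
                           pixel_size_um = 10), "at most 4 feasible")
  expect_error(detect_rois(matrix(TRUE, 5, 5), 1, 1, 100), "larger than")
})

# --- SBR --------------------------------------------------------------

test_that("pixel SBR is exact arithmetic on a clean two-level layer", {
  layer <- matrix(100, 40, 40)
  layer[10:20, 10:20] <- 500
  rec <- compute_sbr(layer, mode = "pixel")
  expect_equal(rec$sbr, 5)
  expect_equal(rec$n_rois, 1)
})

test_that("SBR is invariant to rescaling the layer", {
  ph <- tiny_phantom(seed = 21)
  layer <- render_marker_scene(ph, "CD3")
  a <- compute_sbr(bare(layer), mode = "pixel")$sbr
  b <- compute_sbr(bare(layer) * 3.7, mode = "pixel")$sbr
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("pure background raises a single-class error", {
  expect_error(
    suppressWarnings(compute_sbr(matrix(100, 30, 30), mode = "pixel")),
    "all ROIs excluded|constant")
})

test_that("generator-ledgered SBR is recovered within 5% relative, pixel mode", {
  spec <- tiny_spec(seed = 22)
  run <- simulate_run(spec)
  gt <- run$ground_truth$true_sbr
  for (mk in c("CD20", "CD3")) { # cycle-1 markers: layer = own stain only
    scene <- render_marker_scene(run$phantom, mk)
    layer <- seqifr:::with_seed(99, quantize16(
      seqifr:::add_camera_noise(bare(scene), spec$noise)))
    rec <- compute_sbr(layer, mode = "pixel")
    expect_lt(abs(rec$sbr - gt[[mk]]) / gt[[mk]], 0.05)
  }
})

test_that("cell-mode SBR classifies positive and negative cells", {
  panel <- marker_panel("Ki67", compartment = "nuclear", prevalence = 0.4)
  ph <- make_phantom(50, panel, canvas_size = c(134, 177), seed = 6,
                     nucleus_radius = 5)
  dapi <- render_dapi_scene(ph)
  layer <- render_marker_scene(ph, "Ki67")
  rec <- compute_sbr(bare(layer), mode = "cell", dapi = dapi)
  expect_equal(rec$mode, "cell")
  n_cells <- rec$roi_means$n_signal + rec$roi_means$n_background
  # segmentation finds roughly the planted cell count
  expect_gt(n_cells, 0.8 * 50); expect_lt(n_cells, 1.2 * 50)
  # positive fraction near the planted prevalence
  expect_equal(rec$roi_means$n_signal / n_cells,
               mean(ph$phenotypes[, "Ki67"]), tolerance = 0.15)
  expect_gt(rec$sbr, 2)
  expect_error(compute_sbr(layer, mode = "cell"), "DAPI")
})

# --- elution efficiency ----------------------------------------------

make_triplet <- function(pos_val_stain, pos_val_elu, neg_ctrl_pos = 100,
                         bg = 50, elu_bg = 50) {
  pos <- matrix(FALSE, 20, 20); pos[1:10, ] <- TRUE
  mk <- function(pv, nv) { m <- matrix(nv, 20, 20); m[1:10, ] <- pv; m }
  elution_triplet(neg_ctrl = mk(neg_ctrl_pos, bg),
                  staining = mk(pos_val_stain, bg),
                  elu_neg_ctrl = mk(pos_val_elu, elu_bg),
                  pos_mask = pos, neg_mask = !pos)
}

test_that("elution efficiency reproduces its defining arithmetic", {
  # identical negative controls before and after elution: 100%
  expect_equal(elution_efficiency(make_triplet(1000, 100)), 100)
  # stain fully surviving elution, no NEG change: 0%
  expect_equal(elution_efficiency(make_triplet(1000, 1000)), 0)
  # worked example: POS means stain 1000, neg 100, elu 109; NEG unchanged
  expect_equal(elution_efficiency(make_triplet(1000, 109)), 99)
})

test_that("the NEG term cancels global background changes from the elution cycle", {
  # elu shifted +30 everywhere (POS and NEG alike): still 100%
  tri <- make_triplet(1000, 130, neg_ctrl_pos = 100, bg = 50, elu_bg = 80)
  expect_equal(elution_efficiency(tri), 100)
  ph <- tiny_phantom(seed = 30)
  tri2 <- simulate_elution_triplet(ph, "CD20", 0.05, seed = 2,
                                   elution_background_shift = 40)
  expect_equal(elution_efficiency(tri2), 95, tolerance = 0.5)
})

test_that("elution efficiency is invariant to adding a constant to all three images", {
  ph <- tiny_phantom(seed = 31)
  tri <- simulate_elution_triplet(ph, "CD3", 0.1, seed = 3)
  e0 <- elution_efficiency(tri)
  for (const in c(-50, 13.7, 5000)) {
    tri2 <- tri
    tri2$neg_ctrl <- tri$neg_ctrl + const
    tri2$staining <- tri$staining + const
    tri2$elu_neg_ctrl <- tri$elu_neg_ctrl + const
    expect_lt(abs(elution_efficiency(tri2) - e0), 1e-9)
  }
})

test_that("degenerate stain contrast is an error and masks must be sane", {
  pos <- matrix(FALSE, 10, 10); pos[1:5, ] <- TRUE
  flat <- matrix(100, 10, 10)
  tri <- elution_triplet(flat, flat + 0, flat, pos_mask = pos,
                         neg_mask = !pos)
  expect_error(elution_efficiency(tri), "not positive")
  expect_error(elution_triplet(flat, flat, flat, pos_mask = pos,
                               neg_mask = pos), "overlap")
  expect_error(elution_triplet(flat, flat, flat,
                               pos_mask = matrix(FALSE, 10, 10),
                               neg_mask = !pos), "non-empty")
})

test_that("automatic POS/NEG masks recover the stained compartment", {
  ph <- tiny_phantom(seed = 32)
  tri_auto <- with(simulate_elution_triplet(ph, "CD20", 0.05, seed = 4),
                   elution_triplet(neg_ctrl, staining, elu_neg_ctrl))
  expect_equal(elution_efficiency(tri_auto), 95, tolerance = 1)
})

# --- stability curve --------------------------------------------------

fake_sbr <- function(v) structure(list(sbr = v, mode = "pixel", n_rois = 1,
                                       roi_means = NULL),
                                  class = "sbr_record")

test_that("stability curves normalize to the initial staining", {
  flat <- stability_curve(fake_sbr(8), list(`5` = fake_sbr(8),
                                            `10` = fake_sbr(8)))
  expect_equal(flat$sbr_percent_of_initial, c(100, 100, 100))
  expect_equal(flat$checkpoints, c(0, 5, 10))
  cur <- stability_curve(fake_sbr(10), list(`5` = fake_sbr(9.44)))
  expect_equal(cur$sbr_percent_of_initial[2], 94.4)
  expect_warning(stability_curve(fake_sbr(0.9), list(`5` = fake_sbr(0.9))),
                 "unstained")
  expect_error(stability_curve(fake_sbr(5), list(`10` = fake_sbr(4),
                                                 `5` = fake_sbr(4))),
               "strictly increasing")
})

test_that("a per-cycle decay d yields a 100(1-d)^k curve from the generator", {
  ph <- tiny_phantom(seed = 33)
  d <- 0.02
  ss <- simulate_stability_series(ph, "CD20", checkpoints = c(1, 5, 10),
                                  decay_per_cycle = d, seed = 5)
  init <- compute_sbr(ss$initial, mode = "pixel")
  post <- lapply(ss$post, function(l) compute_sbr(l, mode = "pixel"))
  cur <- stability_curve(init, post, marker = "CD20")
  expected <- 100 * (1 - d)^c(0, 1, 5, 10)
  expect_equal(cur$sbr_percent_of_initial, expected, tolerance = 0.015)
})

# --- repeatability CV -------------------------------------------------

test_that("repeatability CV follows its definition", {
  expect_equal(repeatability_cv(c(4, 5, 6)), 20) # sample sd 1, mean 5
  expect_equal(repeatability_cv(rep(3.7, 5)), 0)
  expect_error(repeatability_cv(5), "at least two")
  expect_error(repeatability_cv(c(1, -1)), "positive")
})

test_that("CV across noise-only repeated runs stays within the noise budget", {
  ph <- tiny_phantom(seed = 34)
  sbrs <- vapply(1:4, function(s) {
    scene <- render_marker_scene(ph, "CD68")
    layer <- seqifr:::with_seed(100 + s, quantize16(
      seqifr:::add_camera_noise(bare(scene),
                                list(gain = 0.5, read_sigma = 2))))
    compute_sbr(layer, mode = "pixel")$sbr
  }, numeric(1))
  expect_lt(repeatability_cv(sbrs), 2)
  expect_identical(repeatability_cv(rep(sbrs[1], 3)), 0)
})

# --- uniformity -------------------------------------------------------

uniform_layer_fixture <- function(gradient_x = 0) {
  # 5x5 grid of 24 px ROIs on a 120x120 canvas of uniform staining
  base <- matrix(100, 120, 120)
  blobs <- expand.grid(y = seq(6, 114, by = 12), x = seq(6, 114, by = 12))
  for (i in seq_len(nrow(blobs)))
    base[blobs$y[i] + (-2:2), blobs$x[i] + (-2:2)] <- 1000
  if (gradient_x != 0) {
    g <- 1 + gradient_x * (matrix(0:119, 120, 120, byrow = TRUE) / 119 - 0.5)
    base <- base * g
  }
  base
}

test_that("uniform staining has zero axis variation", {
  layer <- uniform_layer_fixture()
  rois <- detect_rois(matrix(TRUE, 120, 120), n_rois = 25,
                      roi_size_mm = 0.24, pixel_size_um = 10)
  up <- uniformity_profile(layer, rois, exposure_ms = 100)
  expect_equal(up$variation_x, 0)
  expect_equal(up$variation_y, 0)
  expect_length(up$normalized_means, 25)
})

test_that("a left-right gradient shows up on the x axis and matches brute-force CV", {
  layer <- uniform_layer_fixture(gradient_x = 0.10)
  rois <- detect_rois(matrix(TRUE, 120, 120), n_rois = 25,
                      roi_size_mm = 0.24, pixel_size_um = 10)
  up <- uniformity_profile(layer, rois, exposure_ms = 100)
  expect_gt(up$variation_x, up$variation_y)
  # brute force: CV over column groups of the ledgered ROI means
  g <- round(rois$cx_mm / 0.05)
  means <- vapply(seq_len(nrow(rois)), function(i) {
    px <- layer[rois$y0[i] + 1:24, rois$x0[i] + 1:24]
    mean(px[px > otsu_threshold(px)]) / 100
  }, numeric(1))
  brute <- 100 * sd(tapply(means, g, mean)) / mean(tapply(means, g, mean))
  expect_lt(abs(up$variation_x - brute), 2)
})

test_that("flat-field correction strictly reduces uniformity variation on a vignetted mosaic", {
  spec <- acquisition_spec(grid_shape = c(3, 3), tile_size = c(40, 40),
                           overlap_fraction = 0, cycle_drift = NULL,
                           noise = NULL, seed = 40)
  vig <- vignette_field(spec, "TRITC")
  scene <- uniform_layer_fixture()[1:120, 1:120]
  tiles_raw <- list(); tiles_corr <- list()
  ref <- build_flatfield_reference(lapply(1:9, function(i)
    field_of_view(quantize16(3000 * vig), "TRITC", 1,
                  c((i - 1) %/% 3, (i - 1) %% 3), 100, c(0, 0))), "TRITC")
  for (i in 1:9) {
    r <- (i - 1) %/% 3; cc <- (i - 1) %% 3
    crop <- scene[r * 40 + 1:40, cc * 40 + 1:40]
    f <- field_of_view(quantize16(crop * vig), "TRITC", 1, c(r, cc), 100,
                       c(r * 40, cc * 40))
    tiles_raw[[i]] <- f
    tiles_corr[[i]] <- apply_flatfield(f, ref)
  }
  rois <- detect_rois(matrix(TRUE, 120, 120), n_rois = 25,
                      roi_size_mm = 0.24, pixel_size_um = 10)
  up_raw <- uniformity_profile(stitch(tiles_raw, c(3, 3), 0), rois, 100)
  up_corr <- uniformity_profile(stitch(tiles_corr, c(3, 3), 0), rois, 100)
  expect_lt(up_corr$variation_x, up_raw$variation_x)
  expect_lt(up_corr$variation_y, up_raw$variation_y)
})
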