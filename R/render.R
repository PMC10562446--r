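# Rendering of multi-cycle tiled acquisitions from a tissue phantom, with
# a complete ground-truth ledger.
#
# Signal model per marker channel at cycle k (grey values at reference
# exposure, before vignette and noise):
#
#   scene = AF + baseline + delta_current + sum_prev prod(residuals) * delta
#
# where `baseline` is the non-specific secondary-antibody background
# (refreshed by every cycle's incubation, unchanged by elution) and
# `delta` the specific above-baseline stain of a marker in its positive
# compartment. Elution leaves a fraction `elution_residual` of the
# specific signal; under this model the Methods-style elution-efficiency
# estimator equals 100 * (1 - residual) exactly in the noise-free limit.
# The whole scene drifts rigidly per cycle, is cut into overlapping tiles,
# multiplied by the per-channel vignette, scaled by exposure, and sampled
# with Poisson-Gaussian camera noise quantized to 16 bits.

#' Construct a field of view (one camera tile)
#'
#' @param pixels Numeric matrix, grey values in `[0, 65535]`.
#' @param channel Channel name.
#' @param cycle Cycle index (1-based; 0 denotes the autofluorescence
#'   baseline acquisition).
#' @param grid_pos Integer `(row, col)`, 0-based grid position.
#' @param exposure_ms Positive exposure time in milliseconds.
#' @param stage_offset_px `(y, x)` nominal top-left coordinate of the tile
#'   in the mosaic frame, 0-based.
#' @return An object of class `field_of_view`.
#' @export
field_of_view <- function(pixels, channel, cycle, grid_pos, exposure_ms,
                          stage_offset_px) {
  stopifnot(is.matrix(pixels), length(grid_pos) == 2,
            length(stage_offset_px) == 2)
  if (exposure_ms <= 0) stop_bad("field_of_view: exposure_ms must be positive")
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop_bad("field_of_view: pixel values must lie in [0, 65535]")
  structure(
    list(pixels = pixels, channel = channel, cycle = as.integer(cycle),
         grid_pos = as.integer(grid_pos), exposure_ms = exposure_ms,
         stage_offset_px = as.numeric(stage_offset_px)),
    class = "field_of_view")
}

#' @export
print.field_of_view <- function(x, ...) {
  cat(sprintf("field_of_view: cycle %d %s tile (%d, %d), %dx%d px, %g ms\n",
              x$cycle, x$channel, x$grid_pos[1], x$grid_pos[2],
              nrow(x$pixels), ncol(x$pixels), x$exposure_ms))
  invisible(x)
}

# Noise-free channel scene (reference exposure, mosaic frame, no drift).
channel_scene <- function(phantom, spec, channel, cycle) {
  if (channel == "DAPI") return(render_dapi_scene(phantom))
  pan <- phantom$panel
  on_ch <- pan[pan$channel == channel & pan$cycle <= cycle, , drop = FALSE]
  cur <- pan[pan$channel == channel & pan$cycle == cycle, , drop = FALSE]
  baseline <- if (nrow(cur) > 0) cur$negative_intensity[1] else
    mean(pan$negative_intensity)
  af <- phantom$af_field[[channel]]
  if (is.null(af)) af <- 0
  scene <- af + baseline
  for (i in seq_len(nrow(on_ch))) {
    m <- on_ch[i, ]
    scale <- if (m$cycle == cycle) 1 else
      prod(spec$elution_residual[m$cycle:(cycle - 1)])
    if (scale < 1e-12) next # residual decayed below any grey level
    full <- render_marker_scene(phantom, m$marker, intensity_scale = 1)
    delta <- full - m$negative_intensity # specific signal only
    scene <- scene + scale * delta
  }
  scene
}

# Cut a (possibly drifted) canvas scene into vignetted, exposed, noisy,
# quantized tiles.
scene_to_tiles <- function(scene, spec, channel, cycle, noise_seed) {
  geom <- tile_geometry(spec)
  vig <- vignette_field(spec, channel)
  expo <- spec$exposure_ms[[channel]]
  scale <- expo / spec$reference_exposure_ms
  th <- spec$tile_size[1]; tw <- spec$tile_size[2]
  with_seed(noise_seed, {
    lapply(seq_len(nrow(geom$offsets)), function(i) {
      oy <- geom$offsets$offset_y[i]; ox <- geom$offsets$offset_x[i]
      tile <- scene[(oy + 1):(oy + th), (ox + 1):(ox + tw)]
      expected <- tile * scale * vig
      px <- quantize16(add_camera_noise(expected, spec$noise))
      field_of_view(px, channel, cycle,
                    c(geom$offsets$row[i], geom$offsets$col[i]),
                    expo, c(oy, ox))
    })
  })
}

#' Render all tiles of one staining cycle
#'
#' Renders DAPI plus the cycle's marker channels, including residual
#' carry-over from earlier cycles' markers scaled by the elution residual
#' fractions, applies the cycle's rigid drift, vignetting, exposure and
#' camera noise.
#'
#' @param phantom A `tissue_phantom`.
#' @param spec An `acq_spec`; the phantom canvas must match the mosaic
#'   size implied by the grid.
#' @param cycle Cycle index in `[1, n_cycles]`.
#' @return List with `fovs` (list of `field_of_view`, all channels) and
#'   `truth` (the cycle's drift transform and per-marker residual scales).
#' @export
render_cycle <- function(phantom, spec, cycle) {
  if (!is_count(cycle) || cycle < 1 || cycle > spec$n_cycles)
    stop_bad("render_cycle: cycle must be in [1, n_cycles]")
  geom <- tile_geometry(spec)
  if (!all(phantom$canvas_size == geom$canvas_size))
    stop_bad("render_cycle: phantom canvas ", phantom$canvas_size[1], "x",
             phantom$canvas_size[2], " does not match mosaic ",
             geom$canvas_size[1], "x", geom$canvas_size[2])
  pan <- phantom$panel
  if (any(pan$cycle == cycle) &&
      !all(pan$channel[pan$cycle == cycle] %in% spec$channels))
    stop_bad("render_cycle: cycle ", cycle, " markers use unknown channels")
  drift <- cycle_drift_transforms(spec)[[cycle]]
  fovs <- list()
  scales <- list()
  for (ch in spec$channels) {
    scene <- channel_scene(phantom, spec, ch, cycle)
    if (!is_identity_transform(drift)) scene <- resample(scene, drift)
    fovs <- c(fovs, scene_to_tiles(scene, spec, ch, cycle,
                                   derive_seed(spec$seed, 31, cycle,
                                               match(ch, spec$channels))))
    if (ch != "DAPI") {
      on_ch <- pan[pan$channel == ch & pan$cycle <= cycle, , drop = FALSE]
      if (nrow(on_ch) > 0)
        scales[[ch]] <- stats::setNames(
          vapply(seq_len(nrow(on_ch)), function(i) {
            if (on_ch$cycle[i] == cycle) 1 else
              prod(spec$elution_residual[on_ch$cycle[i]:(cycle - 1)])
          }, numeric(1)), on_ch$marker)
    }
  }
  list(fovs = fovs,
       truth = list(drift = drift, residual_scales = scales))
}

#' Render the pre-staining autofluorescence baseline acquisition
#'
#' Marker channels contain only the tissue autofluorescence field (times
#' vignette, exposure and noise); the DAPI channel contains the nuclear
#' counterstain, present from the start of the run. Recorded as cycle 0,
#' in the reference (undrifted) frame.
#'
#' @param phantom A `tissue_phantom`.
#' @param spec An `acq_spec`.
#' @return List of `field_of_view` tiles for every channel.
#' @export
render_autofluorescence_baseline <- function(phantom, spec) {
  geom <- tile_geometry(spec)
  if (!all(phantom$canvas_size == geom$canvas_size))
    stop_bad("render_autofluorescence_baseline: phantom/grid size mismatch")
  fovs <- list()
  for (ch in spec$channels) {
    scene <- if (ch == "DAPI") render_dapi_scene(phantom) else {
      af <- phantom$af_field[[ch]]
      if (is.null(af)) matrix(0, geom$canvas_size[1], geom$canvas_size[2])
      else af
    }
    fovs <- c(fovs, scene_to_tiles(scene, spec, ch, 0L,
                                   derive_seed(spec$seed, 29,
                                               match(ch, spec$channels))))
  }
  fovs
}

#' Simulate flat-field calibration tiles
#'
#' Renders fields of view of a featureless, uniformly fluorescent target
#' (constant expected intensity times the channel's vignette, plus camera
#' noise) — the dedicated calibration acquisition from which per-channel
#' flat-field references are built.
#'
#' @param spec An `acq_spec`.
#' @param channel Channel name.
#' @param n Number of calibration tiles.
#' @param level Expected grey value of the flat target at tile centre.
#' @return List of `field_of_view` (cycle 0, grid position (0, 0)).
#' @export
simulate_calibration_fovs <- function(spec, channel, n = 20, level = 5000) {
  vig <- vignette_field(spec, channel)
  with_seed(derive_seed(spec$seed, 37, match(channel, spec$channels)), {
    lapply(seq_len(n), function(i) {
      px <- quantize16(add_camera_noise(level * vig, spec$noise))
      field_of_view(px, channel, 0L, c(0L, 0L),
                    spec$exposure_ms[[channel]], c(0, 0))
    })
  })
}

# Expected pixel-based SBR per marker from the noise-free scene at the
# marker's own staining cycle: mean over its positive compartment vs the
# rest of the canvas, on the AF-subtracted channel scene (includes
# carry-over from earlier cycles' markers on the same channel).
scene_true_sbr <- function(phantom, spec) {
  pan <- phantom$panel
  vapply(seq_len(nrow(pan)), function(j) {
    m <- pan[j, ]
    scene <- channel_scene(phantom, spec, m$channel, m$cycle)
    af <- phantom$af_field[[m$channel]]
    if (!is.null(af)) scene <- scene - af
    pos <- attr(render_marker_scene(phantom, m$marker), "pos_mask")
    mean(scene[pos]) / mean(scene[!pos])
  }, numeric(1)) |> stats::setNames(pan$marker)
}

#' Simulate a complete seqIF acquisition with ground truth
#'
#' Runs the autofluorescence baseline plus all staining cycles and
#' assembles the ground-truth ledger used by parameter-recovery tests.
#'
#' @param spec An `acq_spec`.
#' @param phantom Optional `tissue_phantom`; generated to match the grid
#'   (using `spec$seed`, `n_nuclei` and `panel`) when `NULL`.
#' @param panel Marker panel used when `phantom` is `NULL`.
#' @param n_nuclei Number of cells when `phantom` is `NULL`.
#' @return An object of class `seqif_run`: `phantom`, `spec`, `baseline`
#'   (cycle-0 tiles), `cycles` (list of per-cycle tile lists) and
#'   `ground_truth`.
#' @export
simulate_run <- function(spec, phantom = NULL,
                         panel = marker_panel(c("CD20", "CD3", "panCK", "CD68")),
                         n_nuclei = 60) {
  if (is.null(phantom)) {
    geom <- tile_geometry(spec)
    phantom <- make_phantom(n_nuclei, panel, canvas_size = geom$canvas_size,
                            seed = spec$seed)
  }
  baseline <- render_autofluorescence_baseline(phantom, spec)
  cycles <- vector("list", spec$n_cycles)
  drifts <- vector("list", spec$n_cycles)
  residual_scales <- vector("list", spec$n_cycles)
  for (k in seq_len(spec$n_cycles)) {
    rc <- render_cycle(phantom, spec, k)
    cycles[[k]] <- rc$fovs
    drifts[[k]] <- rc$truth$drift
    residual_scales[[k]] <- rc$truth$residual_scales
  }
  pan <- phantom$panel
  true_sbr <- scene_true_sbr(phantom, spec)
  gt <- structure(
    list(spec = spec,
         # transforms mapping each cycle's mosaic back to the cycle-1 frame
         per_cycle_transforms = lapply(drifts, invert_rigid),
         per_cycle_drift = drifts,
         per_cycle_residual_scales = residual_scales,
         elution_residual = spec$elution_residual,
         true_elution_efficiency = 100 * (1 - spec$elution_residual),
         true_sbr = true_sbr,
         vignette = lapply(stats::setNames(spec$channels, spec$channels),
                           function(ch) vignette_field(spec, ch)),
         af_field = phantom$af_field,
         nuclei = phantom$nuclei,
         phenotypes = phantom$phenotypes),
    class = "ground_truth")
  structure(list(phantom = phantom, spec = spec, baseline = baseline,
                 cycles = cycles, ground_truth = gt),
            class = "seqif_run")
}

#' @export
print.seqif_run <- function(x, ...) {
  cat(sprintf("seqif_run: %d cycles + AF baseline, %d tiles total\n",
              x$spec$n_cycles,
              length(x$baseline) + sum(lengths(x$cycles))))
  invisible(x)
}

#' Simulate an elution-efficiency measurement triplet
#'
#' Generates the three registered images the elution-efficiency estimator
#' needs: the secondary-antibody-only negative control before staining,
#' the full stain, and the negative control re-imaged after elution with a
#' known residual fraction of the specific signal left behind. Background
#' (autofluorescence + non-specific secondary binding) is additive and
#' unchanged by elution, so the true efficiency is exactly
#' `100 * (1 - residual)`.
#'
#' @param phantom A `tissue_phantom`.
#' @param marker Marker to stain.
#' @param residual Fraction of specific signal surviving elution, in
#'   `[0, 1]`.
#' @param noise Camera noise model as in [acquisition_spec()], or `NULL`.
#' @param seed Integer seed.
#' @param elution_background_shift Optional constant added to the
#'   post-elution negative control everywhere (a global background change
#'   caused by the elution cycle; cancelled by the estimator's NEG term).
#' @return An `elution_triplet` with ground-truth positive/negative masks.
#' @export
simulate_elution_triplet <- function(phantom, marker, residual,
                                     noise = list(gain = 0.5, read_sigma = 2),
                                     seed = 1,
                                     elution_background_shift = 0) {
  if (residual < 0 || residual > 1)
    stop_bad("simulate_elution_triplet: residual must be in [0, 1]")
  j <- match(marker, phantom$panel$marker)
  if (is.na(j)) stop_bad("simulate_elution_triplet: unknown marker")
  row <- phantom$panel[j, ]
  ch <- row$channel
  af <- phantom$af_field[[ch]]
  if (is.null(af)) af <- matrix(0, phantom$canvas_size[1], phantom$canvas_size[2])
  stain <- render_marker_scene(phantom, marker)
  pos <- attr(stain, "pos_mask")
  delta <- stain - row$negative_intensity
  neg_ctrl_scene <- af + row$negative_intensity
  staining_scene <- af + stain
  elu_scene <- af + row$negative_intensity + residual * delta +
    elution_background_shift
  imgs <- with_seed(derive_seed(seed, 41), {
    lapply(list(neg_ctrl_scene, staining_scene, elu_scene), function(s)
      quantize16(add_camera_noise(s, noise)))
  })
  neg_mask <- !dilate_mask(pos, 3)
  elution_triplet(neg_ctrl = imgs[[1]], staining = imgs[[2]],
                  elu_neg_ctrl = imgs[[3]], pos_mask = pos,
                  neg_mask = neg_mask)
}

#' Simulate an epitope-stability staining series
#'
#' Produces background-subtracted staining layers of one marker at the
#' initial staining and after each elution-cycle checkpoint, with the
#' specific stain intensity solved so that the true signal-to-background
#' ratio follows a prescribed retention schedule (e.g. `(1 - d)^k` for a
#' per-cycle epitope decay `d`).
#'
#' @param phantom A `tissue_phantom`.
#' @param marker Marker to stain.
#' @param checkpoints Strictly increasing elution-cycle counts, e.g.
#'   `c(1, 5, 10, 15, 20)`.
#' @param retention Per-checkpoint target SBR as a fraction of the initial
#'   SBR; either a vector matching `checkpoints` or computed from
#'   `decay_per_cycle`.
#' @param decay_per_cycle Per-cycle fractional SBR loss `d`, used when
#'   `retention` is `NULL`: retention at checkpoint `k` is `(1 - d)^k`.
#' @param noise Camera noise model, or `NULL`.
#' @param seed Integer seed.
#' @return List with `initial` (layer), `post` (named list of layers keyed
#'   by checkpoint), `pos_mask`, and the `retention` schedule used.
#' @export
simulate_stability_series <- function(phantom, marker, checkpoints = c(1, 5, 10, 15, 20),
                                      retention = NULL, decay_per_cycle = 0.01,
                                      noise = list(gain = 0.5, read_sigma = 2),
                                      seed = 1) {
  if (is.unsorted(checkpoints, strictly = TRUE))
    stop_bad("simulate_stability_series: checkpoints must be strictly increasing")
  if (is.null(retention)) retention <- (1 - decay_per_cycle)^checkpoints
  if (length(retention) != length(checkpoints))
    stop_bad("simulate_stability_series: retention must match checkpoints")
  j <- match(marker, phantom$panel$marker)
  if (is.na(j)) stop_bad("simulate_stability_series: unknown marker")
  row <- phantom$panel[j, ]
  p <- row$positive_intensity; n <- row$negative_intensity
  sbr0 <- p / n
  scale_for <- function(ret) {
    target_pos <- ret * sbr0 * n
    s <- (target_pos - n) / (p - n)
    if (s < 0) stop_bad("simulate_stability_series: retention ", ret,
                        " drives the stain below background; unreachable")
    s
  }
  render_one <- function(scale, sub_seed) {
    scene <- render_marker_scene(phantom, marker, intensity_scale = scale)
    with_seed(derive_seed(seed, 43, sub_seed),
              quantize16(add_camera_noise(scene, noise)))
  }
  initial <- render_one(1, 0)
  post <- lapply(seq_along(checkpoints), function(i)
    render_one(scale_for(retention[i]), i))
  names(post) <- as.character(checkpoints)
  list(initial = initial, post = post,
       pos_mask = attr(render_marker_scene(phantom, marker), "pos_mask"),
       checkpoints = checkpoints, retention = retention)
}
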