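# Mosaic assembly: stitch tiles into per-cycle mosaics, estimate the
# cross-cycle rigid (Euclidean) transform from the DAPI channel, resample
# every layer into the cycle-1 frame, optionally subtract the
# autofluorescence baseline, and emit the final multi-layer stack.

# Per-tile feathering weight: linear ramps across the overlap strip on
# edges that have a neighbour, so overlapping weights sum to 1 exactly.
feather_weight <- function(tile_size, overlap_px, has_prev, has_next) {
  ramp <- function(n, ov, prev, nxt) {
    w <- rep(1, n)
    if (ov > 0) {
      r <- (seq_len(ov) - 0.5) / ov
      if (prev) w[seq_len(ov)] <- r
      if (nxt) w[n - seq_len(ov) + 1] <- r
    }
    w
  }
  outer(ramp(tile_size[1], overlap_px[1], has_prev[1], has_next[1]),
        ramp(tile_size[2], overlap_px[2], has_prev[2], has_next[2]))
}

#' Stitch one cycle+channel's tiles into a mosaic
#'
#' Places each tile at its stage offset and blends overlap strips with
#' linear feathering. With zero overlap the mosaic is the exact block
#' concatenation of the tiles.
#'
#' @param fovs List of `field_of_view` tiles of a single cycle and
#'   channel, covering the full grid.
#' @param grid_shape Integer `(rows, cols)`.
#' @param overlap_fraction Overlap fraction used at acquisition.
#' @return Float mosaic matrix.
#' @export
stitch <- function(fovs, grid_shape, overlap_fraction) {
  if (length(fovs) == 0) stop_bad("stitch: no tiles given")
  chans <- unique(vapply(fovs, `[[`, character(1), "channel"))
  cycs <- unique(vapply(fovs, function(f) f$cycle, integer(1)))
  if (length(chans) != 1 || length(cycs) != 1)
    stop_bad("stitch: tiles must be from a single cycle and channel")
  tile_size <- dim(fovs[[1]]$pixels)
  pos <- t(vapply(fovs, function(f) f$grid_pos, integer(2)))
  want <- expand.grid(row = 0:(grid_shape[1] - 1), col = 0:(grid_shape[2] - 1))
  have <- paste(pos[, 1], pos[, 2])
  missing <- want[!paste(want$row, want$col) %in% have, , drop = FALSE]
  if (nrow(missing) > 0)
    stop_bad("stitch: incomplete grid; missing positions ",
             paste(sprintf("(%d, %d)", missing$row, missing$col),
                   collapse = ", "))
  if (length(fovs) != grid_shape[1] * grid_shape[2])
    stop_bad("stitch: expected ", grid_shape[1] * grid_shape[2],
             " tiles for a ", grid_shape[1], "x", grid_shape[2],
             " grid, got ", length(fovs))
  step <- pmax(round(tile_size * (1 - overlap_fraction)), 1)
  ov <- tile_size - step
  canvas <- c((grid_shape[1] - 1) * step[1] + tile_size[1],
              (grid_shape[2] - 1) * step[2] + tile_size[2])
  acc <- matrix(0, canvas[1], canvas[2])
  wacc <- matrix(0, canvas[1], canvas[2])
  for (f in fovs) {
    r <- f$grid_pos[1]; cc <- f$grid_pos[2]
    w <- feather_weight(tile_size, ov,
                        has_prev = c(r > 0, cc > 0),
                        has_next = c(r < grid_shape[1] - 1,
                                     cc < grid_shape[2] - 1))
    ys <- r * step[1] + seq_len(tile_size[1])
    xs <- cc * step[2] + seq_len(tile_size[2])
    acc[ys, xs] <- acc[ys, xs] + w * f$pixels
    wacc[ys, xs] <- wacc[ys, xs] + w
  }
  acc / wacc
}

#' Estimate the rigid transform aligning one DAPI mosaic onto another
#'
#' Phase correlation provides a coarse integer translation; a Nelder-Mead
#' refinement over (rotation, dy, dx) then minimizes the masked mean
#' squared intensity difference of the bilinearly warped moving image
#' against the reference. Returns the transform mapping `moving` onto
#' `reference`, i.e. `resample(moving, tf)` is aligned with `reference`.
#'
#' @param reference,moving Same-shaped mosaics with DAPI content.
#' @param max_shift_px Search bound for the coarse translation.
#' @param presmooth_sigma Gaussian presmoothing applied to both images
#'   before matching (stabilizes the cost surface on hard-edged nuclei).
#' @return A `rigid_transform` (rotation about the image centre).
#' @export
estimate_transform <- function(reference, moving, max_shift_px = 20,
                               presmooth_sigma = 1) {
  stopifnot(is.matrix(reference), is.matrix(moving))
  if (!all(dim(reference) == dim(moving)))
    stop_bad("estimate_transform: mosaics must share a shape")
  if (stats::sd(reference) < 1e-8 || stats::sd(moving) < 1e-8)
    stop_bad("estimate_transform: registration failed, image has no features")
  ref <- reference; mov <- moving
  if (presmooth_sigma > 0) {
    ref <- EBImage::gblur(ref, presmooth_sigma)
    mov <- EBImage::gblur(mov, presmooth_sigma)
  }
  h <- nrow(ref); w <- ncol(ref)
  # phase correlation: moving(y) ~ ref(y - t)  =>  peak at t
  Fr <- stats::fft(ref - mean(ref))
  Fm <- stats::fft(mov - mean(mov))
  R <- Fm * Conj(Fr)
  R <- R / pmax(Mod(R), 1e-12)
  corr <- Re(stats::fft(R, inverse = TRUE))
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  t0 <- c(pk[1] - 1, pk[2] - 1)
  t0 <- ifelse(t0 > c(h, w) / 2, t0 - c(h, w), t0)
  if (any(abs(t0) > max_shift_px))
    t0 <- pmax(pmin(t0, max_shift_px), -max_shift_px)
  ctr <- (c(h, w) - 1) / 2
  # central crop avoids drift-exposed borders dominating the cost
  m <- ceiling(max(abs(t0)) + 6)
  ys <- (m + 1):(h - m); xs <- (m + 1):(w - m)
  cost <- function(par) {
    tf <- rigid_transform(par[1], par[2:3], ctr)
    al <- resample(mov, tf)
    v <- attr(al, "valid")[ys, xs]
    d <- (al[ys, xs] - ref[ys, xs])[v]
    mean(d * d)
  }
  # phase peak is the content shift; the aligner starts at its negation
  fit <- stats::optim(c(0, -t0[1], -t0[2]), cost, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 800,
                                     parscale = c(0.1, 1, 1)))
  rigid_transform(fit$par[1], fit$par[2:3], ctr)
}

#' Subtract the autofluorescence baseline from a layer
#'
#' @param layer Image registered to the reference frame.
#' @param af_baseline Autofluorescence baseline image in the same frame.
#' @param exposure_ratio Ratio layer-exposure / baseline-exposure used to
#'   scale the baseline before subtraction.
#' @return `pmax(layer - af_baseline * exposure_ratio, 0)`.
#' @export
subtract_autofluorescence <- function(layer, af_baseline, exposure_ratio = 1) {
  if (!all(dim(layer) == dim(af_baseline)))
    stop_bad("subtract_autofluorescence: shape mismatch")
  pmax(layer - af_baseline * exposure_ratio, 0)
}

#' Assemble a complete acquisition into an aligned multi-layer stack
#'
#' For every cycle: flat-field-correct the tiles (optional), stitch each
#' channel, estimate the cycle's rigid transform from its DAPI mosaic
#' against cycle 1, and resample the marker channels into the cycle-1
#' frame. Marker layers are named from the panel when given, else
#' `cycleK_CHANNEL`. Optionally subtracts the (stitched, corrected)
#' autofluorescence baseline from every marker layer, scaled by the
#' exposure ratio.
#'
#' @param acq A `seqif_run` or `seqif_acquisition` (from [simulate_run()]
#'   or [read_acquisition()]).
#' @param flatfield Named list of `flatfield_ref` per channel, `TRUE` to
#'   build references from all of the acquisition's own tiles per channel,
#'   or `FALSE`/`NULL` to skip correction.
#' @param subtract_af Logical; subtract the AF baseline from marker
#'   layers (requires baseline tiles in the acquisition).
#' @param panel Optional marker panel (`marker`, `cycle`, `channel`) used
#'   to name marker layers.
#' @param keep_af_layers Logical; append the stitched AF baseline marker
#'   channels as extra layers.
#' @param crop_margin_px `"auto"` (default) trims from every side the
#'   largest corner displacement among the estimated cycle transforms, so
#'   no layer contains resampling fill; a number trims that many pixels;
#'   0 disables cropping.
#' @return A `seqif_stack`: cycle-1 DAPI reference layer first, then
#'   marker layers in cycle order. The estimated per-cycle transforms are
#'   attached as `$transforms`.
#' @export
assemble_run <- function(acq, flatfield = TRUE, subtract_af = FALSE,
                         panel = NULL, keep_af_layers = FALSE,
                         crop_margin_px = "auto") {
  spec <- acq$spec
  if (is.null(panel) && !is.null(acq$phantom)) panel <- acq$phantom$panel
  chans <- spec$channels
  marker_chans <- setdiff(chans, "DAPI")
  refs <- NULL
  if (isTRUE(flatfield)) {
    all_fovs <- c(acq$baseline, do.call(c, acq$cycles))
    refs <- lapply(stats::setNames(chans, chans), function(ch)
      build_flatfield_reference(all_fovs, ch))
  } else if (is.list(flatfield)) {
    refs <- flatfield
  }
  correct <- function(fovs) {
    if (is.null(refs)) return(fovs)
    lapply(fovs, function(f) apply_flatfield(f, refs[[f$channel]]))
  }
  stitch_channel <- function(fovs, ch) {
    sel <- Filter(function(f) f$channel == ch, fovs)
    stitch(correct(sel), spec$grid_shape, spec$overlap_fraction)
  }
  n_cycles <- length(acq$cycles)
  exposure <- spec$exposure_ms
  # cycle mosaics + transforms
  dapi_ref <- NULL
  layers <- list(); meta <- list()
  transforms <- vector("list", n_cycles)
  af_mosaics <- NULL
  if ((subtract_af || keep_af_layers)) {
    if (length(acq$baseline) == 0)
      stop_bad("assemble_run: AF subtraction requested but the acquisition ",
               "has no baseline tiles")
    af_mosaics <- lapply(stats::setNames(marker_chans, marker_chans),
                         function(ch) stitch_channel(acq$baseline, ch))
  }
  for (k in seq_len(n_cycles)) {
    fovs <- acq$cycles[[k]]
    dapi_k <- tryCatch(
      stitch_channel(fovs, "DAPI"),
      error = function(e) stop_bad("assemble_run: cycle ", k, " DAPI: ",
                                   conditionMessage(e)))
    if (k == 1) {
      dapi_ref <- dapi_k
      transforms[[k]] <- rigid_transform(0, c(0, 0),
                                         (dim(dapi_ref) - 1) / 2)
    } else {
      transforms[[k]] <- tryCatch(
        estimate_transform(dapi_ref, dapi_k),
        error = function(e) stop_bad("assemble_run: cycle ", k,
                                     " registration: ", conditionMessage(e)))
    }
    for (ch in marker_chans) {
      mk <- NULL
      if (!is.null(panel)) {
        hit <- panel$marker[panel$cycle == k & panel$channel == ch]
        if (length(hit) == 1) mk <- hit
      }
      nm <- if (!is.null(mk)) mk else sprintf("cycle%02d_%s", k, ch)
      mos <- tryCatch(
        stitch_channel(fovs, ch),
        error = function(e) stop_bad("assemble_run: cycle ", k, " ", ch,
                                     ": ", conditionMessage(e)))
      aligned <- resample(mos, transforms[[k]])
      if (subtract_af)
        aligned <- subtract_autofluorescence(
          aligned, af_mosaics[[ch]],
          exposure_ratio = exposure[[ch]] / exposure[[ch]])
      layers[[nm]] <- aligned
      meta[[length(meta) + 1]] <- data.frame(
        name = nm, marker = if (!is.null(mk)) mk else NA_character_,
        cycle = k, channel = ch, exposure_ms = exposure[[ch]],
        is_reference = FALSE, stringsAsFactors = FALSE)
    }
  }
  out_layers <- c(list(DAPI = dapi_ref), layers)
  out_meta <- rbind(
    data.frame(name = "DAPI", marker = "DAPI", cycle = 1, channel = "DAPI",
               exposure_ms = exposure[["DAPI"]], is_reference = TRUE,
               stringsAsFactors = FALSE),
    do.call(rbind, meta))
  if (keep_af_layers) {
    for (ch in marker_chans) {
      nm <- paste0("AF_", ch)
      out_layers[[nm]] <- af_mosaics[[ch]]
      out_meta <- rbind(out_meta, data.frame(
        name = nm, marker = NA_character_, cycle = 0, channel = ch,
        exposure_ms = exposure[[ch]], is_reference = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  if (identical(crop_margin_px, "auto")) {
    d <- dim(dapi_ref)
    corners <- rbind(c(0, 0), c(0, d[2] - 1), c(d[1] - 1, 0), d - 1)
    crop_margin_px <- max(vapply(transforms, function(tf)
      max(abs(transform_points(tf, corners) - corners)), numeric(1)))
    crop_margin_px <- ceiling(crop_margin_px)
  }
  if (crop_margin_px > 0) {
    m <- crop_margin_px
    d <- dim(out_layers[[1]])
    if (2 * m >= min(d))
      stop_bad("assemble_run: crop margin ", m, " px consumes the mosaic")
    out_layers <- lapply(out_layers, function(x) {
      x <- x[(m + 1):(d[1] - m), (m + 1):(d[2] - m)]
      attr(x, "valid") <- NULL
      x
    })
  }
  stk <- seqif_stack(out_layers, out_meta, spec$pixel_size_um)
  stk$transforms <- transforms
  stk
}
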