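# Flat-field (vignetting) correction. A per-channel reference image is
# built by averaging many fields of view, smoothing away scene structure,
# and normalizing on a floating-point scale so the lowest pixel value is
# exactly 1; each FoV is then divided by its reference. Corner pixels (at
# the reference minimum) are unchanged while the brighter centre is
# dimmed, flattening the mosaic's tiling pattern.

#' Build a per-channel flat-field reference image
#'
#' @param fovs List of `field_of_view` tiles (mixed channels allowed; only
#'   `channel` is used).
#' @param channel Channel to build the reference for.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels; default
#'   tile_width / 16, enough to erase cell-scale structure while keeping
#'   the low-order vignette bowl.
#' @param method `"mean"` (default) or `"median"` pixelwise averaging;
#'   median resists bright cells in the training tiles.
#' @return An object of class `flatfield_ref` with fields `channel`,
#'   `image` (float, min exactly 1), `n_fovs`, `smoothing_sigma`.
#' @export
build_flatfield_reference <- function(fovs, channel, smoothing_sigma = NULL,
                                      method = c("mean", "median")) {
  method <- match.arg(method)
  sel <- Filter(function(f) f$channel == channel, fovs)
  if (length(sel) == 0)
    stop_bad("build_flatfield_reference: no FoVs of channel '", channel, "'")
  if (length(sel) == 1)
    warning("build_flatfield_reference: only one FoV of channel '", channel,
            "'; reference built in degraded single-tile mode", call. = FALSE)
  dims <- vapply(sel, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop_bad("build_flatfield_reference: tiles must share one shape")
  if (is.null(smoothing_sigma)) smoothing_sigma <- dims[2, 1] / 16
  arr <- array(unlist(lapply(sel, `[[`, "pixels")),
               dim = c(dims[1, 1], dims[2, 1], length(sel)))
  avg <- if (method == "mean") rowMeans(arr, dims = 2) else
    apply(arr, c(1, 2), stats::median)
  sm <- if (smoothing_sigma > 0)
    EBImage::gblur(avg, sigma = smoothing_sigma, boundary = "replicate")
  else avg
  sm <- pmax(sm, .Machine$double.eps)
  ref <- sm / min(sm)
  structure(list(channel = channel, image = ref, n_fovs = length(sel),
                 smoothing_sigma = smoothing_sigma, method = method),
            class = "flatfield_ref")
}

#' @export
print.flatfield_ref <- function(x, ...) {
  cat(sprintf("flatfield_ref (%s): %dx%d px from %d FoVs, sigma %.1f, range [%.4f, %.4f]\n",
              x$channel, nrow(x$image), ncol(x$image), x$n_fovs,
              x$smoothing_sigma, min(x$image), max(x$image)))
  invisible(x)
}

#' Apply flat-field correction to one field of view
#'
#' Divides the tile pixelwise by its channel's reference image. Because
#' the reference is >= 1 everywhere with minimum exactly 1, correction
#' never brightens a pixel: the darkest-corner pixels are unchanged and
#' the centre is dimmed. The result is kept in floating point;
#' quantization back to 16 bits happens at stack-write time.
#'
#' @param fov A `field_of_view` (or bare matrix).
#' @param ref A `flatfield_ref` of the same channel and tile shape.
#' @return Corrected `field_of_view` with float `pixels` (or float matrix
#'   if a matrix was given).
#' @export
apply_flatfield <- function(fov, ref) {
  stopifnot(inherits(ref, "flatfield_ref"))
  if (is.matrix(fov)) {
    if (!all(dim(fov) == dim(ref$image)))
      stop_bad("apply_flatfield: shape mismatch")
    return(fov / ref$image)
  }
  stopifnot(inherits(fov, "field_of_view"))
  if (!all(dim(fov$pixels) == dim(ref$image)))
    stop_bad("apply_flatfield: tile is ", nrow(fov$pixels), "x",
             ncol(fov$pixels), " but reference is ", nrow(ref$image), "x",
             ncol(ref$image))
  if (fov$channel != ref$channel)
    stop_bad("apply_flatfield: channel mismatch (tile ", fov$channel,
             ", reference ", ref$channel, ")")
  out <- fov
  out$pixels <- fov$pixels / ref$image
  out
}

#' Save / load a flat-field reference (float TIFF + JSON provenance)
#'
#' @param ref A `flatfield_ref`.
#' @param path Output TIFF path; provenance goes to `<path>.json`.
#' @return `path` invisibly; `load_flatfield_reference()` returns the
#'   `flatfield_ref`.
#' @export
save_flatfield_reference <- function(ref, path) {
  tiff::writeTIFF(ref$image / max(ref$image), path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channel = ref$channel, n_fovs = ref$n_fovs,
         smoothing_sigma = ref$smoothing_sigma, method = ref$method,
         max_value = max(ref$image)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_flatfield_reference
#' @export
load_flatfield_reference <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path) * meta$max_value
  img <- img / min(img) # restore exact min-1 normalization
  structure(list(channel = meta$channel, image = img, n_fovs = meta$n_fovs,
                 smoothing_sigma = meta$smoothing_sigma,
                 method = meta$method),
            class = "flatfield_ref")
}

#' Power of the tile-grid periodicity in a mosaic
#'
#' Diagnostic for residual tiling structure: sums the 2-D spectral power
#' at the tile-grid fundamental frequencies (and harmonics) along each
#' axis. On a flat scene a vignetted mosaic shows strong grid-frequency
#' power; after flat-field correction it should drop by an order of
#' magnitude.
#'
#' @param mosaic Numeric matrix (stitched mosaic).
#' @param grid_shape Integer `(rows, cols)` of the tile grid.
#' @param n_harmonics Number of harmonics of the grid frequency to sum.
#' @return Scalar power (|FFT|^2, mean-removed image).
#' @export
mosaic_grid_power <- function(mosaic, grid_shape, n_harmonics = 3) {
  m <- mosaic - mean(mosaic)
  F2 <- Mod(stats::fft(m))^2
  h <- nrow(m); w <- ncol(m)
  p <- 0
  for (k in seq_len(n_harmonics)) {
    fy <- (k * grid_shape[1]) %% h
    fx <- (k * grid_shape[2]) %% w
    p <- p + F2[fy + 1, 1] + F2[h - fy + ifelse(fy == 0, 1 - h, 1), 1] +
      F2[1, fx + 1] + F2[1, w - fx + ifelse(fx == 0, 1 - w, 1)]
  }
  p / (h * w)
}
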