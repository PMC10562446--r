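# Acquisition geometry: tile grid, overlap, per-channel vignette,
# exposures, inter-cycle drift, elution residuals and the camera noise
# model. Defaults mirror the instrument scaled down for desk-size runs:
# the full-scale scan is a 17 x 21 grid (357 tiles) at 0.23 um/px in three
# channels (DAPI, TRITC, Cy5), two markers per cycle.

#' Describe a tiled multi-cycle acquisition
#'
#' @param grid_shape Integer `(rows, cols)` of the tile grid. The
#'   instrument's full scan is `c(17, 21)`; the default `c(3, 4)` keeps
#'   simulated runs seconds-scale.
#' @param tile_size Integer `(height, width)` of one field of view in px.
#' @param overlap_fraction Fraction of tile size shared between adjacent
#'   tiles, in `[0, 1)`.
#' @param channels Ordered channel names; first must be the DAPI
#'   counterstain channel.
#' @param pixel_size_um Pixel size in micrometres (instrument: 0.23).
#' @param n_cycles Number of staining cycles.
#' @param exposure_ms Named numeric vector of per-channel exposure times in
#'   milliseconds, constant across cycles.
#' @param vignette_strength Named per-channel depth of the multiplicative
#'   vignette bowl in `[0, 1)`; 0 disables vignetting (field equals 1
#'   everywhere).
#' @param cycle_drift Either `NULL` (no drift), `"random"` (small random
#'   rigid drift per cycle, <= `drift_max_px` translation and
#'   <= `drift_max_deg` rotation), or a `n_cycles x 3` matrix of
#'   `(rotation_deg, dy_px, dx_px)` rows. Cycle 1 is always identity.
#' @param drift_max_px,drift_max_deg Bounds used when `cycle_drift =
#'   "random"`.
#' @param elution_residual Fraction of specific marker signal surviving
#'   each elution, scalar or per-cycle vector, in `[0, 1]`; 0 is perfect
#'   elution.
#' @param noise `NULL` to disable noise, or a list with `gain` (grey
#'   values per photon, Poisson shot noise) and `read_sigma` (Gaussian
#'   read noise sd in grey values).
#' @param seed Integer seed governing all randomness of the simulated run.
#' @return An object of class `acq_spec`.
#' @export
acquisition_spec <- function(grid_shape = c(3, 4),
                             tile_size = c(48, 48),
                             overlap_fraction = 0.1,
                             channels = c("DAPI", "TRITC", "Cy5"),
                             pixel_size_um = 0.23,
                             n_cycles = 2,
                             exposure_ms = c(DAPI = 50, TRITC = 100, Cy5 = 100),
                             vignette_strength = c(DAPI = 0.25, TRITC = 0.3,
                                                   Cy5 = 0.2),
                             cycle_drift = "random",
                             drift_max_px = 5, drift_max_deg = 0.5,
                             elution_residual = 0.05,
                             noise = list(gain = 0.5, read_sigma = 2),
                             seed = 1) {
  stopifnot(length(grid_shape) == 2, length(tile_size) == 2)
  if (any(grid_shape < 1) || any(tile_size < 4))
    stop_bad("acquisition_spec: grid_shape >= 1 and tile_size >= 4 required")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_bad("acquisition_spec: overlap_fraction must be in [0, 1)")
  if (channels[1] != "DAPI")
    stop_bad("acquisition_spec: first channel must be DAPI")
  if (!is_count(n_cycles) || n_cycles < 1)
    stop_bad("acquisition_spec: n_cycles must be a positive integer")
  elution_residual <- rep_len(elution_residual, n_cycles)
  if (any(elution_residual < 0 | elution_residual > 1))
    stop_bad("acquisition_spec: elution_residual must be in [0, 1]")
  if (!all(channels %in% names(exposure_ms)))
    stop_bad("acquisition_spec: exposure_ms must name every channel")
  if (any(exposure_ms <= 0))
    stop_bad("acquisition_spec: exposures must be positive")
  vignette_strength <- vignette_strength[channels]
  if (anyNA(vignette_strength) || any(vignette_strength < 0) ||
      any(vignette_strength >= 1))
    stop_bad("acquisition_spec: vignette_strength must name every channel, values in [0, 1)")
  if (is.matrix(cycle_drift)) {
    if (nrow(cycle_drift) != n_cycles || ncol(cycle_drift) != 3)
      stop_bad("acquisition_spec: cycle_drift matrix must be n_cycles x 3")
  } else if (!is.null(cycle_drift) && !identical(cycle_drift, "random")) {
    stop_bad("acquisition_spec: cycle_drift must be NULL, 'random' or a matrix")
  }
  if (!is.null(noise) &&
      (!is.list(noise) || is.null(noise$gain) || is.null(noise$read_sigma)))
    stop_bad("acquisition_spec: noise must be NULL or list(gain, read_sigma)")
  structure(
    list(grid_shape = as.integer(grid_shape),
         tile_size = as.integer(tile_size),
         overlap_fraction = overlap_fraction,
         channels = channels,
         pixel_size_um = pixel_size_um,
         n_cycles = as.integer(n_cycles),
         exposure_ms = exposure_ms,
         reference_exposure_ms = 100,
         vignette_strength = vignette_strength,
         cycle_drift = cycle_drift,
         drift_max_px = drift_max_px,
         drift_max_deg = drift_max_deg,
         elution_residual = elution_residual,
         noise = noise,
         seed = as.integer(seed)),
    class = "acq_spec")
}

#' @export
print.acq_spec <- function(x, ...) {
  cat(sprintf("acq_spec: %dx%d grid of %dx%d px tiles (overlap %.0f%%), %d cycles, channels %s\n",
              x$grid_shape[1], x$grid_shape[2], x$tile_size[1],
              x$tile_size[2], 100 * x$overlap_fraction, x$n_cycles,
              paste(x$channels, collapse = "/")))
  invisible(x)
}

#' Tile grid geometry of an acquisition
#'
#' @param spec An `acq_spec`.
#' @return List with `step` `(dy, dx)` between tile origins, `offsets`
#'   (data.frame of 0-based `(row, col, offset_y, offset_x)` per tile) and
#'   `canvas_size` of the stitched mosaic.
#' @export
tile_geometry <- function(spec) {
  step <- round(spec$tile_size * (1 - spec$overlap_fraction))
  step <- pmax(step, 1L)
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  g <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  offs <- data.frame(row = g$row, col = g$col,
                     offset_y = g$row * step[1], offset_x = g$col * step[2])
  canvas <- c((rows - 1L) * step[1] + spec$tile_size[1],
              (cols - 1L) * step[2] + spec$tile_size[2])
  list(step = step, offsets = offs, canvas_size = as.integer(canvas))
}

#' Per-channel multiplicative vignette field on one tile
#'
#' Radially symmetric polynomial bowl, brightest (exactly 1) at the tile
#' centre and darker towards the corners, emulating angle-dependent light
#' loss in the optical path.
#'
#' @param spec An `acq_spec`.
#' @param channel Channel name.
#' @return Float matrix of `tile_size`, values in `(0, 1]`, max exactly 1.
#' @export
vignette_field <- function(spec, channel) {
  a <- spec$vignette_strength[[channel]]
  h <- spec$tile_size[1]; w <- spec$tile_size[2]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  yy <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  r2 <- ((yy - cy)^2 + (xx - cx)^2) / (cy^2 + cx^2)
  v <- 1 - a * r2
  v / max(v) # max exactly 1 at centre
}

# Materialize per-cycle drift transforms (cycle 1 identity). Rotation
# centre is the mosaic canvas centre.
cycle_drift_transforms <- function(spec) {
  geom <- tile_geometry(spec)
  ctr <- (geom$canvas_size - 1) / 2
  n <- spec$n_cycles
  if (is.null(spec$cycle_drift)) {
    mat <- matrix(0, n, 3)
  } else if (is.matrix(spec$cycle_drift)) {
    mat <- spec$cycle_drift
  } else {
    mat <- with_seed(derive_seed(spec$seed, 23), {
      cbind(stats::runif(n, -spec$drift_max_deg, spec$drift_max_deg),
            stats::runif(n, -spec$drift_max_px, spec$drift_max_px),
            stats::runif(n, -spec$drift_max_px, spec$drift_max_px))
    })
  }
  mat[1, ] <- 0 # cycle 1 defines the reference frame
  lapply(seq_len(n), function(k)
    rigid_transform(mat[k, 1], mat[k, 2:3], ctr))
}

# Poisson-Gaussian camera: photons ~ Pois(E/gain), grey = gain*photons +
# N(0, read_sigma). `NULL` noise returns the expectation unchanged.
add_camera_noise <- function(expected, noise) {
  if (is.null(noise)) return(expected)
  g <- noise$gain
  lam <- pmax(expected, 0) / g
  shot <- matrix(stats::rpois(length(lam), as.vector(lam)),
                 nrow(expected), ncol(expected)) * g
  shot + matrix(stats::rnorm(length(lam), 0, noise$read_sigma),
                nrow(expected), ncol(expected))
}
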