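# Cell-phantom tissue model: nuclei, per-marker phenotypes, subcellular
# compartment rendering and a smooth autofluorescence field. The phantom
# stands in for a stained tissue section (e.g. FFPE tonsil) so that every
# downstream stage can be exercised against known ground truth.

#' Define a marker panel for the phantom
#'
#' Builds the per-marker description used by [make_phantom()] and the
#' renderer. Each marker has a subcellular localisation pattern, a positive
#' prevalence among cells, and positive / non-specific (negative) staining
#' intensities on the 16-bit grey-value scale.
#'
#' @param markers Character vector of marker names.
#' @param compartment Per-marker localisation, one of `"nuclear"`,
#'   `"cytoplasmic"`, `"membrane"` (recycled).
#' @param prevalence Per-marker probability that a cell is positive
#'   (recycled).
#' @param positive_intensity,negative_intensity Mean grey value of the
#'   specific stain in positive cells and of the non-specific baseline over
#'   the tissue (recycled). Positive must exceed negative.
#' @param cycle,channel Optional explicit cycle (1-based) and fluorescence
#'   channel (`"TRITC"` or `"Cy5"`) assignment; by default markers are
#'   scheduled two per cycle, alternating TRITC / Cy5, in panel order.
#' @return A `data.frame` with one row per marker.
#' @export
marker_panel <- function(markers,
                         compartment = "membrane",
                         prevalence = 0.3,
                         positive_intensity = 3000,
                         negative_intensity = 300,
                         cycle = NULL,
                         channel = NULL) {
  n <- length(markers)
  if (n == 0) stop_bad("marker_panel: at least one marker required")
  if (anyDuplicated(markers)) stop_bad("marker_panel: duplicate marker names")
  compartment <- rep_len(compartment, n)
  if (!all(compartment %in% c("nuclear", "cytoplasmic", "membrane")))
    stop_bad("marker_panel: compartment must be nuclear, cytoplasmic or membrane")
  prevalence <- rep_len(prevalence, n)
  positive_intensity <- rep_len(positive_intensity, n)
  negative_intensity <- rep_len(negative_intensity, n)
  if (any(positive_intensity <= negative_intensity))
    stop_bad("marker_panel: positive_intensity must exceed negative_intensity")
  if (any(prevalence < 0 | prevalence > 1))
    stop_bad("marker_panel: prevalence must be in [0, 1]")
  if (is.null(cycle)) cycle <- (seq_len(n) + 1L) %/% 2L
  if (is.null(channel)) channel <- c("TRITC", "Cy5")[(seq_len(n) - 1L) %% 2L + 1L]
  data.frame(marker = as.character(markers), compartment = compartment,
             prevalence = prevalence,
             positive_intensity = positive_intensity,
             negative_intensity = negative_intensity,
             cycle = as.integer(cycle), channel = as.character(channel),
             stringsAsFactors = FALSE)
}

# Smooth, bandlimited, nonnegative autofluorescence field: a few random
# low-frequency cosine modes rescaled to [min_level, max_level].
make_af_field <- function(canvas_size, mean_level = 300, n_modes = 3,
                          rel_amplitude = 0.4) {
  h <- canvas_size[1]; w <- canvas_size[2]
  yy <- matrix(0:(h - 1) / h, h, w)
  xx <- matrix(0:(w - 1) / w, h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (k in seq_len(n_modes)) {
    fy <- stats::runif(1, 0.3, 1.5)
    fx <- stats::runif(1, 0.3, 1.5)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + cos(2 * pi * (fy * yy + fx * xx) + ph)
  }
  f <- f / n_modes                     # in [-1, 1]
  mean_level * (1 + rel_amplitude * f) # nonnegative for rel_amplitude < 1
}

#' Generate a synthetic tissue phantom
#'
#' Lays out non-overlapping circular nuclei on the canvas, assigns each
#' cell a positive/negative phenotype per marker by its prevalence, and
#' draws a smooth autofluorescence field per marker channel.
#'
#' @param n_nuclei Number of cells (>= 1).
#' @param panel Marker panel from [marker_panel()].
#' @param canvas_size Integer `(height, width)` of the phantom canvas in
#'   pixels.
#' @param seed Integer seed; identical seeds give field-by-field identical
#'   phantoms.
#' @param nucleus_radius Mean nucleus radius in pixels.
#' @param af_level Mean autofluorescence grey value per marker channel.
#' @param dapi_intensity Mean DAPI grey value inside nuclei.
#' @return An object of class `tissue_phantom`.
#' @export
make_phantom <- function(n_nuclei, panel, canvas_size = c(134, 177),
                         seed = 1, nucleus_radius = 4,
                         af_level = 300, dapi_intensity = 8000) {
  if (!is_count(n_nuclei) || n_nuclei < 1)
    stop_bad("make_phantom: n_nuclei must be a positive integer")
  stopifnot(is.data.frame(panel), length(canvas_size) == 2)
  h <- canvas_size[1]; w <- canvas_size[2]
  margin <- ceiling(nucleus_radius * 2.2) # room for membrane/cytoplasm rings
  if (2 * margin >= h || 2 * margin >= w)
    stop_bad("make_phantom: canvas too small for the requested nucleus radius")
  # capacity check: dart-throwing needs free area
  if (n_nuclei * (2.5 * nucleus_radius)^2 > 0.5 * (h - 2 * margin) * (w - 2 * margin))
    stop_bad("make_phantom: impossible geometry, ", n_nuclei,
             " nuclei cannot fit on a ", h, "x", w, " canvas")
  with_seed(derive_seed(seed, 11), {
    centers <- matrix(NA_real_, 0, 2)
    min_d2 <- (2.4 * nucleus_radius)^2
    tries <- 0
    while (nrow(centers) < n_nuclei && tries < 200 * n_nuclei) {
      tries <- tries + 1
      p <- c(stats::runif(1, margin, h - 1 - margin),
             stats::runif(1, margin, w - 1 - margin))
      if (nrow(centers) == 0 ||
          min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) > min_d2)
        centers <- rbind(centers, p)
    }
    if (nrow(centers) < n_nuclei)
      stop_bad("make_phantom: impossible geometry, could only place ",
               nrow(centers), " of ", n_nuclei, " nuclei")
    radii <- pmax(2, stats::rnorm(n_nuclei, nucleus_radius, nucleus_radius / 10))
    radii <- pmin(radii, nucleus_radius * 1.5)
    pheno <- matrix(FALSE, n_nuclei, nrow(panel),
                    dimnames = list(NULL, panel$marker))
    for (j in seq_len(nrow(panel))) {
      pheno[, j] <- stats::runif(n_nuclei) < panel$prevalence[j]
      # guarantee both classes exist for reasonably sized phantoms
      if (n_nuclei >= 10) {
        if (!any(pheno[, j])) pheno[sample.int(n_nuclei, 1), j] <- TRUE
        if (all(pheno[, j]))  pheno[sample.int(n_nuclei, 1), j] <- FALSE
      }
    }
    chans <- unique(panel$channel)
    af <- lapply(chans, function(ch) make_af_field(canvas_size, af_level))
    names(af) <- chans
    structure(
      list(canvas_size = as.integer(canvas_size),
           nuclei = data.frame(cy = centers[, 1], cx = centers[, 2],
                               radius = radii),
           phenotypes = pheno,
           panel = panel,
           af_field = af,
           dapi_intensity = dapi_intensity,
           seed = seed),
      class = "tissue_phantom")
  })
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("tissue_phantom: %d nuclei on %dx%d canvas, %d markers (%s)\n",
              nrow(x$nuclei), x$canvas_size[1], x$canvas_size[2],
              nrow(x$panel), paste(x$panel$marker, collapse = ", ")))
  invisible(x)
}

# Rasterize one compartment for the cells selected by `which_cells`.
# nuclear: filled disk; cytoplasmic: annulus r..1.6r; membrane: thin ring
# at 1.6r..1.9r. Hard-edged (no antialiasing) so analytic oracles are exact.
compartment_mask <- function(phantom, which_cells, compartment) {
  h <- phantom$canvas_size[1]; w <- phantom$canvas_size[2]
  mask <- matrix(FALSE, h, w)
  nuc <- phantom$nuclei[which_cells, , drop = FALSE]
  for (i in seq_len(nrow(nuc))) {
    r <- nuc$radius[i]
    r_out <- switch(compartment, nuclear = r, cytoplasmic = 1.6 * r,
                    membrane = 1.9 * r)
    r_in <- switch(compartment, nuclear = 0, cytoplasmic = r,
                   membrane = 1.6 * r)
    y0 <- max(0, floor(nuc$cy[i] - r_out)); y1 <- min(h - 1, ceiling(nuc$cy[i] + r_out))
    x0 <- max(0, floor(nuc$cx[i] - r_out)); x1 <- min(w - 1, ceiling(nuc$cx[i] + r_out))
    ys <- y0:y1; xs <- x0:x1
    d2 <- outer((ys - nuc$cy[i])^2, (xs - nuc$cx[i])^2, `+`)
    mask[ys + 1, xs + 1] <- mask[ys + 1, xs + 1] |
      (d2 <= r_out^2 & d2 >= r_in^2)
  }
  mask
}

#' Render the noise-free staining scene of one marker
#'
#' The ideal (noise-free, autofluorescence-free) stain image: the marker's
#' non-specific baseline everywhere on the canvas plus the specific signal
#' in the positive cells' compartment. Intensities are grey values at the
#' channel's reference exposure.
#'
#' @param phantom A `tissue_phantom`.
#' @param marker Marker name present in the phantom's panel.
#' @param intensity_scale Multiplier on the specific (above-baseline)
#'   signal; used to emulate epitope decay or incomplete elution.
#' @return Float matrix of the canvas size, plus attributes `"pos_mask"`
#'   (positive compartment pixels).
#' @export
render_marker_scene <- function(phantom, marker, intensity_scale = 1) {
  j <- match(marker, phantom$panel$marker)
  if (is.na(j)) stop_bad("render_marker_scene: unknown marker '", marker, "'")
  row <- phantom$panel[j, ]
  pos <- compartment_mask(phantom, which(phantom$phenotypes[, j]),
                          row$compartment)
  scene <- matrix(row$negative_intensity, phantom$canvas_size[1],
                  phantom$canvas_size[2])
  scene[pos] <- row$negative_intensity +
    intensity_scale * (row$positive_intensity - row$negative_intensity)
  attr(scene, "pos_mask") <- pos
  scene
}

#' Render the noise-free DAPI (nuclear counterstain) scene
#'
#' @param phantom A `tissue_phantom`.
#' @return Float matrix: `dapi_intensity` inside every nucleus, a low
#'   tissue background elsewhere.
#' @export
render_dapi_scene <- function(phantom) {
  nuc_mask <- compartment_mask(phantom, seq_len(nrow(phantom$nuclei)),
                               "nuclear")
  scene <- matrix(phantom$dapi_intensity * 0.02, phantom$canvas_size[1],
                  phantom$canvas_size[2])
  scene[nuc_mask] <- phantom$dapi_intensity
  scene
}
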