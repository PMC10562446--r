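# Shared fixtures: small phantoms and acquisition specs, built in code so
# the suite ships no binary data.

default_panel <- function() {
  marker_panel(c("CD20", "CD3", "panCK", "CD68"),
               compartment = c("membrane", "membrane", "cytoplasmic",
                               "nuclear"),
               prevalence = c(0.4, 0.3, 0.3, 0.25))
}

tiny_spec <- function(...) {
  args <- list(grid_shape = c(3, 4), tile_size = c(48, 48),
               overlap_fraction = 0.1, n_cycles = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(acquisition_spec, args)
}

# noise-free, drift-free, vignette-free spec for exactness tests
degenerate_spec <- function(...) {
  args <- list(cycle_drift = NULL, noise = NULL,
               vignette_strength = c(DAPI = 0, TRITC = 0, Cy5 = 0))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(tiny_spec, args)
}

tiny_phantom <- function(spec = tiny_spec(), seed = 2,
                         panel = default_panel(), n_nuclei = 60) {
  make_phantom(n_nuclei, panel, canvas_size = tile_geometry(spec)$canvas_size,
               seed = seed)
}

# brute-force Otsu oracle: naive scan over every histogram cut, class
# statistics recomputed from scratch at each candidate
otsu_bruteforce <- function(x, n_bins = 256) {
  x <- as.vector(x)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best <- -Inf; best_k <- NA
  for (k in seq_len(n_bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    v <- (n0 / length(x)) * (n1 / length(x)) * (m0 - m1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  breaks[best_k + 1]
}

# strip dim-extraneous attributes (e.g. resampling validity masks) for
# bitwise layer comparisons
bare <- function(m) { attributes(m) <- list(dim = dim(m)); m }

dapi_mosaic_for <- function(seed = 2) {
  spec <- tiny_spec(seed = seed)
  ph <- tiny_phantom(spec, seed = seed)
  render_dapi_scene(ph)
}
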