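# Reading and writing tiled acquisitions (plain TIFF tiles + CSV/JSON
# sidecars) and the final multi-layer stack (multi-page 16-bit TIFF with a
# companion OME-XML metadata file, the OME "companion file" layout).

tile_filename <- function(cycle, channel, row, col) {
  sprintf("c%02d_%s_r%02d_c%02d.tif", cycle, channel, row, col)
}

write_tiff16 <- function(pixels, path, compression = "none") {
  tiff::writeTIFF(pixels / 65535, path, bits.per.sample = 16L,
                  compression = compression)
}

read_tiff16 <- function(path) {
  img <- tiff::readTIFF(path)
  round(img * 65535)
}

#' Write a simulated or imported acquisition as a tile directory
#'
#' Writes one 16-bit TIFF per field of view plus `tiles.csv` (tile_id,
#' file, cycle, channel, grid position, exposure, stage offset) and
#' `acquisition.json` (grid geometry, channels, pixel size).
#'
#' @param run A `seqif_run` from [simulate_run()], or a list with `spec`
#'   plus `baseline`/`cycles` tile lists.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_tiles <- function(run, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fovs <- c(run$baseline, do.call(c, run$cycles))
  rows <- lapply(seq_along(fovs), function(i) {
    f <- fovs[[i]]
    fn <- tile_filename(f$cycle, f$channel, f$grid_pos[1], f$grid_pos[2])
    write_tiff16(f$pixels, file.path(path, fn))
    data.frame(tile_id = sub("\\.tif$", "", fn), file = fn,
               cycle = f$cycle, channel = f$channel,
               grid_row = f$grid_pos[1], grid_col = f$grid_pos[2],
               exposure_ms = f$exposure_ms,
               offset_y = f$stage_offset_px[1],
               offset_x = f$stage_offset_px[2])
  })
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(path, "tiles.csv"), row.names = FALSE)
  spec <- run$spec
  jsonlite::write_json(
    list(grid_shape = spec$grid_shape, tile_size = spec$tile_size,
         overlap_fraction = spec$overlap_fraction, channels = spec$channels,
         pixel_size_um = spec$pixel_size_um, n_cycles = spec$n_cycles,
         exposure_ms = as.list(spec$exposure_ms),
         reference_exposure_ms = spec$reference_exposure_ms),
    file.path(path, "acquisition.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tiled acquisition from disk
#'
#' Loads every tile declared in the `tiles.csv` sidecar, grouped by cycle
#' and channel. Missing or unreadable tiles raise an error naming the tile
#' and its grid position.
#'
#' @param path Directory written by [write_tiles()] (or a compatible
#'   layout).
#' @return An object of class `seqif_acquisition`: `spec` (geometry
#'   metadata), `baseline` (cycle-0 tiles, possibly empty) and `cycles`
#'   (list of tile lists, one per cycle).
#' @export
read_acquisition <- function(path) {
  csv <- file.path(path, "tiles.csv")
  jsn <- file.path(path, "acquisition.json")
  if (!file.exists(csv) || !file.exists(jsn))
    stop_bad("read_acquisition: ", path,
             " lacks tiles.csv / acquisition.json sidecars")
  meta <- utils::read.csv(csv, stringsAsFactors = FALSE)
  spec_meta <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  grid <- spec_meta$grid_shape
  if (any(meta$grid_row < 0 | meta$grid_row >= grid[1] |
          meta$grid_col < 0 | meta$grid_col >= grid[2]))
    stop_bad("read_acquisition: metadata declares grid positions outside the ",
             grid[1], "x", grid[2], " grid")
  fovs <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    fp <- file.path(path, m$file)
    if (!file.exists(fp))
      stop_bad("read_acquisition: missing tile ", m$tile_id,
               " at grid position (", m$grid_row, ", ", m$grid_col, ")")
    px <- tryCatch(read_tiff16(fp), error = function(e)
      stop_bad("read_acquisition: corrupt tile ", m$tile_id,
               " at grid position (", m$grid_row, ", ", m$grid_col, "): ",
               conditionMessage(e)))
    field_of_view(px, m$channel, m$cycle, c(m$grid_row, m$grid_col),
                  m$exposure_ms, c(m$offset_y, m$offset_x))
  })
  cyc <- vapply(fovs, function(f) f$cycle, integer(1))
  n_cycles <- spec_meta$n_cycles
  expo <- unlist(spec_meta$exposure_ms)
  structure(
    list(spec = list(grid_shape = as.integer(grid),
                     tile_size = as.integer(spec_meta$tile_size),
                     overlap_fraction = spec_meta$overlap_fraction,
                     channels = spec_meta$channels,
                     pixel_size_um = spec_meta$pixel_size_um,
                     n_cycles = as.integer(n_cycles),
                     exposure_ms = expo,
                     reference_exposure_ms = spec_meta$reference_exposure_ms),
         baseline = fovs[cyc == 0],
         cycles = lapply(seq_len(n_cycles), function(k) fovs[cyc == k])),
    class = "seqif_acquisition")
}

#' Construct a multi-layer seqIF stack
#'
#' @param layers Named list of same-sized numeric matrices.
#' @param metadata `data.frame` with one row per layer: `name`, `marker`,
#'   `cycle`, `channel`, `exposure_ms`, `is_reference` (exactly one `TRUE`,
#'   the cycle-1 DAPI registration reference).
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `seqif_stack`.
#' @export
seqif_stack <- function(layers, metadata, pixel_size_um) {
  stopifnot(is.list(layers), is.data.frame(metadata))
  if (length(layers) != nrow(metadata))
    stop_bad("seqif_stack: one metadata row per layer required")
  dims <- vapply(layers, dim, integer(2))
  if (length(layers) > 1 && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop_bad("seqif_stack: all layers must share identical dimensions")
  need <- c("name", "marker", "cycle", "channel", "exposure_ms", "is_reference")
  if (!all(need %in% names(metadata)))
    stop_bad("seqif_stack: metadata must have columns ",
             paste(need, collapse = ", "))
  if (sum(metadata$is_reference) != 1)
    stop_bad("seqif_stack: exactly one layer must be the registration reference")
  if (anyDuplicated(metadata$name))
    stop_bad("seqif_stack: layer names must be unique")
  names(layers) <- metadata$name
  structure(list(layers = layers, metadata = metadata,
                 pixel_size_um = pixel_size_um),
            class = "seqif_stack")
}

#' @export
print.seqif_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("seqif_stack: %d layers of %dx%d px (%.3g um/px)\n",
              length(x$layers), d[1], d[2], x$pixel_size_um))
  print(utils::head(x$metadata, 10))
  if (nrow(x$metadata) > 10) cat("...\n")
  invisible(x)
}

companion_path <- function(path) {
  paste0(sub("\\.ome\\.tiff?$|\\.tiff?$", "", path), ".companion.ome")
}

build_ome_xml <- function(stack) {
  d <- dim(stack$layers[[1]])
  doc <- xml2::xml_new_root(
    "OME", xmlns = "http://www.openmicroscopy.org/Schemas/OME/2016-06")
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0", Name = "seqIF stack")
  px <- xml2::xml_add_child(
    img, "Pixels", ID = "Pixels:0", DimensionOrder = "XYCZT", Type = "uint16",
    SizeX = as.character(d[2]), SizeY = as.character(d[1]),
    SizeC = as.character(length(stack$layers)), SizeZ = "1", SizeT = "1",
    PhysicalSizeX = as.character(stack$pixel_size_um),
    PhysicalSizeY = as.character(stack$pixel_size_um),
    PhysicalSizeXUnit = "µm", PhysicalSizeYUnit = "µm")
  md <- stack$metadata
  for (i in seq_len(nrow(md))) {
    xml2::xml_add_child(px, "Channel",
                        ID = sprintf("Channel:0:%d", i - 1),
                        Name = md$name[i])
  }
  for (i in seq_len(nrow(md))) {
    xml2::xml_add_child(px, "Plane", TheC = as.character(i - 1), TheZ = "0",
                        TheT = "0",
                        ExposureTime = as.character(md$exposure_ms[i]),
                        ExposureTimeUnit = "ms")
  }
  sa <- xml2::xml_add_child(doc, "StructuredAnnotations")
  ann <- xml2::xml_add_child(sa, "XMLAnnotation", ID = "Annotation:seqif")
  val <- xml2::xml_add_child(ann, "Value")
  root <- xml2::xml_add_child(val, "SeqIF")
  for (i in seq_len(nrow(md))) {
    xml2::xml_add_child(root, "Layer",
                        index = as.character(i - 1),
                        name = md$name[i], marker = as.character(md$marker[i]),
                        cycle = as.character(md$cycle[i]),
                        channel = as.character(md$channel[i]),
                        exposure_ms = as.character(md$exposure_ms[i]),
                        reference = if (md$is_reference[i]) "true" else "false")
  }
  doc
}

#' Write a seqIF stack as OME-TIFF (companion-file layout)
#'
#' Pixel data go to a multi-page 16-bit TIFF (layers quantized with
#' [quantize16()]); channel names, pixel size, exposures and per-layer
#' marker/cycle metadata go to an OME-XML companion file next to it
#' (`<stem>.companion.ome`). The pair round-trips bit-exactly through
#' [read_stack()].
#'
#' @param stack A `seqif_stack`.
#' @param path Output TIFF path (e.g. `run.ome.tiff`).
#' @param compression `"none"` (default) or `"deflate"` (lossless zlib).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, compression = c("none", "deflate")) {
  compression <- match.arg(compression)
  stopifnot(inherits(stack, "seqif_stack"))
  dims <- vapply(stack$layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop_bad("write_stack: mismatched layer shapes; nothing written")
  pages <- lapply(stack$layers, function(m) quantize16(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = compression)
  xml2::write_xml(build_ome_xml(stack), companion_path(path))
  invisible(path)
}

#' Read a seqIF stack written by [write_stack()]
#'
#' @param path Path to the multi-page TIFF; its `.companion.ome` OME-XML
#'   file must sit next to it.
#' @return A `seqif_stack`.
#' @export
read_stack <- function(path) {
  comp <- companion_path(path)
  if (!file.exists(path)) stop_bad("read_stack: no such file: ", path)
  if (!file.exists(comp))
    stop_bad("read_stack: ", path, " has no OME-XML companion (", comp,
             "); for a bare TIFF without channel metadata use ",
             "tiff::readTIFF() and construct the stack manually")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_bad("read_stack: cannot parse ", path, ": ",
                               conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  layers <- lapply(pages, function(p) round(p * 65535))
  doc <- tryCatch(xml2::read_xml(comp), error = function(e)
    stop_bad("read_stack: cannot parse companion OME-XML: ",
             conditionMessage(e)))
  ns <- c(ome = "http://www.openmicroscopy.org/Schemas/OME/2016-06")
  px <- xml2::xml_find_first(doc, ".//ome:Pixels", ns)
  if (inherits(px, "xml_missing"))
    stop_bad("read_stack: companion file lacks OME Pixels metadata")
  psz <- as.numeric(xml2::xml_attr(px, "PhysicalSizeX"))
  lay <- xml2::xml_find_all(doc, ".//ome:SeqIF/ome:Layer", ns)
  if (length(lay) != length(layers))
    stop_bad("read_stack: companion metadata declares ", length(lay),
             " layers but the TIFF holds ", length(layers))
  md <- data.frame(
    name = xml2::xml_attr(lay, "name"),
    marker = xml2::xml_attr(lay, "marker"),
    cycle = as.integer(xml2::xml_attr(lay, "cycle")),
    channel = xml2::xml_attr(lay, "channel"),
    exposure_ms = as.numeric(xml2::xml_attr(lay, "exposure_ms")),
    is_reference = xml2::xml_attr(lay, "reference") == "true",
    stringsAsFactors = FALSE)
  ord <- order(as.integer(xml2::xml_attr(lay, "index")))
  seqif_stack(layers, md[ord, , drop = FALSE], psz)
}
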