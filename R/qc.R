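# Quality-control statistics for seqIF runs: Otsu signal segmentation,
# ROI detection, signal-to-background ratios (pixel- and cell-based),
# elution efficiency, epitope-stability curves, repeatability CV and
# signal-uniformity profiling.

#' Otsu threshold of an image
#'
#' Histogram threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over equal-width bins spanning the observed
#' intensity range. Intended for background-subtracted images; returns the
#' threshold in native grey units (pixels strictly above it are signal).
#'
#' @param image Numeric matrix or vector; must not be constant.
#' @param n_bins Number of histogram bins (default 256, common practice
#'   for 16-bit fluorescence data).
#' @return Scalar threshold (upper edge of the background class).
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  x <- as.vector(image)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop_bad("otsu_threshold: constant image, no threshold exists")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(counts)
  total <- w0[n_bins]
  sum0 <- cumsum(counts * mids)
  mu_total <- sum0[n_bins] / total
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- sum0 / w0
  mu1 <- (sum0[n_bins] - sum0) / w1
  bcv <- ifelse(valid, (w0 / total) * (w1 / total) * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv) # first maximizer on ties
  breaks[k + 1]
}

# Binary mask dilation by a disc of radius r px.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- EBImage::makeBrush(2 * ceiling(r) + 1, shape = "disc")
  EBImage::dilate(mask * 1, k) > 0
}

#' Automatically detect non-overlapping square ROIs inside a tissue mask
#'
#' Scans candidate positions (coarse-to-fine strides, row-major, so the
#' result is deterministic) and greedily accepts squares fully contained
#' in the tissue mask that do not overlap previously accepted ROIs.
#'
#' @param tissue_mask Logical matrix (TRUE = tissue).
#' @param n_rois Number of ROIs requested (the assay convention is 6 for
#'   SBR work, 25 for uniformity profiling).
#' @param roi_size_mm Side length of each square ROI in millimetres.
#' @param pixel_size_um Pixel size in micrometres.
#' @return `data.frame` with 0-based `y0, x0` (top-left), `size_px`, and
#'   ROI centres in mm (`cy_mm`, `cx_mm`).
#' @export
detect_rois <- function(tissue_mask, n_rois = 6, roi_size_mm = 1,
                        pixel_size_um) {
  stopifnot(is.matrix(tissue_mask))
  size_px <- max(1L, round(roi_size_mm * 1000 / pixel_size_um))
  h <- nrow(tissue_mask); w <- ncol(tissue_mask)
  if (size_px > h || size_px > w)
    stop_bad("detect_rois: a ", roi_size_mm, " mm ROI is ", size_px,
             " px, larger than the image")
  area <- size_px^2
  if (sum(tissue_mask) < n_rois * area)
    stop_bad("detect_rois: insufficient tissue for ", n_rois, " ROIs (at most ",
             floor(sum(tissue_mask) / area), " feasible by area)")
  # integral image for O(1) full-containment tests
  ii <- rbind(0, cbind(0, apply(apply(tissue_mask * 1, 2, cumsum), 1, cumsum)))
  ii <- t(ii) # ii[y+1, x+1] = sum of mask[1..y, 1..x]
  boxsum <- function(y0, x0) # 0-based top-left
    ii[y0 + size_px + 1, x0 + size_px + 1] - ii[y0 + 1, x0 + size_px + 1] -
    ii[y0 + size_px + 1, x0 + 1] + ii[y0 + 1, x0 + 1]
  accepted <- matrix(numeric(0), 0, 2)
  overlaps <- function(y0, x0) {
    if (nrow(accepted) == 0) return(FALSE)
    any(abs(accepted[, 1] - y0) < size_px & abs(accepted[, 2] - x0) < size_px)
  }
  for (stride in unique(pmax(1L, c(size_px, ceiling(size_px / 2),
                                   ceiling(size_px / 4), 1L)))) {
    ys <- seq(0, h - size_px, by = stride)
    xs <- seq(0, w - size_px, by = stride)
    for (y0 in ys) for (x0 in xs) {
      if (nrow(accepted) >= n_rois) break
      if (boxsum(y0, x0) == area && !overlaps(y0, x0))
        accepted <- rbind(accepted, c(y0, x0))
    }
    if (nrow(accepted) >= n_rois) break
  }
  if (nrow(accepted) < n_rois)
    stop_bad("detect_rois: only ", nrow(accepted),
             " non-overlapping ROIs fit inside the tissue; requested ",
             n_rois)
  data.frame(y0 = accepted[, 1], x0 = accepted[, 2], size_px = size_px,
             cy_mm = (accepted[, 1] + size_px / 2) * pixel_size_um / 1000,
             cx_mm = (accepted[, 2] + size_px / 2) * pixel_size_um / 1000)
}

roi_pixels <- function(layer, roi) {
  layer[(roi$y0 + 1):(roi$y0 + roi$size_px),
        (roi$x0 + 1):(roi$x0 + roi$size_px)]
}

#' Segment nuclei in a DAPI image
#'
#' Gaussian smoothing, Otsu foreground threshold, then watershed on the
#' distance map to split touching nuclei. An intensity-based segmenter
#' adequate for disc-shaped synthetic nuclei (trained-model nuclear
#' segmentation is out of scope).
#'
#' @param dapi DAPI image matrix.
#' @param sigma Smoothing sigma in px.
#' @param min_px Minimum object size in px (smaller labels dropped).
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(dapi, sigma = 1, min_px = 5) {
  sm <- EBImage::gblur(dapi, sigma)
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  dm <- EBImage::distmap(fg * 1)
  lab <- EBImage::watershed(dm, tolerance = 1)
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_px)
  lab[!(lab %in% keep)] <- 0L
  lab
}

#' Signal-to-background ratio of a marker layer
#'
#' Pixel mode: Otsu splits each ROI into signal and background pixels;
#' the SBR is the pooled mean signal intensity over the pooled mean
#' background intensity. Cell mode: nuclei are segmented on the DAPI
#' layer, per-cell mean marker intensities (over a small dilation of each
#' nucleus) are classified positive/negative by Otsu on the cell means,
#' and the SBR is mean(positive cells) / mean(negative cells).
#'
#' @param layer Marker image (background-subtracted for pixel mode).
#' @param rois ROI table from [detect_rois()]; `NULL` treats the whole
#'   image as one ROI.
#' @param mode `"pixel"` or `"cell"`.
#' @param dapi DAPI image (required for cell mode).
#' @param min_class_px Minimum pixels (or cells) per class for a ROI to
#'   count; single-class ROIs are excluded with a warning.
#' @return An object of class `sbr_record`: `sbr`, `mode`, `n_rois`,
#'   `roi_means` (per-ROI signal/background means).
#' @export
compute_sbr <- function(layer, rois = NULL, mode = c("pixel", "cell"),
                        dapi = NULL, min_class_px = 10) {
  mode <- match.arg(mode)
  if (is.null(rois))
    rois <- data.frame(y0 = 0, x0 = 0, size_px = NA, cy_mm = NA, cx_mm = NA)
  if (is.na(rois$size_px[1]) && nrow(rois) == 1) {
    rois$size_px <- NA # whole image
  }
  if (nrow(rois) < 1) stop_bad("compute_sbr: at least one ROI required")
  if (mode == "cell") {
    if (is.null(dapi)) stop_bad("compute_sbr: cell mode needs a DAPI image")
    lab <- segment_nuclei(dapi)
    lab <- dilate_labels(lab, 2) # cell region = nucleus + 2 px margin
    cells <- sort(unique(lab[lab > 0]))
    if (length(cells) < 4)
      stop_bad("compute_sbr: too few cells segmented for cell mode")
    means <- vapply(cells, function(k) mean(layer[lab == k]), numeric(1))
    thr <- otsu_threshold(means)
    pos <- means > thr
    if (!any(pos) || all(pos))
      stop_bad("compute_sbr: cell classification collapsed to one class")
    rec <- list(sbr = mean(means[pos]) / mean(means[!pos]), mode = "cell",
                n_rois = 1L,
                roi_means = data.frame(roi = 1, signal_mean = mean(means[pos]),
                                       background_mean = mean(means[!pos]),
                                       n_signal = sum(pos),
                                       n_background = sum(!pos)))
    return(structure(rec, class = "sbr_record"))
  }
  sig <- numeric(0); bg <- numeric(0); rows <- list()
  for (i in seq_len(nrow(rois))) {
    px <- if (is.na(rois$size_px[i])) layer else roi_pixels(layer, rois[i, ])
    thr <- tryCatch(otsu_threshold(px), error = function(e) NA_real_)
    if (is.na(thr)) {
      warning("compute_sbr: ROI ", i, " is single-class, excluded",
              call. = FALSE)
      next
    }
    s <- px[px > thr]; b <- px[px <= thr]
    if (length(s) < min_class_px || length(b) < min_class_px) {
      warning("compute_sbr: ROI ", i, " is effectively single-class, excluded",
              call. = FALSE)
      next
    }
    sig <- c(sig, s); bg <- c(bg, b)
    rows[[length(rows) + 1]] <- data.frame(
      roi = i, signal_mean = mean(s), background_mean = mean(b),
      n_signal = length(s), n_background = length(b))
  }
  if (length(rows) == 0)
    stop_bad("compute_sbr: all ROIs excluded (single class); no SBR defined")
  if (mean(bg) <= 0)
    stop_bad("compute_sbr: background mean is not positive")
  structure(list(sbr = mean(sig) / mean(bg), mode = "pixel",
                 n_rois = length(rows), roi_means = do.call(rbind, rows)),
            class = "sbr_record")
}

dilate_labels <- function(lab, r) {
  if (r <= 0) return(lab)
  k <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  as.matrix(EBImage::dilate(lab, k))
}

#' @export
print.sbr_record <- function(x, ...) {
  cat(sprintf("sbr_record (%s mode): SBR = %.3f over %d ROI(s)\n",
              x$mode, x$sbr, x$n_rois))
  invisible(x)
}

#' Bundle the three images of an elution-efficiency measurement
#'
#' `neg_ctrl` is the secondary-antibody-only image before staining,
#' `staining` the full stain, `elu_neg_ctrl` the secondary-only image
#' after elution; all registered to one frame. When the masks are not
#' supplied, POS is the Otsu-positive area of `staining - neg_ctrl` and
#' NEG is the area outside a 3 px dilation of POS.
#'
#' @param neg_ctrl,staining,elu_neg_ctrl Same-shaped image matrices.
#' @param pos_mask,neg_mask Optional logical masks; must be disjoint and
#'   non-empty.
#' @param dilate_px Dilation margin separating POS from NEG when masks
#'   are derived automatically.
#' @return An object of class `elution_triplet`.
#' @export
elution_triplet <- function(neg_ctrl, staining, elu_neg_ctrl,
                            pos_mask = NULL, neg_mask = NULL, dilate_px = 3) {
  d <- dim(staining)
  if (!all(dim(neg_ctrl) == d) || !all(dim(elu_neg_ctrl) == d))
    stop_bad("elution_triplet: images must share one shape")
  if (is.null(pos_mask)) {
    diff <- staining - neg_ctrl
    thr <- otsu_threshold(diff)
    pos_mask <- diff > thr
  }
  if (is.null(neg_mask)) neg_mask <- !dilate_mask(pos_mask, dilate_px)
  if (!any(pos_mask) || !any(neg_mask))
    stop_bad("elution_triplet: POS and NEG masks must be non-empty")
  if (any(pos_mask & neg_mask))
    stop_bad("elution_triplet: POS and NEG masks overlap")
  structure(list(neg_ctrl = neg_ctrl, staining = staining,
                 elu_neg_ctrl = elu_neg_ctrl, pos_mask = pos_mask,
                 neg_mask = neg_mask),
            class = "elution_triplet")
}

#' Elution efficiency of an antibody-stripping cycle
#'
#' Implements the difference-based estimator
#' \deqn{\left(1 - \frac{(Elu - Neg)_{POS} - (Elu - Neg)_{NEG}}
#'       {(Staining - Neg)_{POS}}\right) \times 100}
#' where each subscripted term is the mean of the pixelwise difference
#' over the POS (positively stained) or NEG (unstained tissue) mask. The
#' NEG term cancels global background changes caused by the elution
#' cycle, so the statistic is invariant to adding any constant to all
#' three images.
#'
#' @param triplet An `elution_triplet`.
#' @return Efficiency in percent (100 = perfect elution).
#' @export
elution_efficiency <- function(triplet) {
  stopifnot(inherits(triplet, "elution_triplet"))
  pos <- triplet$pos_mask; neg <- triplet$neg_mask
  d_elu <- triplet$elu_neg_ctrl - triplet$neg_ctrl
  stain_contrast <- mean((triplet$staining - triplet$neg_ctrl)[pos])
  if (stain_contrast <= 0)
    stop_bad("elution_efficiency: stain contrast (Staining - NegCtrl)_POS is ",
             "not positive; efficiency undefined")
  (1 - (mean(d_elu[pos]) - mean(d_elu[neg])) / stain_contrast) * 100
}

#' Epitope-stability curve from SBR records
#'
#' Expresses each checkpoint's SBR as a percentage of the initial
#' staining's SBR (checkpoint 0 is 100% by definition).
#'
#' @param initial `sbr_record` of the initial staining.
#' @param post_elution Named list (names = elution-cycle counts) or list
#'   of `sbr_record`s with a `checkpoints` vector.
#' @param checkpoints Elution-cycle counts; taken from `names(post_elution)`
#'   when `NULL`.
#' @param marker Marker name carried into the result.
#' @return An object of class `stability_curve`: `checkpoints` (leading
#'   0) and `sbr_percent_of_initial`.
#' @export
stability_curve <- function(initial, post_elution, checkpoints = NULL,
                            marker = NA_character_) {
  stopifnot(inherits(initial, "sbr_record"))
  if (is.null(checkpoints)) checkpoints <- as.numeric(names(post_elution))
  if (anyNA(checkpoints) || is.unsorted(checkpoints, strictly = TRUE))
    stop_bad("stability_curve: checkpoints must be strictly increasing")
  if (length(checkpoints) != length(post_elution))
    stop_bad("stability_curve: one record per checkpoint required")
  modes <- vapply(post_elution, `[[`, character(1), "mode")
  if (any(modes != initial$mode))
    stop_bad("stability_curve: all records must use the same SBR mode")
  if (initial$sbr <= 1)
    warning("stability_curve: initial SBR <= 1, marker effectively unstained",
            call. = FALSE)
  vals <- vapply(post_elution, function(r) 100 * r$sbr / initial$sbr,
                 numeric(1))
  structure(list(marker = marker, checkpoints = c(0, checkpoints),
                 sbr_percent_of_initial = c(100, unname(vals))),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("stability_curve (%s):\n", x$marker))
  print(stats::setNames(round(x$sbr_percent_of_initial, 1),
                        x$checkpoints))
  invisible(x)
}

#' Repeatability coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation, the
#' statistic used to compare SBR or mean signal intensity across repeated
#' runs, days, stainers or instruments.
#'
#' @param values Numeric vector of at least 2 positive values.
#' @return CV in percent.
#' @export
repeatability_cv <- function(values) {
  if (length(values) < 2)
    stop_bad("repeatability_cv: at least two values required")
  if (any(values <= 0))
    stop_bad("repeatability_cv: values must be positive")
  cv_percent(values)
}

#' Signal-uniformity profile over a grid of ROIs
#'
#' For each ROI the Otsu-positive pixels' mean intensity is normalized by
#' exposure time; the axis variations are the CV (%) of ROI means grouped
#' by horizontal position (variation_x) and by vertical position
#' (variation_y).
#'
#' @param layer Marker image.
#' @param rois ROI table from [detect_rois()] (the assay convention uses
#'   25).
#' @param exposure_ms Exposure time of the layer in ms.
#' @param group_tol_mm ROI centres closer than this along an axis are
#'   pooled into one position group.
#' @return An object of class `uniformity_profile`: per-ROI normalized
#'   means and centres, `variation_x`, `variation_y` (percent).
#' @export
uniformity_profile <- function(layer, rois, exposure_ms, group_tol_mm = 0.05) {
  means <- numeric(0); keep <- integer(0)
  for (i in seq_len(nrow(rois))) {
    px <- roi_pixels(layer, rois[i, ])
    thr <- tryCatch(otsu_threshold(px), error = function(e) NA_real_)
    posv <- if (is.na(thr)) numeric(0) else px[px > thr]
    if (length(posv) == 0) {
      warning("uniformity_profile: ROI ", i, " has no positive pixels, excluded",
              call. = FALSE)
      next
    }
    means <- c(means, mean(posv) / exposure_ms)
    keep <- c(keep, i)
  }
  if (length(means) < 2)
    stop_bad("uniformity_profile: fewer than two usable ROIs")
  r <- rois[keep, , drop = FALSE]
  group_cv <- function(pos_mm) {
    g <- round(pos_mm / group_tol_mm)
    gm <- tapply(means, g, mean)
    if (length(gm) < 2) return(0)
    cv_percent(as.numeric(gm))
  }
  structure(list(roi_centers = data.frame(x_mm = r$cx_mm, y_mm = r$cy_mm),
                 normalized_means = means,
                 variation_x = group_cv(r$cx_mm),
                 variation_y = group_cv(r$cy_mm)),
            class = "uniformity_profile")
}

#' @export
print.uniformity_profile <- function(x, ...) {
  cat(sprintf("uniformity_profile: %d ROIs, variation x %.2f%%, y %.2f%%\n",
              length(x$normalized_means), x$variation_x, x$variation_y))
  invisible(x)
}
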