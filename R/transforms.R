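# Rigid (Euclidean) transforms in the mosaic plane and bilinear resampling.
#
# Convention: images are matrices indexed [row = y, col = x], 0-based
# pixel-centre coordinates. A transform maps moving-frame coordinates onto
# reference-frame coordinates:
#
#   x_ref = R(theta) (x_mov - c) + c + t
#
# with R a counter-clockwise rotation by `rotation_deg`, `c` the rotation
# centre and `t = (dy, dx)` the translation in pixels.

#' Construct a rigid (Euclidean) transform
#'
#' @param rotation_deg Rotation angle in degrees (counter-clockwise).
#' @param translation_px Numeric length-2 `(dy, dx)` translation in pixels.
#' @param center Numeric length-2 `(cy, cx)` rotation centre in pixels
#'   (0-based). Defaults to the origin; most callers pass the image centre.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, translation_px = c(0, 0),
                            center = c(0, 0)) {
  stopifnot(length(rotation_deg) == 1, length(translation_px) == 2,
            length(center) == 2)
  if (!all(is.finite(c(rotation_deg, translation_px, center))))
    stop_bad("rigid_transform: all parameters must be finite")
  structure(
    list(rotation_deg = as.numeric(rotation_deg),
         translation_px = as.numeric(translation_px),
         center = as.numeric(center)),
    class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.3f, %.3f) px, center (%.1f, %.1f)\n",
              x$rotation_deg, x$translation_px[1], x$translation_px[2],
              x$center[1], x$center[2]))
  invisible(x)
}

#' Test whether a transform is the exact identity
#' @param tf A `rigid_transform`.
#' @return Logical.
#' @export
is_identity_transform <- function(tf) {
  tf$rotation_deg == 0 && all(tf$translation_px == 0)
}

rot_mat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid transform to (y, x) points
#' @param tf A `rigid_transform`.
#' @param pts Two-column matrix of (y, x) coordinates.
#' @return Transformed two-column matrix.
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  R <- rot_mat(tf$rotation_deg)
  ctr <- matrix(tf$center, nrow(pts), 2, byrow = TRUE)
  tr <- matrix(tf$translation_px, nrow(pts), 2, byrow = TRUE)
  t(R %*% t(pts - ctr)) + ctr + tr
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform` (same rotation centre).
#' @export
invert_rigid <- function(tf) {
  Rinv <- rot_mat(-tf$rotation_deg)
  t_new <- -as.numeric(Rinv %*% tf$translation_px)
  rigid_transform(-tf$rotation_deg, t_new, tf$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#' Both must share the same rotation centre.
#'
#' @param second,first `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_rigid <- function(second, first) {
  if (!isTRUE(all.equal(second$center, first$center)))
    stop_bad("compose_rigid: transforms must share a rotation centre")
  R2 <- rot_mat(second$rotation_deg)
  t_new <- as.numeric(R2 %*% first$translation_px) + second$translation_px
  rigid_transform(second$rotation_deg + first$rotation_deg, t_new,
                  second$center)
}

#' Resample an image through a rigid transform (bilinear)
#'
#' Warps `img` into the reference frame of `tf`, i.e. the output at
#' reference coordinate y equals `img` sampled at `tf^-1(y)` with bilinear
#' interpolation. Pixels that map outside the input are filled with `fill`
#' and flagged `FALSE` in the `"valid"` attribute mask. Applying the exact
#' identity returns the input unchanged, bit for bit.
#'
#' @param img Numeric matrix.
#' @param tf A `rigid_transform` mapping `img`'s frame onto the reference
#'   frame.
#' @param fill Fill value for out-of-frame pixels (default 0).
#' @return Numeric matrix of the same shape, with a logical `"valid"`
#'   attribute matrix marking in-frame pixels.
#' @export
resample <- function(img, tf, fill = 0) {
  stopifnot(is.matrix(img))
  if (!all(is.finite(c(tf$rotation_deg, tf$translation_px))))
    stop_bad("resample: transform must be finite")
  if (is_identity_transform(tf)) {
    attr(img, "valid") <- matrix(TRUE, nrow(img), ncol(img))
    return(img)
  }
  h <- nrow(img); w <- ncol(img)
  inv <- invert_rigid(tf)
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  R <- rot_mat(inv$rotation_deg)
  cy <- inv$center[1]; cx <- inv$center[2]
  ty <- inv$translation_px[1]; tx <- inv$translation_px[2]
  sy <- R[1, 1] * (yy - cy) + R[1, 2] * (xx - cx) + cy + ty
  sx <- R[2, 1] * (yy - cy) + R[2, 2] * (xx - cx) + cx + tx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0;  fx <- sx - x0
  valid <- sy >= 0 & sy <= (h - 1) & sx >= 0 & sx <= (w - 1)
  # clamp corners so indexing is safe; invalid pixels overwritten below
  y0c <- pmin(pmax(y0, 0), h - 1); y1c <- pmin(y0c + 1, h - 1)
  x0c <- pmin(pmax(x0, 0), w - 1); x1c <- pmin(x0c + 1, w - 1)
  at <- function(yi, xi) img[cbind(as.vector(yi) + 1, as.vector(xi) + 1)]
  v <- (1 - fy) * (1 - fx) * at(y0c, x0c) +
       (1 - fy) * fx       * at(y0c, x1c) +
       fy       * (1 - fx) * at(y1c, x0c) +
       fy       * fx       * at(y1c, x1c)
  out <- matrix(v, h, w)
  out[!valid] <- fill
  attr(out, "valid") <- valid
  out
}
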