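#' RGB to YCbCr conversion (ITU-R BT.601, full range)
#'
#' Y = 0.299 R + 0.587 G + 0.114 B;
#' Cb = 128 - 0.168736 R - 0.331264 G + 0.5 B;
#' Cr = 128 + 0.5 R - 0.418688 G - 0.081312 B; clipped to \[0, 255\].
#' This full-range variant is the common image-editing convention.
#'
#' @param rgb Numeric array `[y, x, 3]` with 8-bit values 0..255.
#' @param round Round to integer counts (default TRUE).
#' @return Array `[y, x, 3]` of Y, Cb, Cr.
#' @examples
#' rgb_to_ycbcr(array(c(255, 0, 0), c(1, 1, 3)))  # 76, 85, 255
#' @export
rgb_to_ycbcr <- function(rgb, round = TRUE) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  out <- array(c(y, cb, cr), dim = c(dim(rgb)[1:2], 3))
  if (round) out <- round(out)
  clamp(out, 0, 255)
}

#' YCbCr to RGB conversion (inverse BT.601 full range)
#'
#' @param ycbcr Array `[y, x, 3]` of Y, Cb, Cr in 0..255.
#' @param round Round to integer counts (default TRUE).
#' @return RGB array clipped to \[0, 255\].
#' @export
ycbcr_to_rgb <- function(ycbcr, round = TRUE) {
  y <- ycbcr[, , 1]; cb <- ycbcr[, , 2] - 128; cr <- ycbcr[, , 3] - 128
  r <- y + 1.402 * cr
  g <- y - 0.344136 * cb - 0.714136 * cr
  b <- y + 1.772 * cb
  out <- array(c(r, g, b), dim = c(dim(ycbcr)[1:2], 3))
  if (round) out <- round(out)
  clamp(out, 0, 255)
}

#' Per-channel YCbCr threshold box
#'
#' @param y_min,y_max,cb_min,cb_max,cr_min,cr_max Channel bounds in
#'   \[0, 255\] with min <= max.
#' @return Object of class `ycbcr_thresholds`.
#' @export
ycbcr_thresholds <- function(y_min = 0, y_max = 255, cb_min = 0, cb_max = 255,
                             cr_min = 0, cr_max = 255) {
  t <- list(y_min = y_min, y_max = y_max, cb_min = cb_min, cb_max = cb_max,
            cr_min = cr_min, cr_max = cr_max)
  for (ch in c("y", "cb", "cr")) {
    lo <- t[[paste0(ch, "_min")]]; hi <- t[[paste0(ch, "_max")]]
    if (lo > hi) stopf("%s_min > %s_max", ch, ch)
    if (lo < 0 || hi > 255) stopf("%s bounds must lie in [0, 255]", ch)
  }
  structure(t, class = "ycbcr_thresholds")
}

#' Derive a signal-threshold box from the overlay rendering parameters
#'
#' Because alpha blending is channel-wise linear and the BT.601 transform
#' is affine, every possible blended overlay pixel lies inside the YCbCr
#' bounding box of the blends of the overlay colour with the 8 RGB-cube
#' corners. That box (plus a small margin) segments the overlay exactly,
#' whatever the underlying optical colours.
#'
#' @param color Overlay RGB colour used by [merge_overlay()].
#' @param alpha Blend weight used by [merge_overlay()].
#' @param margin Extra slack per channel in counts (default 2).
#' @return A [ycbcr_thresholds()].
#' @export
default_signal_thresholds <- function(color = c(0, 80, 255), alpha = 0.9,
                                      margin = 2) {
  corners <- as.matrix(expand.grid(r = c(0, 255), g = c(0, 255), b = c(0, 255)))
  blends <- (1 - alpha) * corners + rep(alpha * color, each = 8)
  ycc <- rgb_to_ycbcr(array(blends, c(8, 1, 3)), round = FALSE)
  lo <- clamp(apply(ycc, 3, min) - margin, 0, 255)
  hi <- clamp(apply(ycc, 3, max) + margin, 0, 255)
  ycbcr_thresholds(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
}

#' Threshold a YCbCr image into a signal mask
#'
#' A pixel enters the mask iff all six channel bounds hold; a
#' morphological opening (radius 1) then drops isolated pixels.
#'
#' @param ycbcr Array `[y, x, 3]` from [rgb_to_ycbcr()].
#' @param t A [ycbcr_thresholds()].
#' @param open Apply the radius-1 opening (default TRUE).
#' @return Logical matrix.
#' @export
threshold_signal <- function(ycbcr, t, open = TRUE) {
  stopifnot(inherits(t, "ycbcr_thresholds"))
  y <- ycbcr[, , 1]; cb <- ycbcr[, , 2]; cr <- ycbcr[, , 3]
  mask <- y >= t$y_min & y <= t$y_max &
    cb >= t$cb_min & cb <= t$cb_max &
    cr >= t$cr_min & cr <= t$cr_max
  if (open && any(mask)) {
    k <- EBImage::makeBrush(3, shape = "diamond")
    mask <- EBImage::opening(mask * 1, k) > 0.5
  }
  mask
}

#' Extract the brain outer border from an optical slice image
#'
#' Otsu thresholding on luma, generalised to three classes (a TTC-style
#' image is trimodal: dark background, red viable tissue, white infarct);
#' the lower of the two optimal thresholds separates background from
#' tissue. The largest 8-connected component above it is kept and its
#' holes filled, yielding a single simply-connected tissue mask (the
#' phantom/TTC convention of background darker than tissue is assumed).
#'
#' @param rgb RGB array `[y, x, 3]`, 0..255.
#' @return Logical brain mask.
#' @export
brain_outline <- function(rgb) {
  y <- rgb_to_ycbcr(rgb, round = FALSE)[, , 1]
  if (diff(range(y)) < 1e-9)
    stopf("no foreground found: image luma is uniform")
  thr <- otsu3_lower(y)
  fg <- y > thr
  if (!any(fg)) stopf("no foreground found above Otsu threshold")
  lab <- EBImage::bwlabel(fg * 1)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  EBImage::fillHull(mask * 1) > 0.5
}

# lower threshold of two-threshold (three-class) Otsu on 0..255 data;
# maximises between-class variance over all threshold pairs
otsu3_lower <- function(y) {
  h <- tabulate(pmin(pmax(round(as.vector(y)), 0), 255) + 1L, 256L)
  w <- h / sum(h)
  lev <- 0:255
  cw <- cumsum(w)
  cm <- cumsum(w * lev)
  mu <- cm[256]
  best <- -Inf; bt <- 0L
  for (t1 in 1:254) {
    w0 <- cw[t1]
    if (w0 <= 0) next
    m0 <- cm[t1] / w0
    t2 <- (t1 + 1):255
    w1 <- cw[t2] - cw[t1]
    w2 <- 1 - cw[t2]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    m1 <- (cm[t2] - cm[t1]) / w1
    m2 <- (mu - cm[t2]) / pmax(w2, 1e-300)
    v <- w0 * (m0 - mu)^2 + w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2
    v[!ok] <- -Inf
    i <- which.max(v)
    if (v[i] > best) { best <- v[i]; bt <- t1 }
  }
  bt - 1 # threshold between bins: pixels > bt-1 are foreground
}

#' Split a brain mask into contralateral and ipsilateral hemispheres
#'
#' A straight vertical cut at `midline_x` (default: x-centroid of the
#' mask); left of the cut is contralateral, right is ipsilateral.
#'
#' @param mask Logical brain mask (rows = y).
#' @param pitch Pixel pitch, cm.
#' @param midline_x Midline x-coordinate in cm; NULL for the centroid.
#' @return List with logical `contra` and `ipsi` masks, `midline_x`, and
#'   areas `A_contra`, `A_ipsi` in cm^2 (pixel count x pixel area; the
#'   two masks partition the input exactly).
#' @export
split_hemispheres <- function(mask, pitch, midline_x = NULL) {
  if (!any(mask)) stopf("empty brain mask")
  xc <- pixel_centers(ncol(mask), pitch)
  if (is.null(midline_x)) {
    wx <- matrix(xc, nrow(mask), ncol(mask), byrow = TRUE)
    midline_x <- mean(wx[mask])
  }
  right <- matrix(xc >= midline_x, nrow(mask), ncol(mask), byrow = TRUE)
  contra <- mask & !right
  ipsi <- mask & right
  list(contra = contra, ipsi = ipsi, midline_x = midline_x,
       A_contra = sum(contra) * pitch^2, A_ipsi = sum(ipsi) * pitch^2)
}
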