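#' Detect the four fiducial droplets in a scan image
#'
#' Searches a window of radius `search_radius` around each nominal grid
#' fiducial position for an intensity peak, then localises the droplet as
#' the intensity-weighted centroid of the region above half-maximum. The
#' centroid is evaluated on a bilinearly upsampled window with a circular
#' aperture re-centred iteratively, which removes the asymmetric-window
#' truncation bias of a plain pixel-grid centroid (subpixel accuracy well
#' below the scan pitch). Because the four nominal positions are
#' symmetric under a 180-degree rotation of the grid, correspondence is
#' assigned by ranking the droplets' integrated intensities against the
#' configured distinct droplet amounts rather than by window position.
#'
#' @param img A [scan_image()] in the scanner frame.
#' @param g A [grid_layout()].
#' @param search_radius Window half-size, cm (default 0.25).
#' @param droplet_amount The configured droplet amounts in fiducial order
#'   (used for intensity-rank correspondence); must be distinct.
#' @return A data.frame with one row per fiducial: `label` (index into
#'   `g$fiducials`, i.e. which configured droplet this is), `x_cm`,
#'   `y_cm` (scanner frame), `window` (which nominal window it was found
#'   in), `peak` and `integral`.
#' @export
detect_fiducials <- function(img, g, search_radius = 0.25,
                             droplet_amount = c(1.0, 0.8, 0.6, 0.4)) {
  stopifnot(inherits(img, "scan_image"), inherits(g, "slide_grid"))
  if (anyDuplicated(droplet_amount))
    stopf("droplet amounts must be distinct for rank-based correspondence")
  v <- img$values
  xc <- pixel_centers(ncol(v), img$pitch)
  yc <- pixel_centers(nrow(v), img$pitch)
  found <- vector("list", 4)
  fails <- character(0)
  upsample <- 8
  for (i in 1:4) {
    fx <- g$fiducials[i, 1]; fy <- g$fiducials[i, 2]
    cols <- which(abs(xc - fx) <= search_radius)
    rows <- which(abs(yc - fy) <= search_radius)
    w <- v[rows, cols, drop = FALSE]
    pk <- max(w)
    if (!is.finite(pk) || pk <= 0) {
      fails <- c(fails, sprintf("window %d at (%.2f, %.2f) cm: no positive peak", i, fx, fy))
      next
    }
    ux <- seq(fx - search_radius, fx + search_radius, by = img$pitch / upsample)
    uy <- seq(fy - search_radius, fy + search_radius, by = img$pitch / upsample)
    UX <- matrix(ux, length(uy), length(ux), byrow = TRUE)
    UY <- matrix(uy, length(uy), length(ux))
    uw <- matrix(bilinear_sample(v, as.vector(UX) / img$pitch + 0.5,
                                 as.vector(UY) / img$pitch + 0.5), length(uy))
    upk <- max(uw)
    cx <- UX[which.max(uw)]; cy <- UY[which.max(uw)]
    for (it in 1:6) {
      sel <- uw >= upk / 2 &
        (UX - cx)^2 + (UY - cy)^2 <= (0.7 * search_radius)^2
      wt <- uw * sel
      cx <- sum(UX * wt) / sum(wt)
      cy <- sum(UY * wt) / sum(wt)
    }
    found[[i]] <- data.frame(window = i, x_cm = cx, y_cm = cy,
                             peak = pk, integral = sum(w))
  }
  if (length(fails) > 0)
    stopf("fiducial detection failed:\n  %s", paste(fails, collapse = "\n  "))
  det <- do.call(rbind, found)
  # brightest detected droplet <-> largest configured amount, etc.
  det$label <- order(droplet_amount, decreasing = TRUE)[rank(-det$integral)]
  det[, c("label", "x_cm", "y_cm", "window", "peak", "integral")]
}

#' Fit an exact four-point homography (DLT)
#'
#' Solves the 8-unknown direct linear transform mapping four source
#' points to four destination points; with exactly four correspondences
#' the projective transform is exactly determined and the forward-mapping
#' residual at the points is at rounding level.
#'
#' @param src,dst 4 x 2 matrices of (x, y) coordinates; no three points
#'   of either set may be collinear.
#' @return A 3 x 3 matrix of class `homography`, normalised so the
#'   bottom-right entry is 1 (unit Frobenius norm if that entry is ~0).
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == 4, nrow(dst) == 4, ncol(src) == 2, ncol(dst) == 2)
  check_collinear <- function(p, name) {
    combs <- utils::combn(4, 3)
    scale2 <- max(apply(p, 2, function(c) diff(range(c))))^2
    for (j in seq_len(ncol(combs))) {
      i <- combs[, j]
      a <- p[i[2], ] - p[i[1], ]; b <- p[i[3], ] - p[i[1], ]
      if (abs(a[1] * b[2] - a[2] * b[1]) < 1e-9 * scale2)
        stopf("degenerate configuration: %s points %s are collinear",
              name, paste(i, collapse = ", "))
    }
  }
  check_collinear(src, "source")
  check_collinear(dst, "destination")
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; xp <- dst[i, 1]; yp <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -xp * x, -xp * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -yp * x, -yp * y)
    b[2 * i - 1] <- xp
    b[2 * i] <- yp
  }
  h <- solve(A, b)
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  H <- normalize_homography(H)
  if (abs(det(H)) < 1e-12) stopf("fitted homography is singular")
  structure(H, class = c("homography", "matrix"))
}

normalize_homography <- function(H) {
  if (abs(H[3, 3]) > 1e-12) H / H[3, 3] else H / sqrt(sum(H^2))
}

#' Apply a homography to 2D points
#'
#' @param H 3 x 3 homography.
#' @param pts n x 2 matrix of (x, y).
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  q <- H %*% pts
  t(q[1:2, , drop = FALSE] / rep(q[3, ], each = 2))
}

#' Warp a scan image into the optical frame through a homography
#'
#' Inverse-mapping resampling with bilinear interpolation: each target
#' pixel centre (optical cm coordinates) is pulled back through `H^-1`
#' and sampled in the source image; out-of-domain pixels are 0. When
#' `preserve_mass = TRUE` (default) each output value is multiplied by
#' the local Jacobian determinant of the inverse map, so integrated
#' signal is preserved under the coordinate change (the amplitude map is
#' a density).
#'
#' @param img Source [scan_image()].
#' @param H [fit_homography()] result mapping source cm coordinates to
#'   target cm coordinates.
#' @param target_shape `c(ny, nx)` of the output raster.
#' @param target_pitch Output pixel pitch, cm.
#' @param preserve_mass Apply the Jacobian density correction.
#' @return A [scan_image()] with `frame = "optical"`.
#' @export
warp <- function(img, H, target_shape, target_pitch, preserve_mass = TRUE) {
  stopifnot(inherits(img, "scan_image"))
  Hi <- solve(H)
  ny <- target_shape[1]; nx <- target_shape[2]
  tx <- pixel_centers(nx, target_pitch)
  ty <- pixel_centers(ny, target_pitch)
  P <- cbind(rep(tx, each = ny), rep(ty, times = nx))
  q <- Hi %*% rbind(t(P), 1)
  wq <- q[3, ]
  sx <- q[1, ] / wq
  sy <- q[2, ] / wq
  vals <- bilinear_sample(img$values, sx / img$pitch + 0.5, sy / img$pitch + 0.5)
  if (preserve_mass) {
    # local area scale of a projective map: det(Hi) / w^3
    vals <- vals * abs(det(Hi) / wq^3)
  }
  scan_image(matrix(vals, ny, nx), target_pitch, "optical")
}

#' Overlay a warped signal image on an optical slice image
#'
#' Pixels whose signal exceeds `threshold` are alpha-blended with the
#' overlay colour; all other pixels pass through unchanged.
#'
#' @param optical RGB array `[y, x, 3]`, 0..255.
#' @param signal A [scan_image()] in the optical frame with the same
#'   raster shape.
#' @param color Overlay RGB colour (default strong blue, distinct from
#'   both TTC red and infarct white).
#' @param alpha Blend weight of the overlay colour in (0, 1\].
#' @param threshold Absolute signal threshold; the default, half the
#'   signal maximum, recovers the support of a PSF-blurred uniform
#'   source at its true boundary.
#' @return RGB array `[y, x, 3]`.
#' @export
merge_overlay <- function(optical, signal, color = c(0, 80, 255), alpha = 0.9,
                          threshold = NULL) {
  stopifnot(inherits(signal, "scan_image"))
  if (!all(dim(optical)[1:2] == dim(signal$values)))
    stopf("optical (%s) and signal (%s) shapes differ",
          paste(dim(optical)[1:2], collapse = "x"),
          paste(dim(signal$values), collapse = "x"))
  if (is.null(threshold)) threshold <- 0.5 * max(signal$values)
  mask <- signal$values > threshold
  out <- optical
  for (ch in 1:3) {
    m <- out[, , ch]
    m[mask] <- (1 - alpha) * m[mask] + alpha * color[ch]
    out[, , ch] <- m
  }
  out
}

#' Serialize a homography to JSON (row-major, with normalization note)
#' @param H A homography matrix.
#' @param path Output path.
#' @export
write_homography_json <- function(H, path) {
  jsonlite::write_json(list(matrix_row_major = as.vector(t(H)),
                            normalization = "bottom-right entry = 1"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_homography_json
#' @export
read_homography_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(matrix(j$matrix_row_major, 3, 3, byrow = TRUE),
            class = c("homography", "matrix"))
}
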