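#' Slide-grid geometry for the scanner platform
#'
#' The slide carries an `n_cols` x `n_rows` labelled grid (cells numbered
#' 1..25 in row-major order, row 1 at top, column 1 at left). Four
#' fiducial reference points sit on the midpoints between cell pairs
#' (1,2), (4,5), (21,22) and (24,25); SPION droplets placed there anchor
#' the registration between scanner and optical coordinates. The
#' measurement head scans along vertical lines and shifts `step_width`
#' between lines, `n_shifts` times, right to left.
#'
#' @param width,height Total grid extent in cm (default 3.0 x 2.4).
#' @param n_cols,n_rows Grid subdivision (default 5 x 5).
#' @param step_width Lateral shift between scan lines, cm (default 0.3).
#' @param n_shifts Number of scan lines (default 10).
#' @return An object of class `slide_grid` with computed `cell_width`,
#'   `cell_height` and the 4 x 2 `fiducials` matrix (x_cm, y_cm).
#' @examples
#' g <- grid_layout(3.0, 2.4)
#' g$cell_width    # 0.6
#' g$fiducials
#' @export
grid_layout <- function(width = 3.0, height = 2.4, n_cols = 5L, n_rows = 5L,
                        step_width = 0.3, n_shifts = 10L) {
  if (!is_scalar_num(width) || !is_scalar_num(height) || width <= 0 || height <= 0)
    stopf("width and height must be positive")
  cw <- width / n_cols
  ch <- height / n_rows
  cell_mid <- function(cells) {
    # centre of mass of the named cells (row-major labels starting at 1)
    r <- (cells - 1) %/% n_cols
    c <- (cells - 1) %% n_cols
    c(mean(c + 0.5) * cw, mean(r + 0.5) * ch)
  }
  fid <- rbind(cell_mid(c(1, 2)), cell_mid(c(4, 5)),
               cell_mid(c(21, 22)), cell_mid(c(24, 25)))
  colnames(fid) <- c("x_cm", "y_cm")
  rownames(fid) <- c("top_left", "top_right", "bottom_left", "bottom_right")
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 total_width = width, total_height = height,
                 cell_width = cw, cell_height = ch,
                 fiducials = fid,
                 step_width = step_width, n_shifts = as.integer(n_shifts)),
            class = "slide_grid")
}

#' Scan-line x positions of the raster trajectory
#'
#' The head traverses `n_shifts` vertical lines spaced `step_width`
#' apart, ordered right to left and centred on the grid width.
#'
#' @param g A [grid_layout()].
#' @return Numeric vector of x positions (cm), decreasing.
#' @export
scan_trajectory <- function(g) {
  stopifnot(inherits(g, "slide_grid"))
  span <- (g$n_shifts - 1) * g$step_width
  margin <- (g$total_width - span) / 2
  if (margin < 0) stopf("scan lines (%g cm span) exceed grid width", span)
  seq(g$total_width - margin, by = -g$step_width, length.out = g$n_shifts)
}

#' 2D scan-image / concentration-map container
#'
#' A plain matrix of values on a square-pixel raster tied to slide
#' coordinates: origin at the top-left corner, x rightward (columns), y
#' downward (rows), pixel centres at (i - 0.5) * pitch.
#'
#' @param values Numeric matrix (rows = y, cols = x).
#' @param pitch Pixel pitch, cm per pixel.
#' @param frame Coordinate frame tag, `"scanner"` or `"optical"`.
#' @return Object of class `scan_image`.
#' @export
scan_image <- function(values, pitch, frame = c("scanner", "optical")) {
  frame <- match.arg(frame)
  stopifnot(is.matrix(values), is.numeric(values), is_scalar_num(pitch), pitch > 0)
  structure(list(values = values, pitch = pitch, frame = frame),
            class = "scan_image")
}

#' Empty concentration map covering a slide grid
#'
#' @param g A [grid_layout()].
#' @param pitch Pixel pitch in cm (default 0.05, the along-line sampling
#'   pitch).
#' @return A zero-valued [scan_image()] in the scanner frame.
#' @export
empty_conc_map <- function(g, pitch = 0.05) {
  nx <- as.integer(round(g$total_width / pitch))
  ny <- as.integer(round(g$total_height / pitch))
  scan_image(matrix(0, ny, nx), pitch, "scanner")
}

#' Isotropic Gaussian point-spread kernel
#'
#' Models the sensitivity footprint of the measurement coil pair as an
#' isotropic Gaussian truncated at 3 sigma and normalised to unit sum, so
#' convolution conserves total signal away from borders.
#'
#' @param fwhm Full width at half maximum, cm.
#' @param pixel_pitch Pixel pitch, cm.
#' @return A square odd-sized matrix summing to 1. `fwhm -> 0` degenerates
#'   to the 1 x 1 identity kernel.
#' @export
psf_kernel <- function(fwhm = 0.15, pixel_pitch = 0.05) {
  if (!is_scalar_num(fwhm) || fwhm < 0) stopf("fwhm must be >= 0")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- ceiling(3 * sigma / pixel_pitch)
  if (r == 0) return(matrix(1, 1, 1))
  ax <- (-r:r) * pixel_pitch
  k <- outer(ax, ax, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  k / sum(k)
}

#' Simulate raster-scan acquisition of a concentration map
#'
#' Per pixel, the measured `f1 + 2 f2` amplitude is
#' `cal_slope * (psf %*% conc)` -- the small-signal mixing amplitude for
#' the local particle amount, spatially blurred by the coil footprint.
#' Optionally only the `n_shifts` scan-line columns are retained and the
#' image is rebuilt by linear interpolation across lines, emulating the
#' instrument's coarse lateral sampling.
#'
#' @param conc A [scan_image()] holding particle amount per pixel
#'   (non-negative), registered to the grid frame.
#' @param g A [grid_layout()].
#' @param psf Kernel matrix from [psf_kernel()] (default FWHM 0.15 cm at
#'   the map's pitch).
#' @param cal An `fmmd_calibration` or a plain positive slope (signal
#'   units per unit amount; default 1).
#' @param noise_sd Additive white Gaussian noise sd (signal units).
#' @param seed RNG seed for the noise.
#' @param line_sampled If TRUE, decimate to the scan-line columns and
#'   linearly interpolate back to the full raster.
#' @return A [scan_image()] in the scanner frame.
#' @export
acquire <- function(conc, g, psf = NULL, cal = 1, noise_sd = 0, seed = NULL,
                    line_sampled = FALSE) {
  stopifnot(inherits(conc, "scan_image"), inherits(g, "slide_grid"))
  if (any(conc$values < 0)) stopf("concentration map must be non-negative")
  if (is.null(psf)) psf <- psf_kernel(0.15, conc$pitch)
  slope <- if (inherits(cal, "fmmd_calibration") || is.list(cal)) cal$slope else cal
  if (!is_scalar_num(slope) || slope <= 0) stopf("calibration slope must be > 0")
  blurred <- conv2_zero(conc$values, psf)
  sig <- slope * blurred
  if (line_sampled) {
    xc <- pixel_centers(ncol(sig), conc$pitch)
    lines_x <- sort(scan_trajectory(g))
    cols <- vapply(lines_x, function(x) which.min(abs(xc - x)), integer(1))
    samp <- sig[, cols, drop = FALSE]
    sig <- t(apply(samp, 1, function(row)
      stats::approx(xc[cols], row, xout = xc, rule = 2)$y))
  }
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, matrix(stats::rnorm(length(sig), sd = noise_sd),
                                        nrow(sig)))
  scan_image(sig, conc$pitch, "scanner")
}

# 2D convolution with zero padding outside the image (EBImage's FFT
# filter with explicit zero boundary); kernel must be odd-sized.
conv2_zero <- function(m, k) {
  if (nrow(k) == 1 && ncol(k) == 1) return(m * k[1, 1])
  EBImage::filter2(m, k, boundary = 0)
}

#' Deposit the four fiducial SPION droplets onto a concentration map
#'
#' Adds disk-shaped deposits centred on the grid fiducials. The four
#' amounts default to distinct values so that droplet intensity ranking
#' disambiguates the 180-degree rotational symmetry of the fiducial
#' layout during registration.
#'
#' @param conc A [scan_image()] concentration map.
#' @param g A [grid_layout()].
#' @param droplet_amount Total amount per droplet; length 1 or 4
#'   (default `c(1.0, 0.8, 0.6, 0.4)` in fiducial order top-left,
#'   top-right, bottom-left, bottom-right).
#' @param droplet_radius Disk radius, cm (default 0.06).
#' @return The map with droplets added; each droplet's integrated amount
#'   equals its requested amount exactly (uniform distribution over the
#'   disk's pixels).
#' @export
add_fiducial_droplets <- function(conc, g, droplet_amount = c(1.0, 0.8, 0.6, 0.4),
                                  droplet_radius = 0.06) {
  stopifnot(inherits(conc, "scan_image"), inherits(g, "slide_grid"))
  amounts <- rep_len(droplet_amount, 4)
  v <- conc$values
  xc <- pixel_centers(ncol(v), conc$pitch)
  yc <- pixel_centers(nrow(v), conc$pitch)
  for (i in 1:4) {
    if (amounts[i] == 0) next
    fx <- g$fiducials[i, 1]; fy <- g$fiducials[i, 2]
    if (fx - droplet_radius < 0 || fx + droplet_radius > ncol(v) * conc$pitch ||
        fy - droplet_radius < 0 || fy + droplet_radius > nrow(v) * conc$pitch)
      stopf("fiducial droplet %d overlaps the map border", i)
    d2 <- outer((yc - fy)^2, (xc - fx)^2, `+`)
    disk <- d2 <= droplet_radius^2
    if (!any(disk)) stopf("droplet radius %g cm below pixel pitch", droplet_radius)
    v[disk] <- v[disk] + amounts[i] / sum(disk)
  }
  scan_image(v, conc$pitch, conc$frame)
}

#' Write / read a scan image as 32-bit float TIFF with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records pixel pitch, frame tag and value
#' scale, since TIFF stores normalised floats.
#'
#' @param img A [scan_image()].
#' @param path Output TIFF path.
#' @return `path` invisibly (write); a [scan_image()] (read).
#' @export
write_scan_tiff <- function(img, path) {
  stopifnot(inherits(img, "scan_image"))
  tiff::writeTIFF(img$values / max(img$values, 1e-300), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_pitch_cm = img$pitch, frame = img$frame,
                            value_scale = max(img$values, 1e-300)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scan_tiff
#' @export
read_scan_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  v <- tiff::readTIFF(path) * meta$value_scale
  scan_image(v, meta$pixel_pitch_cm, meta$frame)
}

#' Write a scan image as long-format CSV (x_cm, y_cm, amplitude)
#' @param img A [scan_image()].
#' @param path Output CSV path.
#' @export
write_scan_csv <- function(img, path) {
  stopifnot(inherits(img, "scan_image"))
  xc <- pixel_centers(ncol(img$values), img$pitch)
  yc <- pixel_centers(nrow(img$values), img$pitch)
  df <- data.frame(x_cm = rep(xc, each = nrow(img$values)),
                   y_cm = rep(yc, times = ncol(img$values)),
                   amplitude = as.vector(img$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
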