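#' Synthetic coronal brain-slice phantom with one-sided infarct
#'
#' Generates a ground-truth slice for pipeline testing: two mirrored
#' half-brain superellipse lobes about a vertical midline, an ipsilateral
#' (right) lobe optionally swollen by an isotropic edema factor, and an
#' infarct region grown inside the ipsilateral lobe until its area equals
#' `infarct_fraction` of the ipsilateral area (to one-pixel granularity).
#' Boundary roughness is seeded and mirror-symmetric about the midline,
#' so at `edema_factor = 1` the hemispheres have exactly equal areas.
#'
#' The map covers the full slide-grid extent; the brain sits centrally so
#' it occupies the inner 3 x 3 cells of the 5 x 5 grid, clear of the
#' fiducial positions.
#'
#' @param width_cm,height_cm Map extent in cm (defaults 3.0 x 2.4, the
#'   slide grid).
#' @param pitch Pixel pitch in cm (default 0.01).
#' @param infarct_fraction Target `A_infarct / A_ipsi` in \[0, 1).
#' @param edema_factor Isotropic linear scaling of the ipsilateral lobe
#'   (>= 1); hemisphere area scales as its square.
#' @param roughness Relative amplitude of the seeded boundary
#'   perturbation (default 0.08).
#' @param seed RNG seed; same seed gives a bit-identical phantom.
#' @param lobe_rx,lobe_ry Lobe semi-axes as fractions of width/height.
#' @param superellipse_exp Superellipse exponent (default 2.5).
#' @return Object of class `slice_phantom`: logical `brain_mask` and
#'   `infarct_mask` matrices (rows = y), numeric `conc_map` (amount/cm^2,
#'   zero until [bind_spions()]), `pitch`, `midline_x` (cm), and `truth`
#'   record with `A_contra`, `A_ipsi`, `A_infarct` (cm^2),
#'   `infarct_fraction` and the edema-corrected `effective_pct`.
#' @export
make_slice <- function(width_cm = 3.0, height_cm = 2.4, pitch = 0.01,
                       infarct_fraction = 0.5, edema_factor = 1.0,
                       roughness = 0.08, seed = NULL,
                       lobe_rx = 0.28, lobe_ry = 0.26,
                       superellipse_exp = 2.5) {
  if (infarct_fraction < 0 || infarct_fraction >= 1)
    stopf("infarct_fraction must be in [0, 1)")
  if (edema_factor < 1) stopf("edema_factor must be >= 1")
  nx <- as.integer(round(width_cm / pitch))
  ny <- as.integer(round(height_cm / pitch))
  xc <- pixel_centers(nx, pitch)
  yc <- pixel_centers(ny, pitch)
  mid <- width_cm / 2
  cy <- height_cm / 2
  ax <- lobe_rx * width_cm
  ay <- lobe_ry * height_cm
  p <- superellipse_exp

  # mirror-symmetric radial roughness: cos(k (theta - pi/2)) harmonics are
  # even under x-reflection (theta -> pi - theta)
  coefs <- with_seed(seed, stats::rnorm(4, sd = 1 / (1:4)))
  coefs <- coefs / max(1, sqrt(sum(coefs^2)))
  X <- matrix(xc, ny, nx, byrow = TRUE)
  Y <- matrix(yc, ny, nx)
  side_r <- X >= mid
  e <- ifelse(side_r, edema_factor, 1)
  u <- (X - mid) / (ax * e)
  v <- (Y - cy) / (ay * e)
  r <- (abs(u)^p + abs(v)^p)^(1 / p)
  th <- atan2(v, u)
  s <- matrix(0, ny, nx)
  for (k in 1:4) s <- s + coefs[k] * cos(k * (th - pi / 2))
  brain <- r <= 1 + roughness * s

  # grow the infarct from a mid-lateral seed point inside the ipsi lobe;
  # selecting the k nearest pixels pins the area fraction exactly
  ipsi <- brain & side_r
  n_ipsi <- sum(ipsi)
  if (n_ipsi == 0) stopf("degenerate geometry: empty ipsilateral lobe")
  sx <- mid + 0.55 * edema_factor * ax
  sy <- cy
  icoef <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                     stats::rnorm(4, sd = 1 / (1:4)))
  d <- sqrt((X - sx)^2 + (Y - sy)^2)
  tho <- atan2(Y - sy, X - sx)
  dn <- matrix(0, ny, nx)
  for (k in 1:4) dn <- dn + icoef[k] * cos(k * tho + k)
  d <- d * pmax(0.2, 1 + 2 * roughness * dn)
  infarct <- matrix(FALSE, ny, nx)
  k_target <- as.integer(round(infarct_fraction * n_ipsi))
  if (k_target > 0) {
    di <- d[ipsi]
    thr <- sort(di, partial = k_target)[k_target]
    infarct <- ipsi & d <= thr
    # resolve ties so the count is exact
    extra <- sum(infarct) - k_target
    if (extra > 0) {
      idx <- which(infarct & d == thr)
      infarct[idx[seq_len(extra)]] <- FALSE
    }
  }

  px_area <- pitch^2
  a_contra <- sum(brain & !side_r) * px_area
  a_ipsi <- n_ipsi * px_area
  a_inf <- sum(infarct) * px_area
  truth <- list(
    A_contra = a_contra, A_ipsi = a_ipsi, A_infarct = a_inf,
    infarct_fraction = if (n_ipsi > 0) a_inf / a_ipsi else 0,
    effective_pct = infarct_percent(a_contra, a_ipsi, a_inf))
  structure(list(brain_mask = brain, infarct_mask = infarct,
                 conc_map = matrix(0, ny, nx), infarct_d = d,
                 pitch = pitch, width_cm = width_cm, height_cm = height_cm,
                 midline_x = mid, edema_factor = edema_factor,
                 truth = truth, seed = seed),
            class = "slice_phantom")
}

#' Infarct fraction needed to hit a target edema-corrected percentage
#'
#' Inverts the edema-corrected infarct formula for the generator: with
#' hemisphere area ratio `edema_factor^2`, a per-slice fraction
#' `1 - (1 - target/100) / edema_factor^2` yields the requested
#' percentage.
#'
#' @param target_pct Desired edema-corrected infarct percentage.
#' @param edema_factor Linear edema scaling of the ipsilateral lobe.
#' @return The `infarct_fraction` to pass to [make_slice()].
#' @export
fraction_for_effective <- function(target_pct, edema_factor = 1.0) {
  f <- 1 - (1 - target_pct / 100) / edema_factor^2
  if (f < 0 || f >= 1)
    stopf("target %g%% infeasible at edema_factor %g", target_pct, edema_factor)
  f
}

#' Bind SPIONs to the phantom's infarct (activated-microglia surrogate)
#'
#' Fills the concentration map with `density` (amount per cm^2) on the
#' infarct, optionally on only the innermost `coverage` fraction of it
#' (microglial activation need not span the whole infarct), with seeded
#' multiplicative texture.
#'
#' @param p A [make_slice()] phantom.
#' @param density Amount per cm^2 on covered pixels (> 0).
#' @param heterogeneity Relative sd of the multiplicative texture
#'   (default 0: uniform).
#' @param coverage Fraction of the infarct area carrying particles
#'   (default 1); pixels nearest the infarct seed are covered first.
#' @param seed RNG seed for the texture.
#' @return The phantom with `conc_map` filled (non-negative, supported on
#'   the infarct mask).
#' @export
bind_spions <- function(p, density = 1, heterogeneity = 0, coverage = 1,
                        seed = NULL) {
  stopifnot(inherits(p, "slice_phantom"))
  if (density <= 0) stopf("density must be > 0")
  if (coverage < 0 || coverage > 1) stopf("coverage must be in [0, 1]")
  mask <- p$infarct_mask
  n_inf <- sum(mask)
  if (n_inf > 0 && coverage < 1) {
    k <- as.integer(round(coverage * n_inf))
    cov <- matrix(FALSE, nrow(mask), ncol(mask))
    if (k > 0) {
      di <- p$infarct_d[mask]
      thr <- sort(di, partial = k)[k]
      cov <- mask & p$infarct_d <= thr
    }
    mask <- cov
  }
  conc <- matrix(0, nrow(mask), ncol(mask))
  if (sum(mask) > 0) {
    tex <- 1
    if (heterogeneity > 0) {
      noise <- with_seed(seed, matrix(stats::rnorm(length(mask)), nrow(mask)))
      noise <- conv2_zero(noise, psf_kernel(6 * p$pitch, p$pitch))
      noise <- noise / stats::sd(noise)
      tex <- 1 + heterogeneity * noise[mask]
    }
    conc[mask] <- pmax(0, density * tex)
  }
  p$conc_map <- conc
  p
}

#' Synthetic z-stack of coronal slice phantoms
#'
#' Emulates serial 40 um cryosections with every k-th section scanned:
#' slice silhouettes follow an ellipsoidal axial profile peaking
#' mid-stack, and the infarct is present only over a contiguous index
#' range with a smooth per-slice fraction profile.
#'
#' @param n_sections Total number of cut sections (default 629).
#' @param sampled Indices of the scanned sections (default
#'   `seq(135, 345, by = 15)`, i.e. every 15th section between 135 and
#'   345 -- 15 slices).
#' @param section_thickness_um Cut thickness in micrometres (default 40).
#' @param infarct_fraction Peak per-slice `A_infarct / A_ipsi`; either a
#'   scalar (flat profile) or the peak of an elliptical profile when
#'   `fraction_profile = "elliptical"`.
#' @param fraction_profile `"flat"` (same fraction on every infarcted
#'   slice) or `"elliptical"`.
#' @param infarct_range Section-index range carrying infarct (default the
#'   sampled range).
#' @param edema_factor,roughness,pitch,width_cm,height_cm Per-slice
#'   parameters, see [make_slice()].
#' @param spion_density,spion_coverage,spion_heterogeneity Passed to
#'   [bind_spions()] per slice.
#' @param seed Stack seed; slice i uses `seed + 10 * i`.
#' @return Object of class `stack_phantom`: `slices` (list of
#'   `slice_phantom`), `slice_indices`, `z_spacing_cm`
#'   (`sampling step x thickness`), and `truth` with per-slice areas,
#'   summed volumes (cm^3) and the aggregate edema-corrected percentage.
#' @export
make_stack <- function(n_sections = 629L, sampled = seq(135L, 345L, by = 15L),
                       section_thickness_um = 40,
                       infarct_fraction = 0.5, fraction_profile = c("flat", "elliptical"),
                       infarct_range = range(sampled),
                       edema_factor = 1.0, roughness = 0.08,
                       pitch = 0.01, width_cm = 3.0, height_cm = 2.4,
                       spion_density = 1, spion_coverage = 1,
                       spion_heterogeneity = 0, seed = 1L) {
  fraction_profile <- match.arg(fraction_profile)
  sampled <- as.integer(sampled)
  if (any(sampled < 1L | sampled > n_sections))
    stopf("sampled indices must lie within 1..%d", n_sections)
  steps <- diff(sampled)
  if (length(unique(steps)) > 1L) stopf("sampled indices must be evenly spaced")
  z_spacing <- steps[1] * section_thickness_um * 1e-4 # um -> cm

  mid_i <- (n_sections + 1) / 2
  half_i <- n_sections / 2
  axial <- function(i) sqrt(pmax(0.02, 1 - ((i - mid_i) / half_i)^2))
  frac_of <- function(i) {
    if (i < infarct_range[1] || i > infarct_range[2]) return(0)
    if (fraction_profile == "flat") return(infarct_fraction)
    m <- mean(infarct_range); h <- diff(infarct_range) / 2
    infarct_fraction * sqrt(pmax(0, 1 - ((i - m) / max(h, 1))^2))
  }
  slices <- lapply(sampled, function(i) {
    sc <- axial(i)
    p <- make_slice(width_cm, height_cm, pitch,
                    infarct_fraction = frac_of(i),
                    edema_factor = edema_factor, roughness = roughness,
                    seed = seed + 10L * i,
                    lobe_rx = 0.28 * sc, lobe_ry = 0.26 * sc)
    bind_spions(p, density = spion_density, coverage = spion_coverage,
                heterogeneity = spion_heterogeneity, seed = seed + 10L * i + 5L)
  })
  per <- do.call(rbind, lapply(seq_along(slices), function(j) {
    tr <- slices[[j]]$truth
    data.frame(slice_index = sampled[j], A_contra = tr$A_contra,
               A_ipsi = tr$A_ipsi, A_infarct = tr$A_infarct,
               V_infarct_pct = tr$effective_pct)
  }))
  agg <- list(
    V_contra_cm3 = sum(per$A_contra) * z_spacing,
    V_ipsi_cm3 = sum(per$A_ipsi) * z_spacing,
    V_infarct_cm3 = sum(per$A_infarct) * z_spacing,
    effective_pct = infarct_percent(sum(per$A_contra), sum(per$A_ipsi),
                                    sum(per$A_infarct)))
  structure(list(slices = slices, slice_indices = sampled,
                 n_sections = as.integer(n_sections),
                 section_thickness_um = section_thickness_um,
                 sampling_interval = steps[1], z_spacing_cm = z_spacing,
                 truth = list(per_slice = per, aggregate = agg), seed = seed),
            class = "stack_phantom")
}

#' Render a phantom slice as an RGB optical image
#'
#' `ttc` style mimics a tetrazolium-stained section photograph: dark
#' background, red viable tissue (high Cr), achromatic white infarct;
#' `fluorescence` style shows a green marker signal on the infarct over a
#' dark section.
#'
#' @param p A [make_slice()] phantom.
#' @param style `"ttc"` or `"fluorescence"`.
#' @return Numeric array `[y, x, 3]` with 8-bit values in 0..255.
#' @export
render_optical <- function(p, style = c("ttc", "fluorescence")) {
  style <- match.arg(style)
  ny <- nrow(p$brain_mask); nx <- ncol(p$brain_mask)
  img <- array(0, c(ny, nx, 3))
  paint <- function(img, mask, rgbv) {
    for (ch in 1:3) {
      m <- img[, , ch]; m[mask] <- rgbv[ch]; img[, , ch] <- m
    }
    img
  }
  if (style == "ttc") {
    img <- paint(img, !p$brain_mask, c(15, 15, 15))
    img <- paint(img, p$brain_mask & !p$infarct_mask, c(200, 30, 30))
    img <- paint(img, p$infarct_mask, c(248, 248, 248))
  } else {
    img <- paint(img, !p$brain_mask, c(8, 8, 8))
    img <- paint(img, p$brain_mask & !p$infarct_mask, c(40, 40, 40))
    img <- paint(img, p$infarct_mask, c(40, 230, 60))
  }
  img
}

#' Save a phantom stack to a directory
#'
#' Writes `optical_###.png`, `conc_###.tiff` (+ JSON sidecars),
#' `brain_###.png` / `infarct_###.png` truth masks (0/255) and
#' `truth.json` (areas in cm^2, fractions, seed, z-spacing).
#'
#' @param stack A [make_stack()] result.
#' @param dir Output directory (created if needed).
#' @param style Optical rendering style.
#' @return `dir`, invisibly.
#' @export
save_phantom <- function(stack, dir, style = "ttc") {
  stopifnot(inherits(stack, "stack_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(stack$slices)) {
    p <- stack$slices[[j]]
    tag <- sprintf("%03d", stack$slice_indices[j])
    write_rgb_png(render_optical(p, style), file.path(dir, paste0("optical_", tag, ".png")))
    write_scan_tiff(scan_image(p$conc_map, p$pitch, "optical"),
                    file.path(dir, paste0("conc_", tag, ".tiff")))
    write_mask_png(p$brain_mask, file.path(dir, paste0("brain_", tag, ".png")))
    write_mask_png(p$infarct_mask, file.path(dir, paste0("infarct_", tag, ".png")))
  }
  truth <- list(slice_indices = stack$slice_indices,
                z_spacing_cm = stack$z_spacing_cm,
                section_thickness_um = stack$section_thickness_um,
                pitch_cm = stack$slices[[1]]$pitch,
                midline_x_cm = stack$slices[[1]]$midline_x,
                seed = stack$seed,
                per_slice = stack$truth$per_slice,
                aggregate = stack$truth$aggregate)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

# ---- small raster I/O helpers (8-bit PNG via the png package) ----

#' Write an RGB array (0..255) as PNG
#' @param img Numeric `[y, x, 3]` array, values 0..255.
#' @param path Output path.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Read a PNG as an RGB array (0..255)
#' @param path PNG path.
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' Write / read a binary mask as 0/255 grayscale PNG
#' @param mask Logical matrix.
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}
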