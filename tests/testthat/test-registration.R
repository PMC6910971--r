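# Fiducial detection, four-point homography, warping, overlay.

test_that("homography fit: identity, translation, projective round trip", {
  g <- grid_layout()
  H <- fit_homography(g$fiducials, g$fiducials)
  expect_equal(unclass(H), diag(3), tolerance = 1e-9, ignore_attr = TRUE)

  dst <- cbind(g$fiducials[, 1] + 2, g$fiducials[, 2] - 3)
  Ht <- fit_homography(g$fiducials, dst)
  expect_equal(Ht[1:2, 3], c(2, -3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(Ht[3, ], c(0, 0, 1), tolerance = 1e-9, ignore_attr = TRUE)

  H0 <- matrix(c(0.95, -0.08, 0.2, 0.05, 1.1, -0.12, 0.02, -0.015, 1),
               3, 3, byrow = TRUE)
  fit <- fit_homography(g$fiducials, apply_homography(H0, g$fiducials))
  expect_lt(max(abs(fit - H0)), 1e-6)
  # forward residual at the 4 points
  expect_lt(max(abs(apply_homography(fit, g$fiducials) -
                      apply_homography(H0, g$fiducials))), 1e-8)
})

test_that("degenerate fiducial configurations are rejected by name", {
  src <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1)) # points 1,2,3 collinear
  dst <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_error(fit_homography(src, dst), "collinear.*1, 2, 3|1, 2, 3.*collinear")
})

test_that("fiducial detection: subpixel centres and rank-based labels", {
  g <- grid_layout()
  # droplets deposited at fine pitch, blurred, then sampled at scan pitch:
  # the acquisition geometry of the pipeline
  conc <- empty_conc_map(g, 0.01)
  amt <- add_fiducial_droplets(conc, g)
  field <- acquire(amt, g, psf_kernel(0.15, 0.01))
  Hid <- fit_homography(g$fiducials, g$fiducials)
  img <- warp(field, Hid, c(48, 60), 0.05, preserve_mass = FALSE)
  img$frame <- "scanner"
  fid <- detect_fiducials(img, g)
  fid <- fid[order(fid$window), ]
  err <- sqrt(rowSums((as.matrix(fid[, c("x_cm", "y_cm")]) - g$fiducials)^2))
  expect_lt(max(err), 0.5 * 0.05) # within half a scan pixel
  expect_equal(fid$label, 1:4)    # amounts 1.0 > 0.8 > 0.6 > 0.4 in order

  # 180-degree rotated acquisition: labels still follow intensity ranking
  rot <- img
  rot$values <- img$values[nrow(img$values):1, ncol(img$values):1]
  frot <- detect_fiducials(rot, g)
  # droplet 1 (largest amount) now sits in the bottom-right window
  expect_equal(frot$window[frot$label == 1], 4L)
  expect_equal(frot$window[frot$label == 4], 1L)

  blank <- scan_image(matrix(0, 48, 60), 0.05, "scanner")
  expect_error(detect_fiducials(blank, g), "no positive peak")
})

test_that("warp: identity, integer translation, inverse round trip", {
  img <- scan_image_from_fn(60, 48, 0.05,
                            function(y, x) exp(-((x - 1.5)^2 + (y - 1.2)^2) / 0.2))
  Hid <- structure(diag(3), class = c("homography", "matrix"))
  out <- warp(img, Hid, dim(img$values), 0.05)
  expect_lt(max(abs(out$values - img$values)), 1e-6)
  expect_identical(out$frame, "optical")

  Ht <- structure(matrix(c(1, 0, 0.25, 0, 1, -0.15, 0, 0, 1), 3, 3, byrow = TRUE),
                  class = c("homography", "matrix"))
  sh <- warp(img, Ht, dim(img$values), 0.05)
  # +0.25 cm in x is exactly +5 pixels; interior pixels exact
  expect_equal(sh$values[10:40, 20:50], img$values[13:43, 15:45], tolerance = 1e-9)

  Hp <- structure(matrix(c(1.02, 0.03, 0.1, -0.02, 0.98, 0.05, 0.004, -0.003, 1),
                         3, 3, byrow = TRUE), class = c("homography", "matrix"))
  fwd <- warp(img, Hp, dim(img$values), 0.05)
  back <- warp(fwd, structure(solve(Hp), class = class(Hp)), dim(img$values), 0.05)
  interior <- img$values[10:38, 12:48]
  expect_lt(max(abs(back$values[10:38, 12:48] - interior)), 0.01 * max(interior))
})

test_that("warp preserves integrated signal for moderate area changes", {
  img <- scan_image_from_fn(80, 80, 0.02,
                            function(y, x) exp(-((x - 0.8)^2 + (y - 0.8)^2) / 0.02))
  for (s in c(0.75, 1.3)) { # |det| = s^2 in [0.5, 2]
    H <- structure(matrix(c(s, 0.05, 0.1, -0.03, s, 0.1, 0.01, 0.005, 1),
                          3, 3, byrow = TRUE), class = c("homography", "matrix"))
    out <- warp(img, H, c(160, 160), 0.02)
    expect_equal(sum(out$values), sum(img$values),
                 tolerance = 0.02 * sum(img$values))
  }
})

test_that("overlay: pass-through, pure colour at alpha 1, area equals mask", {
  p <- make_slice(infarct_fraction = 0.4, pitch = 0.02, seed = 3)
  optical <- render_optical(p, "ttc")
  zero <- scan_image(matrix(0, nrow(optical), ncol(optical)), 0.02, "optical")
  expect_identical(merge_overlay(optical, zero, threshold = 0.5), optical)

  sig <- scan_image(matrix(as.numeric(p$infarct_mask), nrow(optical)), 0.02, "optical")
  pure <- merge_overlay(optical, sig, color = c(0, 80, 255), alpha = 1)
  i <- which(p$infarct_mask, arr.ind = TRUE)[1, ]
  expect_equal(pure[i[1], i[2], ], c(0, 80, 255))

  merged <- merge_overlay(optical, sig, alpha = 0.9)
  mask <- threshold_signal(rgb_to_ycbcr(merged), default_signal_thresholds(),
                           open = FALSE)
  expect_equal(sum(mask), sum(sig$values > 0.5 * max(sig$values)))

  expect_error(merge_overlay(optical[1:10, 1:10, , drop = FALSE], sig), "shapes differ")
})

test_that("homography JSON round trip", {
  H <- fit_homography(grid_layout()$fiducials,
                      grid_layout()$fiducials + matrix(rnorm(8, sd = 0.05), 4, 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_homography_json(H, f)
  expect_equal(unclass(read_homography_json(f)), unclass(H), tolerance = 1e-12)
})
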