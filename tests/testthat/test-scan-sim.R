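# Slide grid geometry and raster-scan image formation.

test_that("grid layout reproduces the instrument cell and fiducial geometry", {
  g <- grid_layout(3.0, 2.4)
  expect_equal(g$cell_width, 0.6)
  expect_equal(g$cell_height, 0.48)
  expect_equal(unname(g$fiducials),
               rbind(c(0.6, 0.24), c(2.4, 0.24), c(0.6, 2.16), c(2.4, 2.16)))
  # fiducial set is symmetric under 180-degree rotation of the grid
  rot <- cbind(3.0 - g$fiducials[, 1], 2.4 - g$fiducials[, 2])
  expect_equal(unname(rot[order(rot[, 1], rot[, 2]), ]),
               unname(g$fiducials[order(g$fiducials[, 1], g$fiducials[, 2]), ]))
  expect_equal(grid_layout(1, 1)$cell_width, 0.2)
  expect_equal(grid_layout(1, 1)$cell_height, 0.2)
})

test_that("scan trajectory: 10 lines, 0.3 cm right-to-left steps spanning the grid", {
  g <- grid_layout()
  tr <- scan_trajectory(g)
  expect_length(tr, 10)
  expect_equal(unique(round(diff(tr), 12)), -0.3)
  expect_equal(tr[1] - tr[length(tr)], 2.7)
  expect_true(all(tr > 0 & tr < 3))
  # centred: equal margins either side
  expect_equal(3 - tr[1], tr[length(tr)])
})

test_that("PSF kernel is normalised, compact and mass conserving", {
  k <- psf_kernel(0.15, 0.05)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k, t(k)) # isotropic
  expect_identical(psf_kernel(0, 0.05), matrix(1, 1, 1))
  # point source away from borders: blurred mass conserved
  conc <- scan_image(matrix(0, 48, 60), 0.05, "scanner")
  conc$values[24, 30] <- 2.5
  img <- acquire(conc, grid_layout(), psf = k, cal = 1)
  expect_equal(sum(img$values), 2.5, tolerance = 1e-6 * 2.5)
})

test_that("acquisition: impulse response, shift invariance, monotonicity", {
  g <- grid_layout()
  k <- psf_kernel(0.15, 0.05)
  zero <- acquire(scan_image(matrix(0, 48, 60), 0.05, "scanner"), g, k)
  expect_true(all(zero$values == 0))
  expect_identical(zero$frame, "scanner")

  conc <- scan_image(matrix(0, 48, 60), 0.05, "scanner")
  conc$values[20, 30] <- 1
  img <- acquire(conc, g, k, cal = 3)
  r <- (nrow(k) - 1) / 2
  patch <- img$values[(20 - r):(20 + r), (30 - r):(30 + r)]
  expect_equal(patch, 3 * k, tolerance = 1e-9)

  conc2 <- scan_image(matrix(0, 48, 60), 0.05, "scanner")
  conc2$values[15, 12] <- 1
  conc2$values[30, 45] <- 1
  img2 <- acquire(conc2, g, k)
  s1 <- sum(img2$values[(15 - r):(15 + r), (12 - r):(12 + r)])
  s2 <- sum(img2$values[(30 - r):(30 + r), (45 - r):(45 + r)])
  expect_equal(s1, s2, tolerance = 1e-6)

  # raising one concentration never lowers any pixel
  bumped <- conc2
  bumped$values[20, 20] <- 0.7
  img3 <- acquire(bumped, g, k)
  expect_true(all(img3$values - img2$values >= -1e-15))

  expect_error(acquire(scan_image(matrix(-1, 4, 4), 0.05, "scanner"), g), "non-negative")
})

test_that("seeded noise is reproducible and off by default", {
  g <- grid_layout()
  conc <- scan_image(matrix(1, 48, 60), 0.05, "scanner")
  a <- acquire(conc, g, noise_sd = 0.01, seed = 42)
  b <- acquire(conc, g, noise_sd = 0.01, seed = 42)
  c <- acquire(conc, g, noise_sd = 0.01, seed = 43)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("fiducial droplets deposit the exact requested amounts at the fiducials", {
  g <- grid_layout()
  conc <- empty_conc_map(g, 0.05)
  with_d <- add_fiducial_droplets(conc, g, droplet_amount = c(1, 0.8, 0.6, 0.4))
  expect_equal(sum(with_d$values), 2.8, tolerance = 1e-12)
  unchanged <- add_fiducial_droplets(conc, g, droplet_amount = 0)
  expect_identical(unchanged$values, conc$values)

  # acquired signal peaks at the fiducial coordinates
  img <- acquire(with_d, g)
  for (i in 1:4) {
    win <- which(img$values == max(img$values * as.numeric(
      outer(abs((seq_len(48) - 0.5) * 0.05 - g$fiducials[i, 2]) < 0.2,
            abs((seq_len(60) - 0.5) * 0.05 - g$fiducials[i, 1]) < 0.2, `&`))),
      arr.ind = TRUE)
    # peak pixel within half a pitch of the fiducial
    expect_lt(abs((win[1, 2] - 0.5) * 0.05 - g$fiducials[i, 1]), 0.051)
  }

  tiny <- scan_image(matrix(0, 6, 6), 0.05, "scanner")
  expect_error(add_fiducial_droplets(tiny, g), "border")
})

test_that("scan image TIFF and CSV round trips preserve geometry and values", {
  img <- scan_image_from_fn(30, 24, 0.1, function(y, x) exp(-((x - 1)^2 + (y - 1)^2)))
  f <- withr::local_tempfile(fileext = ".tiff")
  write_scan_tiff(img, f)
  back <- read_scan_tiff(f)
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$pitch, img$pitch)
  expect_identical(back$frame, img$frame)

  fc <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(img, fc)
  df <- read.csv(fc)
  expect_equal(nrow(df), 30 * 24)
  expect_equal(max(df$x_cm), 2.95)
  expect_equal(sum(df$amplitude), sum(img$values), tolerance = 1e-9)
})
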