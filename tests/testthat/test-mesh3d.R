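# Volume stacking, surface extraction, caps, normals, overlap, export.

test_that("volume stacking: depth arithmetic and bookkeeping", {
  masks <- lapply(1:5, function(i) matrix(i %% 2, 6, 7))
  v <- build_volume(masks, 0.06, 0.02)
  expect_equal(dim(v$values), c(5, 6, 7))
  expect_equal(v$dz, 0.06)

  vi <- build_volume(masks, 0.06, 0.02, interp = "linear", k = 2)
  expect_equal(dim(vi$values)[1], 3 * 5 - 2)
  expect_equal(vi$dz, 0.02)

  # voxel sum x voxel volume equals slice areas x dz (no interp)
  expect_equal(sum(v$values) * v$dz * v$dy * v$dx,
               sum(vapply(masks, sum, numeric(1))) * 0.02^2 * 0.06,
               tolerance = 1e-12)
  expect_error(build_volume(list(matrix(0, 2, 2), matrix(0, 3, 3)), 1, 1),
               "geometries differ")
})

test_that("marching tetrahedra: sphere volume, watertightness, equivariance", {
  v <- sphere_volume_stack(10)
  m <- isosurface(v)
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 4 / 3 * pi * 1000, tolerance = 0.03 * 4188.79)
  expect_true(all(m$faces >= 1 & m$faces <= nrow(m$vertices)))

  # whole-voxel translation moves every vertex identically
  masks <- lapply(1:14, function(i) {
    mm <- matrix(0, 16, 18); if (i >= 4 && i <= 11) mm[5:12, 6:14] <- 1; mm })
  shifted <- c(masks[-1], masks[1]) # object one plane earlier
  m1 <- isosurface(build_volume(masks, 1, 1))
  m2 <- isosurface(build_volume(shifted, 1, 1))
  expect_equal(sort(m2$vertices[, 3]), sort(m1$vertices[, 3]) - 1, tolerance = 1e-12)

  # interior box volume close to the voxel count
  vb <- build_volume(masks, 1, 1)
  mb <- isosurface(vb)
  expect_true(is_watertight(mb))
  expect_equal(mesh_volume(mb), sum(vb$values), tolerance = 0.05 * sum(vb$values))
})

test_that("empty and full volumes yield empty meshes with diagnostics", {
  empty <- build_volume(list(matrix(0, 4, 4), matrix(0, 4, 4)), 1, 1)
  me <- isosurface(empty)
  expect_equal(nrow(me$faces), 0)
  expect_match(attr(me, "diagnostic"), "below level")
  full <- build_volume(list(matrix(1, 4, 4), matrix(1, 4, 4)), 1, 1)
  expect_match(attr(isosurface(full), "diagnostic"), "above level")
})

test_that("isocaps close boundary-clipped objects watertightly", {
  # box touching the z = 0 face
  masks <- lapply(1:10, function(i) {
    m <- matrix(0, 12, 14); if (i <= 6) m[3:9, 4:11] <- 1; m })
  v <- build_volume(masks, 1, 1)
  s <- isosurface(v)
  cp <- isocaps(v)
  expect_false(is_watertight(s)) # open at the boundary
  u <- merge_meshes(s, cp)
  expect_true(is_watertight(u))

  # cap area equals the supra-level cross-section on that face
  z0 <- cp$faces[rowSums(matrix(cp$vertices[t(cp$faces), 3], ncol = 3, byrow = TRUE) == 0.5) == 3, , drop = FALSE]
  tri_area <- function(F) {
    a <- cp$vertices[F[, 1], , drop = FALSE]
    b <- cp$vertices[F[, 2], , drop = FALSE]
    c <- cp$vertices[F[, 3], , drop = FALSE]
    u <- b - a; w <- c - a
    0.5 * sqrt(rowSums(cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                             u[, 3] * w[, 1] - u[, 1] * w[, 3],
                             u[, 1] * w[, 2] - u[, 2] * w[, 1])^2))
  }
  expect_equal(sum(tri_area(z0)), sum(v$values[1, , ]), tolerance = 0.02 * 56)

  # strictly interior object: no caps
  vi <- sphere_volume_stack(5, 15)
  expect_equal(nrow(isocaps(vi)$faces), 0)
})

test_that("gradient normals: radial on a sphere, unit length, sign flip", {
  v <- sphere_volume_stack(8)
  m <- isonormals(v, isosurface(v))
  expect_equal(sqrt(rowSums(m$normals^2)), rep(1, nrow(m$normals)),
               tolerance = 1e-6)
  ctr <- (dim(v$values)[1] + 1) / 2 - 0.5 # cm of grid centre (unit pitch)
  radial <- m$vertices - matrix(ctr, nrow(m$vertices), 3)
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, pmax(-1, rowSums(radial * m$normals)))) * 180 / pi
  expect_lt(mean(ang), 5)

  vneg <- v
  vneg$values <- 1 - v$values
  mneg <- isonormals(vneg, m)
  expect_equal(mneg$normals, -m$normals, tolerance = 1e-9)
})

test_that("Dice coincidence: identity, disjoint, nested half volume", {
  cube <- function(zr, yr, xr) build_volume(lapply(1:8, function(i) {
    m <- matrix(0, 8, 8); if (i %in% zr) m[yr, xr] <- 1; m }), 1, 1)
  a <- cube(1:8, 1:8, 1:8)
  b <- cube(1:4, 1:8, 1:8)
  d0 <- cube(1:2, 1:2, 1:2); d1 <- cube(5:6, 5:6, 5:6)
  expect_equal(as.numeric(coincidence_ratio(a, a)), 1)
  expect_equal(as.numeric(coincidence_ratio(d0, d1)), 0)
  dice <- coincidence_ratio(b, a)
  expect_equal(as.numeric(dice), 2 / 3)
  expect_equal(attr(dice, "iou"), 1 / 2)
  empty <- cube(integer(0), 1, 1)
  expect_warning(expect_true(is.na(coincidence_ratio(empty, empty))), "empty")
})

test_that("mesh export: PLY round trip, OBJ indexing, STL structure", {
  v <- sphere_volume_stack(4, 12)
  m <- isonormals(v, isosurface(v))
  dir <- withr::local_tempdir()

  ply <- file.path(dir, "s.ply")
  export_mesh(m, ply)
  back <- read_mesh_ply(ply)
  expect_identical(back$faces, m$faces)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(back$normals, m$normals, tolerance = 1e-6)
  hdr <- readLines(ply, n = 8)
  expect_true(sprintf("element vertex %d", nrow(m$vertices)) %in% hdr)

  obj <- file.path(dir, "s.obj")
  export_mesh(m, obj)
  lines <- readLines(obj)
  f1 <- strsplit(grep("^f ", lines, value = TRUE)[1], " ")[[1]]
  expect_equal(as.integer(f1[-1]), m$faces[1, ]) # 1-based indices
  expect_true(min(as.integer(unlist(lapply(strsplit(grep("^f ", lines, value = TRUE), " "), `[`, -1)))) == 1)

  stl <- file.path(dir, "s.stl")
  export_mesh(m, stl)
  sl <- readLines(stl)
  expect_equal(sum(grepl("^facet normal", sl)), nrow(m$faces))
  expect_error(export_mesh(m, file.path(dir, "s.xyz")), "unsupported")
})
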