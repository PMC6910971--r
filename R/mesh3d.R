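#' Voxel volume from a stack of 2D masks
#'
#' Stacks per-slice masks into a (z, y, x) scalar field of 0/1 floats.
#' With `interp = "linear"`, `k` linearly interpolated planes are
#' inserted between each pair of consecutive slices (depth becomes
#' `n + (n-1) k`) and the z-spacing shrinks accordingly, giving
#' near-isotropic voxels for meshing.
#'
#' @param masks List of logical/numeric matrices with identical
#'   dimensions.
#' @param z_spacing Physical slice spacing, cm.
#' @param pitch In-plane pixel pitch, cm.
#' @param interp `"none"` or `"linear"`.
#' @param k Number of interpolated planes per gap (default 2).
#' @param provenance Optional source slice indices.
#' @return Object of class `volume_stack`: `values` array (z, y, x) in
#'   \[0, 1\], voxel size `dz`, `dy`, `dx` (cm), `provenance`.
#' @export
build_volume <- function(masks, z_spacing, pitch, interp = c("none", "linear"),
                         k = 2L, provenance = NULL) {
  interp <- match.arg(interp)
  n <- length(masks)
  stopifnot(n >= 1)
  d <- dim(masks[[1]])
  for (m in masks) if (!all(dim(m) == d)) stopf("mask geometries differ")
  planes <- lapply(masks, function(m) matrix(as.numeric(m), d[1], d[2]))
  dz <- z_spacing
  if (interp == "linear" && n > 1 && k > 0) {
    out <- list(planes[[1]])
    for (i in seq_len(n - 1)) {
      for (j in seq_len(k)) {
        t <- j / (k + 1)
        out[[length(out) + 1]] <- (1 - t) * planes[[i]] + t * planes[[i + 1]]
      }
      out[[length(out) + 1]] <- planes[[i + 1]]
    }
    planes <- out
    dz <- z_spacing / (k + 1)
  }
  nz <- length(planes)
  v <- array(0, c(nz, d[1], d[2]))
  for (i in seq_len(nz)) v[i, , ] <- planes[[i]]
  structure(list(values = v, dz = dz, dy = pitch, dx = pitch,
                 provenance = provenance),
            class = "volume_stack")
}

#' Triangular surface mesh container
#'
#' @param vertices n x 3 matrix of (x, y, z) in cm (volume frame).
#' @param faces m x 3 integer matrix of vertex indices, counterclockwise
#'   seen from outside.
#' @param normals Optional n x 3 unit per-vertex normals.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stopf("face indices out of range")
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

# voxel-centre coordinate of grid index i along an axis with pitch d
.vox_coord <- function(i, d) (i - 0.5) * d

# The six tetrahedra of the Kuhn subdivision of the unit cube, as corner
# offsets (ox, oy, oz). This subdivision tiles space compatibly: shared
# cube faces are split along the same diagonal in neighbouring cubes, so
# the extracted surface is crack-free.
.kuhn_tets <- list(
  rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)),
  rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(1,1,1)),
  rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,1,1)),
  rbind(c(0,0,0), c(0,1,0), c(0,1,1), c(1,1,1)),
  rbind(c(0,0,0), c(0,0,1), c(1,0,1), c(1,1,1)),
  rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(1,1,1)))

#' Extract an isosurface by marching tetrahedra
#'
#' Each grid cell (cube spanned by 8 neighbouring voxel centres) is
#' decomposed into 6 tetrahedra (Kuhn subdivision); within each
#' tetrahedron the level crossing is triangulated with vertices placed
#' on cell edges by linear interpolation. Faces are oriented outward
#' (from values above `level` towards values below). The surface is
#' closed wherever the object does not touch the volume boundary;
#' boundary intersections are closed by [isocaps()].
#'
#' @param v A [build_volume()] `volume_stack`.
#' @param level Iso-level (default 0.5, the midpoint of binary masks).
#' @return A [surface_mesh()]. For an empty or full volume an empty mesh
#'   is returned with a `diagnostic` attribute explaining why.
#' @export
isosurface <- function(v, level = 0.5) {
  stopifnot(inherits(v, "volume_stack"))
  a <- v$values
  if (all(a <= level) || all(a > level)) {
    m <- surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
    attr(m, "diagnostic") <- if (all(a <= level))
      "volume entirely below level: empty mesh" else
        "volume entirely above level: empty mesh"
    return(m)
  }
  tris <- .march_tets(a, level, v$dx, v$dy, v$dz)
  weld_mesh(tris)
}

# Core marching-tetrahedra triangle soup generator. Returns a 3N x 3
# matrix of triangle vertices (consecutive triples), outward-oriented.
.march_tets <- function(a, level, dx, dy, dz) {
  dm <- dim(a)
  nz <- dm[1]; ny <- dm[2]; nx <- dm[3]
  if (nz < 2 || ny < 2 || nx < 2) return(matrix(0, 0, 3))
  ab <- a > level
  # active cells: mixed above/below among the 8 corners
  idx <- function(z, y, x) ab[z, y, x, drop = FALSE]
  zs <- 1:(nz - 1); ys <- 1:(ny - 1); xs <- 1:(nx - 1)
  S <- idx(zs, ys, xs) + idx(zs + 1, ys, xs) + idx(zs, ys + 1, xs) +
    idx(zs, ys, xs + 1) + idx(zs + 1, ys + 1, xs) + idx(zs + 1, ys, xs + 1) +
    idx(zs, ys + 1, xs + 1) + idx(zs + 1, ys + 1, xs + 1)
  act <- which(S > 0 & S < 8)
  if (length(act) == 0) return(matrix(0, 0, 3))
  cz <- (act - 1) %% (nz - 1) + 1
  cy <- ((act - 1) %/% (nz - 1)) %% (ny - 1) + 1
  cx <- (act - 1) %/% ((nz - 1) * (ny - 1)) + 1
  base <- cz + (cy - 1) * nz + (cx - 1) * nz * ny
  soup <- vector("list", 64)
  si <- 0L
  for (tet in .kuhn_tets) {
    off <- tet[, 3] + tet[, 2] * nz + tet[, 1] * nz * ny # (ox,oy,oz) -> lin
    V <- cbind(a[base + off[1]], a[base + off[2]], a[base + off[3]], a[base + off[4]])
    B <- V > level
    case <- B[, 1] + 2L * B[, 2] + 4L * B[, 3] + 8L * B[, 4]
    # physical corner positions, per tet corner: list of n x 3
    P <- lapply(1:4, function(j) cbind(
      .vox_coord(cx + tet[j, 1], dx),
      .vox_coord(cy + tet[j, 2], dy),
      .vox_coord(cz + tet[j, 3], dz)))
    interp <- function(i, j, sel) {
      t <- (level - V[sel, i]) / (V[sel, j] - V[sel, i])
      P[[i]][sel, , drop = FALSE] * (1 - t) + P[[j]][sel, , drop = FALSE] * t
    }
    singles <- list(c(1L, 14L), c(2L, 13L), c(4L, 11L), c(8L, 7L))
    for (sp in seq_along(singles)) {
      i <- sp # the lone vertex
      oth <- setdiff(1:4, i)
      for (inv in c(FALSE, TRUE)) {
        cs <- if (!inv) singles[[sp]][1] else singles[[sp]][2]
        sel <- which(case == cs)
        if (length(sel) == 0) next
        q1 <- interp(i, oth[1], sel)
        q2 <- interp(i, oth[2], sel)
        q3 <- interp(i, oth[3], sel)
        # reference point on the "above" side
        ref <- if (!inv) P[[i]][sel, , drop = FALSE] else
          (P[[oth[1]]][sel, , drop = FALSE] + P[[oth[2]]][sel, , drop = FALSE] +
             P[[oth[3]]][sel, , drop = FALSE]) / 3
        si <- si + 1L
        soup[[si]] <- .orient_tris(q1, q2, q3, ref)
      }
    }
    pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
    for (pr in pairs) {
      cs <- sum(2L^(pr - 1L))
      sel <- which(case == cs)
      if (length(sel) == 0) next
      bo <- setdiff(1:4, pr)
      e11 <- interp(pr[1], bo[1], sel)
      e12 <- interp(pr[1], bo[2], sel)
      e21 <- interp(pr[2], bo[1], sel)
      e22 <- interp(pr[2], bo[2], sel)
      ref <- (P[[pr[1]]][sel, , drop = FALSE] + P[[pr[2]]][sel, , drop = FALSE]) / 2
      si <- si + 1L
      soup[[si]] <- .orient_tris(e11, e12, e22, ref)
      si <- si + 1L
      soup[[si]] <- .orient_tris(e11, e22, e21, ref)
    }
  }
  do.call(rbind, soup[seq_len(si)])
}

# Orient triangles (rows of q1,q2,q3) so normals point away from the
# above-level reference points; returns stacked rows q1,q2,q3 per triangle.
.orient_tris <- function(q1, q2, q3, ref) {
  u <- q2 - q1; w <- q3 - q1
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  cen <- (q1 + q2 + q3) / 3
  d <- cen - ref
  flip <- nx * d[, 1] + ny * d[, 2] + nz * d[, 3] < 0
  if (any(flip)) {
    tmp <- q2[flip, , drop = FALSE]
    q2[flip, ] <- q3[flip, , drop = FALSE]
    q3[flip, ] <- tmp
  }
  n <- nrow(q1)
  out <- matrix(0, 3 * n, 3)
  out[seq(1, 3 * n, by = 3), ] <- q1
  out[seq(2, 3 * n, by = 3), ] <- q2
  out[seq(3, 3 * n, by = 3), ] <- q3
  out
}

# Weld a triangle soup (3N x 3 vertex rows) into an indexed mesh,
# merging vertices that agree to 1e-7 cm. Degenerate (zero-area)
# triangles are dropped.
weld_mesh <- function(soup) {
  if (is.null(soup) || nrow(soup) == 0)
    return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  key <- paste(round(soup[, 1], 7), round(soup[, 2], 7), round(soup[, 3], 7))
  uk <- !duplicated(key)
  verts <- soup[uk, , drop = FALSE]
  map <- match(key, key[uk])
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
  surface_mesh(verts, faces[!deg, , drop = FALSE])
}

#' Planar boundary caps closing an isosurface at the volume faces
#'
#' Triangulates the above-level regions on the six boundary planes of
#' the volume, using the same cell diagonals and edge interpolation as
#' [isosurface()], so that the union of the two meshes is watertight
#' (every edge shared by exactly two faces) wherever the object meets
#' the boundary. Caps are oriented outward (out of the volume domain).
#'
#' @param v A `volume_stack`.
#' @param level Iso-level (default 0.5).
#' @return A [surface_mesh()]; empty if the object is strictly interior.
#' @export
isocaps <- function(v, level = 0.5) {
  stopifnot(inherits(v, "volume_stack"))
  a <- v$values
  dm <- dim(a)
  nz <- dm[1]; ny <- dm[2]; nx <- dm[3]
  soup <- list()
  # plane spec: values matrix W[i1, i2] over axes (a1, a2), a function
  # pos(i1, i2) -> n x 3 cm coords, and outward normal sign
  planes <- list(
    list(W = t(a[1, , ]), pos = function(i, j) cbind(.vox_coord(i, v$dx), .vox_coord(j, v$dy), .vox_coord(1, v$dz)), nrm = c(0, 0, -1)),
    list(W = t(a[nz, , ]), pos = function(i, j) cbind(.vox_coord(i, v$dx), .vox_coord(j, v$dy), .vox_coord(nz, v$dz)), nrm = c(0, 0, 1)),
    list(W = a[, 1, ], pos = function(i, j) cbind(.vox_coord(j, v$dx), .vox_coord(1, v$dy), .vox_coord(i, v$dz)), nrm = c(0, -1, 0)),
    list(W = a[, ny, ], pos = function(i, j) cbind(.vox_coord(j, v$dx), .vox_coord(ny, v$dy), .vox_coord(i, v$dz)), nrm = c(0, 1, 0)),
    list(W = t(a[, , 1]), pos = function(i, j) cbind(.vox_coord(1, v$dx), .vox_coord(i, v$dy), .vox_coord(j, v$dz)), nrm = c(-1, 0, 0)),
    list(W = t(a[, , nx]), pos = function(i, j) cbind(.vox_coord(nx, v$dx), .vox_coord(i, v$dy), .vox_coord(j, v$dz)), nrm = c(1, 0, 0)))
  # NOTE on local axes: for x/y/z planes the in-plane axes are taken in
  # the global order ((y,z), (x,z), (x,y)); the Kuhn subdivision splits
  # every boundary cell along the local (0,0)-(1,1) diagonal.
  for (pl in planes) {
    W <- pl$W
    n1 <- nrow(W); n2 <- ncol(W)
    if (max(W) <= level) next
    cells <- which(matrix(TRUE, n1 - 1, n2 - 1))
    i <- (cells - 1) %% (n1 - 1) + 1
    j <- (cells - 1) %/% (n1 - 1) + 1
    # two triangles per cell, local corners (0,0),(1,0),(1,1) and
    # (0,0),(1,1),(0,1) on axes (a1, a2)
    for (tri in list(rbind(c(0, 0), c(1, 0), c(1, 1)),
                     rbind(c(0, 0), c(1, 1), c(0, 1)))) {
      w1 <- W[cbind(i + tri[1, 1], j + tri[1, 2])]
      w2 <- W[cbind(i + tri[2, 1], j + tri[2, 2])]
      w3 <- W[cbind(i + tri[3, 1], j + tri[3, 2])]
      p1 <- pl$pos(i + tri[1, 1], j + tri[1, 2])
      p2 <- pl$pos(i + tri[2, 1], j + tri[2, 2])
      p3 <- pl$pos(i + tri[3, 1], j + tri[3, 2])
      soup[[length(soup) + 1]] <-
        .clip_plane_tris(p1, p2, p3, w1, w2, w3, level, pl$nrm)
    }
  }
  weld_mesh(do.call(rbind, soup))
}

# Clip boundary-plane triangles to the above-level region; orient each
# emitted triangle so its normal matches the outward plane normal.
.clip_plane_tris <- function(p1, p2, p3, w1, w2, w3, level, nrm) {
  b1 <- w1 > level; b2 <- w2 > level; b3 <- w3 > level
  nab <- b1 + b2 + b3
  out <- list()
  ip <- function(pa, pb, wa, wb, sel) {
    t <- (level - wa[sel]) / (wb[sel] - wa[sel])
    pa[sel, , drop = FALSE] * (1 - t) + pb[sel, , drop = FALSE] * t
  }
  emit <- function(q1, q2, q3) {
    u <- q2 - q1; w <- q3 - q1
    cnx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cnz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    flip <- cnx * nrm[1] + cny * nrm[2] + cnz * nrm[3] < 0
    if (any(flip)) {
      tmp <- q2[flip, , drop = FALSE]
      q2[flip, ] <- q3[flip, , drop = FALSE]
      q3[flip, ] <- tmp
    }
    n <- nrow(q1)
    m <- matrix(0, 3 * n, 3)
    m[seq(1, 3 * n, 3), ] <- q1
    m[seq(2, 3 * n, 3), ] <- q2
    m[seq(3, 3 * n, 3), ] <- q3
    out[[length(out) + 1]] <<- m
  }
  sel <- which(nab == 3)
  if (length(sel)) emit(p1[sel, , drop = FALSE], p2[sel, , drop = FALSE], p3[sel, , drop = FALSE])
  # one vertex above
  P <- list(p1, p2, p3); Wv <- list(w1, w2, w3); Bv <- list(b1, b2, b3)
  for (k in 1:3) {
    o <- setdiff(1:3, k)
    sel <- which(nab == 1 & Bv[[k]])
    if (length(sel)) {
      emit(P[[k]][sel, , drop = FALSE],
           ip(P[[k]], P[[o[1]]], Wv[[k]], Wv[[o[1]]], sel),
           ip(P[[k]], P[[o[2]]], Wv[[k]], Wv[[o[2]]], sel))
    }
    # k is the lone below vertex
    sel <- which(nab == 2 & !Bv[[k]])
    if (length(sel)) {
      A <- P[[o[1]]][sel, , drop = FALSE]
      Bq <- P[[o[2]]][sel, , drop = FALSE]
      iBk <- ip(P[[o[2]]], P[[k]], Wv[[o[2]]], Wv[[k]], sel)
      iAk <- ip(P[[o[1]]], P[[k]], Wv[[o[1]]], Wv[[k]], sel)
      emit(A, Bq, iBk)
      emit(A, iBk, iAk)
    }
  }
  if (length(out) == 0) return(matrix(0, 0, 3))
  do.call(rbind, out)
}

#' Concatenate two meshes and weld shared vertices
#' @param a,b `surface_mesh` objects.
#' @return A welded [surface_mesh()].
#' @export
merge_meshes <- function(a, b) {
  soup_of <- function(m) {
    if (nrow(m$faces) == 0) return(matrix(0, 0, 3))
    idx <- as.vector(t(m$faces))
    m$vertices[idx, , drop = FALSE]
  }
  weld_mesh(rbind(soup_of(a), soup_of(b)))
}

#' Gradient-based per-vertex normals
#'
#' The scalar field is presmoothed with a Gaussian (sigma = 1 voxel,
#' separable), its gradient taken by central differences, trilinearly
#' interpolated at each mesh vertex, negated (outward points from high
#' to low values) and normalised. Vertices with a vanishing field
#' gradient fall back to the average of adjacent face normals.
#'
#' @param v The `volume_stack` the mesh was extracted from.
#' @param mesh A [surface_mesh()] with vertices inside the volume domain.
#' @param sigma Smoothing sigma in voxels (default 1).
#' @return The mesh with unit `normals` filled in.
#' @export
isonormals <- function(v, mesh, sigma = 1) {
  stopifnot(inherits(v, "volume_stack"), inherits(mesh, "surface_mesh"))
  if (nrow(mesh$vertices) == 0) return(mesh)
  sm <- gauss_smooth3d(v$values, sigma)
  g <- grad3d(sm) # list gz, gy, gx in index units
  dm <- dim(v$values)
  # vertex cm -> fractional grid indices
  iz <- clamp(mesh$vertices[, 3] / v$dz + 0.5, 1, dm[1])
  iy <- clamp(mesh$vertices[, 2] / v$dy + 0.5, 1, dm[2])
  ix <- clamp(mesh$vertices[, 1] / v$dx + 0.5, 1, dm[3])
  gx <- trilinear(g$gx, iz, iy, ix) / v$dx
  gy <- trilinear(g$gy, iz, iy, ix) / v$dy
  gz <- trilinear(g$gz, iz, iy, ix) / v$dz
  n <- cbind(-gx, -gy, -gz)
  len <- sqrt(rowSums(n^2))
  bad <- len < 1e-12
  if (any(bad)) {
    fn <- vertex_face_normals(mesh)
    n[bad, ] <- fn[bad, , drop = FALSE]
    len[bad] <- sqrt(rowSums(n[bad, , drop = FALSE]^2))
    len[len < 1e-300] <- 1
  }
  mesh$normals <- n / len
  mesh
}

# separable Gaussian smoothing of a 3D array (sigma in voxels)
gauss_smooth3d <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    dm <- dim(a)
    out <- array(0, dm)
    for (s in (-r):r) {
      idx <- clamp(seq_len(dm[axis]) + s, 1, dm[axis]) # replicate border
      w <- k[s + r + 1]
      out <- out + w * switch(axis,
                              a[idx, , , drop = FALSE],
                              a[, idx, , drop = FALSE],
                              a[, , idx, drop = FALSE])
    }
    out
  }
  conv_axis(conv_axis(conv_axis(a, 1), 2), 3)
}

# central-difference gradient (index units), one-sided at the borders
grad3d <- function(a) {
  dm <- dim(a)
  diff_axis <- function(axis) {
    n <- dm[axis]
    hi <- clamp(seq_len(n) + 1, 1, n)
    lo <- clamp(seq_len(n) - 1, 1, n)
    den <- (hi - lo)
    sl <- function(idx) switch(axis, a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
    d <- sl(hi) - sl(lo)
    scale <- array(0, dm)
    per <- 1 / den
    if (axis == 1) scale[] <- per else if (axis == 2)
      scale[] <- rep(per, each = dm[1]) else
        scale[] <- rep(per, each = dm[1] * dm[2])
    d * scale
  }
  list(gz = diff_axis(1), gy = diff_axis(2), gx = diff_axis(3))
}

# trilinear interpolation in array a at fractional indices (1-based)
trilinear <- function(a, iz, iy, ix) {
  dm <- dim(a)
  z0 <- clamp(floor(iz), 1, dm[1] - 1); y0 <- clamp(floor(iy), 1, dm[2] - 1)
  x0 <- clamp(floor(ix), 1, dm[3] - 1)
  tz <- iz - z0; ty <- iy - y0; tx <- ix - x0
  g <- function(dz, dy, dx) a[cbind(z0 + dz, y0 + dy, x0 + dx)]
  (1 - tz) * ((1 - ty) * ((1 - tx) * g(0, 0, 0) + tx * g(0, 0, 1)) +
                ty * ((1 - tx) * g(0, 1, 0) + tx * g(0, 1, 1))) +
    tz * ((1 - ty) * ((1 - tx) * g(1, 0, 0) + tx * g(1, 0, 1)) +
            ty * ((1 - tx) * g(1, 1, 0) + tx * g(1, 1, 1)))
}

# area-weighted average of adjacent face normals per vertex
vertex_face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  out <- matrix(0, nrow(V), 3)
  if (nrow(F) == 0) return(out)
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  for (c in 1:3) {
    for (ch in 1:3) {
      acc <- tapply(fn[, ch], F[, c], sum)
      out[as.integer(names(acc)), ch] <- out[as.integer(names(acc)), ch] + acc
    }
  }
  out
}

#' Mesh-enclosed volume by the divergence theorem
#'
#' Sum of signed tetrahedron volumes against the origin; exact for
#' closed, consistently outward-oriented meshes (e.g. the union of
#' [isosurface()] and [isocaps()]).
#'
#' @param mesh A [surface_mesh()].
#' @return Enclosed volume (cm^3, or voxel^3 for unit-pitch volumes).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(0)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
            a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
            a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6)
}

#' Edge-manifold (watertightness) audit
#'
#' @param mesh A [surface_mesh()].
#' @return TRUE iff every undirected edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Dice coincidence ratio between two modality volumes
#'
#' `2 |A intersect B| / (|A| + |B|)` on the binarized (value > 0.5)
#' volumes; the score the pipeline uses to compare, e.g., the
#' signal-derived infarct volume with a reference volume. If geometries
#' differ, `b` is resampled to `a`'s grid by nearest neighbour in
#' physical coordinates.
#'
#' @param a,b `volume_stack` objects.
#' @return Dice score in \[0, 1\], with the intersection-over-union
#'   stored in attribute `iou`; `NA` (with a warning) when both volumes
#'   are empty.
#' @export
coincidence_ratio <- function(a, b) {
  stopifnot(inherits(a, "volume_stack"), inherits(b, "volume_stack"))
  A <- a$values > 0.5
  if (!all(dim(a$values) == dim(b$values)) ||
      abs(a$dz - b$dz) + abs(a$dy - b$dy) + abs(a$dx - b$dx) > 1e-12) {
    dm <- dim(a$values)
    iz <- clamp(round(((seq_len(dm[1]) - 0.5) * a$dz) / b$dz + 0.5), 1, dim(b$values)[1])
    iy <- clamp(round(((seq_len(dm[2]) - 0.5) * a$dy) / b$dy + 0.5), 1, dim(b$values)[2])
    ix <- clamp(round(((seq_len(dm[3]) - 0.5) * a$dx) / b$dx + 0.5), 1, dim(b$values)[3])
    B <- (b$values > 0.5)[iz, iy, ix, drop = FALSE]
  } else B <- b$values > 0.5
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) {
    warning("both volumes empty: Dice undefined")
    return(NA_real_)
  }
  ninter <- sum(A & B)
  dice <- 2 * ninter / (na + nb)
  attr(dice, "iou") <- ninter / (na + nb - ninter)
  dice
}

#' Export a surface mesh to PLY, OBJ or STL
#'
#' ASCII formats; PLY round-trips vertices and faces through
#' [read_mesh_ply()] (coordinates written with enough digits to
#' reproduce to 1e-6). OBJ faces are 1-based; STL stores the triangle
#' soup with face normals.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param format `"ply"`, `"obj"` or `"stl"`; default from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = tools::file_ext(path)) {
  format <- tolower(format)
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  fmt_v <- function(x) sprintf("%.9g", x)
  if (format == "ply") {
    has_n <- !is.null(mesh$normals)
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 if (has_n) c("property float nx", "property float ny", "property float nz"),
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    M <- if (has_n) cbind(V, mesh$normals) else V
    writeLines(apply(M, 1, function(r) paste(fmt_v(r), collapse = " ")), con)
    if (nrow(F) > 0)
      writeLines(paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  } else if (format == "obj") {
    if (nrow(V) > 0)
      writeLines(paste("v", fmt_v(V[, 1]), fmt_v(V[, 2]), fmt_v(V[, 3])), con)
    if (nrow(F) > 0)
      writeLines(paste("f", F[, 1], F[, 2], F[, 3]), con)
  } else if (format == "stl") {
    writeLines("solid mesh", con)
    if (nrow(F) > 0) {
      u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
      w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
      n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
      n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
      for (i in seq_len(nrow(F))) {
        writeLines(c(sprintf("facet normal %s %s %s", fmt_v(n[i, 1]), fmt_v(n[i, 2]), fmt_v(n[i, 3])),
                     "  outer loop",
                     sprintf("    vertex %s %s %s", fmt_v(V[F[i, 1], 1]), fmt_v(V[F[i, 1], 2]), fmt_v(V[F[i, 1], 3])),
                     sprintf("    vertex %s %s %s", fmt_v(V[F[i, 2], 1]), fmt_v(V[F[i, 2], 2]), fmt_v(V[F[i, 2], 3])),
                     sprintf("    vertex %s %s %s", fmt_v(V[F[i, 3], 1]), fmt_v(V[F[i, 3], 2]), fmt_v(V[F[i, 3], 3])),
                     "  endloop", "endfacet"), con)
      }
    }
    writeLines("endsolid mesh", con)
  } else stopf("unsupported mesh format '%s'", format)
  invisible(path)
}

#' Read an ASCII PLY file written by [export_mesh()]
#' @param path PLY path.
#' @return A [surface_mesh()].
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  has_n <- any(grepl("property float nx", lines))
  vl <- lines[(endh + 1):(endh + nv)]
  vm <- matrix(as.numeric(unlist(strsplit(vl, " "))), nrow = nv, byrow = TRUE)
  verts <- vm[, 1:3, drop = FALSE]
  normals <- if (has_n) vm[, 4:6, drop = FALSE] else NULL
  faces <- matrix(0L, 0, 3)
  if (nf > 0) {
    fl <- lines[(endh + nv + 1):(endh + nv + nf)]
    fm <- matrix(as.integer(unlist(strsplit(fl, " "))), nrow = nf, byrow = TRUE)
    faces <- fm[, 2:4, drop = FALSE] + 1L
  }
  surface_mesh(verts, faces, normals)
}
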