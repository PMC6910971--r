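# Shared fixtures, generated in code at test time.

options(pfmmd.verbose = FALSE)

default_excitation <- function(...) excitation_config(...)

# particle with dimensionless drive xi = moment_scale (H1 = H2 = 1)
particle_xi <- function(xi, amount = 1, saturation = 1) {
  langevin_particle(moment_scale = xi, saturation = saturation, amount = amount)
}

# windowless DFT-bin amplitude oracle at an exact bin frequency
dft_bin_amplitude <- function(x, f, sample_rate) {
  n <- length(x)
  k <- f * n / sample_rate
  stopifnot(abs(k - round(k)) < 1e-9)
  2 * Mod(stats::fft(x)[round(k) + 1]) / n
}

# voxelized sphere volume (unit voxels), radius r, grid n^3
sphere_volume_stack <- function(r = 10, n = 2 * r + 5) {
  ctr <- (n + 1) / 2
  ax <- (1:n) - ctr
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  mask <- d2 <= r^2
  build_volume(lapply(1:n, function(i) mask[i, , ]), 1, 1)
}

# small fast pipeline configuration (coarse phantom, few slices)
tiny_run_config <- function(...) {
  default_run_config(
    phantom = list(pitch = 0.02, sampled_from = 225L, sampled_to = 270L,
                   sampled_by = 15L),
    mesh = list(downsample = 2L),
    ...)
}

scan_image_from_fn <- function(nx, ny, pitch, fn) {
  xc <- (seq_len(nx) - 0.5) * pitch
  yc <- (seq_len(ny) - 0.5) * pitch
  scan_image(outer(yc, xc, fn), pitch, "scanner")
}
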