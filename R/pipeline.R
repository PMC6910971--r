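#' Default run configuration for the end-to-end pipeline
#'
#' Returns the full nested configuration with every stage's parameters;
#' pass overrides as a nested list (or edit the returned list). The
#' configuration is fully serialisable: a run is reproducible from
#' config + seed alone.
#'
#' @param ... Nested overrides, e.g. `phantom = list(pitch = 0.005)`.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    grid = list(width = 3.0, height = 2.4, step_width = 0.3, n_shifts = 10L),
    excitation = list(f1 = 1000, f2 = 50, H1 = 1, H2 = 1,
                      sample_rate = 20000, n_periods = 1L,
                      moment_scale = 0.3, saturation = 1),
    phantom = list(n_sections = 629L, sampled_from = 135L, sampled_to = 345L,
                   sampled_by = 15L, section_thickness_um = 40,
                   pitch = 0.01, infarct_fraction = 0.5,
                   fraction_profile = "flat", edema_factor = 1.0,
                   roughness = 0.08, spion_density = 1, spion_coverage = 1,
                   spion_heterogeneity = 0, style = "ttc"),
    scan = list(pitch = 0.05, psf_fwhm = 0.15, noise_sd = 0,
                droplet_amount = c(1.0, 0.8, 0.6, 0.4), droplet_radius = 0.06,
                line_sampled = FALSE),
    distortion = list(rotation_deg = 2, tx_cm = 0.05, ty_cm = -0.04,
                      perspective_x = 0.01, perspective_y = 0.015),
    registration = list(search_radius = 0.25),
    segmentation = list(overlay_color = c(0, 80, 255), overlay_alpha = 0.9,
                        threshold_margin = 2, signal_threshold_rel = 0.5),
    mesh = list(downsample = 2L, interp = "none", interp_k = 2L,
                formats = "ply"))
  utils::modifyList(cfg, list(...))
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults from
#' [default_run_config()]; unknown fields are reported with their paths.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stopf("config must be YAML or JSON, got '%s'", ext)
  base <- default_run_config()
  bad <- character(0)
  for (top in names(user)) {
    if (!top %in% names(base)) { bad <- c(bad, top); next }
    if (is.list(base[[top]])) {
      for (kk in names(user[[top]]))
        if (!kk %in% names(base[[top]])) bad <- c(bad, paste(top, kk, sep = "."))
    }
  }
  if (length(bad) > 0)
    stopf("unknown config fields: %s", paste(bad, collapse = ", "))
  utils::modifyList(base, user)
}

# the simulated scanner->optical distortion as a homography
distortion_homography <- function(d, center = c(1.5, 1.2)) {
  th <- d$rotation_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  Tc <- diag(3); Tc[1:2, 3] <- center
  Tci <- diag(3); Tci[1:2, 3] <- -center
  Tt <- diag(3); Tt[1:2, 3] <- c(d$tx_cm, d$ty_cm)
  P <- diag(3); P[3, 1] <- d$perspective_x; P[3, 2] <- d$perspective_y
  H <- Tt %*% Tc %*% R %*% P %*% Tci
  structure(normalize_homography(H), class = c("homography", "matrix"))
}

run_log <- function(dir, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"), sprintf(fmt, ...))
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE, sep = "")
  if (isTRUE(getOption("pfmmd.verbose", TRUE))) message(line)
}

slice_tags <- function(dir) {
  f <- list.files(file.path(dir, "phantom"), pattern = "^conc_\\d+\\.tiff$")
  sub("^conc_(\\d+)\\.tiff$", "\\1", f)
}

read_truth_json <- function(dir) {
  jsonlite::read_json(file.path(dir, "phantom", "truth.json"),
                      simplifyVector = TRUE)
}

#' Pipeline stages on a run directory
#'
#' Each stage reads the previous stage's files inside `dir` and writes
#' its own outputs there, so a monolithic [run_pipeline()] call and a
#' sequence of standalone stage invocations produce identical results.
#' `stage_phantom` writes `phantom/`; `stage_scan` writes `scan/`;
#' `stage_register` writes `registered/` and `merged/`; `stage_segment`
#' writes `masks/`; `stage_quantify` writes the infarct reports;
#' `stage_mesh` writes `mesh/` (surfaces and the Dice overlap score).
#'
#' @param cfg A `run_config` list.
#' @param dir Run directory.
#' @return The written file paths, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_phantom <- function(cfg, dir) {
  ph <- cfg$phantom
  stack <- make_stack(
    n_sections = ph$n_sections,
    sampled = seq(ph$sampled_from, ph$sampled_to, by = ph$sampled_by),
    section_thickness_um = ph$section_thickness_um,
    infarct_fraction = ph$infarct_fraction,
    fraction_profile = ph$fraction_profile,
    edema_factor = ph$edema_factor, roughness = ph$roughness,
    pitch = ph$pitch, width_cm = cfg$grid$width, height_cm = cfg$grid$height,
    spion_density = ph$spion_density, spion_coverage = ph$spion_coverage,
    spion_heterogeneity = ph$spion_heterogeneity, seed = cfg$seed)
  save_phantom(stack, file.path(dir, "phantom"), style = ph$style)
  invisible(list.files(file.path(dir, "phantom"), full.names = TRUE))
}

#' @rdname pipeline_stages
#' @export
stage_scan <- function(cfg, dir) {
  g <- grid_layout(cfg$grid$width, cfg$grid$height,
                   step_width = cfg$grid$step_width, n_shifts = cfg$grid$n_shifts)
  truth <- read_truth_json(dir)
  ex <- cfg$excitation
  e <- excitation_config(ex$f1, ex$f2, ex$H1, ex$H2, ex$sample_rate, ex$n_periods)
  pref <- langevin_particle(ex$moment_scale, ex$saturation, amount = 1)
  cal <- calibrate_quantification(pref, e)
  H_true <- distortion_homography(cfg$distortion,
                                  center = c(cfg$grid$width, cfg$grid$height) / 2)
  sc <- cfg$scan
  out <- file.path(dir, "scan")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ny <- as.integer(round(cfg$grid$height / sc$pitch))
  nx <- as.integer(round(cfg$grid$width / sc$pitch))
  tags <- slice_tags(dir)
  files <- character(0)
  for (k in seq_along(tags)) {
    dens <- read_scan_tiff(file.path(dir, "phantom", paste0("conc_", tags[k], ".tiff")))
    # per-pixel amounts in the slide (optical) frame, droplets included
    amt <- scan_image(dens$values * dens$pitch^2, dens$pitch, "scanner")
    amt <- add_fiducial_droplets(amt, g, sc$droplet_amount, sc$droplet_radius)
    # the mixing amplitude is a pointwise reading of the PSF-weighted
    # local amount: blur at the fine slide pitch, then let the scanner
    # sample that smooth field through the geometric distortion
    psf <- psf_kernel(sc$psf_fwhm, amt$pitch)
    field <- acquire(amt, g, psf, cal, line_sampled = FALSE)
    img <- warp(field, solve(H_true), c(ny, nx), sc$pitch, preserve_mass = FALSE)
    img$frame <- "scanner"
    img$values <- pmax(img$values, 0)
    if (sc$noise_sd > 0)
      img$values <- img$values +
        with_seed(cfg$seed + 1000L + k,
                  matrix(stats::rnorm(length(img$values), sd = sc$noise_sd), ny))
    if (isTRUE(sc$line_sampled)) {
      xc <- pixel_centers(nx, sc$pitch)
      lines_x <- sort(scan_trajectory(g))
      colsel <- vapply(lines_x, function(x) which.min(abs(xc - x)), integer(1))
      img$values <- t(apply(img$values[, colsel, drop = FALSE], 1, function(row)
        stats::approx(xc[colsel], row, xout = xc, rule = 2)$y))
    }
    f <- file.path(out, paste0("scan_", tags[k], ".tiff"))
    write_scan_tiff(img, f)
    files <- c(files, f)
  }
  jsonlite::write_json(list(slope = cal$slope, a12_max = cal$a12_max),
                       file.path(out, "calibration.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}

#' @rdname pipeline_stages
#' @export
stage_register <- function(cfg, dir) {
  g <- grid_layout(cfg$grid$width, cfg$grid$height,
                   step_width = cfg$grid$step_width, n_shifts = cfg$grid$n_shifts)
  truth <- read_truth_json(dir)
  reg_dir <- file.path(dir, "registered")
  mrg_dir <- file.path(dir, "merged")
  dir.create(reg_dir, showWarnings = FALSE)
  dir.create(mrg_dir, showWarnings = FALSE)
  opt_pitch <- truth$pitch_cm
  sg <- cfg$segmentation
  tags <- slice_tags(dir)
  files <- character(0)
  for (tag in tags) {
    img <- read_scan_tiff(file.path(dir, "scan", paste0("scan_", tag, ".tiff")))
    fid <- detect_fiducials(img, g, cfg$registration$search_radius,
                            cfg$scan$droplet_amount)
    utils::write.csv(fid, file.path(reg_dir, paste0("fiducials_", tag, ".csv")),
                     row.names = FALSE)
    H <- fit_homography(as.matrix(fid[, c("x_cm", "y_cm")]),
                        g$fiducials[fid$label, , drop = FALSE])
    write_homography_json(H, file.path(reg_dir, paste0("homography_", tag, ".json")))
    optical <- read_rgb_png(file.path(dir, "phantom", paste0("optical_", tag, ".png")))
    sig <- warp(img, H, dim(optical)[1:2], opt_pitch, preserve_mass = FALSE)
    sig$values <- pmax(sig$values, 0)
    # the specimen occupies the central 3 x 3 grid cells; the fiducial
    # droplets on the outer ring are adjustment points, not sample signal
    xc <- pixel_centers(ncol(sig$values), opt_pitch)
    yc <- pixel_centers(nrow(sig$values), opt_pitch)
    inner <- outer(yc >= g$cell_height & yc <= g$total_height - g$cell_height,
                   xc >= g$cell_width & xc <= g$total_width - g$cell_width, `&`)
    sig$values[!inner] <- 0
    write_scan_tiff(sig, file.path(reg_dir, paste0("signal_", tag, ".tiff")))
    merged <- merge_overlay(optical, sig, color = sg$overlay_color,
                            alpha = sg$overlay_alpha,
                            threshold = sg$signal_threshold_rel * max(sig$values))
    f <- file.path(mrg_dir, paste0("merged_", tag, ".png"))
    write_rgb_png(merged, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname pipeline_stages
#' @export
stage_segment <- function(cfg, dir) {
  out <- file.path(dir, "masks")
  dir.create(out, showWarnings = FALSE)
  sg <- cfg$segmentation
  thr <- default_signal_thresholds(sg$overlay_color, sg$overlay_alpha,
                                   sg$threshold_margin)
  files <- character(0)
  for (tag in slice_tags(dir)) {
    optical <- read_rgb_png(file.path(dir, "phantom", paste0("optical_", tag, ".png")))
    merged <- read_rgb_png(file.path(dir, "merged", paste0("merged_", tag, ".png")))
    brain <- brain_outline(optical)
    sig <- threshold_signal(rgb_to_ycbcr(merged), thr)
    sig <- sig & brain # MaskPair invariant: signal within the outer border
    f1 <- file.path(out, paste0("brain_", tag, ".png"))
    f2 <- file.path(out, paste0("signal_", tag, ".png"))
    write_mask_png(brain, f1)
    write_mask_png(sig, f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}

#' @rdname pipeline_stages
#' @export
stage_quantify <- function(cfg, dir) {
  truth <- read_truth_json(dir)
  tags <- slice_tags(dir)
  pitch <- truth$pitch_cm
  zsp <- truth$z_spacing_cm
  mid <- truth$midline_x_cm
  rd <- function(sub, pre) lapply(tags, function(tg)
    read_mask_png(file.path(dir, sub, paste0(pre, tg, ".png"))))
  seg_brain <- rd("masks", "brain_")
  seg_sig <- rd("masks", "signal_")
  tr_brain <- rd("phantom", "brain_")
  tr_inf <- rd("phantom", "infarct_")
  idx <- as.integer(tags)
  rep_pfmmd <- stack_report(seg_brain, seg_sig, pitch, zsp, "pfmmd",
                            midline_x = mid, slice_indices = idx)
  rep_truth <- stack_report(tr_brain, tr_inf, pitch, zsp, "truth",
                            midline_x = mid, slice_indices = idx)
  f1 <- file.path(dir, "report_pfmmd.csv")
  f2 <- file.path(dir, "report_truth.csv")
  write_report_csv(rep_pfmmd, f1)
  write_report_csv(rep_truth, f2)
  smry <- list(pfmmd = rep_pfmmd$aggregate, truth = rep_truth$aggregate,
               generator_aggregate_pct = truth$aggregate$effective_pct)
  jsonlite::write_json(smry, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, file.path(dir, "summary.json")))
}

#' @rdname pipeline_stages
#' @export
stage_mesh <- function(cfg, dir) {
  truth <- read_truth_json(dir)
  out <- file.path(dir, "mesh")
  dir.create(out, showWarnings = FALSE)
  f <- max(1L, as.integer(cfg$mesh$downsample))
  down <- function(m) m[seq(1, nrow(m), by = f), seq(1, ncol(m), by = f)]
  tags <- slice_tags(dir)
  rd <- function(sub, pre) lapply(tags, function(tg)
    down(read_mask_png(file.path(dir, sub, paste0(pre, tg, ".png")))))
  pitch <- truth$pitch_cm * f
  zsp <- truth$z_spacing_cm
  vols <- list(brain = build_volume(rd("phantom", "brain_"), zsp, pitch,
                                    cfg$mesh$interp, cfg$mesh$interp_k),
               infarct_signal = build_volume(rd("masks", "signal_"), zsp, pitch,
                                             cfg$mesh$interp, cfg$mesh$interp_k),
               infarct_truth = build_volume(rd("phantom", "infarct_"), zsp, pitch,
                                            cfg$mesh$interp, cfg$mesh$interp_k))
  files <- character(0)
  for (nm in names(vols)) {
    surf <- merge_meshes(isosurface(vols[[nm]]), isocaps(vols[[nm]]))
    surf <- isonormals(vols[[nm]], surf)
    for (fmt in cfg$mesh$formats) {
      fp <- file.path(out, paste0(nm, ".", fmt))
      export_mesh(surf, fp, fmt)
      files <- c(files, fp)
    }
  }
  dice <- coincidence_ratio(vols$infarct_signal, vols$infarct_truth)
  jsonlite::write_json(list(dice_signal_vs_truth = as.numeric(dice),
                            iou_signal_vs_truth = as.numeric(attr(dice, "iou"))),
                       file.path(out, "dice.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(out, "dice.json")))
}

#' Run the full p-FMMD simulation and quantification pipeline
#'
#' phantom -> scan -> register -> segment -> quantify -> mesh, writing
#' all stage outputs, a manifest (path, stage, config hash), a log and
#' the resolved configuration into `dir`. Identical config + seed
#' reproduce identical reports.
#'
#' @param config A `run_config` list, or a path to a YAML/JSON config.
#' @param dir Output run directory (created; default `config$output_dir`
#'   or a tempdir subdirectory).
#' @return Invisibly, a list with the run `dir`, the parsed infarct
#'   `summary`, and the mesh `dice` score.
#' @export
run_pipeline <- function(config = default_run_config(), dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(dir)) dir <- file.path(tempdir(), sprintf("pfmmd_run_%d", cfg$seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "config_resolved.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stages <- list(phantom = stage_phantom, scan = stage_scan,
                 register = stage_register, segment = stage_segment,
                 quantify = stage_quantify, mesh = stage_mesh)
  manifest <- list()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    files <- stages[[nm]](cfg, dir)
    dt <- proc.time()[["elapsed"]] - t0
    run_log(dir, "stage %-9s %5.1fs  %d file(s)", nm, dt, length(files))
    manifest <- c(manifest, lapply(files, function(f)
      list(path = f, stage = nm, config_hash = cfg_hash)))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  smry <- jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
  dice <- jsonlite::read_json(file.path(dir, "mesh", "dice.json"), simplifyVector = TRUE)
  invisible(list(dir = dir, summary = smry, dice = dice$dice_signal_vs_truth))
}
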