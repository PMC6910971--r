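#' Edema-corrected infarct percentage
#'
#' \deqn{V_{infarct}(\%) = \frac{A_{contra} - (A_{ipsi} - A_{infarct})}
#' {A_{contra}} \times 100}
#'
#' Referencing the contralateral hemisphere removes the swelling bias:
#' edema inflates the ipsilateral area, and subtracting the non-infarcted
#' ipsilateral tissue from the contralateral area measures the tissue
#' actually lost. With no edema (`a_ipsi == a_contra`) this reduces to
#' `100 * a_infarct / a_contra`.
#'
#' @param a_contra Contralateral hemisphere area (> 0), cm^2.
#' @param a_ipsi Ipsilateral hemisphere area, cm^2.
#' @param a_infarct Infarct area, cm^2, with `0 <= a_infarct <= a_ipsi`.
#' @return Percentage (vectorised over its arguments).
#' @examples
#' infarct_percent(100, 110, 60)  # 50: 10% swelling corrected away
#' @export
infarct_percent <- function(a_contra, a_ipsi, a_infarct) {
  if (any(a_contra <= 0)) stopf("a_contra must be > 0")
  if (any(a_infarct < 0) || any(a_infarct > a_ipsi))
    stopf("require 0 <= a_infarct <= a_ipsi")
  (a_contra - (a_ipsi - a_infarct)) / a_contra * 100
}

#' Per-slice and stack-aggregated infarct report
#'
#' Applies the edema-corrected formula to every slice and to the stack
#' aggregate. Aggregation sums areas across slices before applying the
#' formula (volume-consistent, since every slice shares the same
#' z-spacing), rather than averaging per-slice percentages.
#'
#' @param brain_masks List of logical brain masks (one per slice).
#' @param infarct_masks List of logical infarct/signal masks, same
#'   geometry; each is clipped to its slice's ipsilateral hemisphere so
#'   that `A_infarct <= A_ipsi` always holds.
#' @param pitch Pixel pitch, cm.
#' @param z_spacing Inter-slice spacing, cm.
#' @param modality Tag: `"pfmmd"`, `"ttc_like"`, `"mri_like"` or
#'   `"truth"`.
#' @param midline_x Midline (cm); NULL for per-slice mask centroids.
#' @param slice_indices Optional section indices for the rows.
#' @return Object of class `infarct_report`: `per_slice` data.frame
#'   (slice_index, A_contra, A_ipsi, A_infarct in cm^2, V_infarct_pct),
#'   `aggregate` list (summed areas, volumes in cm^3 via z-spacing, and
#'   overall V_infarct_pct), `modality`, `z_spacing`.
#' @export
stack_report <- function(brain_masks, infarct_masks, pitch, z_spacing,
                         modality = c("pfmmd", "ttc_like", "mri_like", "truth"),
                         midline_x = NULL, slice_indices = NULL) {
  modality <- match.arg(modality)
  n <- length(brain_masks)
  if (n < 1 || length(infarct_masks) != n)
    stopf("need >= 1 slice and matching mask lists")
  if (is.null(slice_indices)) slice_indices <- seq_len(n)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    bm <- brain_masks[[j]]; im <- infarct_masks[[j]]
    if (!all(dim(bm) == dim(im)))
      stopf("slice %d: brain and infarct mask geometries differ", j)
    h <- split_hemispheres(bm, pitch, midline_x)
    a_inf <- sum(im & h$ipsi) * pitch^2
    rows[[j]] <- data.frame(slice_index = slice_indices[j],
                            A_contra = h$A_contra, A_ipsi = h$A_ipsi,
                            A_infarct = a_inf,
                            V_infarct_pct = infarct_percent(h$A_contra, h$A_ipsi, a_inf))
  }
  per <- do.call(rbind, rows)
  agg <- list(A_contra = sum(per$A_contra), A_ipsi = sum(per$A_ipsi),
              A_infarct = sum(per$A_infarct),
              V_contra_cm3 = sum(per$A_contra) * z_spacing,
              V_ipsi_cm3 = sum(per$A_ipsi) * z_spacing,
              V_infarct_cm3 = sum(per$A_infarct) * z_spacing,
              V_infarct_pct = infarct_percent(sum(per$A_contra), sum(per$A_ipsi),
                                              sum(per$A_infarct)))
  structure(list(per_slice = per, aggregate = agg, modality = modality,
                 z_spacing = z_spacing),
            class = "infarct_report")
}

#' Mean and SEM of aggregate infarct percentages across replicates
#'
#' @param reports A list of `infarct_report` objects (possibly of mixed
#'   modality), or a plain numeric vector of percentages.
#' @return A data.frame with one row per modality: `modality`, `n`,
#'   `mean`, `sem` (sd/sqrt(n); NA when n < 2).
#' @export
summarize_replicates <- function(reports) {
  if (is.numeric(reports)) {
    v <- reports; mods <- rep("pfmmd", length(v))
  } else {
    v <- vapply(reports, function(r) r$aggregate$V_infarct_pct, numeric(1))
    mods <- vapply(reports, function(r) r$modality, character(1))
  }
  out <- do.call(rbind, lapply(split(v, mods), function(x)
    data.frame(n = length(x), mean = mean(x),
               sem = if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_)))
  out <- cbind(modality = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Write an infarct report as CSV (per-slice rows plus aggregate row)
#' @param report An `infarct_report`.
#' @param path Output CSV path.
#' @export
write_report_csv <- function(report, path) {
  per <- report$per_slice
  agg <- report$aggregate
  per$row_type <- "slice"
  per <- rbind(per, data.frame(slice_index = NA, A_contra = agg$A_contra,
                               A_ipsi = agg$A_ipsi, A_infarct = agg$A_infarct,
                               V_infarct_pct = agg$V_infarct_pct,
                               row_type = "aggregate"))
  per$modality <- report$modality
  utils::write.csv(per, path, row.names = FALSE)
  invisible(path)
}
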