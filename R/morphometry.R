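## morphometry_stats: necrosis size measurement and comparison statistics.

#' Measure the size of a binary mask
#'
#' Area is the absolute foreground pixel count times the pixel area. The
#' maximum diameter is the Feret (maximum caliper) diameter, computed as
#' the largest pairwise distance between convex-hull boundary pixel
#' centers plus one pixel (so the caliper spans pixel extents, and a
#' single-pixel mask has diameter one pixel), times the spacing.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @param spacingMm pixel edge length in mm.
#' @param ablationId,modality identifiers recorded on the row.
#' @return one-row data.frame: ablation_id, modality, area_mm2,
#'   max_diameter_mm.
#' @export
measureSize <- function(mask, spacingMm, ablationId = "ablation",
                        modality = "CECT") {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  area <- nrow(idx) * spacingMm^2
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  if (nrow(pts) > 3L) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
  }
  dmax <- if (nrow(pts) == 1L) 0 else max(stats::dist(pts))
  data.frame(ablation_id = ablationId, modality = modality,
             area_mm2 = area,
             max_diameter_mm = (dmax + 1) * spacingMm)
}

#' Compare measured sizes against the histologic reference
#'
#' Paired two-sided t-test on areas (the same ablations are measured by
#' each modality), Pearson correlation, and the mean squared error of the
#' areas (mm^4). A zero-variance difference is flagged degenerate with
#' p = 1 when the measurements agree exactly and p = 0 when they differ by
#' an exact constant.
#'
#' @param measured numeric vector of areas from one modality, mm2.
#' @param reference numeric vector of histology areas, mm2 (same order).
#' @return data.frame: p_value, pearson_r, mse, degenerate.
#' @export
compareSizes <- function(measured, reference) {
  stopifnot(length(measured) == length(reference), length(measured) >= 3)
  d <- measured - reference
  mse <- mean(d^2)
  r <- if (stats::sd(measured) == 0 || stats::sd(reference) == 0)
    NA_real_ else stats::cor(measured, reference)
  if (stats::sd(d) == 0) {
    return(data.frame(p_value = if (all(d == 0)) 1 else 0,
                      pearson_r = r, mse = mse, degenerate = TRUE))
  }
  p <- stats::t.test(measured, reference, paired = TRUE)$p.value
  data.frame(p_value = p, pearson_r = r, mse = mse, degenerate = FALSE)
}

#' Cohort morphometry report
#'
#' One row per modality (plus a histology row) with the mean area, mean
#' maximum diameter, and the paired comparison against histology: t-test
#' p-value, Pearson r, mean squared error of areas.
#'
#' @param sizes data.frame of per-ablation, per-modality measurements with
#'   columns ablation_id, modality, area_mm2, max_diameter_mm.
#' @param referenceSizes data.frame of histology measurements with columns
#'   ablation_id, area_mm2, max_diameter_mm.
#' @param modalities modalities to report, in row order.
#' @return data.frame in the report column order: modality, mean_area_mm2,
#'   mean_max_diameter_mm, p_value, pearson_r, mse.
#' @export
cohortReport <- function(sizes, referenceSizes,
                         modalities = unique(sizes$modality)) {
  ref <- referenceSizes[order(referenceSizes$ablation_id), ]
  out <- data.frame(modality = "Histology",
                    mean_area_mm2 = mean(ref$area_mm2),
                    mean_max_diameter_mm = mean(ref$max_diameter_mm),
                    p_value = NA_real_, pearson_r = NA_real_,
                    mse = NA_real_)
  for (m in modalities) {
    sub <- sizes[sizes$modality == m, , drop = FALSE]
    sub <- sub[match(ref$ablation_id, sub$ablation_id), , drop = FALSE]
    if (anyNA(sub$area_mm2)) {
      warning("missing measurements for modality ", m, "; row omitted")
      next
    }
    cmp <- if (nrow(ref) >= 3) {
      compareSizes(sub$area_mm2, ref$area_mm2)
    } else {
      # too few pairs for inferential statistics; report the MSE only
      data.frame(p_value = NA_real_, pearson_r = NA_real_,
                 mse = mean((sub$area_mm2 - ref$area_mm2)^2))
    }
    out <- rbind(out, data.frame(modality = m,
                                 mean_area_mm2 = mean(sub$area_mm2),
                                 mean_max_diameter_mm = mean(sub$max_diameter_mm),
                                 p_value = cmp$p_value,
                                 pearson_r = cmp$pearson_r,
                                 mse = cmp$mse))
  }
  out
}
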