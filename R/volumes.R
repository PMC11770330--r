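#' Lesion volume in cubic centimeters
#'
#' Volume is the voxel count times the voxel volume implied by the affine
#' (absolute determinant of its 3x3 block, in mm^3), divided by 1000.
#'
#' @param mask a `lesion_mask`.
#' @return volume in cm^3.
#' @examples
#' g <- array(0L, c(10, 10, 10)); g[1:10, 1:10, 1:10] <- 1L
#' m <- lesion_mask(g, diag(c(1, 1, 1, 1)), kind = "infarct")
#' lesion_volume(m)  # 1 cm^3
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  stop_if(!is_binary_grid(mask$grid), "lesion grid must be binary")
  sum(mask$grid) * abs(det(mask$affine[1:3, 1:3])) / 1000
}

#' Intracranial-volume normalization
#'
#' Rescales a volume by the ratio of the cohort mean intracranial volume to
#' the subject's intracranial volume, so that lesion burdens are comparable
#' across head sizes.
#'
#' @param raw_cm3 raw volume(s) in cm^3.
#' @param subject_icv subject intracranial volume (cm^3, > 0).
#' @param cohort_mean_icv cohort mean intracranial volume (cm^3, > 0).
#' @return normalized volume(s) in cm^3.
#' @export
normalize_volume <- function(raw_cm3, subject_icv, cohort_mean_icv) {
  stop_if(any(!is.finite(subject_icv)) || any(subject_icv <= 0),
          "subject intracranial volume must be positive")
  stop_if(any(!is.finite(cohort_mean_icv)) || any(cohort_mean_icv <= 0),
          "cohort mean intracranial volume must be positive")
  stop_if(any(raw_cm3 < 0), "raw volume must be nonnegative")
  raw_cm3 * cohort_mean_icv / subject_icv
}

#' Lesion volume per vascular territory
#'
#' Intersects a lesion mask with the template's territory labels and
#' reports the lesion volume (cm^3) within each of the 10 territories plus
#' the dominant territory (largest lesioned volume; ties broken toward the
#' smallest code).
#'
#' @param mask a `lesion_mask` on the template grid.
#' @param template a `template_space`.
#' @return list with `per_territory_cm3` (named length-10 vector) and
#'   `dominant` (integer code, `NA` for an empty mask).
#' @export
territory_volumes <- function(mask, template) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(template, "template_space"))
  check_same_grid(dim(mask$grid), template$shape, "mask and template")
  vox_cm3 <- abs(det(mask$affine[1:3, 1:3])) / 1000
  counts <- tabulate(template$territory_labels[mask$grid == 1L], nbins = 10L)
  vols <- counts * vox_cm3
  names(vols) <- paste0("territory_", 1:10)
  dominant <- if (sum(counts) == 0L) NA_integer_ else
    unname(which.max(vols))
  list(per_territory_cm3 = vols, dominant = dominant)
}

#' Voxelwise lesion incidence map
#'
#' Sums binary lesion masks voxel by voxel: the value at a voxel is the
#' number of subjects with a lesion there.
#'
#' @param masks list of `lesion_mask` objects on a shared grid.
#' @return integer 3-D array.
#' @export
incidence_map <- function(masks) {
  stop_if(length(masks) == 0L, "need at least one mask")
  d <- dim(masks[[1]]$grid)
  out <- array(0L, d)
  for (m in masks) {
    stopifnot(inherits(m, "lesion_mask"))
    check_same_grid(dim(m$grid), d, "masks")
    out <- out + m$grid
  }
  out
}
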