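#' Lesion mask constructor
#'
#' A lesion mask is a subject-level binary 3-D grid with a voxel-to-mm
#' affine and a lesion kind tag (`"infarct"` or `"wmh"`).
#'
#' @param grid binary 3-D array (values 0/1).
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel indices).
#' @param subject_id subject identifier.
#' @param kind `"infarct"` or `"wmh"`.
#' @return an object of class `lesion_mask`.
#' @export
lesion_mask <- function(grid, affine, subject_id = "sub-001",
                        kind = c("infarct", "wmh")) {
  kind <- match.arg(kind)
  stop_if(!is_binary_grid(grid), "lesion grid must be a binary 3-D array")
  stop_if(!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
            abs(det(affine[1:3, 1:3])) < 1e-12,
          "affine must be an invertible 4x4 matrix")
  structure(list(subject_id = subject_id, kind = kind,
                 grid = array(as.integer(grid), dim(grid)),
                 affine = affine),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("Lesion mask %s (%s): %d voxels, %.2f cm^3\n",
              x$subject_id, x$kind, sum(x$grid), lesion_volume(x)))
  invisible(x)
}

#' Sample synthetic lesion masks
#'
#' Emulates the two qualitative lesion regimes of a minor-stroke cohort:
#' infarcts are compact ellipsoidal blobs centered in a randomly chosen
#' vascular territory (hence low pairwise overlap across subjects and no
#' ventricular involvement), while white matter hyperintensities (WMH) are
#' periventricular shells -- every white-matter voxel within a per-subject
#' rim distance of the ventricular surface -- optionally with a few small
#' satellite blobs deeper in the white matter (hence high pairwise overlap).
#'
#' @param template a `template_space`.
#' @param kind `"infarct"` or `"wmh"`.
#' @param n_subjects number of masks to draw.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param infarct_radius_mm range (min, max) of infarct ellipsoid semi-axes.
#' @param wmh_rim_mm range (min, max) of the periventricular rim distance.
#' @param wmh_max_satellites maximum number of satellite WMH blobs per
#'   subject (0 disables satellites; satellites stay in white matter).
#' @return list of `lesion_mask` objects (subjects `sub-001`, ...).
#' @export
sample_lesions <- function(template, kind = c("infarct", "wmh"),
                           n_subjects = 105L, seed = 1L,
                           infarct_radius_mm = c(5, 16),
                           wmh_rim_mm = c(4, 11),
                           wmh_max_satellites = 2L) {
  kind <- match.arg(kind)
  stopifnot(inherits(template, "template_space"))
  shape <- template$shape
  axes <- grid_axes_mm(shape, template$voxel_mm)
  co <- coord_arrays(shape, axes)
  brain <- template$brain_mask == 1L
  vent <- template$ventricle_mask == 1L
  wm <- template$wm_mask == 1L
  allowed_inf <- brain & !vent

  with_seed(seed, lapply(seq_len(n_subjects), function(i) {
    g <- array(0L, shape)
    if (kind == "infarct") {
      terr <- sample.int(10L, 1L)
      cand <- which(allowed_inf & template$territory_labels == terr)
      ctr_lin <- cand[sample.int(length(cand), 1L)]
      ctr <- arrayInd(ctr_lin, shape)
      cmm <- c(axes[[1]][ctr[1]], axes[[2]][ctr[2]], axes[[3]][ctr[3]])
      r <- exp(stats::runif(3, log(infarct_radius_mm[1]),
                            log(infarct_radius_mm[2])))
      blob <- ((co$x - cmm[1]) / r[1])^2 + ((co$y - cmm[2]) / r[2])^2 +
        ((co$z - cmm[3]) / r[3])^2 <= 1
      g[blob & allowed_inf] <- 1L
      if (sum(g) == 0L) g[ctr_lin] <- 1L # degenerate radius vs voxel size
    } else {
      rim <- stats::runif(1, wmh_rim_mm[1], wmh_rim_mm[2])
      g[wm & template$dist_ventricle <= rim] <- 1L
      n_sat <- if (wmh_max_satellites > 0L)
        sample.int(wmh_max_satellites + 1L, 1L) - 1L else 0L
      if (n_sat > 0L) {
        wm_lin <- which(wm)
        for (s in seq_len(n_sat)) {
          ctr <- arrayInd(wm_lin[sample.int(length(wm_lin), 1L)], shape)
          cmm <- c(axes[[1]][ctr[1]], axes[[2]][ctr[2]], axes[[3]][ctr[3]])
          rs <- stats::runif(1, 3, 7)
          blob <- ((co$x - cmm[1])^2 + (co$y - cmm[2])^2 +
                     (co$z - cmm[3])^2) <= rs^2
          g[blob & wm] <- 1L
        }
      }
    }
    lesion_mask(g, template$affine, sprintf("sub-%03d", i), kind)
  }))
}

#' Write / read lesion masks and label grids as NIfTI-1
#'
#' Thin wrappers around the RNifti reader/writer that preserve the affine.
#'
#' @param grid 3-D array (mask or integer labels).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_nifti_grid` returns `path` invisibly; `read_nifti_grid`
#'   returns a list with `grid` and `affine`.
#' @export
write_nifti_grid <- function(grid, affine, path) {
  img <- RNifti::asNifti(grid)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  list(grid = array(as.vector(img), dim(img)), affine = aff)
}
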