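#' Write / read a template space as NIfTI files plus a JSON header
#'
#' The on-disk layout is a directory of NIfTI-1 volumes (`brain`,
#' `ventricle`, `cortex`, `wm` masks; `lobe_labels`, `territory_labels`;
#' `dist_ventricle`, `dist_cortex` in mm) and `meta.json` with the grid
#' geometry.
#'
#' @param template a `template_space`.
#' @param path directory to create/overwrite.
#' @return `write_template` returns `path` invisibly; `read_template` the
#'   reconstructed `template_space`.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "template_space"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  vols <- c("brain_mask", "ventricle_mask", "cortex_mask", "wm_mask",
            "lobe_labels", "territory_labels", "dist_ventricle",
            "dist_cortex")
  for (v in vols) {
    write_nifti_grid(template[[v]], template$affine,
                     file.path(path, paste0(v, ".nii")))
  }
  jsonlite::write_json(
    list(shape = template$shape, affine = as.vector(template$affine),
         voxel_mm = template$voxel_mm, seed = template$seed),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(v) read_nifti_grid(file.path(path, paste0(v, ".nii")))$grid
  int_grid <- function(v) {
    g <- rd(v); array(as.integer(round(g)), dim(g))
  }
  structure(list(
    shape = as.integer(meta$shape),
    affine = matrix(meta$affine, 4, 4),
    voxel_mm = meta$voxel_mm,
    brain_mask = int_grid("brain_mask"),
    ventricle_mask = int_grid("ventricle_mask"),
    cortex_mask = int_grid("cortex_mask"),
    wm_mask = int_grid("wm_mask"),
    lobe_labels = int_grid("lobe_labels"),
    territory_labels = int_grid("territory_labels"),
    dist_ventricle = rd("dist_ventricle"),
    dist_cortex = rd("dist_cortex"),
    seed = meta$seed
  ), class = "template_space")
}
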