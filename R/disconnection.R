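#' Rasterize a streamline onto a voxel grid
#'
#' Samples every polyline segment at a spacing no larger than `step_mm`
#' (endpoints included), maps each sample through the inverse affine, and
#' assigns it to the nearest voxel (voxel-center convention). Samples that
#' fall outside the grid are dropped and the result is deduplicated.
#'
#' Voxel indices are returned 1-based, R's array convention; the affine maps
#' 0-based indices to mm, so the index arithmetic shifts by one internally.
#'
#' @param points n x 3 matrix of mm coordinates (n >= 2).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param grid_shape integer vector of length 3.
#' @param step_mm sampling step along the streamline (> 0).
#' @return integer matrix (m x 3) of unique 1-based voxel indices; it also
#'   carries the linear indices as attribute `"linear"`.
#' @export
rasterize_streamline <- function(points, affine, grid_shape, step_mm = 1) {
  stop_if(!is.matrix(points) || ncol(points) != 3L || nrow(points) < 2L,
          "streamline must be an n x 3 coordinate matrix with n >= 2")
  stop_if(!is.finite(step_mm) || step_mm <= 0, "step_mm must be positive")
  stop_if(abs(det(affine[1:3, 1:3])) < 1e-12, "degenerate affine")
  lin <- rasterize_linear(points, affine, grid_shape, step_mm)
  idx <- arrayInd(lin, grid_shape)
  attr(idx, "linear") <- lin
  idx
}

# Core rasterizer returning sorted unique linear (1-based) voxel indices.
rasterize_linear <- function(points, affine, grid_shape, step_mm) {
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  if (!any(keep)) return(integer(0))
  ns <- pmax(1L, ceiling(len[keep] / step_mm))
  from <- which(keep)
  # sample points: for segment i, fractions 0..1 in ns[i] steps (skip the
  # leading endpoint except for the first segment to avoid duplicates)
  total <- sum(ns) + 1L
  samp <- matrix(0, total, 3L)
  pos <- 1L
  samp[1L, ] <- points[from[1L], ]
  for (i in seq_along(from)) {
    f <- seq_len(ns[i]) / ns[i]
    p0 <- points[from[i], ]
    p1 <- points[from[i] + 1L, ]
    rows <- pos + seq_len(ns[i])
    samp[rows, ] <- outer(1 - f, p0) + outer(f, p1)
    pos <- pos + ns[i]
  }
  v <- mm_to_voxel(samp, affine) # fractional 0-based
  iv <- round(v) + 1
  ok <- iv[, 1] >= 1 & iv[, 1] <= grid_shape[1] &
    iv[, 2] >= 1 & iv[, 2] <= grid_shape[2] &
    iv[, 3] >= 1 & iv[, 3] <= grid_shape[3]
  if (!any(ok)) return(integer(0))
  iv <- iv[ok, , drop = FALSE]
  lin <- as.integer(iv[, 1] + grid_shape[1] * (iv[, 2] - 1) +
                      grid_shape[1] * grid_shape[2] * (iv[, 3] - 1))
  sort(unique(lin))
}

# Rasterize a whole atlas once (masks on a shared grid can then be scored
# by cheap lookups). Returns a list (per tract) of lists (per streamline)
# of linear voxel indices.
#' Precompute rasterized voxel sets for an atlas
#'
#' @param atlas a `streamline_atlas`.
#' @param step_mm sampling step; default half the smallest voxel dimension,
#'   which guarantees no voxel is skipped along a segment.
#' @return nested list of linear voxel indices, class `atlas_raster`.
#' @export
rasterize_atlas <- function(atlas, step_mm = NULL) {
  stopifnot(inherits(atlas, "streamline_atlas"))
  step_mm <- step_mm %||% (min(abs(diag(atlas$affine)[1:3])) / 2)
  out <- lapply(atlas$tracts, function(t) {
    lapply(t$streamlines, rasterize_linear, affine = atlas$affine,
           grid_shape = atlas$shape, step_mm = step_mm)
  })
  structure(out, class = "atlas_raster", step_mm = step_mm,
            shape = atlas$shape)
}

#' Percent disconnection of one tract
#'
#' The fraction (as a percentage) of a tract's streamlines that pass
#' through the lesion mask. A streamline counts as disconnected when at
#' least one of its rasterized voxels lies inside the mask -- the standard
#' disconnectome convention for "passing through".
#'
#' @param tract a tract (list with `name` and `streamlines`) from a
#'   `streamline_atlas`.
#' @param mask a `lesion_mask` on the atlas grid.
#' @param step_mm sampling step; default half the smallest voxel dimension.
#' @return percent disconnection in [0, 100].
#' @export
tract_disconnection <- function(tract, mask, step_mm = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  stop_if(length(tract$streamlines) == 0L, "tract has no streamlines")
  stop_if(!is_binary_grid(mask$grid), "mask must be binary")
  step_mm <- step_mm %||% (min(abs(diag(mask$affine)[1:3])) / 2)
  mv <- as.logical(mask$grid)
  hit <- vapply(tract$streamlines, function(p) {
    lin <- rasterize_linear(p, mask$affine, dim(mask$grid), step_mm)
    length(lin) > 0L && any(mv[lin])
  }, logical(1))
  100 * mean(hit)
}

#' Tract-wise disconnection profile of a lesion mask
#'
#' Applies [tract_disconnection()] over every tract of an atlas, in atlas
#' order. When scoring many masks on a shared grid, pass a precomputed
#' `raster` from [rasterize_atlas()] to avoid re-rasterizing streamlines.
#'
#' @param atlas a `streamline_atlas`.
#' @param mask a `lesion_mask` on the atlas grid.
#' @param step_mm sampling step; default half the smallest voxel dimension.
#' @param raster optional `atlas_raster` precomputed on the same grid.
#' @return a `disconnection_profile`: list with `subject_id`, `kind`, and
#'   `pct`, a named vector of percent disconnection per tract.
#' @export
disconnection_profile <- function(atlas, mask, step_mm = NULL, raster = NULL) {
  stopifnot(inherits(atlas, "streamline_atlas"), inherits(mask, "lesion_mask"))
  check_same_grid(dim(mask$grid), atlas$shape, "mask and atlas")
  stop_if(!is_binary_grid(mask$grid), "mask must be binary")
  mv <- as.logical(mask$grid)
  if (is.null(raster)) {
    step_mm <- step_mm %||% (min(abs(diag(mask$affine)[1:3])) / 2)
    pct <- vapply(atlas$tracts, tract_disconnection, numeric(1),
                  mask = mask, step_mm = step_mm)
  } else {
    check_same_grid(attr(raster, "shape"), dim(mask$grid),
                    "raster and mask")
    pct <- vapply(raster, function(tr) {
      100 * mean(vapply(tr, function(lin) length(lin) > 0L && any(mv[lin]),
                        logical(1)))
    }, numeric(1))
  }
  names(pct) <- atlas_tract_names(atlas)
  structure(list(subject_id = mask$subject_id, kind = mask$kind, pct = pct),
            class = "disconnection_profile")
}

#' @export
print.disconnection_profile <- function(x, ...) {
  cat(sprintf("Disconnection profile %s (%s): %d tracts, %d affected\n",
              x$subject_id, x$kind, length(x$pct), sum(x$pct > 0)))
  top <- sort(x$pct, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(x$pct > 0)))]
  if (length(top)) {
    for (i in seq_along(top)) {
      cat(sprintf("  %5.1f%%  %s\n", top[i], names(top)[i]))
    }
  }
  invisible(x)
}

#' Stack disconnection profiles into a subjects-by-tracts matrix
#'
#' @param profiles list of `disconnection_profile` objects over a shared
#'   atlas.
#' @return numeric matrix (subjects x tracts) of percent disconnection with
#'   subject ids as row names.
#' @export
profile_matrix <- function(profiles) {
  stop_if(length(profiles) == 0L, "no profiles given")
  m <- do.call(rbind, lapply(profiles, `[[`, "pct"))
  rownames(m) <- vapply(profiles, `[[`, character(1), "subject_id")
  m
}
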