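#' Generate a synthetic streamline tract atlas
#'
#' Builds a toy streamline atlas on a template: each tract is a bundle of
#' smooth polylines obtained by spline interpolation through jittered copies
#' of a tract-specific set of control points anchored in the white matter.
#' Tract names are taken from the head of [canonical_registry()] (padded
#' with generic names beyond 70 tracts). All polyline points are confined
#' to the template's bounding box in mm.
#'
#' @param template a `template_space` from [make_template()].
#' @param n_tracts number of tracts (>= 2).
#' @param streamlines_per_tract streamlines per bundle.
#' @param seed integer seed; the atlas is a pure function of its arguments.
#' @param jitter_mm per-streamline control point jitter (mm standard
#'   deviation) controlling bundle thickness.
#' @param n_ctrl number of control points per tract centerline.
#' @param point_spacing_mm approximate spacing of polyline vertices in mm.
#' @return A `streamline_atlas`: list with `tracts` (each a list with `name`
#'   and `streamlines`, a list of n x 3 coordinate matrices in template mm
#'   space), `space_tag`, and the template `shape` and `affine`.
#' @export
make_atlas <- function(template, n_tracts = 24L, streamlines_per_tract = 20L,
                       seed = 1L, jitter_mm = 3, n_ctrl = 5L,
                       point_spacing_mm = 2) {
  stopifnot(inherits(template, "template_space"))
  n_tracts <- as.integer(n_tracts)
  stop_if(n_tracts < 2L, "need at least 2 tracts")
  stop_if(streamlines_per_tract < 1L, "need at least 1 streamline per tract")

  reg <- canonical_registry()
  nm <- if (n_tracts <= length(reg)) reg[seq_len(n_tracts)] else
    c(reg, sprintf("extra bundle %02d", seq_len(n_tracts - length(reg))))

  wm_idx <- which(array(template$wm_mask == 1L, template$shape),
                  arr.ind = TRUE)
  A <- template$affine
  wm_mm <- voxel_to_mm(wm_idx - 1, A)
  half <- template$shape * template$voxel_mm / 2
  lo <- A[1:3, 4] - template$voxel_mm / 2
  hi <- lo + template$shape * template$voxel_mm

  tracts <- with_seed(seed, lapply(seq_len(n_tracts), function(j) {
    # endpoints: one random white-matter point and the farthest of a few
    # candidates, so centerlines span the volume
    a <- wm_mm[sample(nrow(wm_mm), 1L), ]
    cand <- wm_mm[sample(nrow(wm_mm), 25L), , drop = FALSE]
    b <- cand[which.max(colSums((t(cand) - a)^2)), ]
    tt <- seq(0, 1, length.out = n_ctrl)
    ctrl <- outer(1 - tt, a) + outer(tt, b)
    mid <- seq_len(n_ctrl)[-c(1L, n_ctrl)]
    ctrl[mid, ] <- ctrl[mid, ] + matrix(stats::rnorm(length(mid) * 3, 0, 8),
                                        ncol = 3)
    # pull stray control points back toward the interior
    ctrl <- sweep(ctrl, 2, 0.95 * half, function(v, h) pmin(pmax(v, -h), h))

    sl <- lapply(seq_len(streamlines_per_tract), function(s) {
      cj <- ctrl + matrix(stats::rnorm(n_ctrl * 3, 0, jitter_mm), ncol = 3)
      len <- sum(sqrt(rowSums(diff(cj)^2)))
      np <- max(8L, ceiling(len / point_spacing_mm))
      u <- seq(0, 1, length.out = np)
      pts <- vapply(1:3, function(d) {
        stats::spline(tt, cj[, d], xout = u, method = "natural")$y
      }, numeric(np))
      # confine to the grid bounding box
      pts <- sweep(pts, 2, lo, pmax)
      pts <- sweep(pts, 2, hi - 1e-6, pmin)
      # drop consecutive duplicates (can arise from clamping)
      keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
      pts[keep, , drop = FALSE]
    })
    list(name = nm[j], streamlines = sl)
  }))

  structure(list(
    tracts = tracts,
    space_tag = sprintf("synthetic-%s", paste(template$shape, collapse = "x")),
    shape = template$shape,
    affine = template$affine
  ), class = "streamline_atlas")
}

#' @export
print.streamline_atlas <- function(x, ...) {
  ns <- vapply(x$tracts, function(t) length(t$streamlines), integer(1))
  cat(sprintf("Streamline atlas (%s): %d tracts, %d streamlines\n",
              x$space_tag, length(x$tracts), sum(ns)))
  invisible(x)
}

#' Tract names of an atlas
#' @param atlas a `streamline_atlas`.
#' @return character vector of tract names in atlas order.
#' @export
atlas_tract_names <- function(atlas) {
  vapply(atlas$tracts, `[[`, character(1), "name")
}

#' Write / read a streamline atlas as plain text
#'
#' The on-disk layout is a directory holding `header.json` (tract names,
#' space tag, counts) and `coordinates.csv` with one row per polyline vertex
#' (`tract`, `streamline`, `point`, `x`, `y`, `z`; mm coordinates).
#'
#' @param atlas a `streamline_atlas`.
#' @param path directory to create/overwrite.
#' @return `write_atlas` returns `path` invisibly; `read_atlas` returns the
#'   reconstructed `streamline_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "streamline_atlas"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    space_tag = atlas$space_tag,
    shape = atlas$shape,
    affine = as.vector(atlas$affine),
    tract_names = atlas_tract_names(atlas),
    n_streamlines = vapply(atlas$tracts, function(t) length(t$streamlines),
                           integer(1))
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- do.call(rbind, lapply(seq_along(atlas$tracts), function(j) {
    t <- atlas$tracts[[j]]
    do.call(rbind, lapply(seq_along(t$streamlines), function(s) {
      p <- t$streamlines[[s]]
      cbind(tract = j, streamline = s, point = seq_len(nrow(p)), p)
    }))
  }))
  colnames(rows) <- c("tract", "streamline", "point", "x", "y", "z")
  utils::write.csv(as.data.frame(rows), file.path(path, "coordinates.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  co <- utils::read.csv(file.path(path, "coordinates.csv"))
  tracts <- lapply(seq_along(header$tract_names), function(j) {
    cj <- co[co$tract == j, , drop = FALSE]
    sl <- lapply(sort(unique(cj$streamline)), function(s) {
      p <- cj[cj$streamline == s, , drop = FALSE]
      unname(as.matrix(p[order(p$point), c("x", "y", "z")]))
    })
    list(name = header$tract_names[j], streamlines = sl)
  })
  structure(list(
    tracts = tracts,
    space_tag = header$space_tag,
    shape = as.integer(header$shape),
    affine = matrix(header$affine, 4, 4)
  ), class = "streamline_atlas")
}
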