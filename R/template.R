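#' Build a synthetic brain-like template space
#'
#' Constructs an abstract template on a regular voxel grid: a brain ellipsoid
#' with an outer cortical shell, a central elongated ventricular ellipsoid,
#' the white matter in between, nine azimuthal lobar sectors covering the
#' white matter, and ten vascular-territory codes (six supratentorial and
#' four infratentorial sectors) partitioning the brain volume. Euclidean
#' distance maps to the ventricular and cortical surfaces are precomputed
#' because both the white matter hyperintensity generator and the bullseye
#' parcellation consume them.
#'
#' The geometry is deliberately schematic: registration of real scans to a
#' standard space is outside the scope of this package, and every
#' geometry-dependent computation downstream only requires internal
#' consistency (masks disjoint, labels partitioning the volume), not
#' anatomical realism.
#'
#' @param grid_shape integer vector of length 3, voxels per axis (each >= 16).
#' @param voxel_mm numeric vector of length 3, voxel size in mm.
#' @param seed integer seed; the template is a pure function of its arguments.
#' @return An object of class `template_space`: a list with `shape`, `affine`
#'   (4x4 voxel-to-mm map, 0-based voxel indices), `voxel_mm`, binary grids
#'   `brain_mask`, `ventricle_mask`, `cortex_mask`, `wm_mask`, integer grids
#'   `lobe_labels` (codes 1-9 on white matter) and `territory_labels`
#'   (codes 1-10 on brain), and distance maps `dist_ventricle`,
#'   `dist_cortex` (mm).
#' @examples
#' tpl <- make_template(c(24, 24, 24), c(4, 4, 4), seed = 1)
#' length(setdiff(unique(as.vector(tpl$territory_labels)), 0L))  # 10
#' @export
make_template <- function(grid_shape = c(40L, 40L, 40L),
                          voxel_mm = c(4, 4, 4),
                          seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stop_if(length(grid_shape) != 3L || any(grid_shape < 16L),
          "grid too small to host ventricle and cortical shell; ",
          "need at least 16 voxels per axis")
  stop_if(length(voxel_mm) != 3L || any(voxel_mm <= 0),
          "voxel_mm must be 3 positive sizes in mm")

  jit <- with_seed(seed, stats::runif(3, 0.97, 1.03))

  half <- grid_shape * voxel_mm / 2
  axes <- grid_axes_mm(grid_shape, voxel_mm)
  co <- coord_arrays(grid_shape, axes)

  brain_semi <- 0.92 * half * jit
  rho <- sqrt((co$x / brain_semi[1])^2 + (co$y / brain_semi[2])^2 +
                (co$z / brain_semi[3])^2)
  brain <- rho <= 1

  cortex <- brain & rho >= 0.80

  # central ventricle, elongated along y (anterior-posterior)
  vent_semi <- c(0.16, 0.34, 0.16) * half
  vent <- ((co$x / vent_semi[1])^2 + (co$y / vent_semi[2])^2 +
             (co$z / vent_semi[3])^2) <= 1

  wm <- brain & !cortex & !vent
  stop_if(!any(vent) || !any(cortex) || !any(wm),
          "grid too small to host ventricle and cortical shell")

  azim <- atan2(co$y, co$x) # (-pi, pi]

  sector <- function(n) {
    s <- floor((azim + pi) / (2 * pi / n))
    s[s >= n] <- n - 1 # azim == pi lands in the last sector
    s + 1L
  }

  lobe <- array(0L, grid_shape)
  lobe[wm] <- as.integer(sector(9L))[wm]

  # territories: bottom quarter of the brain (z) is infratentorial
  zn <- co$z / brain_semi[3]
  infra <- zn < -0.5
  terr <- array(0L, grid_shape)
  terr[brain & !infra] <- as.integer(sector(6L))[brain & !infra]
  terr[brain & infra] <- as.integer(sector(4L))[brain & infra] + 6L

  affine <- diag(c(voxel_mm, 1))
  affine[1:3, 4] <- -half + voxel_mm / 2 # center of voxel (0,0,0)

  dist_vent <- distance_to_mask(vent, voxel_mm)
  # cortical distance is only meaningful inside the brain; elsewhere 0
  dist_cort <- array(0, grid_shape)
  qin <- which(brain & !cortex, arr.ind = TRUE)
  dist_cort[qin] <- distance_to_mask(cortex, voxel_mm, query = qin)

  structure(list(
    shape = grid_shape,
    affine = affine,
    voxel_mm = voxel_mm,
    brain_mask = array(as.integer(brain), grid_shape),
    ventricle_mask = array(as.integer(vent), grid_shape),
    cortex_mask = array(as.integer(cortex), grid_shape),
    wm_mask = array(as.integer(wm), grid_shape),
    lobe_labels = lobe,
    territory_labels = terr,
    dist_ventricle = dist_vent,
    dist_cortex = dist_cort,
    seed = seed
  ), class = "template_space")
}

#' @export
print.template_space <- function(x, ...) {
  cat("Synthetic template space\n")
  cat(sprintf("  grid: %s voxels at %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(x$voxel_mm, collapse = " x ")))
  cat(sprintf("  brain %d, white matter %d, ventricle %d, cortex %d voxels\n",
              sum(x$brain_mask), sum(x$wm_mask), sum(x$ventricle_mask),
              sum(x$cortex_mask)))
  cat(sprintf("  %d lobar sectors, %d vascular territories\n",
              length(setdiff(unique(as.vector(x$lobe_labels)), 0L)),
              length(setdiff(unique(as.vector(x$territory_labels)), 0L))))
  invisible(x)
}
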