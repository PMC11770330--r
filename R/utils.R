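# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators behave as pure
#' functions of their arguments.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-stage seed derived from a master seed; kept below 2^31.
derive_seed <- function(master_seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master_seed) * 48271 + h * 9973) %% 2147483563L) + 1L
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_binary_grid <- function(x) {
  is.array(x) && length(dim(x)) == 3L && all(x %in% c(0L, 1L))
}

check_same_grid <- function(a_dim, b_dim, what = "inputs") {
  stop_if(!identical(as.integer(a_dim), as.integer(b_dim)),
          sprintf("%s must share the same voxel grid (got %s vs %s)",
                  what, paste(a_dim, collapse = "x"),
                  paste(b_dim, collapse = "x")))
}

# Dirichlet sampler via normalized gammas; alpha recycled to length k.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(g)
  zero <- sw == 0
  if (any(zero)) { # all-underflow rows: fall back to argmax of alpha
    g[zero, which.max(alpha)] <- 1
    sw <- rowSums(g)
  }
  g / sw
}

# Coordinate arrays (mm, offsets from grid center) for a voxel grid.
grid_axes_mm <- function(shape, voxel_mm) {
  lapply(1:3, function(i) {
    (seq_len(shape[i]) - 1 - (shape[i] - 1) / 2) * voxel_mm[i]
  })
}

# Full 3-D coordinate arrays from per-axis center offsets.
coord_arrays <- function(shape, axes) {
  list(
    x = array(rep(axes[[1]], times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(axes[[2]], each = shape[1]), times = shape[3]),
              dim = shape),
    z = array(rep(axes[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}

# Boundary voxels of a binary mask (6-connectivity; includes grid-edge mask
# voxels). Returns an n x 3 integer matrix of 1-based voxel indices.
mask_boundary <- function(mask) {
  d <- dim(mask)
  m <- array(as.logical(mask), d)
  interior <- array(TRUE, d)
  pad_shift <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n;       idx_src[[ax]] <- 1:(n - 1) }
    else        { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    interior <- interior & pad_shift(ax, by)
  }
  which(m & !interior, arr.ind = TRUE)
}

# Euclidean distance (mm) from every voxel center to the nearest voxel of
# `mask` (distance 0 inside the mask). Exact, brute force against the mask
# boundary, chunked to bound memory; intended for the small grids used here.
distance_to_mask <- function(mask, voxel_mm, query = NULL) {
  d <- dim(mask)
  bnd <- mask_boundary(mask)
  stop_if(nrow(bnd) == 0L, "mask is empty; cannot compute distances")
  bmm <- sweep(bnd - 1, 2, voxel_mm, `*`)
  bsq <- rowSums(bmm^2)
  if (is.null(query)) {
    out <- array(0, d)
    qidx <- which(array(!as.logical(mask), d), arr.ind = TRUE)
  } else {
    out <- NULL
    qidx <- query
  }
  qmm <- sweep(qidx - 1, 2, voxel_mm, `*`)
  n <- nrow(qmm)
  res <- numeric(n)
  chunk <- max(1L, as.integer(2.5e6 / max(1L, nrow(bmm))))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    q <- qmm[i:j, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(bmm))) +
      outer(rep(1, nrow(q)), bsq) - 2 * (q %*% t(bmm))
    best <- max.col(-d2, ties.method = "first")
    res[i:j] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(d2)), best)]))
    i <- j + 1L
  }
  if (is.null(out)) return(res)
  out[qidx] <- res
  out
}

# Map 0-based voxel indices (n x 3) through a 4x4 voxel-to-mm affine.
voxel_to_mm <- function(idx0, affine) {
  t(affine[1:3, 1:3] %*% t(idx0) + affine[1:3, 4])
}

# Map mm coordinates (n x 3) to fractional 0-based voxel indices.
mm_to_voxel <- function(mm, affine) {
  H <- solve(affine)
  t(H[1:3, 1:3] %*% t(mm) + H[1:3, 4])
}

# Dice overlap of two binary grids (internal; used by tests and reports).
dice_overlap <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a * b) / (sa + sb)
}
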