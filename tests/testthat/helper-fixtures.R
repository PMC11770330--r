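# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env()

tiny_template <- function() {
  if (is.null(.fixtures$tpl))
    .fixtures$tpl <- make_template(c(20, 20, 20), c(4, 4, 4), seed = 11)
  .fixtures$tpl
}

tiny_atlas <- function() {
  if (is.null(.fixtures$atl))
    .fixtures$atl <- make_atlas(tiny_template(), n_tracts = 6,
                                streamlines_per_tract = 10, seed = 21)
  .fixtures$atl
}

random_mask <- function(template, seed, p = 0.1, kind = "infarct") {
  g <- array(0L, template$shape)
  set.seed(seed)
  g[template$brain_mask == 1L] <-
    rbinom(sum(template$brain_mask), 1L, p)
  lesion_mask(g, template$affine, sprintf("rand-%d", seed), kind)
}

# Per-voxel counting oracle for territory volumes (plain loop).
oracle_territory <- function(mask, template) {
  v <- abs(det(mask$affine[1:3, 1:3])) / 1000
  out <- numeric(10)
  for (i in which(mask$grid == 1L)) {
    t <- template$territory_labels[i]
    if (t > 0) out[t] <- out[t] + v
  }
  out
}

# Per-voxel counting oracle for bullseye parcel loads.
oracle_parcels <- function(mask, parc) {
  v <- abs(det(mask$affine[1:3, 1:3])) / 1000
  out <- numeric(36)
  for (i in which(mask$grid == 1L)) {
    p <- parc$labels[i]
    if (p > 0) out[p] <- out[p] + v
  }
  out
}

# Brute-force per-sample point-in-mask oracle for percent disconnection.
oracle_disconnection <- function(tract, mask, step_mm) {
  H <- solve(mask$affine)
  d <- dim(mask$grid)
  hits <- 0L
  for (p in tract$streamlines) {
    hit <- FALSE
    for (s in seq_len(nrow(p) - 1L)) {
      a <- p[s, ]; b <- p[s + 1L, ]
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      nstep <- max(1L, ceiling(L / step_mm))
      for (f in 0:nstep) {
        q <- a + (f / nstep) * (b - a)
        vx <- round(H[1:3, 1:3] %*% q + H[1:3, 4]) + 1
        if (all(vx >= 1) && all(vx <= d) &&
            mask$grid[vx[1], vx[2], vx[3]] == 1L) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    hits <- hits + hit
  }
  100 * hits / length(tract$streamlines)
}

mean_pairwise_dice <- function(masks) {
  n <- length(masks)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, disconnectr:::dice_overlap(masks[[i]]$grid,
                                               masks[[j]]$grid))
  }
  mean(vals, na.rm = TRUE)
}
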