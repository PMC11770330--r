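test_that("streamline rasterization walks the voxel grid correctly", {
  aff <- diag(4)  # 1 mm isotropic, 0-based voxel centers at integers
  shape <- c(8, 8, 8)
  # axis-aligned path from voxel center (0,0,0) to (4,0,0)
  r <- rasterize_streamline(rbind(c(0, 0, 0), c(4, 0, 0)), aff, shape, 1)
  expect_equal(unname(r[, 1]), 1:5)      # 1-based indices for 0-based 0..4
  expect_true(all(r[, 2:3] == 1))
  # streamline entirely outside the grid
  r2 <- rasterize_streamline(rbind(c(50, 50, 50), c(60, 50, 50)), aff,
                             shape, 1)
  expect_equal(nrow(r2), 0)
  # denser sampling can only add voxels, never lose them
  set.seed(33)
  for (i in 1:5) {
    pts <- matrix(runif(15, 0, 7), ncol = 3)
    coarse <- attr(rasterize_streamline(pts, aff, shape, 0.5), "linear")
    dense <- attr(rasterize_streamline(pts, aff, shape, 0.05), "linear")
    expect_true(all(coarse %in% dense))
  }
  expect_error(rasterize_streamline(rbind(c(0, 0, 0), c(1, 0, 0)),
                                    matrix(0, 4, 4), shape, 1),
               "degenerate")
  expect_error(rasterize_streamline(rbind(c(0, 0, 0), c(1, 0, 0)), aff,
                                    shape, 0), "positive")
})

test_that("percent disconnection counts streamlines through the mask", {
  aff <- diag(4)
  shape <- c(10, 10, 10)
  # 4 parallel streamlines in separate y-corridors
  tract <- list(name = "toy", streamlines = lapply(0:3, function(y) {
    cbind(seq(0, 9, by = 1), y * 2, 4)
  }))
  g <- array(0L, shape)
  g[, 1, 5] <- 1L  # covers only streamline #1 (y = 0 -> voxel row 1)
  mask <- lesion_mask(g, aff)
  expect_equal(tract_disconnection(tract, mask, step_mm = 0.5), 25)

  empty <- lesion_mask(array(0L, shape), aff)
  expect_equal(tract_disconnection(tract, empty, step_mm = 0.5), 0)
  full <- lesion_mask(array(1L, shape), aff)
  expect_equal(tract_disconnection(tract, full, step_mm = 0.5), 100)
  expect_error(tract_disconnection(list(name = "x", streamlines = list()),
                                   mask), "no streamlines")
})

test_that("profiles are monotone under mask growth and subadditive", {
  tpl <- tiny_template()
  atl <- tiny_atlas()
  mA <- random_mask(tpl, 61, p = 0.05)
  # B is a strict superset of A
  gB <- mA$grid
  gB[which(tpl$brain_mask == 1L)[1:200]] <- 1L
  mB <- lesion_mask(gB, tpl$affine)
  pA <- disconnection_profile(atl, mA)$pct
  pB <- disconnection_profile(atl, mB)$pct
  expect_true(all(pA <= pB + 1e-12))

  # disjoint masks: pct(A union B) <= pct(A) + pct(B)
  g1 <- random_mask(tpl, 62, p = 0.05)$grid
  g2 <- random_mask(tpl, 63, p = 0.05)$grid * (1L - g1)
  gu <- pmax(g1, g2)
  p1 <- disconnection_profile(atl, lesion_mask(g1, tpl$affine))$pct
  p2 <- disconnection_profile(atl, lesion_mask(g2, tpl$affine))$pct
  pu <- disconnection_profile(atl, lesion_mask(gu, tpl$affine))$pct
  expect_true(all(pu <= p1 + p2 + 1e-12))

  # empty mask gives the all-zero profile, in atlas order
  p0 <- disconnection_profile(atl, lesion_mask(array(0L, tpl$shape),
                                               tpl$affine))
  expect_equal(unname(p0$pct), rep(0, 6))
  expect_identical(names(p0$pct), atlas_tract_names(atl))
})

test_that("disconnection equals the brute-force point-in-mask oracle", {
  tpl <- tiny_template()
  atl <- tiny_atlas()
  step <- min(tpl$voxel_mm) / 2
  for (s in 1:3) {
    m <- random_mask(tpl, seed = 300 + s, p = 0.08)
    prof <- disconnection_profile(atl, m, step_mm = step)
    oracle <- vapply(atl$tracts, oracle_disconnection, numeric(1),
                     mask = m, step_mm = step)
    expect_equal(unname(prof$pct), oracle)
  }
})

test_that("the canonical tract registry carries 70 unique names", {
  reg <- canonical_registry()
  expect_length(reg, 70)
  expect_false(anyDuplicated(reg) > 0)
  expect_equal(sum(startsWith(reg, "corpus callosum")), 5)
  custom <- canonical_registry(callosal_names = paste0("cc_", 1:5))
  expect_length(custom, 70)
  expect_true(all(paste0("cc_", 1:5) %in% custom))
  expect_error(canonical_registry(callosal_names = c("a", "b")), "5")
})
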