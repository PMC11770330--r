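test_that("lesion volume follows the voxel-count x voxel-volume rule", {
  aff1 <- diag(c(1, 1, 1, 1))
  g <- array(0L, c(12, 12, 12))
  expect_equal(lesion_volume(lesion_mask(g, aff1)), 0)
  g[1:10, 1:10, 1:10] <- 1L
  expect_equal(lesion_volume(lesion_mask(g, aff1)), 1)       # 1000 x 1 mm^3
  aff2 <- diag(c(2, 2, 2, 1))
  g2 <- array(0L, c(5, 5, 5)); g2[] <- 1L                    # 125 voxels
  expect_equal(lesion_volume(lesion_mask(g2, aff2)), 1)      # 125 x 8 / 1000
  g2[1] <- 2L
  expect_error(lesion_mask(g2, aff2), "binary")
})

test_that("ICV normalization is the stated ratio and scale-equivariant", {
  expect_equal(normalize_volume(10, 1400, 1500), 10 * 1500 / 1400)
  expect_equal(normalize_volume(10, 1450, 1450), 10)
  expect_equal(normalize_volume(0, 1400, 1500), 0)
  expect_error(normalize_volume(10, 0, 1500), "positive")
  # equivariance in raw volume, inverse proportionality in subject ICV
  expect_equal(normalize_volume(30, 1400, 1500),
               3 * normalize_volume(10, 1400, 1500))
  expect_equal(normalize_volume(10, 2800, 1500),
               normalize_volume(10, 1400, 1500) / 2)
})

test_that("territory volumes match the per-voxel counting oracle", {
  tpl <- tiny_template()
  # containment: a mask inside one territory
  g <- array(0L, tpl$shape)
  idx <- which(tpl$territory_labels == 3L)[1:20]
  g[idx] <- 1L
  m <- lesion_mask(g, tpl$affine)
  tv <- territory_volumes(m, tpl)
  expect_equal(unname(tv$per_territory_cm3[3]), lesion_volume(m))
  expect_equal(sum(tv$per_territory_cm3[-3]), 0)
  expect_equal(tv$dominant, 3L)

  # saturation: whole brain
  mb <- lesion_mask(tpl$brain_mask, tpl$affine)
  tvb <- territory_volumes(mb, tpl)
  vox <- abs(det(tpl$affine[1:3, 1:3])) / 1000
  expect_equal(unname(tvb$per_territory_cm3),
               tabulate(tpl$territory_labels[tpl$territory_labels > 0],
                        10) * vox)

  # random masks equal the brute-force tally exactly
  for (s in 1:3) {
    mr <- random_mask(tpl, seed = 100 + s)
    tvr <- territory_volumes(mr, tpl)
    expect_equal(unname(tvr$per_territory_cm3), oracle_territory(mr, tpl))
  }

  # grid mismatch rejected
  small <- lesion_mask(array(0L, c(4, 4, 4)), tpl$affine)
  expect_error(territory_volumes(small, tpl), "grid")
})

test_that("incidence map is the voxelwise subject count", {
  tpl <- tiny_template()
  m1 <- random_mask(tpl, 1); m2 <- random_mask(tpl, 2)
  expect_identical(incidence_map(list(m1)), m1$grid)
  # disjoint masks peak at 1
  g2 <- m2$grid * (1L - m1$grid)
  m2d <- lesion_mask(g2, tpl$affine)
  expect_lte(max(incidence_map(list(m1, m2d))), 1)
  # N identical masks peak at N
  expect_equal(max(incidence_map(list(m1, m1, m1))), 3)
})
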