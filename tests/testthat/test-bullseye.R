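test_that("bullseye layers follow relative ventricle-to-cortex depth", {
  tpl <- tiny_template()
  parc <- bullseye_parcellation(tpl)
  wm <- tpl$wm_mask == 1L

  # partition: every white-matter voxel gets exactly one (lobe, layer) code
  expect_true(all(parc$labels[wm] >= 1 & parc$labels[wm] <= 36))
  expect_true(all(parc$labels[!wm] == 0))

  # voxels touching the ventricle are layer 1, those touching cortex layer 4
  layer <- (parc$labels - 1L) %% 4L + 1L
  near_vent <- wm & tpl$dist_ventricle <= min(tpl$voxel_mm)
  near_cort <- wm & tpl$dist_cortex <= min(tpl$voxel_mm)
  expect_true(all(layer[near_vent] == 1L))
  expect_true(all(layer[near_cort] == 4L))

  # layer codes consistent with the depth formula, half-open bins
  d <- tpl$dist_ventricle[wm] / (tpl$dist_ventricle[wm] + tpl$dist_cortex[wm])
  expect_identical(as.integer(layer[wm]), findInterval(d, parc$layer_edges) + 1L)

  expect_error(bullseye_parcellation(tpl, layer_edges = c(0.5, 0.25, 0.75)),
               "increasing")
})

test_that("parcel loads match the per-voxel oracle and sum correctly", {
  tpl <- tiny_template()
  parc <- bullseye_parcellation(tpl)

  empty <- lesion_mask(array(0L, tpl$shape), tpl$affine, kind = "wmh")
  expect_equal(unname(parcel_loads(empty, parc)), rep(0, 36))

  # mask = one full parcel concentrates its load there
  g <- array(0L, tpl$shape); g[parc$labels == 14L] <- 1L
  m14 <- lesion_mask(g, tpl$affine, kind = "wmh")
  pl14 <- parcel_loads(m14, parc)
  expect_equal(unname(pl14[14]), lesion_volume(m14))
  expect_equal(sum(pl14[-14]), 0)

  for (s in 1:3) {
    mr <- random_mask(tpl, seed = 200 + s, kind = "wmh")
    pl <- parcel_loads(mr, parc)
    expect_equal(unname(pl), oracle_parcels(mr, parc))
    # loads sum to the lesion volume restricted to labeled white matter
    inwm <- lesion_mask(mr$grid * (parc$labels > 0), tpl$affine, kind = "wmh")
    expect_equal(sum(pl), lesion_volume(inwm))
  }
})
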