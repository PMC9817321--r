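test_that("threshold_mask is an exact per-voxel window selection", {
  u <- ct_volume(array(-1000L, dim = c(5, 5, 5)), spacing = c(1, 1, 1))
  expect_true(all(threshold_mask(u, tlv_window())$voxels))
  z <- ct_volume(array(0L, dim = c(5, 5, 5)), spacing = c(1, 1, 1))
  expect_false(any(threshold_mask(z, tlv_window())$voxels))

  set.seed(4)
  vox <- array(as.integer(sample(-1024:400, 32^3, replace = TRUE)), dim = c(32, 32, 32))
  vol <- ct_volume(vox, spacing = c(1, 1, 1))
  got <- threshold_mask(vol, flv_window())$voxels
  # independent brute-force comparison, voxel by voxel
  want <- array(FALSE, dim = dim(vox))
  for (i in seq_along(vox)) {
    want[i] <- vox[i] >= -910 && vox[i] <= -600
  }
  expect_identical(got, want)
})

test_that("widening a threshold window never removes voxels", {
  set.seed(5)
  vol <- ct_volume(
    array(as.integer(sample(-1024:200, 20^3, replace = TRUE)), dim = c(20, 20, 20)),
    spacing = c(1, 1, 1)
  )
  narrow <- threshold_mask(vol, threshold_window(-900, -650))$voxels
  wide <- threshold_mask(vol, threshold_window(-1000, -500))$voxels
  expect_true(all(wide[narrow]))
})

test_that("airway segmentation recovers the tracheal column on the phantom", {
  ph <- small_phantom()
  airway <- segment_airway(ph$ct)
  # independent cylinder rasterisation from the generating geometry
  spec <- ph$spec
  d <- spec$dim
  si <- (seq_len(d[1]) - 0.5) * spec$spacing[1]
  ap <- (seq_len(d[2]) - 0.5) * spec$spacing[2]
  rl <- (seq_len(d[3]) - 0.5) * spec$spacing[3]
  in_plane <- outer(
    (ap - spec$trachea$center[1])^2,
    (rl - spec$trachea$center[2])^2, "+"
  ) <= spec$trachea$radius^2
  truth <- outer(si <= spec$trachea$length, in_plane, "&")
  dice <- 2 * sum(airway$voxels & truth) / (sum(airway$voxels) + sum(truth))
  expect_gte(dice, 0.90)
  # the grown airway must not leak into the lung parenchyma
  lung <- ph$lobes$voxels > 0
  expect_lte(sum(airway$voxels & lung) / sum(lung), 0.01)
})

test_that("a phantom without a trachea raises airway-not-found", {
  ph <- build_phantom(lungs_only_spec())
  expect_error(segment_airway(ph$ct), class = "lungflv_airway_not_found")
  # explicit seed on a soft-tissue voxel (mediastinum) is rejected too
  expect_error(
    segment_airway(small_phantom()$ct, seed = c(48, 32, 48)),
    class = "lungflv_airway_not_found"
  )
})

test_that("lung extraction matches the phantom ground truth", {
  ph <- small_phantom()
  airway <- segment_airway(ph$ct)
  tlv <- extract_lungs(ph$ct, airway)
  truth_ml <- sum(ph$truth$per_lobe$total_ml)
  expect_lt(abs(mask_volume_ml(tlv) - truth_ml) / truth_ml, 0.02)
  expect_false(any(tlv$voxels & airway$voxels))
})

test_that("voxels face-connected to the grid boundary are treated as exterior", {
  # two lung-density boxes in a body block: one touches the superior face and
  # must be removed with the exterior air, the interior one survives
  arr <- array(40L, dim = c(24, 24, 24))
  arr[1:6, 9:14, 9:14] <- -800L # touches slice 1
  arr[14:19, 9:14, 9:14] <- -800L # interior
  vol <- ct_volume(arr, spacing = c(2, 2, 2))
  empty <- mask_volume(array(FALSE, dim = dim(arr)), spacing = c(2, 2, 2))
  tlv <- extract_lungs(vol, empty, min_component_ml = 0.5)
  expect_false(any(tlv$voxels[1:6, , ]))
  expect_true(all(tlv$voxels[14:19, 9:14, 9:14]))
})

test_that("the leak guard stops slice-tripling growth while descending", {
  # air column whose area explodes 16-fold at slice 9
  arr <- array(40L, dim = c(16, 20, 20))
  arr[1:8, 10:11, 10:11] <- -1000L
  arr[9:16, 4:17, 4:17] <- -1000L
  vol <- ct_volume(arr, spacing = c(2, 2, 2))
  expect_message(
    airway <- segment_airway(vol, seed = c(1, 10, 10)),
    "leak guard"
  )
  expect_true(all(airway$voxels[1:8, 10:11, 10:11]))
  expect_false(any(airway$voxels[9:16, , ]))
})

test_that("functional mask is the window intersection and a subset of TLV", {
  ph <- small_phantom()
  airway <- segment_airway(ph$ct)
  tlv <- extract_lungs(ph$ct, airway)
  flv <- functional_mask(ph$ct, tlv)
  expect_true(all(tlv$voxels[flv$voxels])) # FLV subset of TLV
  brute <- tlv$voxels & ph$ct$voxels >= -910 & ph$ct$voxels <= -600
  expect_identical(flv$voxels, brute)
  # class fractions: FLV/TLV tracks 1 - non-functional fraction
  ratio <- mask_volume_ml(flv) / mask_volume_ml(tlv)
  expect_lt(abs(ratio - (1 - ph$truth$nonfunctional_fraction)), 0.02)
})

test_that("an all-parenchyma phantom has FLV equal to TLV", {
  ph <- build_phantom(lungs_only_spec(hu_sd = 5))
  empty <- mask_volume(array(FALSE, dim = dim(ph$ct$voxels)),
    spacing = ph$ct$spacing
  )
  tlv <- extract_lungs(ph$ct, empty)
  flv <- functional_mask(ph$ct, tlv)
  expect_identical(flv$voxels, tlv$voxels)
})

test_that("connected-component labelling agrees with a reference flood fill", {
  set.seed(6)
  m <- array(runif(10^3) < 0.35, dim = c(10, 10, 10))
  lab26 <- label_components(m, 26)
  lab6 <- label_components(m, 6)
  expect_identical(lab26 > 0, m)
  expect_identical(lab6 > 0, m)
  # neighbouring selected voxels must share a label at their connectivity
  idx <- which(m, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    for (j in seq_len(nrow(offs))) {
      q <- p + offs[j, ]
      if (any(q < 1) || any(q > 10) || !m[q[1], q[2], q[3]]) next
      expect_identical(lab26[q[1], q[2], q[3]], lab26[p[1], p[2], p[3]])
      if (sum(abs(offs[j, ])) == 1) {
        expect_identical(lab6[q[1], q[2], q[3]], lab6[p[1], p[2], p[3]])
      }
    }
  }
  # 6-connectivity splits what only touches diagonally
  two <- array(FALSE, dim = c(3, 3, 3))
  two[1, 1, 1] <- TRUE
  two[2, 2, 2] <- TRUE
  expect_identical(max(label_components(two, 6)), 2L)
  expect_identical(max(label_components(two, 26)), 1L)
})
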