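test_that("downsampling averages in-plane blocks and doubles the spacing", {
  # 0/10 checkerboard plane collapses to its block mean of 5
  v <- array(0, c(4L, 4L, 2L))
  v[] <- outer(outer(1:4, 1:4, "+"), 1:2, function(xy, z) xy) %% 2 * 10
  vol <- suv_volume(v, c(2.7, 2.7, 2.79), "standard")
  red <- downsample_inplane(vol)
  expect_true(all(red$values == 5))
  expect_equal(red$spacing, c(5.4, 5.4, 2.79))
  expect_identical(red$grid_label, "reduced")

  # uniform volume unchanged
  u <- suv_volume(array(3, c(6L, 6L, 3L)), c(2.7, 2.7, 2.79), "standard")
  expect_true(all(downsample_inplane(u)$values == 3))
})

test_that("downsampling conserves total uptake and never raises SUVmax", {
  set.seed(501)
  for (i in 1:10) {
    v <- array(runif(16 * 16 * 6, 0, 12), c(16L, 16L, 6L))
    vol <- suv_volume(v, c(2.7, 2.7, 2.79), "standard")
    red <- downsample_inplane(vol)
    expect_equal(sum(red$values) * prod(red$spacing),
                 sum(vol$values) * prod(vol$spacing))
    expect_lte(max(red$values), max(vol$values))
  }
  # odd dimensions are padded with a message
  vodd <- suv_volume(array(1, c(5L, 5L, 2L)), c(2.7, 2.7, 2.79), "standard")
  expect_message(downsample_inplane(vodd), "padding")
})

test_that("segmentation thresholds at 41% of the VOI SUVmax", {
  vol <- make_phantom(tumor_suv = 10, background = 0.5)
  seg <- segment_tumor(vol, full_voi(vol))
  expect_equal(seg$threshold_suv, 4.1)
  # uniform SUV-8 sphere on 0.5 background: mask is exactly the sphere
  vol8 <- make_phantom(tumor_suv = 8, background = 0.5)
  seg8 <- segment_tumor(vol8, full_voi(vol8))
  expect_identical(seg8$mask, vol8$values == 8)
  expect_error(segment_tumor(vol, list(lo = c(1, 1, 1), hi = c(200, 10, 10))),
               "box")
  zero <- suv_volume(array(0, c(8L, 8L, 8L)), c(2.7, 2.7, 2.79), "standard")
  expect_error(segment_tumor(zero, full_voi(zero)), "positive voxel")
})

test_that("only the peak-containing connected component survives", {
  dims <- c(40L, 40L, 20L)
  sp <- c(2.7, 2.7, 2.79)
  vol <- make_phantom(dims, sp, semi_axes = c(8, 8, 8),
                      center_mm = c(25, 25, 28), tumor_suv = 10)
  # second, dimmer blob far away inside the same VOI
  blob2 <- make_phantom(dims, sp, semi_axes = c(8, 8, 8),
                        center_mm = c(80, 80, 28), tumor_suv = 7)
  v <- pmax(vol$values, blob2$values)
  both <- suv_volume(v, sp, "standard")
  seg <- segment_tumor(both, full_voi(both))
  # blob2 voxels are above threshold (7 > 4.1) but disconnected from the peak
  expect_true(all(v[seg$mask] == 10))
  expect_identical(sum(seg$mask), sum(v == 10))
  # segmentation invariant: min(masked) >= 0.41 * max(masked)
  expect_gte(min(v[seg$mask]), 0.41 * max(v[seg$mask]))
})

test_that("segmentation invariant holds on random textured phantoms", {
  spec <- cohort_spec(n_patients = 6, seed = 61)
  for (i in 1:6) {
    ph <- generate_pet_volume(spec, i)
    seg <- segment_tumor(ph$volume, ph$voi)
    vals <- ph$volume$values[seg$mask]
    expect_gte(min(vals), 0.41 * max(vals) - 1e-12)
    expect_true(seg$mask[seg$peak[1], seg$peak[2], seg$peak[3]])
  }
})

test_that("first-order features follow their closed forms", {
  # 1000 masked voxels at the standard spacing give MTV 20.339 mL
  v <- array(0.5, c(20L, 20L, 10L))
  v[1:10, 1:10, 1:10] <- 6  # 1000 voxels
  vol <- suv_volume(v, c(2.7, 2.7, 2.79), "standard")
  seg <- segment_tumor(vol, full_voi(vol))
  f <- first_order_features(vol, seg)
  expect_identical(f$n_voxels, 1000L)
  expect_equal(f$mtv, 1000 * 2.7 * 2.7 * 2.79 / 1000)
  expect_equal(f$mtv, 20.3391, tolerance = 1e-6)
  expect_equal(f$suv_max, 6)
  expect_equal(f$suv_mean, 6)
  expect_equal(f$tlg, f$mtv * f$suv_mean)
})

test_that("TLG identity holds to machine precision on textured tumors", {
  spec <- cohort_spec(n_patients = 4, seed = 62)
  for (i in 1:4) {
    ph <- generate_pet_volume(spec, i)
    seg <- segment_tumor(ph$volume, ph$voi)
    f <- first_order_features(ph$volume, seg)
    expect_equal(f$tlg / f$suv_mean, f$mtv, tolerance = 1e-14)
    expect_lte(f$suv_mean, f$suv_max)
  }
})

test_that("intensity entropy respects the 0.25-SUV bin structure", {
  v <- array(0.5, c(12L, 12L, 6L))
  v[3:8, 3:8, 2:5] <- 7
  vol <- suv_volume(v, c(2.7, 2.7, 2.79), "standard")
  seg <- segment_tumor(vol, full_voi(vol))
  # uniform tumor: single level, entropy is the -log2(1+eps) residual
  expect_lt(abs(compute_pet_entropy(vol, seg)), 1e-10)

  # half the voxels at 1.1, half at 1.4: distinct bins, 1 bit
  n_mask <- sum(seg$mask)
  two <- v
  idx <- which(seg$mask)
  two[idx[seq_len(n_mask %/% 2)]] <- 7.1
  two[idx[(n_mask %/% 2 + 1):n_mask]] <- 7.4
  vol2 <- suv_volume(two, c(2.7, 2.7, 2.79), "standard")
  expect_equal(compute_pet_entropy(vol2, seg), 1.0, tolerance = 1e-9)

  # 1.00 and 1.10 share the [1.00, 1.25) bin: entropy collapses to ~0
  three <- v
  three[idx[seq_len(n_mask %/% 2)]] <- 7.00
  three[idx[(n_mask %/% 2 + 1):n_mask]] <- 7.10
  vol3 <- suv_volume(three, c(2.7, 2.7, 2.79), "standard")
  expect_lt(abs(compute_pet_entropy(vol3, seg)), 1e-10)

  # upper bound: H <= log2(Ng) plus the epsilon residual
  spec <- cohort_spec(n_patients = 2, seed = 63)
  ph <- generate_pet_volume(spec, 1)
  segp <- segment_tumor(ph$volume, ph$voi)
  vals <- ph$volume$values[segp$mask]
  ng <- length(unique(floor(vals / 0.25)))
  expect_lte(compute_pet_entropy(ph$volume, segp), log2(ng) + 1e-9)
})

test_that("feature sets segment each grid independently and pair up for ICC", {
  spec <- cohort_spec(n_patients = 3, seed = 64)
  ph <- generate_pet_volume(spec, 1)
  fs <- pet_feature_sets(ph$volume, ph$voi)
  expect_identical(fs$grid_label, c("standard", "reduced"))
  expect_lte(fs$suv_max[2], fs$suv_max[1])
  # uniform tumor: both entropies ~0
  spec0 <- cohort_spec(n_patients = 2, seed = 64, texture_amplitude = 0)
  ph0 <- generate_pet_volume(spec0, 1)
  fs0 <- pet_feature_sets(ph0$volume, ph0$voi)
  expect_lt(abs(fs0$entropy[1]), 1e-10)
  # the derived reduced grid mixes tumor and background in rim blocks, so a
  # handful of partial-volume levels survive; entropy stays far below the
  # textured-cohort range (~4.5 bits) but is not exactly zero
  expect_lt(fs0$entropy[2], 1.5)
})
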