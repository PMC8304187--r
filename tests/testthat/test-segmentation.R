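make_box_case <- function(tumor_suv = 10, bg_suv = 0) {
  arr <- array(bg_suv, c(8, 8, 8))
  arr[3:6, 3:6, 3:6] <- tumor_suv
  voi <- array(FALSE, c(8, 8, 8)); voi[2:7, 2:7, 2:7] <- TRUE
  bg <- array(FALSE, c(8, 8, 8)); bg[1, , ] <- TRUE
  list(vol = suv_volume(arr, c(4, 4, 4)), voi = voi, bg = bg)
}

test_that("the adaptive threshold reduces to 0.3 x tumor SUV for a uniform lesion on zero background", {
  cs <- make_box_case(10, 0)
  seg <- nestle_threshold(cs$vol, cs$voi, cs$bg)
  expect_equal(seg$threshold, 3.0)
  # entire uniform VOI interior is above threshold; zero voxels excluded
  expect_true(all(seg$tumor_mask[3:6, 3:6, 3:6]))
  expect_equal(seg$n_voxels, 64)
})

test_that("threshold is 0.3 x hot-voxel mean + background mean", {
  # lesion with two intensity tiers: hot voxels (> 70% of max = 7.7) mean 10
  arr <- array(1, c(8, 8, 8))                  # background level 1
  arr[3:6, 3:6, 3:6] <- 6                      # below 0.7 * 11 = 7.7
  arr[4:5, 4:5, 4:5] <- c(rep(9, 4), rep(11, 4))  # hot tier, mean 10
  voi <- array(FALSE, c(8, 8, 8)); voi[3:6, 3:6, 3:6] <- TRUE
  bg <- array(FALSE, c(8, 8, 8)); bg[1, , ] <- TRUE
  vol <- suv_volume(arr, c(4, 4, 4))
  seg <- nestle_threshold(vol, voi, bg)
  expect_equal(seg$hot_mean, 10)
  expect_equal(seg$background_mean, 1)
  expect_equal(seg$threshold, 4.0)             # 0.3 * 10 + 1
  expect_true(all(vol$data[seg$tumor_mask] >= 4.0))
})

test_that("threshold and mask match a brute-force enumeration on 50 random phantoms", {
  for (s in 1:50) {
    cs <- random_voi_case(s)
    seg <- nestle_threshold(cs$volume, cs$voi, cs$bg)
    orc <- oracle_nestle(cs$volume$data, cs$voi, cs$bg)
    expect_equal(seg$threshold, orc$threshold, tolerance = 1e-12)
    expect_identical(seg$tumor_mask, orc$tumor)
    # invariant: threshold formula to 1e-9 relative error
    expect_equal(seg$threshold,
                 0.3 * seg$hot_mean + seg$background_mean,
                 tolerance = 1e-9)
  }
})

test_that("raising the background by a constant raises the threshold by exactly that constant", {
  cs <- random_voi_case(99)
  seg0 <- nestle_threshold(cs$volume, cs$voi, cs$bg)
  arr2 <- cs$volume$data
  arr2[cs$bg] <- arr2[cs$bg] + 0.7
  seg1 <- nestle_threshold(suv_volume(arr2, cs$volume$spacing), cs$voi, cs$bg)
  expect_equal(seg1$threshold, seg0$threshold + 0.7, tolerance = 1e-12)
})

test_that("intensity rescaling scales threshold, marrow and liver SUV but not BLR", {
  ph <- generate_phantom(small_phantom_spec(seed = 5))
  voi <- dilate_mask(ph$truth$tumor_mask, 2L)
  bg <- default_background_mask(ph$volume, voi)
  seg0 <- nestle_threshold(ph$volume, voi, bg)
  mm0 <- measure_bone_marrow(ph$volume, ph$truth$vertebra_masks,
                             ph$truth$liver_mask)
  k <- 2.5
  vol_k <- suv_volume(ph$volume$data * k, ph$volume$spacing)
  seg1 <- nestle_threshold(vol_k, voi, bg)
  mm1 <- measure_bone_marrow(vol_k, ph$truth$vertebra_masks,
                             ph$truth$liver_mask)
  expect_equal(seg1$threshold, k * seg0$threshold, tolerance = 1e-12)
  expect_identical(seg1$tumor_mask, seg0$tumor_mask)
  expect_equal(mm1$bm_suv, k * mm0$bm_suv, tolerance = 1e-12)
  expect_equal(mm1$liver_suv, k * mm0$liver_suv, tolerance = 1e-12)
  expect_equal(mm1$blr, mm0$blr, tolerance = 1e-12)
})

test_that("a background hotter than the lesion produces an explicit empty-tumor error", {
  cs <- make_box_case(2, 0)
  cs$vol$data[1, , ] <- 10                      # scorching background
  expect_error(nestle_threshold(cs$vol, cs$voi, cs$bg), "threshold")
})

test_that("isocontour mean handles uniform, enumerated and single-voxel VOIs", {
  d <- c(4, 4, 4)
  vol <- suv_volume(array(2, d), c(4, 4, 4))
  voi <- array(FALSE, d); voi[1:2, 1, 1] <- TRUE
  expect_equal(isocontour_mean(vol, voi, 0.75), 2.0)

  arr <- array(0.1, d); arr[1:3, 1, 1] <- c(2.0, 1.6, 1.4)
  voi3 <- array(FALSE, d); voi3[1:3, 1, 1] <- TRUE
  expect_equal(isocontour_mean(suv_volume(arr, c(4, 4, 4)), voi3, 0.75), 1.8)

  voi1 <- array(FALSE, d); voi1[2, 2, 2] <- TRUE
  arr1 <- array(0, d); arr1[2, 2, 2] <- 3.7
  expect_equal(isocontour_mean(suv_volume(arr1, c(4, 4, 4)), voi1, 0.5), 3.7)

  expect_error(isocontour_mean(vol, voi, 0), "fraction")
  expect_error(isocontour_mean(vol, voi, 1.2), "fraction")
})

test_that("isocontour mean never falls below the plain VOI mean", {
  for (s in 1:10) {
    cs <- random_voi_case(200 + s)
    plain <- mean(cs$volume$data[cs$voi])
    for (f in c(0.25, 0.5, 0.75, 1)) {
      expect_gte(isocontour_mean(cs$volume, cs$voi, f), plain)
    }
  }
})

test_that("bone-marrow measurement averages vertebrae and divides by liver mean", {
  d <- c(20, 6, 6)
  arr <- array(0, d)
  verts <- lapply(1:6, function(i) {
    m <- array(FALSE, d); m[3 * i - 2, 2, 2] <- TRUE; m
  })
  means <- c(1.2, 1.4, 1.6, 1.8, 2.0, 2.2)
  for (i in 1:6) arr[verts[[i]]] <- means[i]
  liver <- array(FALSE, d); liver[19:20, 5, 5] <- TRUE
  arr[liver] <- 2.0
  vol <- suv_volume(arr, c(4, 4, 4))
  mm <- measure_bone_marrow(vol, verts, liver)
  expect_equal(mm$vertebra_suv, means)
  expect_equal(mm$bm_suv, 1.7)
  expect_equal(mm$blr, 0.85)

  # homogeneous case: everything 1.0
  arr1 <- array(0, d)
  for (i in 1:6) arr1[verts[[i]]] <- 1
  arr1[liver] <- 1
  mm1 <- measure_bone_marrow(suv_volume(arr1, c(4, 4, 4)), verts, liver)
  expect_equal(mm1$bm_suv, 1.0)
  expect_equal(mm1$blr, 1.0)

  # five vertebrae after excluding a degenerate one
  arr5 <- array(0, d)
  for (i in 1:5) arr5[verts[[i]]] <- i
  arr5[liver] <- 1
  mm5 <- measure_bone_marrow(suv_volume(arr5, c(4, 4, 4)), verts[1:5], liver)
  expect_equal(mm5$bm_suv, 3.0)

  expect_error(measure_bone_marrow(vol, list(), liver), "vertebral")
  arr0 <- array(0, d); arr0[verts[[1]]] <- 1
  expect_error(measure_bone_marrow(suv_volume(arr0, c(4, 4, 4)),
                                   verts[1], liver), "BLR")
})
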