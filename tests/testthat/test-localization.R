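test_that("binarization thresholds act on the min-max rescaled brain range", {
  nr <- 20; nc <- 20
  brain <- matrix(FALSE, nr, nc); brain[3:18, 3:18] <- TRUE
  sl <- matrix(0, nr, nc)
  sl[brain] <- seq(0, 1, length.out = sum(brain))  # linear ramp
  m07 <- binarize_modality(sl, brain, 0.7)
  # per-pixel oracle
  v <- sl[brain]
  oracle <- (v - min(v)) / (max(v) - min(v)) > 0.7
  expect_equal(m07[brain], oracle)
  expect_false(any(m07[!brain]))
  # monotonicity: higher threshold is a subset
  m09 <- binarize_modality(sl, brain, 0.9)
  expect_true(all(which(m09) %in% which(m07)))
  # degenerate constant slice -> empty mask, not an error
  slc <- matrix(0, nr, nc); slc[brain] <- 0.5
  expect_false(any(binarize_modality(slc, brain, 0.7)))
  expect_false(any(binarize_modality(sl, matrix(FALSE, nr, nc), 0.7)))
})

test_that("connected components are 8-connected and specks are removed", {
  m <- matrix(FALSE, 40, 40)
  m[5, 5] <- TRUE; m[6, 6] <- TRUE; m[7, 7] <- TRUE  # diagonal chain
  cfg <- localization_config(opening_radius = 0, small_object_floor = 1)
  obj <- clean_and_measure(m, cfg)
  expect_length(obj, 1)      # one object under 8-connectivity
  expect_equal(obj[[1]]$area, 3)
  # 3-px speck removed by the floor
  expect_length(clean_and_measure(m, localization_config(
    opening_radius = 0, small_object_floor = 10)), 0)
  expect_length(clean_and_measure(matrix(FALSE, 5, 5)), 0)
})

test_that("a filled square has the analytic shape properties", {
  m <- matrix(FALSE, 60, 60)
  m[11:40, 16:45] <- TRUE  # 30x30 filled square
  obj <- clean_and_measure(m, localization_config(opening_radius = 0,
                                                  small_object_floor = 1))
  expect_length(obj, 1)
  o <- obj[[1]]
  expect_equal(o$area, 900)
  expect_equal(o$solidity, 1.0)
  # ellipse-of-inertia major axis of a filled square of side 30:
  # 4 * sqrt((30^2 - 1) / 12)
  expect_equal(o$major_axis_length, 4 * sqrt((900 - 1) / 12), tolerance = 1e-10)
  expect_gt(o$major_axis_length, 30)
  expect_equal(unname(o$centroid), c(25.5, 30.5))
  expect_equal(unname(o$bbox), c(11, 16, 30, 30))
  # opening with the default disk only rounds the square's corners
  obj2 <- clean_and_measure(m, localization_config())
  expect_gte(obj2[[1]]$area, 880)
  expect_lte(obj2[[1]]$area, 900)
})

test_that("the three object rules are strict and order-independent", {
  mk <- function(solidity, area, axis) {
    list(label_id = 1L, area = area, solidity = solidity,
         major_axis_length = axis, bbox = c(1, 1, 1, 1),
         centroid = c(1, 1), pixels = cbind(1, 1))
  }
  cfg <- localization_config()
  grid <- expand.grid(sol = c(0.69, 0.7, 0.71),
                      area = c(499, 500, 501),
                      axis = c(34, 35, 36))
  for (i in seq_len(nrow(grid))) {
    o <- mk(grid$sol[i], grid$area[i], grid$axis[i])
    kept <- length(filter_t1ce_objects(list(o), cfg)) == 1
    expect_identical(kept, grid$sol[i] > 0.7 && grid$area[i] > 500 &&
                       grid$axis[i] > 35,
                     info = paste(grid[i, ], collapse = "/"))
  }
  # idempotence
  objs <- lapply(seq_len(nrow(grid)), function(i)
    mk(grid$sol[i], grid$area[i], grid$axis[i]))
  once <- filter_t1ce_objects(objs, cfg)
  expect_identical(filter_t1ce_objects(once, cfg), once)
})

test_that("fusion multiplies FLAIR and T2 and applies the strict overlap rule", {
  nr <- 64
  flair <- disk_mask(nr, nr, 30, 30, 12)
  t2 <- disk_mask(nr, nr, 32, 30, 12)
  product <- flair & t2
  cfg <- localization_config(small_object_floor = 5)
  # T1ce object overlapping the product by exactly 20 px: excluded
  prod_idx <- which(product, arr.ind = TRUE)
  inside <- prod_idx[1:20, , drop = FALSE]
  outside <- which(!product & !flair & !t2, arr.ind = TRUE)[1:30, ]
  o20 <- list(label_id = 1L, area = 50L, solidity = 1, major_axis_length = 40,
              bbox = c(1, 1, 1, 1), centroid = c(10, 10),
              pixels = rbind(inside, outside))
  det <- fuse_slice(flair, t2, list(o20), cfg, slice_index = 1L)
  expect_equal(sum(det$fused_mask), sum(product))
  # 21 px overlap: included
  o21 <- o20; o21$pixels <- rbind(prod_idx[1:21, ], outside)
  det21 <- fuse_slice(flair, t2, list(o21), cfg, slice_index = 1L)
  expect_equal(sum(det21$fused_mask), sum(product | {
    m <- matrix(FALSE, nr, nr); m[o21$pixels] <- TRUE; m
  }))
  # empty FLAIR kills the product and hence any T1ce contribution
  det0 <- fuse_slice(matrix(FALSE, nr, nr), t2, list(o21), cfg, 1L)
  expect_false(any(det0$fused_mask))
})

test_that("tracking finds the planted biggest slice and rejects the decoy", {
  spec <- small_phantom_spec(seed = 31)
  s <- generate_phantom(spec)
  zstar <- spec$tumor_center[3]
  # oracle: argmax of the planted per-slice tumor area
  areas <- apply(s$labels > 0, 3, sum)
  expect_equal(which.max(areas), zstar)
  cfg <- small_loc_config()
  norm <- zscore_subject(s)
  det <- detect_slices(norm, s$brain_mask, cfg)
  area <- track_and_find_biggest(det, cfg)
  expect_equal(area$biggest_slice, zstar)
  # the decoy artifact slice holds a larger bright object than the tumor
  # there, but has no sequential support
  art_slice <- spec$artifact$slice
  art_objs <- det[[art_slice]]$objects
  expect_gt(length(art_objs), 1)  # artifact + tumor both detected
  d_art <- sqrt((area$biggest_object$centroid[1] - spec$artifact$center[1])^2 +
                  (area$biggest_object$centroid[2] - spec$artifact$center[2])^2)
  expect_gt(d_art, spec$artifact$radius)  # winner is not the decoy
  # no detections at all -> localization failure error
  empty <- lapply(1:5, function(z)
    fuse_slice(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8), list(), cfg, z))
  expect_error(track_and_find_biggest(empty, cfg), "localization failure")
})

test_that("expected-area masks dilate, shrink monotonically and cover the tumor", {
  spec <- small_phantom_spec(seed = 32)
  s <- generate_phantom(spec)
  cfg <- small_loc_config()
  area <- localize_subject(s, cfg)
  zstar <- area$biggest_slice
  masks <- area$per_slice_masks
  # dilation superset: mask at the biggest slice strictly contains the object
  obj_px <- area$biggest_object$pixels
  expect_true(all(masks[, , zstar][obj_px]))
  expect_gt(sum(masks[, , zstar]), area$biggest_object$area)
  # biggest slice has the maximal mask
  sizes <- apply(masks, 3, sum)
  expect_equal(which.max(sizes), zstar)
  # coverage of planted tumor voxels
  gt <- s$labels > 0
  expect_gte(sum(masks & gt) / sum(gt), 0.99)
  # each nonempty mask is one connected region
  for (z in which(sizes > 0)) {
    expect_equal(max(cascadeseg:::cpp_label8(masks[, , z])), 1)
  }
})

test_that("localization is deterministic", {
  s <- generate_phantom(small_phantom_spec(seed = 33))
  a1 <- localize_subject(s, small_loc_config())
  a2 <- localize_subject(s, small_loc_config())
  expect_identical(a1$per_slice_masks, a2$per_slice_masks)
  expect_identical(a1$biggest_slice, a2$biggest_slice)
})
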