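test_that("label remapping is a bijection over the used labels", {
  m <- class_map()
  expect_equal(unname(m$raw_to_index[as.character(c(0, 1, 2, 4))]), 0:3)
  raw <- array(c(0L, 1L, 2L, 4L), dim = c(2, 2, 1))
  idx <- remap_labels(raw)
  expect_equal(as.vector(idx), 0:3)
  expect_identical(unmap_labels(idx), raw)
  # round trip over a random volume of used labels
  set.seed(5)
  v <- array(sample(c(0L, 1L, 2L, 4L), 200, TRUE), dim = c(10, 10, 2))
  expect_identical(unmap_labels(remap_labels(v)), v)
})

test_that("unused raw label 3 maps to background with a warning", {
  v <- array(c(0L, 3L, 4L, 2L), dim = c(4, 1, 1))
  expect_warning(out <- remap_labels(v), "label 3")
  expect_equal(as.vector(out), c(0L, 0L, 3L, 2L))
  expect_error(remap_labels(array(5L, dim = c(1, 1, 1))), "outside")
  expect_equal(as.vector(remap_labels(array(0L, c(2, 2, 1)))), rep(0L, 4))
})

test_that("brain mask is the nonzero union and is rescale-invariant", {
  set.seed(2)
  d <- c(12, 12, 4)
  flair <- array(0, d); t1 <- array(0, d); t1ce <- array(0, d); t2 <- array(0, d)
  ell <- array(FALSE, d)
  for (z in 1:4) ell[, , z] <- disk_mask(12, 12, 6, 6, 4)
  flair[ell] <- runif(sum(ell), 0.2, 1)
  t1[ell] <- runif(sum(ell), 0.2, 1)
  t1ce[ell] <- runif(sum(ell), 0.2, 1)
  t2[ell] <- runif(sum(ell), 0.2, 1)
  bm <- brain_mask(flair, t1, t1ce, t2)
  # oracle: brute-force scan for any-modality-nonzero voxels
  oracle <- sum(flair != 0 | t1 != 0 | t1ce != 0 | t2 != 0)
  expect_equal(sum(bm), oracle)
  expect_equal(sum(bm), sum(ell))
  expect_identical(brain_mask(10 * flair, 0.3 * t1, t1ce, 7 * t2), bm)
})

test_that("subject construction rejects shape mismatches", {
  a <- array(1, c(8, 8, 3)); b <- array(1, c(8, 8, 4))
  expect_error(subject_volumes(a, a, a, b), "share one shape")
  expect_error(subject_volumes(a, a, a, a, labels = array(0L, c(8, 8, 4))),
               "shape")
  expect_silent(s <- subject_volumes(a, a, a, a))
  expect_equal(dim(s$brain_mask), c(8, 8, 3))
})

test_that("NIfTI save/load of a segmentation round-trips bit-exactly", {
  set.seed(9)
  d <- c(16L, 16L, 5L)
  arr <- array(runif(prod(d), 0.1, 1), d)
  s <- subject_volumes(arr, arr, arr, arr, voxel_spacing = c(1, 1, 1))
  seg <- array(sample(0:3, prod(d), TRUE), d)
  path <- tempfile(fileext = ".nii.gz")
  save_segmentation(seg, s, path)
  back <- RNifti::readNifti(path)
  expect_identical(array(as.integer(back), d), unmap_labels(seg))
  expect_true(all(as.integer(back) %in% c(0L, 1L, 2L, 4L)))
  # all-background segmentation writes an all-zero file
  save_segmentation(array(0L, d), s, path)
  expect_equal(sum(RNifti::readNifti(path) != 0), 0)
  expect_error(save_segmentation(array(0L, c(2, 2, 2)), s, path), "shape")
})

test_that("load_subject reads a manifest-style subject and checks shapes", {
  dir <- tempfile(); dir.create(dir)
  d <- c(20L, 20L, 6L)
  set.seed(3)
  mk <- function(name, dd = d) {
    p <- file.path(dir, name)
    RNifti::writeNifti(RNifti::asNifti(array(runif(prod(dd), 0.1, 1), dd)), p)
    p
  }
  paths <- list(flair = mk("f.nii.gz"), t1 = mk("t1.nii.gz"),
                t1ce = mk("t1ce.nii.gz"), t2 = mk("t2.nii.gz"))
  lab <- file.path(dir, "lab.nii.gz")
  RNifti::writeNifti(
    RNifti::asNifti(array(sample(c(0, 1, 2, 4), prod(d), TRUE), d)), lab)
  s <- load_subject(paths, lab)
  expect_s3_class(s, "subject_volumes")
  expect_equal(dim(s$flair), d)
  expect_true(all(s$labels %in% c(0L, 1L, 2L, 4L)))
  # shape mismatch across modalities errors
  paths_bad <- paths; paths_bad$t2 <- mk("bad.nii.gz", c(20L, 20L, 7L))
  expect_error(load_subject(paths_bad), "share one shape")
  expect_error(load_subject(list(flair = "nope.nii", t1 = paths$t1,
                                 t1ce = paths$t1ce, t2 = paths$t2)),
               "missing")
})
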