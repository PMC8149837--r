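mask3 <- function(idx, d = c(8, 8, 4)) {
  m <- array(FALSE, d); m[idx] <- TRUE; m
}

test_that("Dice matches its closed forms and conventions", {
  a <- mask3(1:50); b <- mask3(1:50)
  expect_equal(dice(a, b), 1.0)
  expect_equal(dice(mask3(1:30), mask3(31:60)), 0.0)
  # |P|=100, |A|=50, overlap 25 -> 1/3
  expect_equal(dice(mask3(1:100), mask3(c(1:25, 101:125))), 1 / 3)
  # both empty -> 1 by convention
  expect_equal(dice(mask3(integer(0)), mask3(integer(0))), 1.0)
  # symmetry
  set.seed(3)
  p <- mask3(sample(256, 40)); g <- mask3(sample(256, 60))
  expect_equal(dice(p, g), dice(g, p))
  expect_error(dice(array(TRUE, c(2, 2, 2)), array(TRUE, c(2, 2, 3))),
               "mismatch")
})

test_that("sensitivity matches its closed forms", {
  g <- mask3(1:50)
  expect_equal(sensitivity(mask3(1:80), g), 1.0)     # P contains A
  expect_equal(sensitivity(mask3(51:80), g), 0.0)    # disjoint
  expect_equal(sensitivity(mask3(c(1:25, 101:150)), g), 0.5)
  expect_true(is.na(sensitivity(mask3(1:5), mask3(integer(0)))))
})

test_that("adding a true-positive voxel never lowers dice or sensitivity", {
  set.seed(41)
  g <- mask3(sample(256, 70))
  p <- mask3(sample(which(g), 20))
  missing <- setdiff(which(g), which(p))
  for (k in head(missing, 10)) {
    p2 <- p; p2[k] <- TRUE
    expect_gte(dice(p2, g), dice(p, g))
    expect_gte(sensitivity(p2, g), sensitivity(p, g))
    p <- p2
  }
})

test_that("percentile Hausdorff distance matches an exhaustive oracle", {
  d <- c(12, 12, 12)
  a <- array(FALSE, d); a[4, 4, 4] <- TRUE
  b <- array(FALSE, d); b[4, 4, 7] <- TRUE  # offset 3 along z
  expect_equal(hausdorff_pct(a, b, percentile = 100), 3.0)
  expect_equal(hausdorff_pct(a, a, percentile = 100), 0.0)
  # exhaustive pairwise surface-distance oracle on small random masks
  set.seed(43)
  p <- array(FALSE, d); p[3:6, 3:5, 2:4] <- TRUE
  g <- array(FALSE, d); g[5:9, 4:7, 3:6] <- TRUE
  surf <- function(m) {
    w <- which(m, arr.ind = TRUE)
    keep <- apply(w, 1, function(v) {
      for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
        q <- v + s
        if (any(q < 1) || any(q > d)) return(TRUE)
        if (!m[q[1], q[2], q[3]]) return(TRUE)
      }
      FALSE
    })
    w[keep, , drop = FALSE]
  }
  sp <- surf(p); sg <- surf(g)
  all_d <- c(
    apply(sp, 1, function(v) min(sqrt(colSums((t(sg) - v)^2)))),
    apply(sg, 1, function(v) min(sqrt(colSums((t(sp) - v)^2))))
  )
  for (pc in c(50, 95, 100)) {
    expect_equal(hausdorff_pct(p, g, percentile = pc),
                 as.numeric(quantile(all_d, pc / 100)))
  }
  # symmetry and spacing scaling
  expect_equal(hausdorff_pct(p, g, 99), hausdorff_pct(g, p, 99))
  expect_equal(hausdorff_pct(a, b, 100, spacing = c(1, 1, 2.5)), 7.5)
  expect_warning(hd <- hausdorff_pct(a, array(FALSE, d)), "empty")
  expect_equal(hd, Inf)
})

test_that("per-region evaluation binarizes by BRATS label sets", {
  rs <- region_specs()
  expect_true(all(rs$Enh %in% rs$Core) && all(rs$Core %in% rs$Whole))
  d <- c(10, 10, 6)
  set.seed(47)
  gt <- array(0L, d)
  gt[2:5, 2:5, 2:4] <- 2L; gt[3:4, 3:4, 2:4] <- 4L; gt[3, 3, 3] <- 1L
  # perfect prediction
  res <- evaluate_subject(gt, gt, subject_id = "s1")
  expect_equal(res$dice, rep(1, 3))
  expect_equal(res$sensitivity, rep(1, 3))
  expect_equal(res$hausdorff_mm, rep(0, 3))
  # hand-counted overlap case on the whole-tumor region
  pred <- gt
  pred[2, 2:5, 2] <- 0L  # remove 4 whole-tumor voxels
  res2 <- evaluate_subject(pred, gt, subject_id = "s1")
  wt <- res2[res2$region == "Whole", ]
  n_gt <- sum(gt > 0); n_pred <- sum(pred > 0)
  expect_equal(wt$dice, 2 * n_pred / (n_pred + n_gt))  # pred subset of gt
  expect_equal(wt$sensitivity, n_pred / n_gt)
  # ground truth without enhancing tumor -> NA sensitivity for Enh
  gt2 <- gt; gt2[gt2 == 4L] <- 2L
  pred2 <- gt2
  res3 <- evaluate_subject(pred2, gt2, subject_id = "s2")
  enh <- res3[res3$region == "Enh", ]
  expect_true(is.na(enh$sensitivity))
  expect_equal(enh$dice, 1.0)  # both empty
  expect_true(is.na(enh$hausdorff_mm))
})
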