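rand_patch_set <- function(n, seed = 1, labels = NULL) {
  set.seed(seed)
  structure(list(
    global = array(rnorm(40 * 40 * 8 * n), c(40, 40, 8, n)),
    local = array(rnorm(15 * 15 * 8 * n), c(15, 15, 8, n)),
    dwa = runif(n),
    label = if (is.null(labels)) sample(0:3, n, TRUE) else labels,
    centers = NULL, subject_id = "toy"
  ), class = "patch_set")
}

test_that("forward pass produces normalized, seed-deterministic probabilities", {
  m <- init_cascade(model_config(), seed = 2)
  ps <- rand_patch_set(12, seed = 3)
  fwd <- cascade_forward(m, ps$global, ps$local, ps$dwa)
  expect_equal(dim(fwd$prob), c(12L, 4L))
  expect_true(all(fwd$prob >= 0 & fwd$prob <= 1))
  expect_lt(max(abs(rowSums(fwd$prob) - 1)), 1e-6)
  # same seed -> same initialization -> identical outputs
  m2 <- init_cascade(model_config(), seed = 2)
  fwd2 <- cascade_forward(m2, ps$global, ps$local, ps$dwa)
  expect_identical(fwd$prob, fwd2$prob)
})

test_that("disabling DWA shrinks the FC input width by exactly one", {
  m_on <- init_cascade(model_config(dwa_enabled = TRUE), seed = 1)
  m_off <- init_cascade(model_config(dwa_enabled = FALSE), seed = 1)
  expect_equal(nrow(m_on$params$fc1$W) - nrow(m_off$params$fc1$W), 1L)
  count <- function(m) sum(vapply(m$params,
                                  function(p) length(p$W) + length(p$b), 1))
  expect_equal(count(m_on) - count(m_off), m_on$config$fc_width)
})

test_that("the cross-entropy loss matches its closed forms", {
  # uniform scores -> ln 4
  u <- matrix(0, 1, 4)
  expect_equal(cascade_loss(u, 0L)$loss, log(4), tolerance = 1e-9)
  expect_equal(cascade_loss(matrix(5, 1, 4), 2L)$loss, log(4),
               tolerance = 1e-9)
  # dominant true-class score -> loss near 0
  expect_lt(cascade_loss(matrix(c(50, 0, 0, 0), 1), 0L)$loss, 1e-12)
  # hand-evaluated case via independent softmax computation
  sc <- matrix(c(2, 1, 0, -1), 1)
  expect_equal(cascade_loss(sc, 0L)$loss,
               -log(exp(2) / sum(exp(c(2, 1, 0, -1)))),
               tolerance = 1e-12)
  expect_error(cascade_loss(matrix(c(NaN, 1, 1, 1), 1), 0L), "non-finite")
})

test_that("the analytic score gradient matches finite differences", {
  set.seed(29)
  worst <- 0
  for (i in 1:100) {
    sc <- matrix(rnorm(4, sd = 2), 1, 4)
    lab <- sample(0:3, 1)
    g <- cascade_loss(sc, lab)$grad
    h <- 1e-6
    for (j in 1:4) {
      sp <- sc; sp[j] <- sp[j] + h
      sm <- sc; sm[j] <- sm[j] - h
      fd <- (cascade_loss(sp, lab)$loss - cascade_loss(sm, lab)$loss) / (2 * h)
      worst <- max(worst, abs(fd - g[j]))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training is reproducible, and zero epochs is the identity", {
  ps <- rand_patch_set(8, seed = 5)
  m <- init_cascade(model_config(), seed = 7)
  t0 <- train_cascade(m, ps, train_config(epochs = 0L, seed = 1))
  expect_identical(t0$params, m$params)
  t1 <- train_cascade(m, ps, train_config(epochs = 2L, seed = 1))
  t2 <- train_cascade(m, ps, train_config(epochs = 2L, seed = 1))
  expect_identical(t1$params, t2$params)
  expect_false(identical(t1$params, m$params))
})

test_that("the model learns a separable two-class toy problem", {
  n <- 48
  set.seed(31)
  labels <- rep(c(0L, 1L), each = n / 2)
  ps <- rand_patch_set(n, seed = 31, labels = labels)
  # class signal: constant offset in every channel
  for (i in seq_len(n)) {
    off <- if (labels[i] == 0L) -1 else 1
    ps$global[, , , i] <- ps$global[, , , i] * 0.1 + off
    ps$local[, , , i] <- ps$local[, , , i] * 0.1 + off
  }
  m <- init_cascade(model_config(), seed = 11)
  tm <- train_cascade(m, ps, train_config(lr = 1e-3, epochs = 25L,
                                          batch_size = 8L, seed = 13))
  expect_lt(tail(tm$loss_curve, 1), head(tm$loss_curve, 1))
  prob <- predict_cascade(tm, ps)
  acc <- mean((max.col(prob) - 1L) == labels)
  expect_gte(acc, 0.99)
})

test_that("dense slice inference equals the patch-based forward pass", {
  set.seed(37)
  m <- init_cascade(model_config(), seed = 17)
  H <- 64L; W <- 64L; pad <- 20L
  slice <- array(rnorm(H * W * 8), c(H, W, 8))
  padded <- array(0, c(H + 2 * pad, W + 2 * pad, 8))
  padded[pad + 1:H, pad + 1:W, ] <- slice
  ctr <- cbind(sample(H, 60, TRUE), sample(W, 60, TRUE))
  dense <- cascadeseg:::dense_slice_forward(m, padded)
  p_dense <- cascadeseg:::dense_predict_centers(m, dense, ctr, 0.42)
  stack <- array(slice, c(H, W, 1L, 8L))
  n <- nrow(ctr)
  xg <- array(0, c(40, 40, 8, n)); xl <- array(0, c(15, 15, 8, n))
  for (i in seq_len(n)) {
    xg[, , , i] <- extract_patch(stack, c(ctr[i, ], 1L), 40L)
    xl[, , , i] <- extract_patch(stack, c(ctr[i, ], 1L), 15L)
  }
  fwd <- cascade_forward(m, xg, xl, rep(0.42, n))
  expect_lt(max(abs(p_dense - fwd$prob)), 1e-10)
})

test_that("segmentation respects the expected-area support", {
  s <- generate_phantom(small_phantom_spec(seed = 43))
  area <- localize_subject(s, small_loc_config())
  m <- init_cascade(model_config(), seed = 19)
  # force the model to always output class 2 (edema)
  m$params$fc2$W[] <- 0
  m$params$fc2$b <- c(0, 0, 10, 0)
  seg <- segment_volume(m, s, area)
  expect_true(all(seg[!area$per_slice_masks] == 0L))
  expect_true(all(seg[area$per_slice_masks] == 2L))
  # forced background -> all-zero volume
  m$params$fc2$b <- c(10, 0, 0, 0)
  seg0 <- segment_volume(m, s, area)
  expect_true(all(seg0 == 0L))
  # empty expected area -> warning + all-zero segmentation
  empty <- array(FALSE, dim(s$flair))
  expect_warning(segz <- segment_volume(m, s, empty), "empty")
  expect_true(all(segz == 0L))
})
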