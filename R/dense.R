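# Dense (fully-convolutional) inference engine.
#
# Classifying every voxel of a slice with the patch network repeats
# almost all convolution work between neighboring centers. The dense
# engine instead runs each route's convolution stack once over the whole
# zero-padded slice and recovers the exact per-center features by
# bookkeeping: a valid 3x3 convolution is shift-equivariant, and each
# 2x2 max-pooling splits centers into two phases per axis, so after the
# two pooling stages the global route needs 4x4 = 16 phase variants of
# the deeper maps ("shift-and-stitch"). Per center, the flattened
# features are then a small window gather from the dense maps, followed
# by the fully-connected head. The result is numerically identical to
# the patch-based forward pass.

# Valid 3x3 convolution of an (H, W, C) array as nine shifted
# submatrix-matmul accumulations (BLAS-friendly, no index gather).
# Wmat rows are ordered (ki fastest, then kj, then channel), matching
# conv_geom().
dense_conv <- function(x, Wmat, b, relu = TRUE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  oH <- H - 2L; oW <- W - 2L
  F <- ncol(Wmat)
  out <- matrix(rep(b, each = oH * oW), oH * oW, F)
  for (kj in 0:2) {
    for (ki in 0:2) {
      rows <- ki + 3L * kj + 9L * (0:(C - 1L)) + 1L
      blk <- x[(1L + ki):(oH + ki), (1L + kj):(oW + kj), , drop = FALSE]
      dim(blk) <- c(oH * oW, C)
      out <- out + blk %*% Wmat[rows, , drop = FALSE]
    }
  }
  if (relu) out[out < 0] <- 0
  dim(out) <- c(oH, oW, F)
  out
}

# 2x2 max-pooling of an (H, W, C) array at a given phase (0 or 1) per
# axis: pooled pairs start at row/col phase+1.
dense_pool_phase <- function(x, py, px) {
  d <- dim(x)
  nt <- (d[1] - py) %/% 2L
  nu <- (d[2] - px) %/% 2L
  i1 <- seq.int(py + 1L, by = 2L, length.out = nt)
  j1 <- seq.int(px + 1L, by = 2L, length.out = nu)
  pmax(pmax(x[i1, j1, , drop = FALSE], x[i1 + 1L, j1, , drop = FALSE]),
       pmax(x[i1, j1 + 1L, , drop = FALSE], x[i1 + 1L, j1 + 1L, , drop = FALSE]))
}

# Run both routes densely over one padded slice. Returns the 4x4 global
# phase variants of the final global map and the dense local map.
dense_slice_forward <- function(model, padded) {
  p <- model$params
  d2 <- dense_conv(dense_conv(padded, p$g1$W, p$g1$b), p$g2$W, p$g2$b)
  # variant index m4 = 2*phase2 + phase1 per axis
  d5 <- rep(list(vector("list", 4L)), 4L)
  for (p1y in 0:1) {
    for (p1x in 0:1) {
      p1 <- dense_pool_phase(d2, p1y, p1x)
      d4 <- dense_conv(dense_conv(p1, p$g4$W, p$g4$b), p$g5$W, p$g5$b)
      for (p2y in 0:1) {
        for (p2x in 0:1) {
          p2 <- dense_pool_phase(d4, p2y, p2x)
          m4y <- 2L * p2y + p1y
          m4x <- 2L * p2x + p1x
          d5[[m4y + 1L]][[m4x + 1L]] <-
            dense_conv(p2, p$g7$W, p$g7$b)
        }
      }
    }
  }
  dl2 <- dense_conv(dense_conv(padded, p$l1$W, p$l1$b), p$l2$W, p$l2$b)
  list(d5 = d5, dl2 = dl2)
}

# Classify a set of centers (1-based (y, x) in the unpadded slice) from
# the dense maps. dwa is one scalar shared by all centers of the slice.
dense_predict_centers <- function(model, dense, centers, dwa) {
  cfg <- model$config
  n <- nrow(centers)
  gf5 <- cfg$global_filters[5]
  lf2 <- cfg$local_filters[2]
  dl <- dense$dl2
  nr_l <- dim(dl)[1]
  loffs <- as.vector(outer(rep(0:10, 11) + rep(0:10, each = 11) * nr_l,
                           (0:(lf2 - 1L)) * nr_l * dim(dl)[2], `+`))
  ay0 <- centers[, 1] - 1L
  ax0 <- centers[, 2] - 1L
  m4y <- ay0 %% 4L; m4x <- ax0 %% 4L
  s0y <- ay0 %/% 4L; s0x <- ax0 %/% 4L
  prob <- matrix(0, n, cfg$n_classes)
  dlvec <- as.vector(dl)
  for (vy in 0:3) {
    for (vx in 0:3) {
      ids <- which(m4y == vy & m4x == vx)
      if (!length(ids)) next
      d5 <- dense$d5[[vy + 1L]][[vx + 1L]]
      nr5 <- dim(d5)[1]
      goffs <- as.vector(outer(rep(0:4, 5) + rep(0:4, each = 5) * nr5,
                               (0:(gf5 - 1L)) * nr5 * dim(d5)[2], `+`))
      gbase <- s0y[ids] + s0x[ids] * nr5
      gfeat <- matrix(as.vector(d5)[outer(goffs, gbase, `+`) + 1L],
                      length(goffs), length(ids))
      lbase <- (ay0[ids] + 13L) + (ax0[ids] + 13L) * nr_l
      lfeat <- matrix(dlvec[outer(loffs, lbase, `+`) + 1L],
                      length(loffs), length(ids))
      feats <- cbind(t(gfeat), t(lfeat))
      if (cfg$dwa_enabled) feats <- cbind(feats, dwa)
      h <- feats %*% model$params$fc1$W +
        rep(model$params$fc1$b, each = length(ids))
      h[h < 0] <- 0
      scores <- h %*% model$params$fc2$W +
        rep(model$params$fc2$b, each = length(ids))
      e <- exp(scores - apply(scores, 1, max))
      prob[ids, ] <- e / rowSums(e)
    }
  }
  prob
}
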