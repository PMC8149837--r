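#' Segment a subject's volume with a trained cascade model
#'
#' Every voxel whose expected-area mask is TRUE is classified by the
#' cascade CNN (argmax class); voxels outside the expected area are
#' normal tissue (0). The result is deterministic given the model and
#' input. Patch extraction is batched per slice over a zero-padded copy
#' of the slice, which reproduces the per-center zero-padded gather
#' exactly.
#'
#' @param model trained `cascade_model`.
#' @param subject a [subject_volumes()].
#' @param area an `expected_area` with masks filled (or any 3D logical
#'   mask to classify inside).
#' @param norm optional precomputed [zscore_subject()].
#' @param batch_size forward batch size (patch engine only).
#' @param engine "dense" shares convolution work across a whole slice
#'   (fast, numerically identical); "patch" runs the patch network per
#'   center and is kept as the reference path.
#' @return integer array of class indices 0..3 (use [unmap_labels()] for
#'   raw labels).
#' @export
segment_volume <- function(model, subject, area, norm = NULL,
                           batch_size = 128L,
                           engine = c("dense", "patch")) {
  engine <- match.arg(engine)
  d <- dim(subject$flair)
  mask3 <- if (inherits(area, "expected_area")) area$per_slice_masks else area
  seg <- array(0L, dim = d)
  if (!any(mask3)) {
    warning("empty expected area; returning an all-background segmentation")
    return(seg)
  }
  if (is.null(norm)) norm <- zscore_subject(subject)
  stack <- channel_stack(subject, norm)
  dwa <- if (inherits(area, "expected_area")) dwa_volume(subject, area) else {
    v <- rep(NA_real_, d[3])
    for (z in seq_len(d[3])) {
      em <- mask3[, , z]
      if (!any(em)) next
      masks <- list(subject$flair[, , z] != 0, subject$t1[, , z] != 0,
                    subject$t1ce[, , z] != 0, subject$t2[, , z] != 0)
      v[z] <- dwa_for_slice(masks, em, slice_index = z)$mean_distance
    }
    v
  }
  cfg <- model$config
  pad <- cfg$global_size %/% 2L
  Hp <- d[1] + 2L * pad; Wp <- d[2] + 2L * pad
  goffs <- patch_offsets(cfg$global_size, cfg$n_channels, Hp, Wp, pad)
  loffs <- patch_offsets(cfg$local_size, cfg$n_channels, Hp, Wp, pad)
  for (z in seq_len(d[3])) {
    m <- mask3[, , z]
    if (!any(m)) next
    ctr <- which(m, arr.ind = TRUE)
    padded <- array(0, dim = c(Hp, Wp, cfg$n_channels))
    padded[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- stack[, , z, ]
    pv <- as.vector(padded)
    pred <- integer(nrow(ctr))
    if (engine == "dense") {
      dense <- dense_slice_forward(model, padded)
      prob <- dense_predict_centers(model, dense, ctr, dwa[z])
      pred <- max.col(prob, ties.method = "first") - 1L
    } else {
      base <- (ctr[, 1] - 1L) + (ctr[, 2] - 1L) * Hp  # pad == global half
      for (start in seq(1, nrow(ctr), by = batch_size)) {
        ids <- start:min(start + batch_size - 1L, nrow(ctr))
        xg <- pv[outer(goffs, base[ids], `+`)]
        xl <- pv[outer(loffs, base[ids], `+`)]
        fwd <- cascade_forward(model, xg, xl,
                               rep(dwa[z], length(ids)), train = FALSE)
        pred[ids] <- max.col(fwd$prob, ties.method = "first") - 1L
      }
    }
    sl <- matrix(0L, d[1], d[2])
    sl[ctr] <- pred
    seg[, , z] <- sl
  }
  seg
}

# 1-based element offsets of a size x size x C patch inside a padded
# (Hp, Wp, C) slice, relative to the base index of the patch center's
# (row-1, col-1) position in the unpadded frame. pad must equal the
# global patch half-size so that base = (y-1) + (x-1)*Hp.
patch_offsets <- function(size, C, Hp, Wp, pad) {
  half <- size %/% 2L
  pi <- rep(0:(size - 1L), times = size * C)
  pj <- rep(rep(0:(size - 1L), each = size), times = C)
  cc <- rep(0:(C - 1L), each = size * size)
  (pad - half + pi) + (pad - half + pj) * Hp + cc * Hp * Wp + 1L
}
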