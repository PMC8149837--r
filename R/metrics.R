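#' Tumor region specifications
#'
#' Regions follow the standard BRATS conventions: enhancing tumor
#' (Enh, raw label 4), tumor core (Core, necrosis + enhancing, labels
#' {1, 4}) and whole tumor (Whole, all tumor labels {1, 2, 4}); edema
#' (label 2) is excluded from the core. As label sets,
#' Enh is a subset of Core is a subset of Whole.
#'
#' @return named list of raw-label vectors.
#' @export
region_specs <- function() {
  list(Enh = 4L, Whole = c(1L, 2L, 4L), Core = c(1L, 4L))
}

#' Dice similarity coefficient
#'
#' `2 |P intersect A| / (|P| + |A|)`; defined as 1 when both masks are
#' empty. Symmetric in its arguments.
#'
#' @param pred,gt logical arrays of one shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("mask shape mismatch")
  np <- sum(pred); na <- sum(gt)
  if (np + na == 0) return(1.0)
  2 * sum(pred & gt) / (np + na)
}

#' Sensitivity (recall, true positive rate)
#'
#' `|P intersect A| / |A|`; NA when the ground truth is empty.
#'
#' @param pred,gt logical arrays of one shape.
#' @return scalar in [0, 1], or NA.
#' @export
sensitivity <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("mask shape mismatch")
  na <- sum(gt)
  if (na == 0) return(NA_real_)
  sum(pred & gt) / na
}

# Surface voxels: mask voxels with at least one 6-neighbor (or image
# border) outside the mask.
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, dy, dx, dz) {
    sh <- array(FALSE, dim = d)
    ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
    sy <- ys + dy; sx <- xs + dx; sz <- zs + dz
    ok_y <- sy >= 1 & sy <= d[1]; ok_x <- sx >= 1 & sx <= d[2]
    ok_z <- sz >= 1 & sz <= d[3]
    sh[ys[ok_y], xs[ok_x], zs[ok_z]] <- mask[sy[ok_y], sx[ok_x], sz[ok_z]]
    acc & sh
  }
  interior <- shift_and(interior, 1, 0, 0)
  interior <- shift_and(interior, -1, 0, 0)
  interior <- shift_and(interior, 0, 1, 0)
  interior <- shift_and(interior, 0, -1, 0)
  interior <- shift_and(interior, 0, 0, 1)
  interior <- shift_and(interior, 0, 0, -1)
  which(mask & !interior, arr.ind = TRUE)
}

# Directed nearest-surface distances (mm) from each point of a to b,
# chunked brute force.
directed_surface_dists <- function(a, b, spacing) {
  a <- sweep(a, 2, spacing, `*`)
  b <- sweep(b, 2, spacing, `*`)
  out <- numeric(nrow(a))
  chunk <- max(1L, floor(2e7 / nrow(b)))
  bt <- t(b)
  bsq <- colSums(bt^2)
  for (start in seq(1, nrow(a), by = chunk)) {
    ids <- start:min(start + chunk - 1L, nrow(a))
    am <- a[ids, , drop = FALSE]
    d2 <- outer(rowSums(am^2), bsq, `+`) - 2 * am %*% bt
    out[ids] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Symmetric percentile Hausdorff surface distance
#'
#' Pools the directed nearest-surface distances in both directions
#' (prediction surface to ground-truth surface and vice versa) and takes
#' the given percentile of the pooled set, scaled by the voxel spacing —
#' the standard robust-Hausdorff construction (HD95-style) at the 99th
#' percentile by default. Symmetric under swapping the masks; +Inf with
#' a warning when either mask is empty.
#'
#' @param pred,gt logical 3D arrays.
#' @param percentile percentile in (0, 100].
#' @param spacing voxel spacing in mm (length 3).
#' @return distance in mm.
#' @export
hausdorff_pct <- function(pred, gt, percentile = 99, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(gt))) stop("mask shape mismatch")
  if (!any(pred) || !any(gt)) {
    warning("empty mask in Hausdorff computation; returning Inf")
    return(Inf)
  }
  sp <- surface_voxels(pred)
  sg <- surface_voxels(gt)
  d_pg <- directed_surface_dists(sp, sg, spacing)
  d_gp <- directed_surface_dists(sg, sp, spacing)
  as.numeric(quantile(c(d_pg, d_gp), percentile / 100, type = 7))
}

#' Evaluate a predicted label volume against ground truth
#'
#' Computes Dice, sensitivity and the percentile Hausdorff distance for
#' each tumor region (Enh, Whole, Core) after binarizing both volumes by
#' the region's raw-label set. Regions absent from the ground truth give
#' NA sensitivity/Hausdorff (and Dice 1 only if also absent from the
#' prediction).
#'
#' @param pred,gt integer arrays with raw labels in {0, 1, 2, 4}.
#' @param spacing voxel spacing in mm.
#' @param percentile Hausdorff percentile.
#' @param subject_id carried into the output.
#' @return data.frame with one row per region: subject, region, dice,
#'   sensitivity, hausdorff_mm.
#' @export
evaluate_subject <- function(pred, gt, spacing = c(1, 1, 1),
                             percentile = 99, subject_id = "subject") {
  stopifnot(identical(dim(pred), dim(gt)))
  specs <- region_specs()
  rows <- lapply(names(specs), function(rg) {
    pm <- array(pred %in% specs[[rg]], dim = dim(pred))
    gm <- array(gt %in% specs[[rg]], dim = dim(gt))
    hd <- if (any(pm) && any(gm)) {
      hausdorff_pct(pm, gm, percentile, spacing)
    } else NA_real_
    data.frame(subject = subject_id, region = rg,
               dice = dice(pm, gm),
               sensitivity = sensitivity(pm, gm),
               hausdorff_mm = hd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
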