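#' Object center from run counts (distance-wise attention geometry)
#'
#' The object's width is the maximum over rows of that row's true-pixel
#' count and its height is the maximum over columns of that column's
#' true-pixel count (run counts, not bounding-box extents — the two
#' differ for concave objects). The starting point (y0, x0) is the
#' minimal row/column index holding a true pixel, and the center is
#' `yc = y0 + H/2`, `xc = x0 + W/2`, kept as floats. Coordinates are
#' 0-based.
#'
#' @param mask nonempty 2D logical mask.
#' @return list with `y0`, `x0`, `H_object`, `W_object`, `yc`, `xc`.
#' @export
object_center <- function(mask) {
  if (!any(mask)) stop("object_center: empty mask")
  row_counts <- rowSums(mask)
  col_counts <- colSums(mask)
  W <- max(row_counts)   # widest row
  H <- max(col_counts)   # tallest column
  y0 <- min(which(row_counts > 0)) - 1  # 0-based
  x0 <- min(which(col_counts > 0)) - 1
  list(y0 = y0, x0 = x0, H_object = H, W_object = W,
       yc = y0 + H / 2, xc = x0 + W / 2)
}

#' Normalized center distance between two masks
#'
#' Euclidean distance between the two [object_center()] centers, divided
#' by the number of rows of the image. Translation-equivariant and
#' symmetric in its two arguments.
#'
#' @param modality_mask,expected_mask nonempty 2D logical masks.
#' @param n_rows number of image rows (defaults to
#'   `nrow(modality_mask)`).
#' @return nonnegative scalar; at most sqrt(2) for square slices.
#' @export
slice_distance <- function(modality_mask, expected_mask,
                           n_rows = nrow(modality_mask)) {
  a <- object_center(modality_mask)
  b <- object_center(expected_mask)
  sqrt((a$xc - b$xc)^2 + (a$yc - b$yc)^2) / n_rows
}

#' Distance-wise attention value for one slice
#'
#' Computes the normalized center distance between each modality's binary
#' brain mask (the nonzero support of the modality on that slice, i.e.
#' the full brain silhouette) and the expected-area mask, and returns
#' their mean. A modality with an empty mask on this slice is dropped
#' from the mean with a flag; if all four are empty the maximal prior
#' distance 1.0 is returned with a warning.
#'
#' @param modality_masks list of four 2D logical masks (flair, t1, t1ce,
#'   t2 order by convention).
#' @param expected_mask nonempty 2D logical expected-area mask.
#' @param slice_index bookkeeping only.
#' @return list of class `dwa_value` with `per_modality_distance`
#'   (length 4, NA where empty), `mean_distance`, `n_used`,
#'   `slice_index`.
#' @export
dwa_for_slice <- function(modality_masks, expected_mask,
                          slice_index = NA_integer_) {
  if (!any(expected_mask)) stop("dwa_for_slice: empty expected mask")
  d <- vapply(modality_masks, function(m) {
    if (!any(m)) return(NA_real_)
    slice_distance(m, expected_mask, n_rows = nrow(expected_mask))
  }, numeric(1))
  used <- sum(!is.na(d))
  if (used == 0) {
    warning("all modality masks empty on slice ", slice_index,
            "; using maximal prior distance 1.0")
    mean_d <- 1.0
  } else {
    mean_d <- mean(d, na.rm = TRUE)
  }
  structure(list(per_modality_distance = d, mean_distance = mean_d,
                 n_used = used, slice_index = slice_index),
            class = "dwa_value")
}

#' Distance-wise attention values for every expected-area slice
#'
#' @param subject a [subject_volumes()] (for the modality supports).
#' @param area an `expected_area` with masks filled.
#' @return numeric vector of length `n_slices`; NA for slices with an
#'   empty expected-area mask.
#' @export
dwa_volume <- function(subject, area) {
  nz <- dim(subject$flair)[3]
  out <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    em <- area$per_slice_masks[, , z]
    if (!any(em)) next
    masks <- list(subject$flair[, , z] != 0, subject$t1[, , z] != 0,
                  subject$t1ce[, , z] != 0, subject$t2[, , z] != 0)
    out[z] <- dwa_for_slice(masks, em, slice_index = z)$mean_distance
  }
  out
}
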