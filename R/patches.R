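#' Stack the eight input channels of a subject
#'
#' Channel order is fixed: raw FLAIR, T1, T1ce, T2, then their z-scored
#' counterparts.
#'
#' @param subject a [subject_volumes()].
#' @param norm a [zscore_subject()] result for the same subject.
#' @return 4D array (rows, cols, slices, 8).
#' @export
channel_stack <- function(subject, norm) {
  d <- dim(subject$flair)
  out <- array(0, dim = c(d, 8L))
  out[, , , 1] <- subject$flair; out[, , , 2] <- subject$t1
  out[, , , 3] <- subject$t1ce;  out[, , , 4] <- subject$t2
  out[, , , 5] <- norm$flair;    out[, , , 6] <- norm$t1
  out[, , , 7] <- norm$t1ce;     out[, , , 8] <- norm$t2
  out
}

#' Extract one multi-channel square patch around a center voxel
#'
#' The patch may extend past the image border (zero-padded) and past the
#' expected area; only its center must lie inside the expected area when
#' `expected_mask` is supplied. For even sizes the center voxel sits at
#' patch index `size/2 + 1` (i.e. offset `size %/% 2`, 0-based), a fixed
#' convention.
#'
#' @param stack 4D channel stack from [channel_stack()].
#' @param center integer (y, x, z), 1-based.
#' @param size patch side length.
#' @param expected_mask optional 3D logical; when given, an off-mask
#'   center is an error.
#' @return array (size, size, n_channels).
#' @export
extract_patch <- function(stack, center, size, expected_mask = NULL) {
  d <- dim(stack)
  y <- center[1]; x <- center[2]; z <- center[3]
  if (!is.null(expected_mask) && !expected_mask[y, x, z]) {
    stop("patch center lies outside the expected area")
  }
  half <- size %/% 2
  ys <- (y - half):(y - half + size - 1)
  xs <- (x - half):(x - half + size - 1)
  out <- array(0, dim = c(size, size, d[4]))
  yi <- ys >= 1 & ys <= d[1]
  xi <- xs >= 1 & xs <= d[2]
  out[yi, xi, ] <- stack[ys[yi], xs[xi], z, ]
  out
}

#' Sample a class-balanced training set from one subject
#'
#' Patch centers are drawn without replacement inside the expected area
#' only, `min(per_class_quota, available)` per class, so lesion and
#' normal-tissue samples are equalized. A class absent within the
#' expected area contributes zero samples with a warning. Reproducible
#' under a fixed seed.
#'
#' @param subject labeled [subject_volumes()].
#' @param area an `expected_area` with masks filled.
#' @param per_class_quota samples per class.
#' @param seed RNG seed.
#' @param norm optional precomputed [zscore_subject()].
#' @param global_size,local_size patch sizes.
#' @return list of class `patch_set`: `global` (40 x 40 x 8 x n),
#'   `local` (15 x 15 x 8 x n), `dwa` (n), `label` (n, class indices
#'   0..3), `centers` (n x 3), `subject_id`.
#' @export
sample_training_set <- function(subject, area, per_class_quota = 100L,
                                seed = 1L, norm = NULL,
                                global_size = 40L, local_size = 15L) {
  stopifnot(!is.null(subject$labels))
  if (is.null(norm)) norm <- zscore_subject(subject)
  idx_labels <- remap_labels(subject$labels)
  inside <- which(area$per_slice_masks)
  lab_in <- idx_labels[inside]
  set.seed(seed)
  picked <- integer(0)
  for (cl in 0:3) {
    pool <- inside[lab_in == cl]
    if (!length(pool)) {
      warning(sprintf("class %d absent within the expected area of %s",
                      cl, subject$subject_id))
      next
    }
    take <- min(per_class_quota, length(pool))
    picked <- c(picked, sample(pool, take))
  }
  d <- dim(subject$flair)
  ctr <- arrayInd(picked, d)
  stack <- channel_stack(subject, norm)
  dwa <- dwa_volume(subject, area)
  n <- nrow(ctr)
  g <- array(0, dim = c(global_size, global_size, 8L, n))
  l <- array(0, dim = c(local_size, local_size, 8L, n))
  for (i in seq_len(n)) {
    g[, , , i] <- extract_patch(stack, ctr[i, ], global_size)
    l[, , , i] <- extract_patch(stack, ctr[i, ], local_size)
  }
  structure(list(
    global = g, local = l,
    dwa = dwa[ctr[, 3]],
    label = idx_labels[picked],
    centers = ctr,
    subject_id = subject$subject_id
  ), class = "patch_set")
}

#' Merge patch sets from several subjects
#'
#' @param sets list of `patch_set`.
#' @return one `patch_set` with concatenated samples.
#' @export
merge_patch_sets <- function(sets) {
  structure(list(
    global = array(unlist(lapply(sets, `[[`, "global")),
                   dim = c(dim(sets[[1]]$global)[1:3],
                           sum(vapply(sets, function(s) dim(s$global)[4], 1L)))),
    local = array(unlist(lapply(sets, `[[`, "local")),
                  dim = c(dim(sets[[1]]$local)[1:3],
                          sum(vapply(sets, function(s) dim(s$local)[4], 1L)))),
    dwa = unlist(lapply(sets, `[[`, "dwa")),
    label = unlist(lapply(sets, `[[`, "label")),
    centers = do.call(rbind, lapply(sets, `[[`, "centers")),
    subject_id = paste(vapply(sets, `[[`, "", "subject_id"), collapse = "+")
  ), class = "patch_set")
}

#' Enumerate inference centers inside the expected area
#'
#' Yields every voxel whose expected-area mask is TRUE in deterministic
#' (z, y, x) lexicographic order.
#'
#' @param area an `expected_area` with masks filled, or a 3D logical
#'   mask.
#' @return integer matrix with columns y, x, z (possibly 0 rows).
#' @export
inference_centers <- function(area) {
  mask <- if (inherits(area, "expected_area")) area$per_slice_masks else area
  w <- which(mask)
  if (!length(w)) {
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("y", "x", "z"))))
  }
  ctr <- arrayInd(w, dim(mask))
  ord <- order(ctr[, 3], ctr[, 1], ctr[, 2])
  ctr <- ctr[ord, , drop = FALSE]
  colnames(ctr) <- c("y", "x", "z")
  ctr
}
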