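#' Configuration of the rule-based tumor localizer
#'
#' Defaults: binarization
#' thresholds 0.7 (FLAIR), 0.7 (T2) and 0.9 (T1ce) on min-max rescaled
#' within-brain intensities; T1ce objects kept only with solidity > 0.7,
#' area > 500 px and major axis length > 35 px (all strict); T1ce objects
#' fused only when overlapping the FLAIR x T2 product mask by more than
#' 20 px. The tracking and enlargement knobs (centroid tolerance, area
#' ratio tolerance, chain length, dilation radius, shrink schedule) are
#' implementation-defined and exposed here.
#'
#' @param thr_flair,thr_t2,thr_t1ce binarization thresholds in (0, 1).
#' @param min_solidity,min_area,min_major_axis strict lower bounds for
#'   keeping a T1ce object.
#' @param min_overlap strict lower bound (px) on the overlap between a
#'   T1ce object and the FLAIR x T2 product mask.
#' @param opening_radius disk radius of the morphological opening applied
#'   to every binarized slice.
#' @param small_object_floor components smaller than this (px) are
#'   discarded after opening.
#' @param track_center_tol max centroid displacement (px) between
#'   consecutive slices for two objects to be chained.
#' @param track_size_ratio_tol max relative area change between chained
#'   neighbors.
#' @param min_chain_length chains shorter than this are not trusted.
#' @param search_radius objects within this distance (px) of the confirmed
#'   chain's position compete for "biggest object".
#' @param enlargement_radius dilation radius (px) of the biggest object at
#'   its slice.
#' @param shrink_per_slice expected-area radius decrease (px) per slice
#'   away from the biggest slice.
#' @param beyond_chain_margin slices beyond the chain plus this margin
#'   shrink at an accelerated rate until empty.
#' @return list of class `localization_config`.
#' @export
localization_config <- function(thr_flair = 0.7, thr_t2 = 0.7,
                                thr_t1ce = 0.9,
                                min_solidity = 0.7, min_area = 500,
                                min_major_axis = 35, min_overlap = 20,
                                opening_radius = 2, small_object_floor = 30,
                                track_center_tol = 15,
                                track_size_ratio_tol = 0.5,
                                min_chain_length = 3,
                                search_radius = 30,
                                enlargement_radius = 10,
                                shrink_per_slice = 0.5,
                                beyond_chain_margin = 5) {
  cfg <- as.list(environment())
  stopifnot(cfg$thr_flair > 0, cfg$thr_flair < 1,
            cfg$thr_t2 > 0, cfg$thr_t2 < 1,
            cfg$thr_t1ce > 0, cfg$thr_t1ce < 1,
            cfg$min_area > 0, cfg$min_major_axis > 0, cfg$min_overlap > 0)
  structure(cfg, class = "localization_config")
}

#' Binarize one normalized slice with a fractional threshold
#'
#' Z-scores are unbounded, so the fractional thresholds are applied after
#' min-max rescaling the slice's within-brain intensities to [0, 1]; the
#' mask is TRUE where the rescaled intensity strictly exceeds the
#' threshold. A degenerate slice (constant within the brain, or empty
#' brain) yields an empty mask. Background is always FALSE.
#'
#' @param norm_slice 2D numeric slice from a z-scored volume.
#' @param brain_slice 2D logical brain mask for the same slice.
#' @param threshold fraction in (0, 1).
#' @return 2D logical mask.
#' @export
binarize_modality <- function(norm_slice, brain_slice, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  out <- matrix(FALSE, nrow(norm_slice), ncol(norm_slice))
  if (!any(brain_slice)) return(out)
  v <- norm_slice[brain_slice]
  rng <- range(v)
  if (diff(rng) < 1e-12) return(out)
  out[brain_slice] <- (norm_slice[brain_slice] - rng[1]) / diff(rng) > threshold
  out
}

# Shape descriptors of the connected components of a binary slice.
# Solidity uses the pixel count of the filled convex hull; the major axis
# length is the standard ellipse-of-inertia measure 4*sqrt(lambda_max) of
# the second central moments of the pixel centers. Coordinates are
# 1-based (row, col) as in R matrices.
measure_objects <- function(mask) {
  if (!any(mask)) return(list())
  lab <- cpp_label8(mask)
  n <- max(lab)
  out <- vector("list", n)
  idx <- which(mask, arr.ind = TRUE)
  labs <- lab[mask]
  for (o in seq_len(n)) {
    pix <- idx[labs == o, , drop = FALSE]
    area <- nrow(pix)
    y <- pix[, 1]; x <- pix[, 2]
    ybar <- mean(y); xbar <- mean(x)
    mu20 <- mean((y - ybar)^2); mu02 <- mean((x - xbar)^2)
    mu11 <- mean((y - ybar) * (x - xbar))
    lam <- (mu20 + mu02) / 2 +
      sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    major <- 4 * sqrt(lam)
    out[[o]] <- list(
      label_id = o,
      area = area,
      solidity = area / convex_hull_area(y, x),
      major_axis_length = major,
      bbox = c(y0 = min(y), x0 = min(x),
               height = diff(range(y)) + 1L, width = diff(range(x)) + 1L),
      centroid = c(y = ybar, x = xbar),
      pixels = pix
    )
  }
  out
}

# Pixel count of the filled convex hull of a pixel set (a pixel belongs
# to the hull if its center is inside or on the hull polygon).
convex_hull_area <- function(y, x) {
  n <- length(y)
  if (n <= 2) return(n)
  h <- chull(x, y)
  if (length(h) < 3) return(n)  # collinear set
  hx <- x[h]; hy <- y[h]  # chull returns vertices clockwise
  cy <- seq(min(y), max(y)); cx <- seq(min(x), max(x))
  gy <- rep(cy, times = length(cx))
  gx <- rep(cx, each = length(cy))
  inside <- rep(TRUE, length(gy))
  m <- length(h)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    # clockwise orientation: interior has non-positive cross product
    cr <- (hx[k2] - hx[k]) * (gy - hy[k]) - (hy[k2] - hy[k]) * (gx - hx[k])
    inside <- inside & (cr <= 1e-9)
    if (!any(inside)) break
  }
  max(sum(inside), n)
}

#' Clean a binary slice and measure its connected components
#'
#' Applies a morphological opening with a disk structuring element, drops
#' components below the small-object floor, and measures the remaining
#' 8-connected components.
#'
#' @param mask 2D logical mask.
#' @param cfg a [localization_config()].
#' @return list of object property lists (area, solidity,
#'   major_axis_length, bbox, centroid, pixels); empty list for an empty
#'   mask.
#' @export
clean_and_measure <- function(mask, cfg = localization_config()) {
  if (!any(mask)) return(list())
  if (cfg$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * cfg$opening_radius + 1, shape = "disc")
    mask <- EBImage::imageData(EBImage::opening(mask * 1, brush)) > 0.5
  }
  objs <- measure_objects(mask)
  Filter(function(o) o$area >= cfg$small_object_floor, objs)
}

#' Keep only T1ce objects passing the three shape rules
#'
#' An object survives iff solidity > `min_solidity` AND area > `min_area`
#' AND major axis length > `min_major_axis` (all strict inequalities).
#' The filter is idempotent and the rules are order-independent.
#'
#' @param objects list of measured objects as from [clean_and_measure()].
#' @param cfg a [localization_config()].
#' @return filtered list.
#' @export
filter_t1ce_objects <- function(objects, cfg = localization_config()) {
  Filter(function(o) {
    o$solidity > cfg$min_solidity &&
      o$area > cfg$min_area &&
      o$major_axis_length > cfg$min_major_axis
  }, objects)
}

#' Fuse the per-modality detections of one slice
#'
#' The fused mask is the pixelwise product (AND) of the cleaned FLAIR and
#' T2 masks, plus every accepted T1ce object whose overlap with that
#' product mask strictly exceeds `min_overlap` pixels. Interior holes of
#' the fused mask are filled — the detected parts are combined into one
#' solid object, since necrotic tissue inside the tumor can fall below
#' the FLAIR/T2 thresholds. Components of the fused mask are then
#' measured for tracking.
#'
#' @param flair_bin,t2_bin cleaned 2D logical masks.
#' @param t1ce_objects accepted T1ce objects ([filter_t1ce_objects()]).
#' @param cfg a [localization_config()].
#' @param slice_index stored for bookkeeping.
#' @return list of class `slice_detection` with `fused_mask`, `objects`
#'   and `slice_index`.
#' @export
fuse_slice <- function(flair_bin, t2_bin, t1ce_objects = list(),
                       cfg = localization_config(), slice_index = NA_integer_) {
  product <- flair_bin & t2_bin
  fused <- product
  for (o in t1ce_objects) {
    overlap <- sum(product[o$pixels])
    if (overlap > cfg$min_overlap) fused[o$pixels] <- TRUE
  }
  if (any(fused)) {
    fused <- EBImage::imageData(EBImage::fillHull(fused * 1)) > 0.5
  }
  objs <- if (any(fused)) {
    Filter(function(o) o$area >= cfg$small_object_floor, measure_objects(fused))
  } else list()
  structure(list(slice_index = slice_index, fused_mask = fused,
                 objects = objs),
            class = "slice_detection")
}

#' Run per-slice detection over a whole subject
#'
#' For every axial slice: binarize the z-scored FLAIR, T2 and T1ce (T1 is
#' not used for localization), clean each mask, apply the three shape
#' rules to the T1ce components, and fuse.
#'
#' @param norm a [zscore_subject()] result.
#' @param brain 3D logical brain mask.
#' @param cfg a [localization_config()].
#' @return list of `slice_detection`, one per slice.
#' @export
detect_slices <- function(norm, brain, cfg = localization_config()) {
  nz <- dim(norm$flair)[3]
  lapply(seq_len(nz), function(z) {
    bs <- brain[, , z]
    fb <- binarize_modality(norm$flair[, , z], bs, cfg$thr_flair)
    tb <- binarize_modality(norm$t2[, , z], bs, cfg$thr_t2)
    cb <- binarize_modality(norm$t1ce[, , z], bs, cfg$thr_t1ce)
    fb_c <- clean_mask(fb, cfg)
    tb_c <- clean_mask(tb, cfg)
    t1ce_obj <- filter_t1ce_objects(clean_and_measure(cb, cfg), cfg)
    fuse_slice(fb_c, tb_c, t1ce_obj, cfg, slice_index = z)
  })
}

# Opening + speck removal without measuring (helper for detect_slices).
clean_mask <- function(mask, cfg) {
  if (!any(mask)) return(mask)
  if (cfg$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * cfg$opening_radius + 1, shape = "disc")
    mask <- EBImage::imageData(EBImage::opening(mask * 1, brush)) > 0.5
  }
  if (!any(mask)) return(mask)
  lab <- cpp_label8(mask)
  keep <- which(tabulate(lab[mask]) >= cfg$small_object_floor)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Track objects across slices and find the biggest true tumor object
#'
#' Objects in consecutive slices are chained when their centroids move at
#' most `track_center_tol` px and their areas change by at most
#' `track_size_ratio_tol` (relative). A chain of at least
#' `min_chain_length` slices confirms a true tumor object; among all
#' confirmed chains the one holding the largest object wins. The biggest
#' object is then re-sought among all slices' objects lying within
#' `search_radius` of the chain's median position, so slices beyond the
#' chain ends still compete. Ties in area resolve to the lowest slice.
#'
#' @param detections list of `slice_detection` from [detect_slices()].
#' @param cfg a [localization_config()].
#' @return list of class `expected_area` (masks not yet filled) with
#'   `biggest_slice`, `biggest_object`, `chain` (data.frame of slice,
#'   area, centroid), and `chain_range`.
#' @export
track_and_find_biggest <- function(detections, cfg = localization_config()) {
  nz <- length(detections)
  if (nz < 3) stop("tracking needs at least 3 slices")
  # chains: list of data.frames (slice, obj, y, x, area)
  chains <- list(); active <- list()
  for (z in seq_len(nz)) {
    objs <- detections[[z]]$objects
    taken <- rep(FALSE, length(objs))
    new_active <- list()
    for (ch in active) {
      last <- ch[nrow(ch), ]
      best <- NA_integer_; best_d <- Inf
      for (k in seq_along(objs)) {
        if (taken[k]) next
        o <- objs[[k]]
        d <- sqrt((o$centroid[1] - last$y)^2 + (o$centroid[2] - last$x)^2)
        rel <- abs(o$area - last$area) / max(o$area, last$area)
        if (d <= cfg$track_center_tol && rel <= cfg$track_size_ratio_tol &&
            d < best_d) {
          best <- k; best_d <- d
        }
      }
      if (!is.na(best)) {
        taken[best] <- TRUE
        o <- objs[[best]]
        ch <- rbind(ch, data.frame(slice = z, obj = best,
                                   y = o$centroid[1], x = o$centroid[2],
                                   area = o$area))
        new_active[[length(new_active) + 1]] <- ch
      } else {
        chains[[length(chains) + 1]] <- ch  # chain ended
      }
    }
    for (k in seq_along(objs)) {
      if (taken[k]) next
      o <- objs[[k]]
      new_active[[length(new_active) + 1]] <-
        data.frame(slice = z, obj = k, y = o$centroid[1], x = o$centroid[2],
                   area = o$area)
    }
    active <- new_active
  }
  chains <- c(chains, active)
  confirmed <- Filter(function(ch) nrow(ch) >= cfg$min_chain_length, chains)
  if (!length(confirmed)) {
    n_obj <- sum(vapply(detections, function(d) length(d$objects), 1L))
    stop(sprintf(paste0("localization failure: no object chain of length >= %d ",
                        "(%d chains seen, %d objects across %d slices)"),
                 cfg$min_chain_length, length(chains), n_obj, nz))
  }
  peak_area <- vapply(confirmed, function(ch) max(ch$area), 1)
  best_chain <- confirmed[[which.max(peak_area)]]
  cy <- stats::median(best_chain$y); cx <- stats::median(best_chain$x)
  # search near the chain position in all slices for the biggest object
  best <- NULL; best_area <- -Inf; best_slice <- NA_integer_
  for (z in seq_len(nz)) {
    for (o in detections[[z]]$objects) {
      d <- sqrt((o$centroid[1] - cy)^2 + (o$centroid[2] - cx)^2)
      if (d > cfg$search_radius) next
      if (o$area > best_area) {
        best <- o; best_area <- o$area; best_slice <- z
      }
    }
  }
  structure(list(
    biggest_slice = best_slice,
    biggest_object = best,
    chain = best_chain,
    chain_range = range(best_chain$slice),
    chain_center = c(y = cy, x = cx),
    per_slice_masks = NULL,
    per_slice_center = NULL,
    enlargement_radius = cfg$enlargement_radius
  ), class = "expected_area")
}

#' Build the enlarged per-slice expected-area masks
#'
#' The biggest object is dilated by `enlargement_radius` at its slice; the
#' mask then shrinks by `shrink_per_slice` px of radius per slice away
#' from the biggest slice, with an accelerated shrink (2 px/slice extra)
#' for slices beyond the confirmed chain plus `beyond_chain_margin`.
#' Each slice's mask is additionally floored at that slice's own tracked
#' chain object dilated by a small radius, so the mask never loses the
#' detected object itself. Every nonempty mask is a single connected
#' region (a morphological neighborhood of one object).
#'
#' @param area an `expected_area` from [track_and_find_biggest()].
#' @param detections the `slice_detection` list (for the per-slice floor).
#' @param shape volume shape (rows, cols, slices).
#' @param cfg a [localization_config()].
#' @return the `expected_area` with `per_slice_masks` (3D logical) and
#'   `per_slice_center` filled.
#' @export
build_expected_masks <- function(area, detections, shape,
                                 cfg = localization_config()) {
  stopifnot(inherits(area, "expected_area"))
  nz <- shape[3]
  obj_mask <- matrix(FALSE, shape[1], shape[2])
  obj_mask[area$biggest_object$pixels] <- TRUE
  # distance of every pixel to the biggest object (0 inside it)
  dist_obj <- EBImage::imageData(EBImage::distmap(1 - obj_mask))
  masks <- array(FALSE, dim = shape)
  centers <- matrix(NA_real_, nz, 2, dimnames = list(NULL, c("y", "x")))
  zstar <- area$biggest_slice
  chain <- area$chain
  for (z in seq_len(nz)) {
    beyond <- max(0, area$chain_range[1] - z, z - area$chain_range[2])
    radius <- cfg$enlargement_radius -
      cfg$shrink_per_slice * abs(z - zstar) -
      2 * max(0, beyond - cfg$beyond_chain_margin)
    m <- if (radius >= 0) dist_obj <= radius else
      matrix(FALSE, shape[1], shape[2])
    row <- chain[chain$slice == z, ]
    if (nrow(row) == 1) {
      o <- detections[[z]]$objects[[row$obj]]
      floor_mask <- matrix(FALSE, shape[1], shape[2])
      floor_mask[o$pixels] <- TRUE
      fd <- EBImage::imageData(EBImage::distmap(1 - floor_mask))
      m <- m | (fd <= 3)
    }
    masks[, , z] <- m
    if (any(m)) {
      w <- which(m, arr.ind = TRUE)
      centers[z, ] <- c(mean(w[, 1]), mean(w[, 2]))
    }
  }
  area$per_slice_masks <- masks
  area$per_slice_center <- centers
  area
}

#' @export
print.expected_area <- function(x, ...) {
  cat(sprintf("<expected_area> biggest slice %d (area %d px), chain slices %d..%d\n",
              x$biggest_slice, x$biggest_object$area,
              x$chain_range[1], x$chain_range[2]))
  if (!is.null(x$per_slice_masks)) {
    cat(sprintf("  masks: %d nonempty slices, %d voxels total\n",
                sum(apply(x$per_slice_masks, 3, any)), sum(x$per_slice_masks)))
  }
  invisible(x)
}

#' Localize the tumor of one subject end to end
#'
#' Runs z-score normalization (if not supplied), per-slice detection,
#' cross-slice tracking and expected-area construction.
#'
#' @param subject a [subject_volumes()].
#' @param cfg a [localization_config()].
#' @param norm optional precomputed [zscore_subject()] result.
#' @return an `expected_area` with masks filled; the slice detections are
#'   attached as attribute `"detections"`.
#' @export
localize_subject <- function(subject, cfg = localization_config(),
                             norm = NULL) {
  if (is.null(norm)) norm <- zscore_subject(subject)
  det <- detect_slices(norm, subject$brain_mask, cfg)
  area <- track_and_find_biggest(det, cfg)
  area <- build_expected_masks(area, det, dim(subject$flair), cfg)
  attr(area, "detections") <- det
  area
}
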