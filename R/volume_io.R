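#' Label mapping between raw BRATS-style labels and class indices
#'
#' Ground-truth volumes use the raw labels 0 (normal tissue), 1 (necrosis),
#' 2 (edema) and 4 (enhancing tumor); label 3 (non-enhancing tumor) is not
#' used. The classifier works on contiguous class indices 0..3, so raw
#' labels are remapped with `0 -> 0, 1 -> 1, 2 -> 2, 4 -> 3` and back.
#'
#' @return A list with `raw_to_index` and `index_to_raw` named integer
#'   vectors forming a bijection over the four used labels.
#' @export
class_map <- function() {
  list(
    raw_to_index = c(`0` = 0L, `1` = 1L, `2` = 2L, `4` = 3L),
    index_to_raw = c(`0` = 0L, `1` = 1L, `2` = 2L, `3` = 4L)
  )
}

#' Remap raw tumor labels to contiguous class indices
#'
#' Raw label 3 is unused by convention; if present it is remapped to 0
#' (normal tissue) with a warning.
#'
#' @param labels integer array with values in 0..4.
#' @param map a [class_map()].
#' @return integer array of the same shape with values in 0..3.
#' @export
remap_labels <- function(labels, map = class_map()) {
  vals <- unique(as.vector(labels))
  if (any(!vals %in% 0:4)) {
    stop("labels contain values outside {0,1,2,3,4}: ",
         paste(setdiff(vals, 0:4), collapse = ", "))
  }
  if (3L %in% vals) {
    warning("raw label 3 is unused; remapping it to 0 (normal tissue)")
  }
  lut <- c(0L, 1L, 2L, 0L, 3L)  # raw 0,1,2,3,4 -> index
  out <- lut[as.vector(labels) + 1L]
  array(out, dim = dim(labels))
}

#' Map class indices back to raw labels
#'
#' @param idx integer array with values in 0..3.
#' @param map a [class_map()].
#' @return integer array with values in {0, 1, 2, 4}.
#' @export
unmap_labels <- function(idx, map = class_map()) {
  vals <- unique(as.vector(idx))
  if (any(!vals %in% 0:3)) stop("class indices must be in {0,1,2,3}")
  lut <- c(0L, 1L, 2L, 4L)
  array(lut[as.vector(idx) + 1L], dim = dim(idx))
}

#' Compute the brain mask of a subject
#'
#' The brain mask is the union of nonzero voxels across the four
#' modalities; BRATS-style volumes are skull-stripped with an exactly-zero
#' background, which makes this the natural support definition. The mask
#' is invariant under positive per-modality intensity rescaling.
#'
#' @param flair,t1,t1ce,t2 3D intensity arrays of one shape.
#' @return logical 3D array.
#' @export
brain_mask <- function(flair, t1, t1ce, t2) {
  (flair != 0) | (t1 != 0) | (t1ce != 0) | (t2 != 0)
}

#' Bundle four co-registered modality volumes into one subject
#'
#' @param flair,t1,t1ce,t2 3D numeric arrays sharing one shape; axial
#'   slices are indexed along the third dimension.
#' @param labels optional integer array with raw labels in {0,1,2,3,4};
#'   label 3 is remapped to 0 with a warning.
#' @param subject_id character identifier.
#' @param voxel_spacing numeric length-3, voxel size in mm.
#' @param reference optional NIfTI image whose header (affine) is kept for
#'   later writing.
#' @return An object of class `subject_volumes`.
#' @export
subject_volumes <- function(flair, t1, t1ce, t2, labels = NULL,
                            subject_id = "subject",
                            voxel_spacing = c(1, 1, 1),
                            reference = NULL) {
  dims <- list(dim(flair), dim(t1), dim(t1ce), dim(t2))
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("modality volumes must be 3D arrays")
  }
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("modality volumes do not share one shape")
  }
  if (!is.null(labels)) {
    if (!identical(dim(labels), dims[[1]])) {
      stop("label volume shape does not match the modalities")
    }
    vals <- unique(as.vector(labels))
    if (any(!vals %in% 0:4)) {
      stop("labels contain values outside {0,1,2,3,4}")
    }
    if (3L %in% vals) {
      warning("raw label 3 is unused; remapping it to 0")
      labels[labels == 3] <- 0L
    }
    storage.mode(labels) <- "integer"
  }
  structure(list(
    flair = flair, t1 = t1, t1ce = t1ce, t2 = t2,
    labels = labels,
    brain_mask = brain_mask(flair, t1, t1ce, t2),
    subject_id = subject_id,
    voxel_spacing = as.numeric(voxel_spacing),
    reference = reference
  ), class = "subject_volumes")
}

#' @export
print.subject_volumes <- function(x, ...) {
  d <- dim(x$flair)
  cat(sprintf("<subject_volumes> %s  %dx%dx%d  spacing %s mm  labels: %s\n",
              x$subject_id, d[1], d[2], d[3],
              paste(signif(x$voxel_spacing, 3), collapse = "x"),
              if (is.null(x$labels)) "none" else "present"))
  invisible(x)
}

#' Load one subject's four modalities (and optional labels) from NIfTI
#'
#' All files must exist, be readable NIfTI and share one shape; the affine
#' of the FLAIR image is retained as the reference header for writing
#' segmentations.
#'
#' @param paths named list/vector with elements `flair`, `t1`, `t1ce`,
#'   `t2` giving file paths.
#' @param label_path optional path to the ground-truth label volume.
#' @param subject_id identifier; defaults to the FLAIR file name stem.
#' @return A [subject_volumes()] object.
#' @export
load_subject <- function(paths, label_path = NULL, subject_id = NULL) {
  need <- c("flair", "t1", "t1ce", "t2")
  paths <- as.list(paths)
  if (!all(need %in% names(paths))) {
    stop("paths must name flair, t1, t1ce and t2 files")
  }
  all_paths <- c(unlist(paths[need]), label_path)
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
  imgs <- lapply(paths[need], RNifti::readNifti)
  dims <- lapply(imgs, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("modality volumes do not share one shape: ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"), ""),
               collapse = " vs "))
  }
  ref <- imgs$flair
  spacing <- RNifti::pixdim(ref)[1:3]
  labels <- NULL
  if (!is.null(label_path)) {
    lab <- RNifti::readNifti(label_path)
    if (!identical(dim(lab), dims[[1]])) stop("label volume shape mismatch")
    labels <- array(as.integer(round(as.array(lab))), dim = dim(lab))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(paths$flair))
  }
  subject_volumes(
    flair = as.array(imgs$flair), t1 = as.array(imgs$t1),
    t1ce = as.array(imgs$t1ce), t2 = as.array(imgs$t2),
    labels = labels, subject_id = subject_id,
    voxel_spacing = as.numeric(spacing), reference = ref
  )
}

#' Write a segmentation as NIfTI with raw labels
#'
#' Class indices are mapped back to raw labels {0,1,2,4} and written with
#' the reference subject's header so the file aligns with the inputs.
#'
#' @param seg integer array of class indices 0..3, same shape as the
#'   reference subject's volumes.
#' @param reference a [subject_volumes()] object.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param map a [class_map()].
#' @return `path`, invisibly.
#' @export
save_segmentation <- function(seg, reference, path, map = class_map()) {
  if (!identical(dim(seg), dim(reference$flair))) {
    stop("segmentation shape does not match the reference subject")
  }
  raw <- unmap_labels(seg, map)
  img <- if (!is.null(reference$reference)) {
    RNifti::asNifti(raw, reference = reference$reference, datatype = "int16")
  } else {
    RNifti::asNifti(raw, datatype = "int16")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a subject manifest
#'
#' A manifest is a CSV with columns `subject_id, flair, t1, t1ce, t2` and
#' optionally `labels`; relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with absolute paths.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "flair", "t1", "t1ce", "t2")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p,
                            file.path(base, p))
  for (col in intersect(c("flair", "t1", "t1ce", "t2", "labels"), names(m))) {
    m[[col]] <- fix(m[[col]])
  }
  m
}
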