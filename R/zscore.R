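#' Z-score normalize one volume within the brain region
#'
#' Subtracts the within-brain mean and divides by the within-brain
#' standard deviation (population form, ddof = 0), leaving background
#' voxels at exactly 0. The result has zero mean and unit variance over
#' the brain mask and is invariant under positive affine rescaling of the
#' input intensities.
#'
#' @param volume 3D numeric array.
#' @param mask logical array of the same shape, TRUE inside the brain;
#'   needs at least 2 voxels and nonzero intensity variance.
#' @return list with `volume` (normalized array), `mean` and `sd`.
#' @export
zscore <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) stop("volume/mask shape mismatch")
  v <- volume[mask]
  if (length(v) < 2) stop("brain mask has fewer than 2 voxels")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) stop("zero intensity variance within the brain mask")
  out <- array(0, dim = dim(volume))
  out[mask] <- (v - mu) / sigma
  list(volume = out, mean = mu, sd = sigma)
}

#' Z-score normalize all four modalities of a subject
#'
#' Normalization is per volume (per subject, per modality), computed over
#' the brain region only.
#'
#' @param subject a [subject_volumes()] object.
#' @return An object of class `normalized_volumes`: per-modality z-scored
#'   arrays (`flair`, `t1`, `t1ce`, `t2`), the `stats` used (per-modality
#'   mean/sd) and the source `subject_id`.
#' @export
zscore_subject <- function(subject) {
  stopifnot(inherits(subject, "subject_volumes"))
  mods <- c("flair", "t1", "t1ce", "t2")
  out <- list()
  stats <- list()
  for (m in mods) {
    z <- zscore(subject[[m]], subject$brain_mask)
    out[[m]] <- z$volume
    stats[[m]] <- c(mean = z$mean, sd = z$sd)
  }
  structure(list(
    flair = out$flair, t1 = out$t1, t1ce = out$t1ce, t2 = out$t2,
    stats = stats, subject_id = subject$subject_id
  ), class = "normalized_volumes")
}

#' @export
print.normalized_volumes <- function(x, ...) {
  cat(sprintf("<normalized_volumes> %s\n", x$subject_id))
  for (m in c("flair", "t1", "t1ce", "t2")) {
    cat(sprintf("  %-5s mean %.4g sd %.4g\n", m,
                x$stats[[m]]["mean"], x$stats[[m]]["sd"]))
  }
  invisible(x)
}
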