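#' Specification of a synthetic multi-modal phantom
#'
#' The phantom emulates the contrast behavior the localization rules rely
#' on: an elliptical "brain" on a zero background, a tumor whose per-slice
#' radius follows the unimodal profile `r(z) = max(0, r_max - slope *
#' |z - z_peak|)` (so tumor area grows and shrinks smoothly across
#' slices), nested sub-regions (necrotic core inside an enhancing rim
#' inside edema), and class-conditional intensities ordered so that tumor
#' is brighter than brain in FLAIR/T2 while the enhancing rim is by far
#' the brightest tissue in T1ce. An optional single-slice bright blob acts
#' as a decoy artifact with no cross-slice support.
#'
#' @param shape integer length-3, volume dimensions (rows, cols, slices).
#' @param brain_center,brain_semiaxes ellipsoid of the brain (voxels).
#' @param tumor_center (y, x, z_peak) of the tumor, 1-based voxel indices.
#' @param r_max maximal tumor radius in pixels, reached at `z_peak`.
#' @param slope radius decrease in pixels per slice away from the peak.
#' @param necrosis_frac,enhancing_frac radii of the necrotic core and the
#'   outer edge of the enhancing rim, as fractions of the local radius;
#'   must satisfy 0 < necrosis_frac < enhancing_frac < 1.
#' @param intensities named list of per-tissue modality means on a [0, 1]
#'   raw scale; see `phantom_intensities()` for the default orderings.
#' @param noise_sd additive Gaussian noise SD.
#' @param artifact NULL, or a list with `center` (y, x), `radius` and
#'   `slice` describing a single-slice bright blob; NULL entries default
#'   to a blob 1.25x the maximal tumor radius on the opposite side of
#'   the brain, six slices below the tumor peak.
#' @param voxel_spacing voxel size in mm.
#' @param seed integer RNG seed; generation is bitwise reproducible.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(240L, 240L, 32L),
                         brain_center = NULL,
                         brain_semiaxes = NULL,
                         tumor_center = NULL,
                         r_max = 24,
                         slope = 2,
                         necrosis_frac = 0.35,
                         enhancing_frac = 0.65,
                         intensities = phantom_intensities(),
                         noise_sd = 0.03,
                         artifact = list(center = NULL, radius = NULL,
                                         slice = NULL),
                         voxel_spacing = c(1, 1, 1),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(brain_center)) brain_center <- c(shape[1] / 2, shape[2] / 2, shape[3] / 2)
  if (is.null(brain_semiaxes)) {
    brain_semiaxes <- c(0.37 * shape[1], 0.30 * shape[2], 0.55 * shape[3])
  }
  if (is.null(tumor_center)) {
    tumor_center <- c(round(brain_center[1] - 0.2 * brain_semiaxes[1]),
                      round(brain_center[2] + 0.2 * brain_semiaxes[2]),
                      round(shape[3] / 2))
  }
  if (!is.null(artifact)) {
    if (is.null(artifact$center)) {
      artifact$center <- c(round(brain_center[1] + 0.45 * brain_semiaxes[1]),
                           round(brain_center[2] - 0.45 * brain_semiaxes[2]))
    }
    if (is.null(artifact$radius)) artifact$radius <- 1.25 * r_max
    if (is.null(artifact$slice)) {
      artifact$slice <- max(1L, as.integer(tumor_center[3]) - 6L)
    }
  }
  stopifnot(necrosis_frac > 0, necrosis_frac < enhancing_frac,
            enhancing_frac < 1)
  structure(list(
    shape = shape, brain_center = brain_center,
    brain_semiaxes = brain_semiaxes, tumor_center = tumor_center,
    r_max = r_max, slope = slope,
    necrosis_frac = necrosis_frac, enhancing_frac = enhancing_frac,
    intensities = intensities, noise_sd = noise_sd, artifact = artifact,
    voxel_spacing = voxel_spacing, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Default per-tissue modality intensities for phantoms
#'
#' Means on a [0, 1] raw scale, chosen to satisfy the contrast orderings
#' the localizer assumes: edema and tumor brighter than brain in FLAIR and
#' T2; the enhancing rim much brighter than everything else in T1ce; the
#' necrotic core dark in T1ce.
#'
#' @return named list of length-4 numeric vectors (flair, t1, t1ce, t2).
#' @export
phantom_intensities <- function() {
  list( #            flair   t1  t1ce    t2
    brain     = c(0.35, 0.45, 0.40, 0.32),
    edema     = c(0.80, 0.50, 0.45, 0.78),
    enhancing = c(0.85, 0.55, 0.95, 0.82),
    necrosis  = c(0.75, 0.30, 0.18, 0.85),
    artifact  = c(0.90, 0.60, 0.95, 0.90)
  )
}

# Per-slice planted tumor radius profile.
phantom_radius <- function(spec, z) {
  pmax(0, spec$r_max - spec$slope * abs(z - spec$tumor_center[3]))
}

# TRUE when the planted tumor fits inside the brain ellipse of every
# slice it touches (conservative bound: center offset plus radius per
# axis).
phantom_fits <- function(spec) {
  if (spec$r_max <= 0) return(TRUE)
  bc <- spec$brain_center; ba <- spec$brain_semiaxes
  tc <- spec$tumor_center
  for (z in seq_len(spec$shape[3])) {
    r <- phantom_radius(spec, z)
    if (r < 1) next
    zrel <- ((z - bc[3]) / ba[3])^2
    if (zrel >= 1) return(FALSE)
    s <- sqrt(1 - zrel)
    fit <- ((abs(tc[1] - bc[1]) + r) / (ba[1] * s))^2 +
      ((abs(tc[2] - bc[2]) + r) / (ba[2] * s))^2
    if (fit > 1) return(FALSE)
  }
  TRUE
}

#' Generate one synthetic multi-modal phantom subject
#'
#' @param spec a [phantom_spec()].
#' @return A [subject_volumes()] object with ground-truth labels in
#'   {0, 1, 2, 4}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  yy <- matrix(seq_len(d[1]), d[1], d[2])
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  mods <- c("flair", "t1", "t1ce", "t2")
  vols <- lapply(mods, function(m) array(0, dim = d))
  names(vols) <- mods
  labels <- array(0L, dim = d)
  ints <- spec$intensities
  bc <- spec$brain_center; ba <- spec$brain_semiaxes
  tc <- spec$tumor_center
  if (!phantom_fits(spec)) {
    stop("tumor does not fit inside the brain ellipsoid")
  }
  for (z in seq_len(d[3])) {
    zrel <- ((z - bc[3]) / ba[3])^2
    if (zrel >= 1) next
    s <- sqrt(1 - zrel)
    brain <- ((yy - bc[1]) / (ba[1] * s))^2 + ((xx - bc[2]) / (ba[2] * s))^2 <= 1
    if (!any(brain)) next
    r <- phantom_radius(spec, z)
    dist_t <- sqrt((yy - tc[1])^2 + (xx - tc[2])^2)
    lab <- matrix(0L, d[1], d[2])
    if (r >= 1) {
      lab[dist_t <= r] <- 2L                              # edema
      lab[dist_t <= spec$enhancing_frac * r] <- 4L        # enhancing rim
      lab[dist_t <= spec$necrosis_frac * r] <- 1L         # necrotic core
      lab[!brain] <- 0L
    }
    art <- NULL
    if (!is.null(spec$artifact) && z == spec$artifact$slice) {
      art <- sqrt((yy - spec$artifact$center[1])^2 +
                    (xx - spec$artifact$center[2])^2) <= spec$artifact$radius
      art <- art & brain
    }
    for (k in seq_along(mods)) {
      sl <- matrix(0, d[1], d[2])
      sl[brain] <- ints$brain[k]
      sl[lab == 2L] <- ints$edema[k]
      sl[lab == 4L] <- ints$enhancing[k]
      sl[lab == 1L] <- ints$necrosis[k]
      if (!is.null(art)) sl[art] <- ints$artifact[k]
      noise <- matrix(rnorm(d[1] * d[2], 0, spec$noise_sd), d[1], d[2])
      sl[brain] <- pmax(sl[brain] + noise[brain], 0.01)   # stay nonzero in brain
      vols[[k]][, , z] <- sl
    }
    labels[, , z] <- lab
  }
  subject_volumes(
    flair = vols$flair, t1 = vols$t1, t1ce = vols$t1ce, t2 = vols$t2,
    labels = labels,
    subject_id = sprintf("phantom_seed%d", spec$seed),
    voxel_spacing = spec$voxel_spacing
  )
}

#' Generate a cohort of phantoms with jittered tumor geometry
#'
#' Tumor centers, peak slices and maximal radii are jittered uniformly
#' around the base specification; each subject gets its own derived seed
#' so the cohort is reproducible as a whole. A draw whose jittered tumor
#' would not fit inside the brain is deterministically contracted toward
#' the base geometry (which must fit) until it does, so every cohort
#' member is geometrically valid while staying within the jitter bounds.
#'
#' @param n number of subjects.
#' @param base_spec a [phantom_spec()] used as template.
#' @param jitter list with `center` (max in-plane displacement, px),
#'   `z` (max peak-slice shift, slices) and `r` (max radius change, px).
#' @param seed cohort seed.
#' @return list of [subject_volumes()].
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            jitter = list(center = 10, z = 3, r = 4),
                            seed = 1L) {
  stopifnot(n >= 1)
  set.seed(stage_seed(seed, "cohort"))
  draws <- matrix(runif(n * 4, -1, 1), n, 4)
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    shrink <- 1
    repeat {
      sp$tumor_center <- c(
        round(base_spec$tumor_center[1] + shrink * draws[i, 1] * jitter$center),
        round(base_spec$tumor_center[2] + shrink * draws[i, 2] * jitter$center),
        max(4L, min(base_spec$shape[3] - 4L,
                    round(base_spec$tumor_center[3] +
                            draws[i, 3] * jitter$z)))
      )
      sp$r_max <- max(base_spec$r_max - jitter$r,
                      base_spec$r_max + shrink * draws[i, 4] * jitter$r)
      if (phantom_fits(sp) || shrink < 1e-3) break
      shrink <- shrink * 0.7
    }
    if (!is.null(sp$artifact)) {
      # keep the decoy's slice offset relative to the tumor peak
      off <- base_spec$artifact$slice - as.integer(base_spec$tumor_center[3])
      sp$artifact$slice <- max(1L, as.integer(sp$tumor_center[3]) + off)
    }
    sp$seed <- stage_seed(seed, sprintf("phantom%03d", i))
    subj <- generate_phantom(sp)
    subj$subject_id <- sprintf("phantom%03d", i)
    subj
  })
}
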