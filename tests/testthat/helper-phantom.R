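# Small phantom specification for fast unit tests (the full-size default
# spec is exercised in the acceptance tests).
small_phantom_spec <- function(seed = 1L, ...) {
  sp <- phantom_spec(
    shape = c(96L, 96L, 20L),
    r_max = 12, slope = 1.5,
    artifact = list(center = NULL, radius = 16, slice = NULL),
    seed = seed,
    ...
  )
  if (!is.null(sp$artifact)) {
    # keep the decoy on a slice where the small tumor is still detectable
    sp$artifact$slice <- as.integer(sp$tumor_center[3]) - 3L
  }
  sp
}

# geometrically feasible jitter for the small brain
small_jitter <- list(center = 3, z = 2, r = 0)

# Localization config scaled to the small phantom (the area/axis rules
# are T1ce-only and the small tumor never reaches 500 px anyway).
small_loc_config <- function(...) {
  localization_config(small_object_floor = 15, search_radius = 20,
                      enlargement_radius = 8, ...)
}

# Draw a disk mask into a matrix.
disk_mask <- function(nr, nc, cy, cx, r) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sqrt((yy - cy)^2 + (xx - cx)^2) <= r
}
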