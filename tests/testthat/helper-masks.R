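# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately avoid the package's distance-transform path: surfaces come
# from explicit neighbour checks and distances from full pairwise
# enumeration.

mask_from_indices <- function(idx, shape, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), name = "test") {
  v <- array(FALSE, dim = shape)
  if (is.vector(idx)) idx <- matrix(idx, ncol = 3, byrow = TRUE)
  v[idx] <- TRUE
  structure_mask(v, image_grid(shape, spacing, origin), name)
}

random_mask <- function(shape, p = 0.25, spacing = c(1, 1, 1), name = "rnd") {
  repeat {
    v <- array(stats::runif(prod(shape)) < p, dim = shape)
    if (any(v)) break
  }
  structure_mask(v, image_grid(shape, spacing), name)
}

# Surface by explicit 6-neighbour inspection (outside the array = unset).
bf_surface_indices <- function(mask) {
  v <- mask$voxels
  dims <- dim(v)
  idx <- which(v, arr.ind = TRUE)
  on_surface <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in seq_len(6)) {
      n <- nb[q, ]
      if (any(n < 1) || any(n > dims)) return(TRUE)
      if (!v[n[1], n[2], n[3]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  idx[on_surface, , drop = FALSE]
}

# Directed nearest-neighbour distances by full pairwise enumeration.
bf_directed <- function(from_idx, to_idx, spacing) {
  fm <- sweep(from_idx - 1, 2, spacing, "*")
  tm <- sweep(to_idx - 1, 2, spacing, "*")
  vapply(seq_len(nrow(fm)), function(r) {
    d2 <- (tm[, 1] - fm[r, 1])^2 + (tm[, 2] - fm[r, 2])^2 +
      (tm[, 3] - fm[r, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

bf_hausdorff <- function(a, b) {
  sa <- bf_surface_indices(a); sb <- bf_surface_indices(b)
  sp <- a$grid$spacing
  max(max(bf_directed(sa, sb, sp)), max(bf_directed(sb, sa, sp)))
}

bf_msd <- function(a, b) {
  sa <- bf_surface_indices(a); sb <- bf_surface_indices(b)
  sp <- a$grid$spacing
  (mean(bf_directed(sa, sb, sp)) + mean(bf_directed(sb, sa, sp))) / 2
}

# Observer models with all noise switched off, for identity pipelines.
zero_noise_models <- function() {
  list(manual = observer_model("manual", radial_sd_mm = 0,
                               systematic_margin_mm = 0,
                               caudal_jitter_slices = 0),
       adjusted = observer_model("adjusted", radial_sd_mm = 0,
                                 systematic_margin_mm = 0,
                                 caudal_jitter_slices = 0),
       ai_only = observer_model("ai_only", radial_sd_mm = 0,
                                systematic_margin_mm = 0,
                                caudal_jitter_slices = 0))
}

small_phantom_study <- function(n_patients = 2, n_manual = 2, n_adjusted = 1,
                                seed = 11, ...) {
  make_cohort(n_patients = n_patients, n_manual = n_manual,
              n_adjusted = n_adjusted, seed = seed, ...)
}
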