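# Fixtures are generated in code; no data files.

# Standard infarct phantom: a large transmural patch with k border-zone
# channels threading the core. Border-zone signal sits at half maximum, and
# a small partial-volume blur reproduces the boundary gradation real LGE
# images show at tissue interfaces.
channels_phantom_spec <- function(k = 3, seed = 1, noise_sigma = 4,
                                  blur_sigma_mm = c(1, 1, 1.5),
                                  width_mm = 6) {
  angles <- c(-110, 0, 110)
  chans <- if (k > 0) {
    lapply(angles[seq_len(k)], bz_channel, width_mm = width_mm)
  } else {
    list()
  }
  patch <- scar_patch(angle_center_deg = 0, angular_extent_deg = 280,
                      apicobasal_extent = 0.5, transmural_extent = 1,
                      channels = chans)
  phantom_spec(scar_patches = list(patch), noise_sigma = noise_sigma,
               blur_sigma_mm = blur_sigma_mm, seed = seed)
}

# Heterogeneous-enhancement phantom: thick partial-volume gradation and low
# noise, emulating a core whose apparent extent depends strongly on the PSI
# window (no channels).
gradation_phantom_spec <- function(seed = 1) {
  patch <- scar_patch(angle_center_deg = 0, angular_extent_deg = 280,
                      apicobasal_extent = 0.5, transmural_extent = 1)
  phantom_spec(scar_patches = list(patch), si_levels = c(20, 50, 100),
               noise_sigma = 2, blur_sigma_mm = c(3, 3, 3), seed = seed)
}

# Spherical-shell phantom (equal semi-axes) with analytic volume.
spherical_shell_spec <- function(r_endo = 22, r_epi = 32, noise_sigma = 0) {
  phantom_spec(grid_shape = c(64L, 64L, 24L), spacing = c(1.3, 1.3, 5),
               endo_radii = rep(r_endo, 3), epi_radii = rep(r_epi, 3),
               scar_patches = list(), noise_sigma = noise_sigma)
}

# Tissue label field built directly from a label array (0/1/2), all-TRUE
# mask. Bypasses PSI mapping so geometric oracles are exact.
field_from_labels <- function(lab, spacing = c(1.3, 1.3, 5)) {
  structure(
    list(labels = lab,
         config = threshold_config(40, 60),
         spacing = as.numeric(spacing),
         mask = array(TRUE, dim(lab))),
    class = "tissue_label_field"
  )
}

# Label array with a centred sphere of core (radius mm) in border zone.
sphere_core_labels <- function(n = 24L, spacing = 1.3, radius = 10) {
  co <- (seq_len(n) - 0.5) * spacing - n * spacing / 2
  X <- array(rep(co, n * n), rep(n, 3))
  Y <- array(rep(rep(co, each = n), n), rep(n, 3))
  Z <- array(rep(co, each = n * n), rep(n, 3))
  lab <- array(1L, rep(n, 3))
  lab[sqrt(X^2 + Y^2 + Z^2) <= radius] <- 2L
  lab
}

# Independent AUC oracle: exhaustive positive-negative pair enumeration.
auc_brute_force <- function(values, labels) {
  vp <- values[labels == 1]
  vn <- values[labels == 0]
  tot <- 0
  for (a in vp) for (b in vn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(vp) * length(vn))
}

# Independent boundary-contact oracle for corridor classification: loops
# over all BZ voxels and their 6 face neighbours.
contact_counts_brute <- function(labels, comp_ids) {
  d <- dim(labels)
  n_comp <- max(comp_ids)
  core <- numeric(n_comp)
  healthy <- numeric(n_comp)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    cid <- comp_ids[i, j, k]
    if (cid == 0L) next
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      lab <- labels[ii, jj, kk]
      if (is.na(lab) || lab == 1L) next
      if (lab == 2L) core[cid] <- core[cid] + 1
      else healthy[cid] <- healthy[cid] + 1
    }
  }
  list(core = core, healthy = healthy)
}
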