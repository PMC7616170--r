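#' Specify a synthetic left-ventricle LGE phantom
#'
#' Defines an ellipsoidal-shell left-ventricular myocardium on a regular
#' voxel grid, with optional scar patches (core plus border-zone rim and,
#' optionally, border-zone channels threading the core), three-level tissue
#' signal intensities and additive Gaussian noise. The long axis of the
#' ventricle is aligned with the slice normal (short-axis acquisition).
#'
#' @param grid_shape Integer length-3: voxels per axis.
#' @param spacing Numeric length-3: voxel spacing in mm. The default matches
#'   a typical short-axis LGE acquisition (1.3 x 1.3 mm in plane, 5 mm
#'   slices).
#' @param lv_center Numeric length-3 centre of the ventricle in mm; defaults
#'   to the grid centre.
#' @param endo_radii,epi_radii Numeric length-3 semi-axes (mm) of the
#'   endocardial and epicardial ellipsoids; `epi_radii` must exceed
#'   `endo_radii` in every component.
#' @param scar_patches List of [scar_patch()] specifications.
#' @param si_levels Named numeric length-3 mean signal intensity (arbitrary
#'   units) for healthy, border-zone and core tissue; must be strictly
#'   increasing (core is brightest on LGE). The default puts border zone at
#'   exactly half the core maximum, the premise of full-width-at-half-maximum
#'   thresholding.
#' @param noise_sigma Standard deviation of additive Gaussian noise, in SI
#'   units; must be non-negative.
#' @param blur_sigma_mm Optional partial-volume blur: standard deviation
#'   (mm, scalar or per-axis) of a Gaussian applied to the noise-free tissue
#'   signal within the myocardium before noise is added, emulating the
#'   scanner point-spread / partial-volume gradation at tissue boundaries.
#'   Default 0 (crisp three-level signal).
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [scar_patch()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 24L),
                         spacing = c(1.3, 1.3, 5.0),
                         lv_center = NULL,
                         endo_radii = c(22, 22, 45),
                         epi_radii = c(32, 32, 55),
                         scar_patches = list(),
                         si_levels = c(healthy = 20, bz = 50, core = 100),
                         noise_sigma = 4,
                         blur_sigma_mm = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop("grid_shape must be three positive integers", call. = FALSE)
  }
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be three positive values (mm)", call. = FALSE)
  }
  if (is.null(lv_center)) {
    lv_center <- grid_shape * spacing / 2
  }
  if (length(endo_radii) != 3 || length(epi_radii) != 3 ||
      any(endo_radii <= 0) || !all(epi_radii > endo_radii)) {
    stop("epi_radii must exceed endo_radii in every component ",
         "(nonempty myocardial shell)", call. = FALSE)
  }
  if (length(si_levels) != 3 || !all(diff(si_levels) > 0)) {
    stop("si_levels must be strictly increasing: healthy < BZ < core",
         call. = FALSE)
  }
  if (noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  blur_sigma_mm <- rep_len(as.numeric(blur_sigma_mm), 3)
  if (any(blur_sigma_mm < 0)) {
    stop("blur_sigma_mm must be >= 0", call. = FALSE)
  }
  for (p in scar_patches) {
    if (!inherits(p, "scar_patch")) {
      stop("scar_patches must be a list of scar_patch() objects",
           call. = FALSE)
    }
  }
  structure(
    list(grid_shape = grid_shape, spacing = as.numeric(spacing),
         lv_center = as.numeric(lv_center),
         endo_radii = as.numeric(endo_radii),
         epi_radii = as.numeric(epi_radii),
         scar_patches = scar_patches,
         si_levels = stats::setNames(as.numeric(si_levels),
                                     c("healthy", "bz", "core")),
         noise_sigma = as.numeric(noise_sigma),
         blur_sigma_mm = blur_sigma_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Specify a scar patch on the phantom ventricle
#'
#' A patch occupies a wedge of the myocardial shell: an angular sector
#' around the long axis, an apicobasal band (fraction of the LV length) and
#' a transmural depth range starting at the endocardium. The interior of
#' the patch is scar core; a border-zone rim of `bz_rim_mm` lines the patch
#' laterally, apicobasally, and on the epicardial side when the patch is
#' non-transmural (subendocardial infarcts touch the endocardium, so no rim
#' is placed there). Channels are carved through the core as border-zone
#' tubes fully enclosed by core.
#'
#' @param angle_center_deg Circumferential centre of the patch, degrees.
#' @param angular_extent_deg Circumferential width of the patch, degrees.
#' @param apicobasal_center Centre of the patch along the long axis as a
#'   fraction of LV length (0 = apex end of the grid, 1 = base end).
#' @param apicobasal_extent Apicobasal size as a fraction of LV length, in
#'   (0, 1].
#' @param transmural_extent Fraction of wall thickness reached by the patch,
#'   in (0, 1]; 1 is transmural.
#' @param bz_rim_mm Thickness of the border-zone rim, mm.
#' @param channels List of [bz_channel()] specifications.
#' @return An object of class `scar_patch`.
#' @export
scar_patch <- function(angle_center_deg = 0,
                       angular_extent_deg = 100,
                       apicobasal_center = 0.5,
                       apicobasal_extent = 0.45,
                       transmural_extent = 1,
                       bz_rim_mm = 2.6,
                       channels = list()) {
  if (transmural_extent <= 0 || transmural_extent > 1) {
    stop("transmural_extent must lie in (0, 1]", call. = FALSE)
  }
  if (apicobasal_extent <= 0 || apicobasal_extent > 1) {
    stop("apicobasal_extent must lie in (0, 1]", call. = FALSE)
  }
  if (angular_extent_deg <= 0 || angular_extent_deg > 360) {
    stop("angular_extent_deg must lie in (0, 360]", call. = FALSE)
  }
  if (bz_rim_mm < 0) stop("bz_rim_mm must be >= 0", call. = FALSE)
  for (ch in channels) {
    if (!inherits(ch, "bz_channel")) {
      stop("channels must be a list of bz_channel() objects", call. = FALSE)
    }
    if (ang_dist_deg(ch$angle_deg, angle_center_deg) >
        angular_extent_deg / 2) {
      stop("channel path must lie inside the patch (angle out of range)",
           call. = FALSE)
    }
  }
  structure(
    list(angle_center_deg = angle_center_deg,
         angular_extent_deg = angular_extent_deg,
         apicobasal_center = apicobasal_center,
         apicobasal_extent = apicobasal_extent,
         transmural_extent = transmural_extent,
         bz_rim_mm = bz_rim_mm,
         channels = channels),
    class = "scar_patch"
  )
}

#' Specify a border-zone channel through the scar core
#'
#' A channel is a border-zone tube carved out of the core, running
#' apicobasally at a fixed circumferential angle and mid-wall depth. The
#' default spans keep the tube strictly inside the core so that it is fully
#' enclosed ("surrounded by scar core") and hence a ground-truth conducting
#' corridor.
#'
#' @param angle_deg Circumferential position of the channel, degrees; must
#'   lie inside the parent patch.
#' @param width_mm Channel width, mm (> 0).
#' @param z_span Length-2 fractions of the core's apicobasal span covered by
#'   the channel (defaults to the middle half).
#' @param depth_span Length-2 fractions of the core's transmural span
#'   covered by the channel (defaults to the middle of the wall).
#' @return An object of class `bz_channel`.
#' @export
bz_channel <- function(angle_deg, width_mm = 4,
                       z_span = c(0.25, 0.75),
                       depth_span = c(0.3, 0.7)) {
  if (width_mm <= 0) stop("channel width must be > 0", call. = FALSE)
  if (length(z_span) != 2 || z_span[1] >= z_span[2] ||
      z_span[1] < 0 || z_span[2] > 1) {
    stop("z_span must be increasing fractions within [0, 1]", call. = FALSE)
  }
  if (length(depth_span) != 2 || depth_span[1] >= depth_span[2] ||
      depth_span[1] < 0 || depth_span[2] > 1) {
    stop("depth_span must be increasing fractions within [0, 1]",
         call. = FALSE)
  }
  structure(list(angle_deg = angle_deg, width_mm = width_mm,
                 z_span = as.numeric(z_span),
                 depth_span = as.numeric(depth_span)),
            class = "bz_channel")
}

#' Generate a synthetic LGE stack from a phantom specification
#'
#' Rasterizes the ellipsoidal myocardial shell, paints ground-truth tissue
#' labels (0 = healthy, 1 = border zone, 2 = core) from the scar patches,
#' and synthesizes signal intensity as the per-class mean plus additive
#' Gaussian noise, clipped at zero. The result is bit-reproducible for a
#' given spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `lge_stack` with fields `image` (3D SI
#'   array), `spacing` (mm), `myocardium_mask` (logical 3D array),
#'   `truth_labels` (integer 3D array, `NA` outside the mask) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  co <- coord_arrays(d, spec$spacing)
  cx <- spec$lv_center[1]; cy <- spec$lv_center[2]; cz <- spec$lv_center[3]
  X <- co$X - cx; Y <- co$Y - cy; Z <- co$Z - cz
  en <- spec$endo_radii; ep <- spec$epi_radii
  m_en <- sqrt((X / en[1])^2 + (Y / en[2])^2 + (Z / en[3])^2)
  m_ep <- sqrt((X / ep[1])^2 + (Y / ep[2])^2 + (Z / ep[3])^2)
  mask <- m_en >= 1 & m_ep <= 1
  if (!any(mask)) {
    stop("phantom specification yields an empty myocardial shell ",
         "(shell does not intersect the grid)", call. = FALSE)
  }

  # Wall-depth proxy: 0 at the endocardium, 1 at the epicardium.
  num <- m_en - 1
  den <- num + (1 - m_ep)
  depth <- array(0, d)
  ok <- den > 0
  depth[ok] <- num[ok] / den[ok]
  theta <- (atan2(Y, X) * 180 / pi) %% 360
  s_ab <- (Z + ep[3]) / (2 * ep[3])  # apicobasal fraction of LV length

  labels <- array(NA_integer_, d)
  labels[mask] <- 0L
  wall_mm <- mean(ep[1:2] - en[1:2])
  r_inplane <- sqrt(X^2 + Y^2)

  for (p in spec$scar_patches) {
    in_ang <- ang_dist_deg(theta, p$angle_center_deg) <=
      p$angular_extent_deg / 2
    in_z <- abs(s_ab - p$apicobasal_center) <= p$apicobasal_extent / 2
    in_d <- depth <= p$transmural_extent
    patch <- mask & in_ang & in_z & in_d
    if (!any(patch)) next
    r_mid <- mean(r_inplane[patch])
    d_theta <- (p$bz_rim_mm / r_mid) * 180 / pi
    d_z <- p$bz_rim_mm / (2 * ep[3])
    d_depth <- if (p$transmural_extent < 1) p$bz_rim_mm / wall_mm else 0
    core <- patch &
      ang_dist_deg(theta, p$angle_center_deg) <=
        p$angular_extent_deg / 2 - d_theta &
      abs(s_ab - p$apicobasal_center) <= p$apicobasal_extent / 2 - d_z &
      depth <= p$transmural_extent - d_depth
    labels[patch] <- 1L
    labels[core] <- 2L

    h_z <- p$apicobasal_extent / 2 - d_z       # core apicobasal half-span
    d_max <- p$transmural_extent - d_depth     # core transmural reach
    for (ch in p$channels) {
      w_theta <- (ch$width_mm / 2 / r_mid) * 180 / pi
      s_lo <- p$apicobasal_center + (ch$z_span[1] - 0.5) * 2 * h_z
      s_hi <- p$apicobasal_center + (ch$z_span[2] - 0.5) * 2 * h_z
      in_ch <- core &
        ang_dist_deg(theta, ch$angle_deg) <= w_theta &
        s_ab >= s_lo & s_ab <= s_hi &
        depth >= ch$depth_span[1] * d_max & depth <= ch$depth_span[2] * d_max
      labels[in_ch] <- 1L
    }
  }

  image <- array(0, d)
  base <- spec$si_levels[labels[mask] + 1L]
  if (any(spec$blur_sigma_mm > 0)) {
    # Mask-normalized smoothing: partial volume between tissue classes
    # without darkening toward the (unmodelled) blood pool and air.
    L <- array(0, d); L[mask] <- base
    W <- array(0, d); W[mask] <- 1
    sig_vox <- spec$blur_sigma_mm / spec$spacing
    Ls <- smooth_gaussian3(L, sig_vox)
    Ws <- smooth_gaussian3(W, sig_vox)
    base <- Ls[mask] / Ws[mask]
  }
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(sum(mask), 0, spec$noise_sigma))
    image[mask] <- pmax(0, base + noise)
  } else {
    image[mask] <- base
  }

  structure(
    list(image = image, spacing = spec$spacing, myocardium_mask = mask,
         truth_labels = labels, spec = spec),
    class = "lge_stack"
  )
}

#' Construct an LGE stack from raw arrays
#'
#' Wraps an image volume, voxel spacing and a myocardium mask (and, for
#' phantoms, ground-truth labels) into the container consumed by the
#' pipeline.
#'
#' @param image 3D numeric array of signal intensities.
#' @param spacing Numeric length-3 voxel spacing, mm.
#' @param myocardium_mask Logical 3D array, same shape as `image`.
#' @param truth_labels Optional integer 3D array in \{0, 1, 2\} inside the
#'   mask, `NA` outside.
#' @return An `lge_stack` object.
#' @export
lge_stack <- function(image, spacing, myocardium_mask, truth_labels = NULL) {
  stopifnot(length(dim(image)) == 3)
  if (!identical(dim(image), dim(myocardium_mask))) {
    stop("image and myocardium_mask must share one shape", call. = FALSE)
  }
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be three positive values (mm)", call. = FALSE)
  }
  if (!any(myocardium_mask)) {
    stop("myocardium_mask must be nonempty", call. = FALSE)
  }
  if (!is.null(truth_labels)) {
    if (!identical(dim(truth_labels), dim(image))) {
      stop("truth_labels must share the image shape", call. = FALSE)
    }
    if (any(!is.na(truth_labels[!myocardium_mask]))) {
      stop("truth_labels must be defined only inside the myocardium mask",
           call. = FALSE)
    }
  }
  structure(
    list(image = image, spacing = as.numeric(spacing),
         myocardium_mask = myocardium_mask, truth_labels = truth_labels,
         spec = NULL),
    class = "lge_stack"
  )
}

#' @export
print.lge_stack <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<lge_stack> %d x %d x %d voxels @ %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  myocardium: %d voxels", sum(x$myocardium_mask)))
  if (!is.null(x$truth_labels)) {
    tab <- tabulate(x$truth_labels[x$myocardium_mask] + 1L, 3L)
    cat(sprintf(" (truth: %d healthy, %d BZ, %d core)",
                tab[1], tab[2], tab[3]))
  }
  cat("\n")
  invisible(x)
}

#' Ground-truth tissue label field of a phantom
#'
#' Converts a phantom's ground-truth labels into the same container produced
#' by [classify_psi()], so that masses, corridors and meshes can be computed
#' against the known geometry.
#'
#' @param stack An `lge_stack` carrying `truth_labels`.
#' @return A `tissue_label_field` object.
#' @export
truth_label_field <- function(stack) {
  stopifnot(inherits(stack, "lge_stack"))
  if (is.null(stack$truth_labels)) {
    stop("stack carries no ground-truth labels", call. = FALSE)
  }
  structure(
    list(labels = stack$truth_labels,
         config = threshold_config(40, 60, name = "ground truth"),
         spacing = stack$spacing,
         mask = stack$myocardium_mask),
    class = "tissue_label_field"
  )
}
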