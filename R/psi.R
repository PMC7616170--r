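#' Compute a full-width-at-half-maximum PSI map
#'
#' Normalizes the myocardial signal intensity to a reference maximum and
#' expresses each voxel as pixel signal intensity (PSI) in percent, the
#' domain of full-width-at-half-maximum scar thresholding: a voxel at half
#' the maximal myocardial signal has PSI 50. Values above the reference
#' (possible in the robust mode) are clipped to 100.
#'
#' @param stack An `lge_stack`.
#' @param mode Reference maximum: `"robust_percentile"` (default) takes a
#'   high percentile of in-mask signal, guarding against isolated hot
#'   voxels; `"global_max"` takes the in-mask maximum exactly.
#' @param percentile Percentile used by the robust mode (default 98).
#' @return An object of class `psi_map` with fields `psi` (3D array in
#'   percent, `NA` outside the mask), `reference_max`, `normalization_mode`,
#'   `spacing` and `mask`.
#' @export
compute_psi <- function(stack, mode = c("robust_percentile", "global_max"),
                        percentile = 98) {
  stopifnot(inherits(stack, "lge_stack"))
  mode <- match.arg(mode)
  mask <- stack$myocardium_mask
  if (!any(mask)) stop("myocardium mask is empty", call. = FALSE)
  si <- stack$image[mask]
  if (any(si < 0)) stop("image must be non-negative", call. = FALSE)
  ref <- if (mode == "global_max") {
    max(si)
  } else {
    stats::quantile(si, percentile / 100, names = FALSE)
  }
  if (ref <= 0) {
    stop("reference maximum is zero (flat zero image in mask)",
         call. = FALSE)
  }
  psi <- array(NA_real_, dim(stack$image))
  psi[mask] <- pmin(100 * si / ref, 100)
  structure(
    list(psi = psi, reference_max = ref, normalization_mode = mode,
         percentile = if (mode == "robust_percentile") percentile else NA,
         spacing = stack$spacing, mask = mask),
    class = "psi_map"
  )
}

#' @export
print.psi_map <- function(x, ...) {
  cat(sprintf("<psi_map> %s normalization, reference max %.3g SI units\n",
              x$normalization_mode, x$reference_max))
  q <- stats::quantile(x$psi[x$mask], c(0, .5, 1))
  cat(sprintf("  PSI in mask: min %.1f%%, median %.1f%%, max %.1f%%\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' Build a concentric-layer shell model of the left ventricle
#'
#' Represents the myocardium as `n_layers` concentric triangulated surfaces
#' from the endocardium (layer 1) to the epicardium (layer `n_layers`),
#' mirroring the layered LV models used clinically for scar visualization.
#' On each slice occupied by the mask, rays are cast from the slice centroid
#' of the mask at `n_theta` equispaced angles; the first contiguous in-mask
#' run along each ray gives the endocardial and epicardial wall radii, and
#' layer k sits at relative wall depth (k-1)/(n_layers-1). Per-vertex PSI is
#' sampled from the PSI volume by (NA-aware) trilinear interpolation.
#'
#' @param stack An `lge_stack`.
#' @param psi Optional `psi_map`; if supplied, each vertex carries a `psi`
#'   value.
#' @param n_layers Number of layers (>= 2); 2 gives just the endocardial and
#'   epicardial surfaces.
#' @param n_theta Angular samples per slice.
#' @param radial_step Ray-march step in mm; defaults to a quarter of the
#'   in-plane spacing.
#' @return An object of class `layered_shell_model`: list of per-layer
#'   surfaces (`vertices` n x 3 mm, `faces` m x 3 indices, `psi`), plus the
#'   slice z-coordinates, angles and wall radii.
#' @export
build_layered_model <- function(stack, psi = NULL, n_layers = 9,
                                n_theta = 96, radial_step = NULL) {
  stopifnot(inherits(stack, "lge_stack"))
  if (n_layers < 2) stop("n_layers must be >= 2", call. = FALSE)
  if (!is.null(psi)) stopifnot(inherits(psi, "psi_map"))
  d <- dim(stack$myocardium_mask)
  sp <- stack$spacing
  if (is.null(radial_step)) radial_step <- min(sp[1:2]) / 4

  slice_has <- which(apply(stack$myocardium_mask, 3, any))
  if (!length(slice_has)) stop("myocardium mask is empty", call. = FALSE)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  r_max <- sqrt((d[1] * sp[1])^2 + (d[2] * sp[2])^2)
  radii <- seq(0, r_max, by = radial_step)

  ns <- length(slice_has)
  r_en <- matrix(NA_real_, ns, n_theta)
  r_ep <- matrix(NA_real_, ns, n_theta)
  centers <- matrix(NA_real_, ns, 2)
  for (si in seq_len(ns)) {
    k <- slice_has[si]
    m2 <- stack$myocardium_mask[, , k]
    ij <- which(m2, arr.ind = TRUE)
    cx <- mean((ij[, 1] - 0.5) * sp[1])
    cy <- mean((ij[, 2] - 0.5) * sp[2])
    centers[si, ] <- c(cx, cy)
    for (ti in seq_len(n_theta)) {
      px <- cx + radii * cos(theta[ti])
      py <- cy + radii * sin(theta[ti])
      ii <- round(px / sp[1] + 0.5)
      jj <- round(py / sp[2] + 0.5)
      inside <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
      hit <- logical(length(radii))
      hit[inside] <- m2[cbind(ii[inside], jj[inside])]
      w <- which(hit)
      if (!length(w)) {
        stop(sprintf(
          "zero wall thickness on slice %d (ray at %.1f deg misses the mask)",
          k, theta[ti] * 180 / pi), call. = FALSE)
      }
      # first contiguous in-mask run = the wall crossed by this ray
      run_end <- w[c(diff(w) != 1L, TRUE)][1]
      r_en[si, ti] <- radii[w[1]]
      r_ep[si, ti] <- radii[run_end]
    }
  }

  z <- (slice_has - 0.5) * sp[3]
  layers <- vector("list", n_layers)
  faces <- shell_faces(ns, n_theta)
  for (lay in seq_len(n_layers)) {
    f <- (lay - 1) / (n_layers - 1)
    r <- r_en + f * (r_ep - r_en)
    vx <- centers[, 1] + r * matrix(cos(theta), ns, n_theta, byrow = TRUE)
    vy <- centers[, 2] + r * matrix(sin(theta), ns, n_theta, byrow = TRUE)
    vz <- matrix(z, ns, n_theta)
    verts <- cbind(as.vector(t(vx)), as.vector(t(vy)), as.vector(t(vz)))
    vpsi <- if (!is.null(psi)) {
      interp_trilinear(psi$psi, sp, verts)
    } else NULL
    layers[[lay]] <- list(vertices = verts, faces = faces, psi = vpsi)
  }

  structure(
    list(n_layers = as.integer(n_layers), layers = layers,
         slice_z = z, theta = theta,
         centers = centers, r_endo = r_en, r_epi = r_ep, spacing = sp),
    class = "layered_shell_model"
  )
}

# Triangulation of the (slice x angle) vertex grid, shared by all layers.
# Vertices are stored angle-fastest: index (si, ti) -> (si - 1) * nt + ti.
shell_faces <- function(ns, nt) {
  if (ns < 2) return(matrix(integer(0), 0, 3))
  out <- vector("list", ns - 1)
  for (si in seq_len(ns - 1)) {
    t0 <- seq_len(nt)
    t1 <- c(seq_len(nt)[-1], 1L)
    a <- (si - 1L) * nt + t0
    b <- (si - 1L) * nt + t1
    a2 <- si * nt + t0
    b2 <- si * nt + t1
    out[[si]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  do.call(rbind, out)
}

#' @export
print.layered_shell_model <- function(x, ...) {
  cat(sprintf(
    "<layered_shell_model> %d layers, %d slices x %d angles (%d vertices/layer)\n",
    x$n_layers, length(x$slice_z), length(x$theta),
    nrow(x$layers[[1]]$vertices)))
  invisible(x)
}
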