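# Labeled volumetric meshes and tissue-interface surface areas.
#
# Voxel path: each in-mask voxel is split into 5 tetrahedra inheriting the
# voxel's tissue label, with the mirrored (checkerboard-parity) variant of
# the 5-tet decomposition so that face diagonals of neighbouring voxels
# coincide and interior facets match exactly.
#
# Layer path: triangular prisms between consecutive shell layers are split
# into 3 tetrahedra each (diagonals chosen consistently from global vertex
# ids), with the element label taken from the classified PSI at the element
# centroid.

# Corner numbering of the unit cube (bit order x, y, z):
# v0=(0,0,0) v1=(1,0,0) v2=(0,1,0) v3=(1,1,0)
# v4=(0,0,1) v5=(1,0,1) v6=(0,1,1) v7=(1,1,1)
tet5_even <- matrix(c(
  0, 1, 3, 5,
  2, 0, 3, 6,
  4, 0, 5, 6,
  7, 3, 5, 6,
  0, 3, 5, 6), ncol = 4, byrow = TRUE) + 1L
tet5_odd <- matrix(c(
  0, 1, 2, 4,
  3, 1, 2, 7,
  5, 1, 4, 7,
  6, 2, 4, 7,
  1, 2, 4, 7), ncol = 4, byrow = TRUE) + 1L

#' Build a labeled tetrahedral volume mesh
#'
#' Converts a classified tissue field (voxel path) or a layered shell model
#' plus PSI map and threshold configuration (layer path) into a tetrahedral
#' mesh in which every element carries a tissue label (0 healthy, 1 border
#' zone, 2 core). See [interface_area()] for the interface metrics computed
#' on such meshes.
#'
#' @param x A `tissue_label_field` or a `layered_shell_model`.
#' @param ... Passed to methods.
#' @return An object of class `labeled_volume_mesh` with fields `vertices`
#'   (n x 3, mm), `elements` (m x 4 vertex indices, positively oriented) and
#'   `labels` (integer per element).
#' @export
build_labeled_mesh <- function(x, ...) {
  UseMethod("build_labeled_mesh")
}

#' @rdname build_labeled_mesh
#' @export
build_labeled_mesh.tissue_label_field <- function(x, ...) {
  mask <- x$mask
  if (!any(mask)) stop("label field covers no voxels", call. = FALSE)
  d <- dim(mask)
  sp <- x$spacing
  vox <- which(mask, arr.ind = TRUE)
  nv <- nrow(vox)
  i <- vox[, 1]; j <- vox[, 2]; k <- vox[, 3]

  # Global corner-grid ids on the (nx+1)(ny+1)(nz+1) lattice.
  nxc <- d[1] + 1L; nyc <- d[2] + 1L
  cid <- function(ci, cj, ck) ci + (cj - 1L) * nxc + (ck - 1L) * nxc * nyc
  corners <- cbind(
    cid(i,      j,      k),       # v0
    cid(i + 1L, j,      k),       # v1
    cid(i,      j + 1L, k),       # v2
    cid(i + 1L, j + 1L, k),       # v3
    cid(i,      j,      k + 1L),  # v4
    cid(i + 1L, j,      k + 1L),  # v5
    cid(i,      j + 1L, k + 1L),  # v6
    cid(i + 1L, j + 1L, k + 1L))  # v7

  parity <- (i + j + k) %% 2L
  vox_lab <- x$labels[cbind(i, j, k)]
  elem_list <- vector("list", 10L)
  lab_list <- vector("list", 10L)
  n_out <- 0L
  for (p in 0:1) {
    rows <- which(parity == p)
    if (!length(rows)) next
    tets <- if (p == 0L) tet5_even else tet5_odd
    for (t in 1:5) {
      n_out <- n_out + 1L
      elem_list[[n_out]] <- corners[rows, tets[t, ], drop = FALSE]
      lab_list[[n_out]] <- vox_lab[rows]
    }
  }
  elements <- do.call(rbind, elem_list[seq_len(n_out)])
  labels <- unlist(lab_list[seq_len(n_out)])

  used <- sort(unique(as.vector(elements)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[elements], ncol = 4)
  ck <- (used - 1L) %/% (nxc * nyc)
  rem <- (used - 1L) %% (nxc * nyc)
  cj <- rem %/% nxc
  ci <- rem %% nxc
  vertices <- cbind(ci * sp[1], cj * sp[2], ck * sp[3])

  mesh <- new_labeled_mesh(vertices, elements, labels, sp)
  attr(mesh, "source_field") <- x
  mesh
}

#' @rdname build_labeled_mesh
#' @param psi A `psi_map` (layer path).
#' @param config A [threshold_config()] (layer path).
#' @param min_volume_mm3 Elements with volume below this tolerance are
#'   dropped as degenerate (layer path).
#' @export
build_labeled_mesh.layered_shell_model <- function(x, psi, config,
                                                   min_volume_mm3 = 1e-9,
                                                   ...) {
  stopifnot(inherits(psi, "psi_map"), inherits(config, "threshold_config"))
  nl <- x$n_layers
  bad <- which(x$r_epi < x$r_endo, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "inverted shell surfaces: epicardial radius below endocardial radius %s",
      paste0("at slice index ", bad[1, 1], ", angle index ", bad[1, 2],
             " (layers 1-", nl, " cross)")), call. = FALSE)
  }
  npl <- nrow(x$layers[[1]]$vertices)  # vertices per layer
  vertices <- do.call(rbind, lapply(x$layers, `[[`, "vertices"))
  faces <- x$layers[[1]]$faces
  tet_list <- vector("list", nl - 1)
  for (lay in seq_len(nl - 1)) {
    off_b <- (lay - 1L) * npl
    off_t <- lay * npl
    prisms <- cbind(faces + off_b, faces + off_t)  # (a,b,c, a',b',c')
    tet_list[[lay]] <- split_prisms(prisms)
  }
  elements <- do.call(rbind, tet_list)

  vol <- tet_signed_volumes(vertices, elements)
  swap <- vol < 0
  if (any(swap)) {
    tmp <- elements[swap, 3L]
    elements[swap, 3L] <- elements[swap, 4L]
    elements[swap, 4L] <- tmp
  }
  keep <- abs(vol) > min_volume_mm3
  elements <- elements[keep, , drop = FALSE]
  if (!nrow(elements)) {
    stop("all layer-path elements are degenerate", call. = FALSE)
  }

  cent <- (vertices[elements[, 1], ] + vertices[elements[, 2], ] +
             vertices[elements[, 3], ] + vertices[elements[, 4], ]) / 4
  cpsi <- interp_trilinear(psi$psi, psi$spacing, cent)
  cpsi[is.na(cpsi)] <- 0  # centroids sampling outside the mask: healthy
  labels <- integer(nrow(elements))
  labels[cpsi >= config$t_low & cpsi <= config$t_high] <- 1L
  labels[cpsi > config$t_high] <- 2L

  new_labeled_mesh(vertices, elements, labels, x$spacing)
}

# Consistent prism -> 3 tets split: the smallest global vertex id is rotated
# to position 0, then the quad-face diagonals follow from comparing global
# ids, so neighbouring prisms agree on shared faces.
split_prisms <- function(pr) {
  n <- nrow(pr)
  # Rotations of (bottom a b c | top d e f) keeping orientation:
  rots <- list(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4),
               c(3, 1, 2, 6, 4, 5), c(4, 6, 5, 1, 3, 2),
               c(6, 5, 4, 3, 2, 1), c(5, 4, 6, 2, 1, 3))
  minpos <- max.col(-pr, ties.method = "first")
  out <- matrix(0L, 3L * n, 4L)
  for (rpos in 1:6) {
    rows <- which(minpos == rpos)
    if (!length(rows)) next
    q <- pr[rows, rots[[rpos]], drop = FALSE]
    # Now q[,1] holds the smallest id: vertices (0:b0,1:b1,2:b2,3:t0,4:t1,5:t2)
    caseA <- pmin(q[, 2], q[, 6]) < pmin(q[, 3], q[, 5])
    idxA <- rows[caseA]; qa <- q[caseA, , drop = FALSE]
    idxB <- rows[!caseA]; qb <- q[!caseA, , drop = FALSE]
    if (length(idxA)) {
      out[3 * (idxA - 1) + 1, ] <- qa[, c(1, 2, 3, 6)]
      out[3 * (idxA - 1) + 2, ] <- qa[, c(1, 2, 6, 5)]
      out[3 * (idxA - 1) + 3, ] <- qa[, c(1, 5, 6, 4)]
    }
    if (length(idxB)) {
      out[3 * (idxB - 1) + 1, ] <- qb[, c(1, 2, 3, 5)]
      out[3 * (idxB - 1) + 2, ] <- qb[, c(1, 5, 3, 6)]
      out[3 * (idxB - 1) + 3, ] <- qb[, c(1, 5, 6, 4)]
    }
  }
  out
}

new_labeled_mesh <- function(vertices, elements, labels, spacing) {
  vol <- tet_signed_volumes(vertices, elements)
  swap <- vol < 0
  if (any(swap)) {
    tmp <- elements[swap, 3L]
    elements[swap, 3L] <- elements[swap, 4L]
    elements[swap, 4L] <- tmp
  }
  structure(
    list(vertices = vertices, elements = elements,
         labels = as.integer(labels), spacing = spacing),
    class = "labeled_volume_mesh"
  )
}

tet_signed_volumes <- function(vertices, elements) {
  a <- vertices[elements[, 1], , drop = FALSE]
  b <- vertices[elements[, 2], , drop = FALSE] - a
  c2 <- vertices[elements[, 3], , drop = FALSE] - a
  d2 <- vertices[elements[, 4], , drop = FALSE] - a
  (b[, 1] * (c2[, 2] * d2[, 3] - c2[, 3] * d2[, 2]) -
     b[, 2] * (c2[, 1] * d2[, 3] - c2[, 3] * d2[, 1]) +
     b[, 3] * (c2[, 1] * d2[, 2] - c2[, 2] * d2[, 1])) / 6
}

#' Total mesh volume
#'
#' @param mesh A `labeled_volume_mesh`.
#' @param units `"ml"` (default) or `"mm3"`.
#' @return Total volume of all elements.
#' @export
mesh_volume <- function(mesh, units = c("ml", "mm3")) {
  stopifnot(inherits(mesh, "labeled_volume_mesh"))
  units <- match.arg(units)
  v <- sum(abs(tet_signed_volumes(mesh$vertices, mesh$elements)))
  if (units == "ml") v / 1000 else v
}

#' @export
print.labeled_volume_mesh <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, 3L)
  cat(sprintf(
    "<labeled_volume_mesh> %d vertices, %d tetrahedra (%d healthy, %d BZ, %d core)\n",
    nrow(x$vertices), nrow(x$elements), tab[1], tab[2], tab[3]))
  cat(sprintf("  volume %.2f mL\n", mesh_volume(x)))
  invisible(x)
}

# Interior facets of a tet mesh: rows of the 4 faces per element, matched
# into pairs. Returns a list with the facet vertex triples and the two
# adjacent element ids.
interior_facets <- function(elements) {
  n <- nrow(elements)
  fc <- rbind(elements[, c(1, 2, 3)], elements[, c(1, 2, 4)],
              elements[, c(1, 3, 4)], elements[, c(2, 3, 4)])
  eid <- rep.int(seq_len(n), 4L)
  lo <- pmin(fc[, 1], fc[, 2], fc[, 3])
  hi <- pmax(fc[, 1], fc[, 2], fc[, 3])
  mid <- fc[, 1] + fc[, 2] + fc[, 3] - lo - hi
  ord <- order(lo, mid, hi, method = "radix")
  lo <- lo[ord]; mid <- mid[ord]; hi <- hi[ord]; eid <- eid[ord]
  same <- lo[-1] == lo[-length(lo)] & mid[-1] == mid[-length(mid)] &
    hi[-1] == hi[-length(hi)]
  first <- which(same)
  list(v = cbind(lo[first], mid[first], hi[first]),
       e1 = eid[first], e2 = eid[first + 1L])
}

#' Interface surface area between tissue classes
#'
#' Sums the areas of interior mesh facets whose two adjacent elements carry
#' labels on opposite sides of the requested pair: for `healthy_vs_he` the
#' border zone and core are merged into one hyperenhanced side; for
#' `bz_vs_core` only facets between border-zone and core elements count.
#'
#' Two estimators are available. `"facet"` sums raw facet areas — the exact
#' staircase boundary of the labeled mesh, conserving every interior facet
#' once. Staircase surfaces systematically exceed the area of the smooth
#' boundary they discretize (for a sphere by a factor approaching 1.5), so
#' `"normal_weighted"` instead weights each facet by the cosine between the
#' facet normal and the local boundary orientation estimated from the
#' gradient of a Gaussian-smoothed class-indicator volume — a convergent
#' voxel surface-area estimator that leaves flat axis-aligned interfaces
#' untouched. The weighted estimator needs the source voxel field and is
#' available for meshes from the voxel path.
#'
#' @param mesh A `labeled_volume_mesh`.
#' @param pair `"healthy_vs_he"` or `"bz_vs_core"`.
#' @param method `"facet"` (default) or `"normal_weighted"`.
#' @param smooth_sigma_mm Smoothing length (mm) for the indicator gradient
#'   of the weighted estimator.
#' @param units `"cm2"` (default) or `"mm2"`.
#' @return The interface area as a single number.
#' @export
interface_area <- function(mesh, pair = c("healthy_vs_he", "bz_vs_core"),
                           method = c("facet", "normal_weighted"),
                           smooth_sigma_mm = 2.6,
                           units = c("cm2", "mm2")) {
  stopifnot(inherits(mesh, "labeled_volume_mesh"))
  pair <- match.arg(pair)
  method <- match.arg(method)
  units <- match.arg(units)

  side <- switch(pair,
    healthy_vs_he = ifelse(mesh$labels == 0L, 1L, 2L),
    bz_vs_core = ifelse(mesh$labels == 1L, 1L,
                        ifelse(mesh$labels == 2L, 2L, 0L))
  )
  fac <- interior_facets(mesh$elements)
  s1 <- side[fac$e1]
  s2 <- side[fac$e2]
  onif <- (s1 == 1L & s2 == 2L) | (s1 == 2L & s2 == 1L)
  if (!any(onif)) {
    return(0)
  }
  v <- fac$v[onif, , drop = FALSE]
  p1 <- mesh$vertices[v[, 1], , drop = FALSE]
  p2 <- mesh$vertices[v[, 2], , drop = FALSE]
  p3 <- mesh$vertices[v[, 3], , drop = FALSE]
  u <- p2 - p1
  w <- p3 - p1
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))

  if (method == "normal_weighted") {
    field <- attr(mesh, "source_field")
    if (is.null(field)) {
      stop("normal_weighted interface areas need a mesh built from a ",
           "tissue label field (voxel path)", call. = FALSE)
    }
    ind <- array(0, dim(field$labels))
    inset <- switch(pair,
      healthy_vs_he = !is.na(field$labels) & field$labels > 0L,
      bz_vs_core = !is.na(field$labels) & field$labels == 2L)
    ind[inset] <- 1
    sigma_vox <- smooth_sigma_mm / field$spacing
    sm <- smooth_gaussian3(ind, sigma_vox)
    g <- indicator_gradient(sm, field$spacing)
    cent <- (p1 + p2 + p3) / 3
    gx <- interp_trilinear(g$x, field$spacing, cent)
    gy <- interp_trilinear(g$y, field$spacing, cent)
    gz <- interp_trilinear(g$z, field$spacing, cent)
    gn <- sqrt(gx^2 + gy^2 + gz^2)
    nh <- cr / sqrt(rowSums(cr^2))
    wgt <- abs(nh[, 1] * gx + nh[, 2] * gy + nh[, 3] * gz) / gn
    wgt[!is.finite(wgt) | gn < 1e-10] <- 1
    areas <- areas * pmin(wgt, 1)
  }

  total <- sum(areas)
  if (units == "cm2") total / 100 else total
}

indicator_gradient <- function(arr, spacing) {
  d <- dim(arr)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (arr[3:d[1], , ] - arr[1:(d[1] - 2), , ]) /
    (2 * spacing[1])
  gy[, 2:(d[2] - 1), ] <- (arr[, 3:d[2], ] - arr[, 1:(d[2] - 2), ]) /
    (2 * spacing[2])
  gz[, , 2:(d[3] - 1)] <- (arr[, , 3:d[3]] - arr[, , 1:(d[3] - 2)]) /
    (2 * spacing[3])
  list(x = gx, y = gy, z = gz)
}

#' Interface report for a labeled mesh
#'
#' The two interface metrics used for outcome prediction: the surface area
#' between healthy myocardium and hyperenhanced tissue (BZ plus core) and
#' between border zone and scar core, in cm^2.
#'
#' @param mesh A `labeled_volume_mesh`.
#' @param method Estimator passed to [interface_area()].
#' @return A list of class `interface_report` with fields
#'   `area_healthy_he_cm2` and `area_bz_core_cm2`.
#' @export
interface_report <- function(mesh, method = "facet") {
  structure(
    list(area_healthy_he_cm2 = interface_area(mesh, "healthy_vs_he",
                                              method = method),
         area_bz_core_cm2 = interface_area(mesh, "bz_vs_core",
                                           method = method),
         method = method),
    class = "interface_report"
  )
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "<interface_report> healthy-HE %.2f cm^2 | BZ-core %.2f cm^2 (%s)\n",
    x$area_healthy_he_cm2, x$area_bz_core_cm2, x$method))
  invisible(x)
}
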