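# Internal geometry and array helpers shared across modules.

#' Voxel volume in millilitres
#'
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return Volume of one voxel in mL.
#' @keywords internal
voxel_volume_ml <- function(spacing) {
  stopifnot(length(spacing) == 3, all(spacing > 0))
  prod(spacing) / 1000
}

# Voxel-centre world coordinates: centre of voxel i along an axis with
# spacing h sits at (i - 0.5) * h.
coord_arrays <- function(dim, spacing) {
  x <- (seq_len(dim[1]) - 0.5) * spacing[1]
  y <- (seq_len(dim[2]) - 0.5) * spacing[2]
  z <- (seq_len(dim[3]) - 0.5) * spacing[3]
  list(
    X = array(rep(x, times = dim[2] * dim[3]), dim),
    Y = array(rep(rep(y, each = dim[1]), times = dim[3]), dim),
    Z = array(rep(z, each = dim[1] * dim[2]), dim)
  )
}

# Angular distance in degrees, wrapped to [0, 180].
ang_dist_deg <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

# Pairs of linear indices (src, dst) of nonzero entries of integer array A
# related by the voxel offset `off`. Used to build adjacency edge lists.
offset_pairs <- function(A, off) {
  d <- dim(A)
  sx <- seq.int(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
  sy <- seq.int(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
  sz <- seq.int(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
  if (!length(sx) || !length(sy) || !length(sz)) {
    return(cbind(integer(0), integer(0)))
  }
  src <- A[sx, sy, sz, drop = FALSE]
  dst <- A[sx + off[1], sy + off[2], sz + off[3], drop = FALSE]
  keep <- src > 0L & dst > 0L
  cbind(src[keep], dst[keep])
}

# 26-connected component labelling of a logical 3D array.
# Returns an integer array: 0 outside `member`, component id inside.
label_components_26 <- function(member) {
  stopifnot(is.logical(member), length(dim(member)) == 3)
  n <- sum(member)
  ids <- array(0L, dim(member))
  if (n == 0L) {
    return(ids)
  }
  ids[member] <- seq_len(n)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0:1))
  offs <- offs[offs[, 3] == 1L | offs[, 2] == 1L |
                 (offs[, 2] == 0L & offs[, 1] == 1L), , drop = FALSE]
  edges <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    offset_pairs(ids, offs[k, ])
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    comp <- seq_len(n)
  } else {
    g <- igraph::make_graph(edges = as.vector(t(edges)), n = n,
                            directed = FALSE)
    comp <- igraph::components(g)$membership
  }
  out <- array(0L, dim(member))
  out[member] <- as.integer(comp)
  out
}

# Separable Gaussian smoothing of a 3D array; sigma given per axis in voxel
# units. Truncated kernels are renormalized at the borders.
smooth_gaussian3 <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3)
  sigma_vox <- rep_len(sigma_vox, 3)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-h, h), sd = s)
    arr <- conv_axis(arr, k, axis)
  }
  arr
}

conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  h <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - h):(i + h)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  perm <- c(axis, setdiff(1:3, axis))
  B <- aperm(arr, perm)
  M <- matrix(B, d[axis], prod(d[-axis]))
  out <- array(K %*% M, d[perm])
  aperm(out, order(perm))
}

# NA-aware trilinear interpolation of a 3D array at world points (mm, n x 3).
# Weights of NA corners are dropped and the remainder renormalized; points
# whose eight surrounding corners are all NA give NA.
interp_trilinear <- function(arr, spacing, pts) {
  stopifnot(length(dim(arr)) == 3, ncol(pts) == 3)
  d <- dim(arr)
  npt <- nrow(pts)
  fi <- sweep(pts, 2, spacing, "/") + 0.5  # fractional voxel index
  i0 <- pmin(pmax(floor(fi), 1), rep(d, each = npt))
  i0 <- matrix(pmin(i0, rep(d - 1L, each = npt) + 0L), ncol = 3)
  i0[, 1] <- pmin(i0[, 1], max(d[1] - 1L, 1L))
  i0[, 2] <- pmin(i0[, 2], max(d[2] - 1L, 1L))
  i0[, 3] <- pmin(i0[, 3], max(d[3] - 1L, 1L))
  fr <- fi - i0
  fr <- pmin(pmax(fr, 0), 1)
  acc <- numeric(npt)
  wacc <- numeric(npt)
  for (cz in 0:1) {
    for (cy in 0:1) {
      for (cx in 0:1) {
        ii <- pmin(i0[, 1] + cx, d[1])
        jj <- pmin(i0[, 2] + cy, d[2])
        kk <- pmin(i0[, 3] + cz, d[3])
        w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
          (if (cy) fr[, 2] else 1 - fr[, 2]) *
          (if (cz) fr[, 3] else 1 - fr[, 3])
        v <- arr[cbind(ii, jj, kk)]
        ok <- !is.na(v) & w > 0
        acc[ok] <- acc[ok] + w[ok] * v[ok]
        wacc[ok] <- wacc[ok] + w[ok]
      }
    }
  }
  out <- rep(NA_real_, npt)
  pos <- wacc > 0
  out[pos] <- acc[pos] / wacc[pos]
  out
}

# Run body with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
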