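#' Detect conducting corridors (border-zone channels through core)
#'
#' A corridor is a connected region of border zone essentially surrounded
#' by scar core — the anatomic substrate for reentrant conduction. Border
#' zone voxels are grouped into 26-connected components; for each component
#' the face-adjacent (6-connected) non-BZ neighbours inside the myocardium
#' are classified as core or healthy contacts, and the component is reported
#' as a corridor when the fraction of core contacts is at least
#' `core_fraction_min` and the component has at least `min_voxels` voxels.
#' Component order is canonical (sorted by minimum linear voxel index), so
#' detection is a pure, order-independent function of the label field.
#'
#' @param field A `tissue_label_field`.
#' @param core_fraction_min Minimal fraction of boundary contacts that must
#'   be core, in (0, 1]; default 2/3.
#' @param min_voxels Minimal component size in voxels; default 5.
#' @param density Myocardial density in g/mL for corridor masses.
#' @return An object of class `corridor_set`: list `corridors` (each with
#'   `voxels` — linear indices —, `n_voxels`, `mass_g`, `core_contacts`,
#'   `healthy_contacts`, `core_fraction`), `total_count`, `total_mass_g`,
#'   and the detection parameters. A field without core yields an empty set.
#' @export
detect_corridors <- function(field, core_fraction_min = 2 / 3,
                             min_voxels = 5L, density = 1.05) {
  stopifnot(inherits(field, "tissue_label_field"))
  if (core_fraction_min <= 0 || core_fraction_min > 1) {
    stop("core_fraction_min must lie in (0, 1]", call. = FALSE)
  }
  labels <- field$labels
  bz <- !is.na(labels) & labels == 1L
  empty <- structure(
    list(corridors = list(), total_count = 0L, total_mass_g = 0,
         spacing = field$spacing, density = density,
         core_fraction_min = core_fraction_min, min_voxels = min_voxels,
         component_ids = array(0L, dim(labels))),
    class = "corridor_set"
  )
  if (!any(bz)) return(empty)

  comp <- label_components_26(bz)
  n_comp <- max(comp)

  # Face-adjacent boundary contacts of each component, classified by the
  # neighbour's tissue class (only neighbours inside the myocardium count).
  core_ct <- numeric(n_comp)
  healthy_ct <- numeric(n_comp)
  offs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  d <- dim(labels)
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    sx <- seq.int(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
    sy <- seq.int(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
    sz <- seq.int(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
    src_comp <- comp[sx, sy, sz, drop = FALSE]
    dst_lab <- labels[sx + off[1], sy + off[2], sz + off[3], drop = FALSE]
    sel <- src_comp > 0L & !is.na(dst_lab) & dst_lab != 1L
    if (!any(sel)) next
    cc <- src_comp[sel]
    ll <- dst_lab[sel]
    tc <- tapply(ll == 2L, cc, sum)
    th <- tapply(ll == 0L, cc, sum)
    idx <- as.integer(names(tc))
    core_ct[idx] <- core_ct[idx] + tc
    healthy_ct[idx] <- healthy_ct[idx] + th
  }

  sizes <- tabulate(comp[comp > 0L], n_comp)
  contacts <- core_ct + healthy_ct
  frac <- ifelse(contacts > 0, core_ct / contacts, 0)
  keep <- which(frac >= core_fraction_min & sizes >= min_voxels)
  if (!length(keep)) return(empty)

  vv <- voxel_volume_ml(field$spacing)
  min_index <- rep(Inf, n_comp)
  lin <- which(comp > 0L)
  cid <- comp[lin]
  min_index[keep] <- vapply(keep, function(k) min(lin[cid == k]), 0)
  keep <- keep[order(min_index[keep])]

  corridors <- lapply(keep, function(k) {
    list(voxels = sort(lin[cid == k]),
         n_voxels = sizes[k],
         mass_g = sizes[k] * vv * density,
         core_contacts = as.integer(core_ct[k]),
         healthy_contacts = as.integer(healthy_ct[k]),
         core_fraction = frac[k])
  })
  ids <- array(0L, d)
  for (i in seq_along(corridors)) ids[corridors[[i]]$voxels] <- i

  structure(
    list(corridors = corridors,
         total_count = length(corridors),
         total_mass_g = sum(vapply(corridors, `[[`, 0, "mass_g")),
         spacing = field$spacing, density = density,
         core_fraction_min = core_fraction_min, min_voxels = min_voxels,
         component_ids = ids),
    class = "corridor_set"
  )
}

#' @export
print.corridor_set <- function(x, ...) {
  cat(sprintf("<corridor_set> %d corridor(s), total mass %.3f g\n",
              x$total_count, x$total_mass_g))
  invisible(x)
}

#' Tabulate a corridor set
#'
#' One row per corridor (size, mass, boundary-contact composition) followed
#' by a totals row whose mass equals the sum of the per-corridor masses.
#'
#' @param set A `corridor_set` from [detect_corridors()].
#' @return A data.frame with columns `corridor_id`, `n_voxels`, `mass_g`,
#'   `core_contacts`, `healthy_contacts`, `core_fraction`.
#' @export
corridor_report <- function(set) {
  stopifnot(inherits(set, "corridor_set"))
  if (set$total_count == 0L) {
    return(data.frame(corridor_id = "total", n_voxels = 0L, mass_g = 0,
                      core_contacts = 0L, healthy_contacts = 0L,
                      core_fraction = NA_real_))
  }
  rows <- do.call(rbind, lapply(seq_along(set$corridors), function(i) {
    co <- set$corridors[[i]]
    data.frame(corridor_id = as.character(i), n_voxels = co$n_voxels,
               mass_g = co$mass_g, core_contacts = co$core_contacts,
               healthy_contacts = co$healthy_contacts,
               core_fraction = co$core_fraction)
  }))
  totals <- data.frame(corridor_id = "total",
                       n_voxels = sum(rows$n_voxels),
                       mass_g = set$total_mass_g,
                       core_contacts = sum(rows$core_contacts),
                       healthy_contacts = sum(rows$healthy_contacts),
                       core_fraction = NA_real_)
  rbind(rows, totals)
}
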