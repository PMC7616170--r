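# File interfaces: NIfTI volumes, legacy ASCII VTK meshes, cohort CSV and
# phantom-spec YAML.

#' Write an LGE stack as NIfTI volumes
#'
#' Writes the image, the myocardium mask and (when present) the
#' ground-truth labels as separate NIfTI files with the voxel spacing in
#' the header.
#'
#' @param stack An `lge_stack`.
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix.
#' @param compress Write `.nii.gz` (default) instead of `.nii`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_stack_nifti <- function(stack, dir, prefix = "stack",
                              compress = TRUE) {
  stopifnot(inherits(stack, "lge_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (compress) ".nii.gz" else ".nii"
  as_nii <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- stack$spacing
    img
  }
  paths <- c(image = file.path(dir, paste0(prefix, "_image", ext)),
             mask = file.path(dir, paste0(prefix, "_mask", ext)))
  RNifti::writeNifti(as_nii(stack$image), paths["image"])
  RNifti::writeNifti(as_nii(array(as.integer(stack$myocardium_mask),
                                  dim(stack$image))), paths["mask"])
  if (!is.null(stack$truth_labels)) {
    lab <- stack$truth_labels
    lab[is.na(lab)] <- -1L  # NIfTI has no NA; -1 marks outside-mask
    paths["labels"] <- file.path(dir, paste0(prefix, "_labels", ext))
    RNifti::writeNifti(as_nii(lab), paths["labels"])
  }
  invisible(paths)
}

#' Read an LGE stack from NIfTI volumes
#'
#' @param image_path,mask_path Paths to the image and myocardium-mask
#'   volumes (mask nonzero inside the myocardium).
#' @param labels_path Optional path to a ground-truth label volume
#'   (negative values are treated as outside-mask).
#' @return An `lge_stack`.
#' @export
read_stack_nifti <- function(image_path, mask_path, labels_path = NULL) {
  img <- RNifti::readNifti(image_path)
  spacing <- RNifti::pixdim(img)[1:3]
  mask <- RNifti::readNifti(mask_path)
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- RNifti::readNifti(labels_path)
    labels <- array(as.integer(lab), dim(lab))
    labels[labels < 0L] <- NA_integer_
  }
  lge_stack(array(as.numeric(img), dim(img)), spacing,
            array(as.logical(mask != 0), dim(mask)), labels)
}

#' Write a PSI map or label field as a NIfTI volume
#'
#' Out-of-mask voxels are written as -1.
#'
#' @param x A `psi_map` or `tissue_label_field`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(x, path) {
  arr <- if (inherits(x, "psi_map")) {
    x$psi
  } else if (inherits(x, "tissue_label_field")) {
    x$labels
  } else {
    stop("x must be a psi_map or tissue_label_field", call. = FALSE)
  }
  arr[is.na(arr)] <- -1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a layered shell model as legacy VTK polydata
#'
#' One ASCII `.vtk` polydata file per layer, with a `psi` point scalar when
#' the model carries per-vertex PSI.
#'
#' @param model A `layered_shell_model`.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Invisibly, the vector of file paths.
#' @export
write_layers_vtk <- function(model, dir, prefix = "layer") {
  stopifnot(inherits(model, "layered_shell_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(model$n_layers)
  for (k in seq_len(model$n_layers)) {
    lay <- model$layers[[k]]
    paths[k] <- file.path(dir, sprintf("%s_%02d.vtk", prefix, k))
    con <- file(paths[k], "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("myocardial shell layer %d of %d", k,
                         model$n_layers),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(lay$vertices))), con)
    writeLines(apply(format(lay$vertices, trim = TRUE), 1, paste,
                     collapse = " "), con)
    nf <- nrow(lay$faces)
    writeLines(sprintf("POLYGONS %d %d", nf, 4 * nf), con)
    writeLines(paste(3, lay$faces[, 1] - 1L, lay$faces[, 2] - 1L,
                     lay$faces[, 3] - 1L), con)
    if (!is.null(lay$psi)) {
      psi <- lay$psi
      psi[is.na(psi)] <- -1
      writeLines(c(sprintf("POINT_DATA %d", length(psi)),
                   "SCALARS psi float 1", "LOOKUP_TABLE default"), con)
      writeLines(format(psi, trim = TRUE), con)
    }
    close(con)
  }
  invisible(paths)
}

#' Write a labeled tetrahedral mesh as legacy VTK unstructured grid
#'
#' ASCII `.vtk` with a `tissue_label` cell scalar (0 healthy, 1 border
#' zone, 2 core).
#'
#' @param mesh A `labeled_volume_mesh`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "labeled_volume_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "labeled myocardial volume mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(mesh$vertices))), con)
  writeLines(apply(format(mesh$vertices, trim = TRUE), 1, paste,
                   collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(paste(4, mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
                   mesh$elements[, 3] - 1L, mesh$elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(10L, ne)), con)  # VTK_TETRA
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$labels), con)
  invisible(path)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A `cohort_table` (or plain data.frame in the same layout).
#' @param path CSV path.
#' @return `write_cohort_csv` invisibly returns `path`; `read_cohort_csv`
#'   returns a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in cohort", call. = FALSE)
  }
  if (!all(df$recurrence %in% c(0L, 1L))) {
    stop("recurrence must be binary", call. = FALSE)
  }
  structure(df, class = c("cohort_table", "data.frame"))
}

#' Write / read a phantom specification as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML path.
#' @return `write_phantom_yaml` invisibly returns `path`;
#'   `read_phantom_yaml` returns a `phantom_spec`.
#' @export
write_phantom_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- unclass(spec)
  lst$scar_patches <- lapply(lst$scar_patches, function(p) {
    pl <- unclass(p)
    pl$channels <- lapply(pl$channels, unclass)
    pl
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  patches <- lapply(lst$scar_patches, function(p) {
    chans <- lapply(p$channels, function(ch) do.call(bz_channel, ch))
    p$channels <- chans
    do.call(scar_patch, p)
  })
  lst$scar_patches <- patches
  lst$si_levels <- unlist(lst$si_levels)
  do.call(phantom_spec, lst)
}

#' Write a report object as JSON
#'
#' Serializes a `mass_report`, `interface_report`, `corridor_set` summary
#' or any plain list of scalars to JSON.
#'
#' @param x The report object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "corridor_set")) {
    x <- list(total_count = x$total_count, total_mass_g = x$total_mass_g,
              core_fraction_min = x$core_fraction_min,
              min_voxels = x$min_voxels,
              corridors = lapply(x$corridors, function(co) {
                co[c("n_voxels", "mass_g", "core_contacts",
                     "healthy_contacts", "core_fraction")]
              }))
  } else {
    x <- unclass(x)
    x$counts <- as.list(x$counts)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
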