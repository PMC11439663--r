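#' Voxel volumes on a common grid: SUVR extraction and lesion mapping
#'
#' These operations assume spatial normalization has already happened: all
#' volumes live on one voxel grid identified by a `space_tag`, and
#' combining volumes from different grids is an error. PET uptake is
#' summarized as the standardized uptake value ratio (SUVR) against a
#' reference region (cerebellar gray matter in the study design this
#' package serves); lesion masks are summarized as a percentage of brain
#' parenchymal volume and accumulated into lesion frequency maps.
#'
#' @name imaging_maps
NULL

#' Construct a labelled volume
#'
#' @param data 3-D numeric array: real intensities, non-negative integer
#'   labels, or a 0/1 mask depending on `kind`.
#' @param kind one of `"intensity"`, `"label"`, `"mask"`.
#' @param voxel_volume_mm3 volume of one voxel in cubic millimetres.
#' @param space_tag identifier of the common grid; volumes are only
#'   combined when their tags and grid shapes agree.
#' @return a `labeled_volume` list with fields `data`, `kind`,
#'   `grid_shape`, `voxel_volume_mm3`, `space_tag`.
#' @export
labeled_volume <- function(data, kind = c("intensity", "label", "mask"),
                           voxel_volume_mm3 = 1, space_tag = "common-grid") {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("volume data must be a 3-D array")
  if (kind == "mask" && !all(data %in% c(0, 1)))
    stop("mask volumes must be 0/1")
  if (kind == "label") {
    if (any(data < 0) || any(data != round(data)))
      stop("label volumes must hold non-negative integers")
    storage.mode(data) <- "integer"
  }
  stopifnot(voxel_volume_mm3 > 0)
  structure(list(data = data, kind = kind, grid_shape = dim(data),
                 voxel_volume_mm3 = voxel_volume_mm3,
                 space_tag = space_tag),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume:%s> %s grid, %.2f mm3/voxel, space '%s'\n",
              x$kind, paste(x$grid_shape, collapse = "x"),
              x$voxel_volume_mm3, x$space_tag))
  invisible(x)
}

check_same_grid <- function(...) {
  vols <- list(...)
  shapes <- vapply(vols, function(v) paste(v$grid_shape, collapse = "x"),
                   "")
  tags <- vapply(vols, function(v) v$space_tag, "")
  if (length(unique(shapes)) > 1L)
    stop("volumes are on different grids: ",
         paste(unique(shapes), collapse = " vs "))
  if (length(unique(tags)) > 1L)
    stop("volumes carry different space tags: ",
         paste(unique(tags), collapse = " vs "))
  invisible(TRUE)
}

#' Read a NIfTI volume as a labelled volume
#'
#' @param path NIfTI file path.
#' @inheritParams labeled_volume
#' @return a `labeled_volume`; voxel volume is taken from the NIfTI pixdim.
#' @export
read_volume <- function(path, kind = c("intensity", "label", "mask"),
                        space_tag = "common-grid") {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  labeled_volume(array(as.numeric(img), dim = dim(img)[1:3]), kind = kind,
                 voxel_volume_mm3 = prod(pd[1:3]), space_tag = space_tag)
}

#' Write a labelled volume as NIfTI
#'
#' @param vol a `labeled_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  side <- vol$voxel_volume_mm3^(1 / 3)
  img <- RNifti::asNifti(vol$data, pixdim = rep(side, 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Regional SUVR against a reference region
#'
#' SUVR of region l = mean PET intensity over the voxels labelled l,
#' divided by the mean intensity over the reference region. The reference
#' region's own SUVR is 1 by construction. Label 0 is background and is
#' skipped. A label present in `region_labels` but absent from the volume
#' yields `NA` with a warning.
#'
#' @param pet intensity `labeled_volume`.
#' @param labels integer-label `labeled_volume` on the same grid.
#' @param reference_label label (or vector of labels) of the reference
#'   region.
#' @param region_labels labels to extract; defaults to every non-zero
#'   label in the volume.
#' @return a `regional_suvr` list: `per_region` (named numeric),
#'   `voxels_per_region`, `reference_label`, `reference_mean`.
#' @export
regional_suvr <- function(pet, labels, reference_label,
                          region_labels = NULL) {
  stopifnot(pet$kind == "intensity", labels$kind == "label")
  check_same_grid(pet, labels)
  lab <- as.vector(labels$data)
  val <- as.vector(pet$data)
  ref_idx <- lab %in% reference_label
  if (!any(ref_idx)) stop("reference region has no voxels")
  ref_mean <- mean(val[ref_idx])
  if (ref_mean <= 0) stop("reference region mean intensity must be positive")
  present <- sort(unique(lab[lab > 0]))
  if (is.null(region_labels)) region_labels <- present
  sums <- tapply(val, lab, sum)
  counts <- tapply(val, lab, length)
  per_region <- stats::setNames(rep(NA_real_, length(region_labels)),
                                region_labels)
  voxels <- stats::setNames(rep(0L, length(region_labels)), region_labels)
  hit <- as.character(region_labels) %in% names(sums) &
    region_labels %in% present
  if (any(!hit))
    warning("empty region label(s): ",
            paste(region_labels[!hit], collapse = ", "))
  key <- as.character(region_labels[hit])
  per_region[hit] <- (sums[key] / counts[key]) / ref_mean
  voxels[hit] <- as.integer(counts[key])
  structure(list(per_region = per_region, voxels_per_region = voxels,
                 reference_label = reference_label,
                 reference_mean = ref_mean),
            class = "regional_suvr")
}

#' Global SUVR from a four-composite map
#'
#' Each composite (frontal, cingulate, lateral parietal, lateral temporal
#' in the AAL-based design) is the unweighted mean of its member regions'
#' SUVRs; the global SUVR is the unweighted mean of the composite values.
#' Set `volume_weighted = TRUE` to weight member regions by voxel count
#' instead. Members missing from the regional table are dropped with a
#' warning; a composite with no present member is an error.
#'
#' @param r a `regional_suvr`.
#' @param composite_map named list of integer label vectors, one per
#'   composite.
#' @param volume_weighted weight member regions by voxel count.
#' @return list with `global_suvr` and `composite_suvr` (named numeric).
#' @export
global_suvr <- function(r, composite_map, volume_weighted = FALSE) {
  stopifnot(length(composite_map) >= 1L)
  comp <- vapply(names(composite_map), function(nm) {
    labs <- as.character(composite_map[[nm]])
    vals <- r$per_region[labs]
    w <- if (volume_weighted) r$voxels_per_region[labs] else
      rep(1, length(labs))
    ok <- !is.na(vals)
    if (!all(ok))
      warning(sprintf("composite '%s': dropping missing region(s) %s", nm,
                      paste(labs[!ok], collapse = ", ")))
    if (!any(ok))
      stop(sprintf("composite '%s' has no region with a SUVR value", nm))
    sum(vals[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  list(global_suvr = mean(comp), composite_suvr = comp)
}

#' WMH volume as a percentage of brain parenchymal volume
#'
#' 100 x (lesion voxels inside the brain mask) / (brain voxels). Lesion
#' voxels falling outside the brain mask trigger a warning and are not
#' counted.
#'
#' @param lesion binary lesion `labeled_volume`.
#' @param brain binary brain-mask `labeled_volume` on the same grid.
#' @return percentage in [0, 100].
#' @export
wmh_volume_fraction <- function(lesion, brain) {
  stopifnot(lesion$kind == "mask", brain$kind == "mask")
  check_same_grid(lesion, brain)
  nb <- sum(brain$data)
  if (nb == 0) stop("brain mask is empty")
  outside <- sum(lesion$data == 1 & brain$data == 0)
  if (outside > 0)
    warning(outside, " lesion voxel(s) outside the brain mask ignored")
  100 * sum(lesion$data == 1 & brain$data == 1) / nb
}

#' Lesion frequency map across subjects
#'
#' Voxel-wise count of how many subjects carry a lesion at each location,
#' with the pooled proportion of lesion voxels relative to total brain
#' volume across subjects.
#'
#' @param masks list of binary lesion `labeled_volume`s, one per subject.
#' @param brain binary brain-mask `labeled_volume` shared by all subjects.
#' @return a `lesion_frequency_map`: `counts` (integer 3-D array),
#'   `proportion`, `n_subjects`.
#' @export
lesion_frequency_map <- function(masks, brain) {
  if (length(masks) == 0L) stop("no lesion masks supplied")
  stopifnot(brain$kind == "mask")
  for (m in masks) {
    stopifnot(m$kind == "mask")
    check_same_grid(m, brain)
  }
  counts <- Reduce(`+`, lapply(masks, function(m) m$data))
  storage.mode(counts) <- "integer"
  total_lesion <- sum(counts)
  structure(list(counts = counts,
                 proportion = total_lesion /
                   (length(masks) * sum(brain$data)),
                 n_subjects = length(masks)),
            class = "lesion_frequency_map")
}
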