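#' Slice-wise impairment percentage of one CST fiber subset
#'
#' For every axial slice (third array axis) in which the lesion overlaps the
#' tract subset, the slice ratio is 100 * (overlap area) / (total subset
#' area in that slice); areas are voxel counts, equivalent to mm^2 at
#' constant in-plane resolution. The impairment percentage is the largest
#' slice ratio, and the reporting slice is the axial index attaining it.
#' With no overlap anywhere the percentage is 0 and the slice is `NA`.
#'
#' @param lesion a `lesion_mask`.
#' @param subset binary 3D array (nonempty) on the same grid as the lesion.
#' @param whole_volume if `TRUE`, use the whole-tract volume as denominator
#'   (single ratio, no slice-wise maximum) instead of the slice-wise rule.
#' @return list with `percentage` in \[0, 100\] and `argmax_slice` (axial
#'   voxel index, `NA` when percentage is 0 or `whole_volume = TRUE`).
#' @export
impairment_percentage <- function(lesion, subset, whole_volume = FALSE) {
  stopifnot(inherits(lesion, "lesion_mask"))
  if (!all(dim(subset) == lesion$grid$shape))
    stop("impairment_percentage: grid mismatch between lesion and subset")
  subset <- subset != 0
  if (!any(subset)) stop("impairment_percentage: empty fiber subset")
  les <- lesion$voxels != 0
  if (whole_volume) {
    pct <- 100 * sum(les & subset) / sum(subset)
    return(list(percentage = pct, argmax_slice = NA_integer_))
  }
  overlap <- apply(les & subset, 3L, sum)
  area <- apply(subset, 3L, sum)
  use <- overlap > 0L
  if (!any(use)) return(list(percentage = 0, argmax_slice = NA_integer_))
  ratio <- 100 * overlap[use] / area[use]
  k <- which.max(ratio)
  list(percentage = ratio[k], argmax_slice = which(use)[k])
}

#' Impairment profile across the four ipsilesional CST subsets
#'
#' @param lesion a `lesion_mask` (may be empty, e.g. for controls: all
#'   percentages are then 0).
#' @param atlas a [make_fiber_atlas()] result on the same grid.
#' @param hemisphere `"left"` or `"right"`; the ipsilesional subsets are used.
#' @return data.frame with columns `subject_id`, `subset` (M1/PMC/SMA/S1),
#'   `percentage`, `argmax_slice`.
#' @export
impairment_profile <- function(lesion, atlas, hemisphere) {
  stopifnot(inherits(atlas, "fiber_atlas"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  if (!same_grid(lesion$grid, atlas$grid))
    stop("impairment_profile: lesion and atlas grids differ")
  subs <- atlas_subset_names(hemisphere)
  out <- lapply(subs, function(nm) {
    r <- if (any(lesion$voxels != 0))
      impairment_percentage(lesion, atlas$subsets[[nm]])
    else list(percentage = 0, argmax_slice = NA_integer_)
    data.frame(subject_id = lesion$subject_id,
               subset = sub("_.*$", "", nm),
               percentage = r$percentage,
               argmax_slice = r$argmax_slice,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Impairment profiles for a cohort
#'
#' @param masks list of `lesion_mask` objects.
#' @param atlas a `fiber_atlas`.
#' @param hemispheres character vector, per-mask ipsilesional side
#'   (`"left"`/`"right"`); controls with empty masks may use either.
#' @return long data.frame, one row per subject x subset.
#' @export
impairment_table <- function(masks, atlas, hemispheres) {
  stopifnot(length(masks) == length(hemispheres))
  do.call(rbind, Map(function(m, h) impairment_profile(m, atlas, h),
                     masks, hemispheres))
}
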