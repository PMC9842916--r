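#' Construct an ellipsoidal lesion mask
#'
#' A voxel belongs to the lesion iff the squared normalised distance from
#' the centre, sum(((v - center) * voxel_size / radii)^2), is <= 1. The
#' ellipsoid is clipped at the grid boundary. Radii smaller than half a
#' voxel degenerate to the single centre voxel.
#'
#' @param grid a [grid_spec()].
#' @param center voxel triple (1-based) of the lesion centre; must lie
#'   inside the grid.
#' @param radii mm triple (or scalar) of ellipsoid semi-axes; all > 0.
#' @param subject_id optional label carried on the mask.
#' @return An object of class `lesion_mask`: list with `grid`, `voxels`
#'   (binary 3D array) and `subject_id`.
#' @export
make_lesion <- function(grid, center, radii, subject_id = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  center <- as.numeric(center)
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  radii <- as.numeric(radii)
  if (any(radii <= 0)) stop("lesion radii must be positive (mm)")
  if (length(center) != 3L || any(center < 1) || any(center > grid$shape))
    stop("lesion center must be a voxel index inside the grid")
  sh <- grid$shape
  # bounding box, clipped to the grid
  half <- ceiling(radii / grid$voxel_size)
  lo <- pmax(1L, as.integer(floor(center - half)))
  hi <- pmin(sh, as.integer(ceiling(center + half)))
  vol <- array(0L, dim = sh)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center[1]) * grid$voxel_size[1] / radii[1])^2
  dy2 <- ((ys - center[2]) * grid$voxel_size[2] / radii[2])^2
  dz2 <- ((zs - center[3]) * grid$voxel_size[3] / radii[3])^2
  d <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  sub <- array(0L, dim = dim(d))
  sub[d <= 1] <- 1L
  vol[xs, ys, zs] <- sub
  lesion_mask(grid, vol, subject_id)
}

#' Wrap a binary volume as a lesion mask
#'
#' @param grid a [grid_spec()].
#' @param voxels binary 3D array on `grid`.
#' @param subject_id optional subject label.
#' @return A `lesion_mask` object.
#' @export
lesion_mask <- function(grid, voxels, subject_id = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"),
            length(dim(voxels)) == 3L, all(dim(voxels) == grid$shape))
  v <- array(as.integer(voxels != 0), dim = grid$shape)
  structure(list(grid = grid, voxels = v, subject_id = subject_id),
            class = "lesion_mask")
}

#' Lesion volume in mm^3
#'
#' Voxel count times voxel volume.
#'
#' @param mask a `lesion_mask`.
#' @return volume in mm^3.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$voxels) * prod(mask$grid$voxel_size)
}

#' Hemisphere containing a lesion
#'
#' Uses the neurological convention that world x < 0 is the left hemisphere
#' (no flip). A lesion with voxels on both sides of the mid-sagittal plane
#' is "bilateral".
#'
#' @param mask a nonempty `lesion_mask`.
#' @return one of `"left"`, `"right"`, `"bilateral"`.
#' @export
hemisphere_of <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  idx <- which(mask$voxels != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("hemisphere_of: empty lesion mask")
  wx <- mask$grid$origin[1] + (idx[, 1] - 1) * mask$grid$voxel_size[1]
  has_l <- any(wx < 0); has_r <- any(wx > 0)
  if (has_l && has_r) "bilateral" else if (has_l) "left" else "right"
}

#' Voxelwise lesion incidence over a cohort
#'
#' @param masks list of `lesion_mask` objects on a common grid.
#' @return list with `grid`, `counts` (integer 3D array, voxelwise number of
#'   lesioned subjects) and `n_subjects`.
#' @export
incidence_map <- function(masks) {
  if (length(masks) < 1L) stop("incidence_map needs at least one mask")
  grid <- masks[[1]]$grid
  counts <- array(0L, dim = grid$shape)
  for (m in masks) {
    stopifnot(inherits(m, "lesion_mask"))
    if (!same_grid(grid, m$grid))
      stop("incidence_map: grid mismatch for subject ", m$subject_id)
    counts <- counts + m$voxels
  }
  structure(list(grid = grid, counts = counts, n_subjects = length(masks)),
            class = "incidence_map")
}

#' Write a lesion mask to NIfTI
#'
#' @param mask a `lesion_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lesion <- function(mask, path) write_volume(mask$voxels, mask$grid, path)

#' Read a lesion mask from NIfTI
#'
#' @param path NIfTI file.
#' @param subject_id optional subject label.
#' @return a `lesion_mask`.
#' @export
read_lesion <- function(path, subject_id = NA_character_) {
  v <- read_volume(path)
  lesion_mask(v$grid, v$volume != 0, subject_id)
}
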