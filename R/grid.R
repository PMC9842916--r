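#' Define a common analysis grid
#'
#' All volumes in a cohort (lesion masks, fiber atlas, incidence maps) live
#' on one regular grid with a diagonal affine: world coordinate of voxel
#' index `v` (1-based) is `origin + (v - 1) * voxel_size`, in mm. By default
#' the grid is centred so that the mid-sagittal plane x = 0 falls between
#' two voxel columns; world x < 0 is the left hemisphere.
#'
#' @param shape integer triple, voxels per axis (x, y, z); each >= 8.
#' @param voxel_size numeric triple (or scalar), mm per voxel along each axis.
#' @param origin numeric triple, world mm of voxel (1,1,1). Default centres
#'   the grid on (0,0,0).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape = c(32L, 32L, 32L), voxel_size = 2, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 8L))
    stop("grid shape must be three integers, each >= 8")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (mm)")
  if (is.null(origin)) origin <- -(shape * voxel_size) / 2 + voxel_size / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have three entries (mm)")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s voxels at %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$shape, b$shape)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Convert voxel indices to world coordinates
#'
#' @param grid a [grid_spec()].
#' @param vox numeric matrix (n x 3) or length-3 vector of 1-based voxel
#'   indices (fractional indices allowed, e.g. cluster centroids).
#' @return matrix (n x 3) of world mm.
#' @export
voxel_to_world <- function(grid, vox) {
  v <- if (is.matrix(vox)) vox else matrix(vox, ncol = 3L)
  sweep(sweep(v - 1, 2L, grid$voxel_size, `*`), 2L, grid$origin, `+`)
}

#' Convert world coordinates to (nearest) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param world matrix (n x 3) or length-3 vector of world mm.
#' @return integer matrix (n x 3) of 1-based voxel indices.
#' @export
world_to_voxel <- function(grid, world) {
  w <- if (is.matrix(world)) world else matrix(world, ncol = 3L)
  v <- sweep(sweep(w, 2L, grid$origin, `-`), 2L, grid$voxel_size, `/`) + 1
  storage.mode(v) <- "double"
  round(v)
}

grid_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid$voxel_size)
  # NIfTI affines map 0-based indices; our origin is voxel (1,1,1)
  aff[1:3, 4] <- grid$origin
  aff
}

#' Write a volume to NIfTI-1
#'
#' @param volume 3D numeric/integer/logical array on `grid`.
#' @param grid a [grid_spec()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, grid, path) {
  stopifnot(length(dim(volume)) == 3L, all(dim(volume) == grid$shape))
  img <- RNifti::asNifti(volume + 0L)
  img <- RNifti::`sform<-`(img, structure(grid_affine(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume and its grid from NIfTI-1
#'
#' Only diagonal (axis-aligned, non-flipped) affines are supported.
#'
#' @param path NIfTI file path.
#' @return list with `volume` (3D array) and `grid` (a [grid_spec()]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 || any(diag(rot) <= 0))
    stop("only diagonal, positively-oriented affines are supported: ", path)
  grid <- grid_spec(dim(img)[1:3], diag(rot), aff[1:3, 4])
  list(volume = array(as.numeric(img), dim = grid$shape), grid = grid)
}
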