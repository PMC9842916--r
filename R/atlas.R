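#' Build a synthetic corticospinal-tract fiber atlas
#'
#' Stands in for a fine-grained map of CST fibers classed by cortical origin
#' (M1, premotor, supplementary motor, S1). Each subset is a contiguous,
#' slightly meandering column of voxels running along the inferior-superior
#' (z) axis through one hemisphere, mirrored into the other hemisphere.
#' Columns span at least half of the z extent, so every axial slice in that
#' range has a well-defined tract cross-section area.
#'
#' @param grid a [grid_spec()]; each axis must be large enough to place four
#'   separated columns in one hemisphere (shape >= c(24, 24, 8)).
#' @param seed integer seed controlling the per-slice meander.
#' @return An object of class `fiber_atlas`: list with `grid` and `subsets`,
#'   a named list of binary 3D arrays with names `<origin>_<hemisphere>`,
#'   e.g. `"M1_left"`.
#' @export
make_fiber_atlas <- function(grid, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  sh <- grid$shape
  if (sh[1] < 24L || sh[2] < 24L || sh[3] < 8L)
    stop("grid too small to place four fiber columns per hemisphere; ",
         "need shape >= c(24, 24, 8)")
  mid <- sh[1] / 2
  # base (x, y) voxel positions of the four columns in the left hemisphere,
  # scaled to the grid; chosen >= ~4 voxels apart so lesions centred on one
  # column rarely graze another
  fx <- c(M1 = 0.28, PMC = 0.28, SMA = 0.40, S1 = 0.44)
  fy <- c(M1 = 0.44, PMC = 0.62, SMA = 0.56, S1 = 0.28)
  base_x <- pmax(3L, pmin(as.integer(round(fx * sh[1])), as.integer(mid) - 2L))
  base_y <- pmax(3L, pmin(as.integer(round(fy * sh[2])), sh[2] - 2L))
  z0 <- max(1L, as.integer(ceiling(sh[3] * 0.25)))
  z1 <- sh[3]
  rng <- local_rng(seed)
  subsets <- list()
  for (k in seq_along(fx)) {
    origin <- names(fx)[k]
    vol <- array(0L, dim = sh)
    # bounded random meander of the column centre across slices
    dx <- dy <- 0L
    for (z in z0:z1) {
      dx <- max(-1L, min(1L, dx + sample_int(rng, -1L:1L)))
      dy <- max(-1L, min(1L, dy + sample_int(rng, -1L:1L)))
      cx <- base_x[k] + dx
      cy <- base_y[k] + dy
      vol[cx:(cx + 1L), cy:(cy + 1L), z] <- 1L
    }
    mir <- vol[sh[1]:1, , , drop = FALSE]
    subsets[[paste0(origin, "_left")]]  <- vol
    subsets[[paste0(origin, "_right")]] <- mir
  }
  structure(list(grid = grid, subsets = subsets), class = "fiber_atlas")
}

#' @export
print.fiber_atlas <- function(x, ...) {
  n <- vapply(x$subsets, sum, numeric(1))
  cat("fiber_atlas with subsets (voxel counts):\n")
  print(n)
  invisible(x)
}

atlas_subset_names <- function(hemisphere) {
  paste0(c("M1", "PMC", "SMA", "S1"), "_", hemisphere)
}

#' Write all atlas subsets as NIfTI volumes
#'
#' @param atlas a [make_fiber_atlas()] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_fiber_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(atlas$subsets), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(atlas$subsets[[nm]], atlas$grid, p)
    p
  }, character(1))
  invisible(paths)
}

# A local RNG stream that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

sample_int <- function(rng, values) with_rng(rng, sample(values, 1L))
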