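#' Voxel volume (3D scalar intensity grid)
#'
#' Axis-aligned CT-like scalar grid. `data[i, j, k]` holds the intensity of
#' the voxel whose centre sits at world coordinate
#' `origin + (i-1, j-1, k-1) * spacing` (mm); the third index is the slice
#' axis. Oblique orientations are not supported.
#'
#' @param data 3D numeric array, all dims >= 2.
#' @param spacing length-3 positive voxel spacing (mm).
#' @param origin length-3 world coordinate of the centre of voxel (1,1,1).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("all volume dimensions must be >= 2")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("all spacing components must be > 0")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, intensity [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' The single shared index-to-mm convention used by every module
#' (voxelisation, isosurface extraction, deviation measurement):
#' `world = origin + (index - 1) * spacing` at voxel centres.
#'
#' @param volume a [voxel_volume()].
#' @param index n x 3 matrix of 1-based (possibly fractional) voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_index_to_world <- function(volume, index) {
  idx <- if (is.null(dim(index))) matrix(index, ncol = 3) else as.matrix(index)
  sweep(sweep(idx, 2, c(1, 1, 1)), 2, volume$spacing, `*`) |>
    sweep(2, volume$origin, `+`)
}

#' @rdname voxel_index_to_world
#' @param world n x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel_index <- function(volume, world) {
  w <- if (is.null(dim(world))) matrix(world, ncol = 3) else as.matrix(world)
  sweep(sweep(w, 2, volume$origin), 2, volume$spacing, `/`) |>
    sweep(2, c(1, 1, 1), `+`)
}
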