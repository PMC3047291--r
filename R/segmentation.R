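#' Threshold segmentation of a CT volume
#'
#' Binary mask of the closed superlevel set: a voxel is foreground exactly
#' where `intensity >= tau`. The `>=` convention is fixed so voxel counts
#' are exactly reproducible. For `tau1 < tau2`, `threshold_mask(v, tau2)` is
#' a subset of `threshold_mask(v, tau1)`.
#'
#' @param volume a [voxel_volume()].
#' @param tau intensity threshold (CT units).
#' @return An object of class `binary_mask`: logical 3D `data` plus the
#'   source `spacing`/`origin`.
#' @export
threshold_mask <- function(volume, tau) {
  structure(list(data = volume$data >= tau, spacing = volume$spacing,
                 origin = volume$origin),
            class = "binary_mask")
}

#' Keep the largest 26-connected component of a mask
#'
#' The voxel analogue of cleaning away tissues that do not belong to the
#' structure of interest: only the largest 26-connected foreground component
#' is retained. Ties are broken in favour of the component containing the
#' lowest linear voxel index.
#'
#' @param mask a `binary_mask` from [threshold_mask()].
#' @return A `binary_mask` with a single component.
#' @export
largest_component <- function(mask) {
  if (!any(mask$data)) stop("nothing segmented: mask is empty")
  lab <- cpp_label26(as.logical(mask$data), dim(mask$data))
  best <- order(-lab$sizes, lab$min_index)[1]
  out <- mask
  out$data <- array(lab$labels == best, dim = dim(mask$data))
  out
}

#' Extract an isosurface mesh from a CT volume (marching cubes)
#'
#' Marching-cubes surface at isovalue `tau`, with vertices placed by linear
#' interpolation along grid edges that cross the isovalue and mapped to
#' world millimetres through the shared voxel-centre convention
#' ([voxel_index_to_world()]). Normals point from the `>= tau` region
#' outward into the `< tau` region. This is the CT reconstruction step whose
#' dependence on the operator's threshold choice the deviation analysis
#' quantifies.
#'
#' @param volume a [voxel_volume()].
#' @param tau isovalue, strictly between the volume's min and max intensity.
#' @param keep_largest if `TRUE`, return only the largest connected surface
#'   component.
#' @return A [tri_mesh()] in world mm.
#' @export
extract_isosurface <- function(volume, tau, keep_largest = FALSE) {
  rng <- range(volume$data)
  if (!(tau > rng[1] && tau < rng[2]))
    stop(sprintf("tau = %g outside the open intensity range (%g, %g): surface empty or degenerate",
                 tau, rng[1], rng[2]))
  mc <- cpp_marching_cubes(as.numeric(volume$data), dim(volume$data), tau)
  if (nrow(mc$vertices) == 0L) stop("empty isosurface at tau = ", tau)
  V <- voxel_index_to_world(volume, mc$vertices + 1)  # C++ indices are 0-based
  mesh <- tri_mesh(V, mc$faces)
  if (keep_largest) mesh <- largest_mesh_component(mesh)
  mesh
}
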