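#' Signed point-to-surface distances
#'
#' For each query point, the magnitude is the exact Euclidean distance to
#' the nearest point on any triangle of `gold` (exact point-to-triangle
#' projection through a bounding-volume hierarchy), and the sign is decided
#' by the angle-weighted pseudo-normal of the closest feature: `+` outside
#' the gold surface (outward-normal side), `-` inside. A positive mean over
#' a test surface therefore reads "test model larger than the gold model".
#'
#' @param points n x 3 matrix of query points (mm).
#' @param gold a [tri_mesh()], watertight or at least consistently oriented
#'   around the queried region (checked; inconsistent orientation is an
#'   error because the sign would be meaningless).
#' @return numeric vector of signed distances (mm).
#' @export
signed_distances <- function(points, gold) {
  audit <- edge_audit(gold)
  if (audit$n_inconsistent > 0L || audit$n_nonmanifold > 0L)
    stop("gold mesh is not consistently oriented: signed distance undefined; supply a watertight/oriented mesh")
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  bvh <- cpp_bvh_build(gold$vertices, gold$faces)
  cpp_bvh_query(bvh, pts)$distance
}

#' Mating-surface region-of-interest specification
#'
#' Selects the region of a test mesh that participates in a comparison —
#' the mating surfaces in guide-fit verification. Either an explicit vertex
#' index set, or one/more seed points with a geodesic radius: vertices whose
#' along-edge (Dijkstra) distance from the mesh vertex nearest to any seed
#' is within `radius`.
#'
#' @param vertex_indices integer vertex indices (1-based), or `NULL`.
#' @param seed_points k x 3 matrix of seed points (mm), or `NULL`.
#' @param radius geodesic radius in mm (required with `seed_points`).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(vertex_indices = NULL, seed_points = NULL, radius = NULL) {
  if (is.null(vertex_indices) && is.null(seed_points))
    stop("roi_spec needs vertex_indices or seed_points")
  if (!is.null(seed_points)) {
    seed_points <- if (is.null(dim(seed_points)))
      matrix(seed_points, ncol = 3) else as.matrix(seed_points)
    if (is.null(radius) || radius <= 0)
      stop("seed-point ROI needs a positive geodesic radius")
  }
  structure(list(vertex_indices = vertex_indices, seed_points = seed_points,
                 radius = radius), class = "roi_spec")
}

roi_vertices <- function(mesh, roi) {
  sel <- integer(0)
  if (!is.null(roi$vertex_indices)) sel <- as.integer(roi$vertex_indices)
  if (!is.null(roi$seed_points)) {
    E <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
    key <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
    E <- E[!duplicated(key), , drop = FALSE]
    w <- sqrt(rowSums((mesh$vertices[E[, 1], , drop = FALSE] -
                       mesh$vertices[E[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(E, directed = FALSE)
    # nearest mesh vertex to each seed
    seeds <- apply(roi$seed_points, 1, function(p)
      which.min(colSums((t(mesh$vertices) - p)^2)))
    dmat <- igraph::distances(g, v = seeds, weights = w)
    sel <- sort(unique(c(sel, which(apply(dmat, 2, min) <= roi$radius))))
  }
  sel
}

#' Extract the ROI submesh of a test mesh
#'
#' Keeps faces all of whose vertices belong to the ROI; vertex indices are
#' remapped, and the original indices are retained in
#' `attr(submesh, "vertex_map")` / `attr(submesh, "face_map")`.
#'
#' @param mesh a [tri_mesh()].
#' @param roi a [roi_spec()].
#' @return A [tri_mesh()] submesh.
#' @export
select_roi <- function(mesh, roi) {
  sel <- roi_vertices(mesh, roi)
  if (length(sel) == 0L) stop("empty ROI selection")
  inroi <- logical(nrow(mesh$vertices))
  inroi[sel] <- TRUE
  keep <- which(inroi[mesh$faces[, 1]] & inroi[mesh$faces[, 2]] &
                inroi[mesh$faces[, 3]])
  if (length(keep) == 0L) stop("ROI selects no complete face")
  submesh_by_faces(mesh, keep)
}

#' Full-field signed deviation of a test surface against the gold surface
#'
#' The 3D-compare operation: seeded area-weighted sampling of
#' `sample_count` points on the (already aligned) test surface — restricted
#' to the mating-surface ROI when given — and signed point-to-surface
#' distances of those samples against the gold mesh. Deviations are sampled
#' on the test (CT-derived) surface and measured towards the gold (optical)
#' surface, so a positive mean means the test reconstruction is larger than
#' the gold standard.
#'
#' @param test a [tri_mesh()], already aligned to `gold` (this function does
#'   not register; see [icp_refine()]).
#' @param gold the gold-standard [tri_mesh()].
#' @param roi optional [roi_spec()] on the test mesh.
#' @param sample_count number of surface samples.
#' @param seed integer seed.
#' @param sample_method `"vertex"` (default) or `"face"`, see
#'   [sample_surface()].
#' @return An object of class `deviation_field`: `sample_points` (n x 3),
#'   `distances` (signed mm), `gold_reference` (a short identifier).
#' @export
compare_surfaces <- function(test, gold, roi = NULL, sample_count = 20000L,
                             seed = 1L, sample_method = "vertex") {
  surf <- if (!is.null(roi)) select_roi(test, roi) else test
  pts <- sample_surface(surf, sample_count, seed = seed,
                        method = sample_method)
  d <- signed_distances(pts, gold)
  if (!all(is.finite(d))) stop("non-finite deviations computed")
  structure(list(sample_points = pts, distances = d,
                 gold_reference = sprintf("tri_mesh<%d vertices,%d faces>",
                                          nrow(gold$vertices), nrow(gold$faces))),
            class = "deviation_field")
}

#' Mean, SD and histogram of a deviation field
#'
#' Summary statistics of the signed deviations: arithmetic mean, population
#' standard deviation (divide by `n` — at the usual 1e4..1e6 surface
#' samples the distinction from the sample SD is negligible, but the
#' convention is fixed), and a histogram with bins of fixed width anchored
#' at 0 covering the full data range.
#'
#' @param field a `deviation_field` from [compare_surfaces()], or a plain
#'   numeric vector of signed distances.
#' @param bin_width histogram bin width in mm.
#' @return An object of class `deviation_stats`: `mean`, `sd`, `n`,
#'   `breaks`, `counts`.
#' @export
deviation_stats <- function(field, bin_width = 0.05) {
  d <- if (inherits(field, "deviation_field")) field$distances else as.numeric(field)
  if (length(d) == 0L) stop("empty deviation field")
  m <- mean(d)
  s <- sqrt(mean((d - m)^2))
  lo <- floor(min(d) / bin_width)
  hi <- ceiling(max(d) / bin_width)
  if (hi == lo) hi <- lo + 1L
  breaks <- seq(lo, hi) * bin_width
  # right-open bins; include.lowest closes the final bin so the maximum is kept
  counts <- as.integer(table(cut(d, breaks = breaks, include.lowest = TRUE,
                                 right = FALSE)))
  structure(list(mean = m, sd = s, n = length(d), breaks = breaks,
                 counts = counts), class = "deviation_stats")
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat(format_deviation_stats(x), "\n")
  invisible(x)
}

#' Render deviation statistics the way comparison reports print them
#'
#' @param stats a `deviation_stats`.
#' @return string like `"mean value -0.008 mm, SD 0.200 mm"`.
#' @export
format_deviation_stats <- function(stats) {
  sprintf("mean value %.3f mm, SD %.3f mm", stats$mean, stats$sd)
}
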