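#' Parameters of the trimmed iterative-closest-point refinement
#'
#' @param max_iterations maximum ICP iterations (>= 1).
#' @param rms_change_tolerance convergence tolerance on the change of the
#'   trimmed RMS between iterations (mm, > 0).
#' @param trim_fraction fraction in `[0, 0.5)` of the worst correspondences
#'   (by distance) discarded before each rigid update; robustifies against
#'   partial overlap between template and cast regions.
#' @param sample_count number of surface samples drawn from the moving mesh.
#' @param seed integer seed for the (area-weighted) sampling.
#' @param capture_distance pre-check distance (mm): a warning is issued when
#'   fewer than half of the sampled moving points start within this distance
#'   of the fixed surface under the initial transform. `NULL` defaults to
#'   10% of the fixed mesh's bounding-box diagonal.
#' @return An object of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, rms_change_tolerance = 1e-6,
                       trim_fraction = 0.1, sample_count = 20000L,
                       seed = 1L, capture_distance = NULL) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (rms_change_tolerance <= 0) stop("rms_change_tolerance must be > 0")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  if (sample_count < 3) stop("sample_count must be >= 3")
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_change_tolerance = rms_change_tolerance,
                 trim_fraction = trim_fraction,
                 sample_count = as.integer(sample_count),
                 seed = as.integer(seed),
                 capture_distance = capture_distance),
            class = "icp_params")
}

#' Surface-based rigid refinement by trimmed ICP (best fitting)
#'
#' Refines an initial rigid alignment (typically from [landmark_register()])
#' by iterative closest point: a fixed, seeded, area-weighted point sample
#' of the moving surface is matched to exact closest points on the fixed
#' surface (point-to-triangle projection through a bounding-volume
#' hierarchy), the worst `trim_fraction` of correspondences is discarded,
#' and the rigid update is solved by the same SVD method as the landmark
#' stage. Iteration stops when the trimmed RMS changes by less than the
#' tolerance or `max_iterations` is reached.
#'
#' The point sample is drawn once before iterating; with correspondences
#' re-trimmed per iteration the trimmed RMS trace is then non-increasing.
#'
#' @param moving,fixed [tri_mesh()] surfaces; `moving` is aligned onto
#'   `fixed`.
#' @param init initial [rigid_transform()] (identity if landmarks are
#'   unavailable and the meshes are already roughly aligned).
#' @param params an [icp_params()].
#' @return list with:
#'   * `transform`: cumulative [rigid_transform()] (includes `init`),
#'   * `converged`: logical,
#'   * `iterations`: iterations run,
#'   * `rms`: final untrimmed RMS point-to-surface distance (mm),
#'   * `rms_trimmed`: final trimmed RMS (mm),
#'   * `trace`: data frame with per-iteration `rms` and `rms_trimmed`.
#' @export
icp_refine <- function(moving, fixed, init = rigid_transform(),
                       params = icp_params()) {
  if (!all(is.finite(moving$vertices)) || !all(is.finite(fixed$vertices)))
    stop("non-finite mesh geometry")
  bvh <- cpp_bvh_build(fixed$vertices, fixed$faces)
  pts0 <- sample_surface(moving, params$sample_count, seed = params$seed)
  n <- nrow(pts0)
  keep_n <- max(3L, floor(n * (1 - params$trim_fraction)))

  cur <- apply_transform(pts0, init)
  d0 <- abs(cpp_bvh_query(bvh, cur)$distance)
  cap <- params$capture_distance
  if (is.null(cap)) {
    ext <- apply(fixed$vertices, 2, range)
    cap <- 0.1 * sqrt(sum((ext[2, ] - ext[1, ])^2))
  }
  if (mean(d0 <= cap) < 0.5)
    warning(sprintf("poor initial overlap: only %.0f%% of sampled points within %.3g mm of the fixed surface",
                    100 * mean(d0 <= cap), cap))

  transform <- init
  trace_rms <- numeric(0)
  trace_trimmed <- numeric(0)
  prev_trimmed <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    q <- cpp_bvh_query(bvh, cur)
    dist <- abs(q$distance)
    ord <- order(dist)
    kept <- ord[seq_len(keep_n)]
    rms_all <- sqrt(mean(dist^2))
    rms_trimmed <- sqrt(mean(dist[kept]^2))
    trace_rms <- c(trace_rms, rms_all)
    trace_trimmed <- c(trace_trimmed, rms_trimmed)
    if (is.finite(prev_trimmed) &&
        abs(prev_trimmed - rms_trimmed) < params$rms_change_tolerance) {
      converged <- TRUE
      break
    }
    prev_trimmed <- rms_trimmed
    upd <- landmark_register(landmark_set(cur[kept, , drop = FALSE],
                                          q$closest[kept, , drop = FALSE]))
    transform <- compose_transform(upd, transform)
    cur <- apply_transform(cur, upd)
  }
  list(transform = transform, converged = converged, iterations = iter,
       rms = trace_rms[length(trace_rms)],
       rms_trimmed = trace_trimmed[length(trace_trimmed)],
       trace = data.frame(iteration = seq_along(trace_rms), rms = trace_rms,
                          rms_trimmed = trace_trimmed))
}
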