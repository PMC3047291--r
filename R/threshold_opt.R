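#' Mean/SD deviation of the isosurface at a given threshold
#'
#' One evaluation of the threshold-calibration objective: extract the
#' isosurface of the CT volume at `tau`, align it to the gold optical mesh
#' (ICP refinement starting at `init`, or apply a fixed precomputed
#' transform), sample the aligned surface and compute signed-deviation
#' statistics against the gold mesh.
#'
#' @param volume a [voxel_volume()] (the CT data).
#' @param tau segmentation threshold, strictly inside the intensity range.
#' @param gold gold-standard [tri_mesh()] (optical scan).
#' @param init initial [rigid_transform()] for the ICP stage.
#' @param icp an [icp_params()].
#' @param roi optional [roi_spec()] applied to the extracted surface.
#' @param sample_count deviation-field sample count.
#' @param seed integer seed.
#' @param fixed_transform if non-`NULL`, a [rigid_transform()] applied as-is
#'   instead of running ICP (used to share one registration across nearby
#'   thresholds).
#' @param keep_largest keep only the largest isosurface component.
#' @return list with `mean`, `sd` (mm), `stats` (full `deviation_stats`),
#'   `transform`, `icp_converged`.
#' @export
deviation_objective <- function(volume, tau, gold, init = rigid_transform(),
                                icp = icp_params(), roi = NULL,
                                sample_count = 20000L, seed = 1L,
                                fixed_transform = NULL, keep_largest = TRUE) {
  mesh <- extract_isosurface(volume, tau, keep_largest = keep_largest)
  if (is.null(fixed_transform)) {
    fit <- icp_refine(mesh, gold, init = init, params = icp)
    transform <- fit$transform
    converged <- fit$converged
  } else {
    transform <- fixed_transform
    converged <- NA
  }
  aligned <- apply_transform(mesh, transform)
  field <- compare_surfaces(aligned, gold, roi = roi,
                            sample_count = sample_count, seed = seed)
  st <- deviation_stats(field)
  list(mean = st$mean, sd = st$sd, stats = st, transform = transform,
       icp_converged = converged)
}

#' Optimal segmentation threshold by minimising the absolute mean deviation
#'
#' The core calibration: the mean signed deviation of the CT isosurface
#' against the optical gold standard decreases monotonically with the
#' threshold (low thresholds inflate the reconstruction, mean > 0; high
#' thresholds shrink it, mean < 0), so the threshold whose absolute mean
#' deviation is minimal is found as the sign change of `mean(tau)`. A
#' coarse grid over the bracket locates the crossing, then bisection on the
#' sign of the mean refines it until `|mean| < tolerance` or the bracket is
#' narrower than `min_bracket`. Registration is computed once at the grid
#' stage (ICP from the bracket-midpoint surface) and reused for every
#' candidate threshold, so registration noise does not leak into the
#' objective; set `re_register = TRUE` to rerun ICP per candidate.
#'
#' If the means at the bracket ends share a sign, the method falls back to
#' the grid minimum of `|mean|` with a warning; if additionally the grid is
#' flat (no variation beyond the tolerance), an error reports that no
#' crossing was found.
#'
#' @param volume a [voxel_volume()].
#' @param gold gold-standard [tri_mesh()].
#' @param bracket length-2 numeric `(tau_lo, tau_hi)` inside the intensity
#'   range.
#' @param init initial [rigid_transform()] for the registration stage.
#' @param icp an [icp_params()].
#' @param roi optional [roi_spec()].
#' @param sample_count deviation-field sample count.
#' @param seed integer seed.
#' @param grid_points coarse grid size (default 9).
#' @param tolerance stop when `|mean|` falls below this (mm).
#' @param min_bracket stop when the tau bracket is narrower than this
#'   (intensity units).
#' @param re_register rerun ICP for every candidate threshold.
#' @param keep_largest keep only the largest isosurface component.
#' @return An object of class `threshold_result`: `tau_star`,
#'   `objective_at_star` (= `|mean|` at `tau_star`), `mean_at_star`,
#'   `sd_at_star`, `trace` (data frame of all evaluated
#'   `(tau, mean, sd)`, in evaluation order), `transform`,
#'   `registration_per_tau`, `method` (`"bisection"` or `"grid-fallback"`).
#' @export
optimize_threshold <- function(volume, gold, bracket, init = rigid_transform(),
                               icp = icp_params(), roi = NULL,
                               sample_count = 20000L, seed = 1L,
                               grid_points = 9L, tolerance = 0.005,
                               min_bracket = 1, re_register = FALSE,
                               keep_largest = TRUE) {
  rng <- range(volume$data)
  if (!(bracket[1] > rng[1] && bracket[2] < rng[2] && bracket[1] < bracket[2]))
    stop("bracket must be an increasing interval strictly inside the intensity range")

  # one registration, computed at the bracket midpoint surface
  mid <- mean(bracket)
  base <- deviation_objective(volume, mid, gold, init = init, icp = icp,
                              roi = roi, sample_count = sample_count,
                              seed = seed, keep_largest = keep_largest)
  shared <- if (re_register) NULL else base$transform

  evals <- list()
  eval_tau <- function(tau) {
    key <- sprintf("%.12g", tau)
    if (!is.null(evals[[key]])) return(evals[[key]])
    r <- deviation_objective(volume, tau, gold, init = base$transform,
                             icp = icp, roi = roi,
                             sample_count = sample_count, seed = seed,
                             fixed_transform = shared,
                             keep_largest = keep_largest)
    evals[[key]] <<- r
    r
  }
  evals[[sprintf("%.12g", mid)]] <- base

  taus <- seq(bracket[1], bracket[2], length.out = grid_points)
  grid <- lapply(taus, eval_tau)
  means <- vapply(grid, `[[`, 0, "mean")

  sign_change <- which(means[-length(means)] > 0 & means[-1] < 0)
  method <- "bisection"
  if (means[1] <= 0 || means[length(means)] >= 0 || length(sign_change) == 0L) {
    if (diff(range(abs(means))) < tolerance && diff(range(means)) < tolerance)
      stop("no sign crossing of the mean deviation inside the bracket and the grid is flat: widen the bracket")
    warning("mean deviation does not change sign across the bracket; falling back to the grid minimum of |mean|")
    method <- "grid-fallback"
    best <- which.min(abs(means))
    tau_star <- taus[best]
    star <- grid[[best]]
  } else {
    lo <- taus[sign_change[1]]; hi <- taus[sign_change[1] + 1L]
    f_lo <- means[sign_change[1]]
    star <- grid[[sign_change[1]]]
    tau_star <- lo
    if (abs(means[sign_change[1] + 1L]) < abs(f_lo)) {
      star <- grid[[sign_change[1] + 1L]]
      tau_star <- hi
    }
    while (abs(star$mean) >= tolerance && (hi - lo) > min_bracket) {
      tau <- (lo + hi) / 2
      r <- eval_tau(tau)
      if (abs(r$mean) < abs(star$mean)) {
        star <- r
        tau_star <- tau
      }
      if (r$mean > 0) lo <- tau else hi <- tau
    }
  }

  keys <- names(evals)
  trace <- data.frame(
    tau = as.numeric(keys),
    mean = vapply(evals, `[[`, 0, "mean"),
    sd = vapply(evals, `[[`, 0, "sd"),
    row.names = NULL)
  trace <- trace[order(trace$tau), ]
  rownames(trace) <- NULL

  structure(list(tau_star = tau_star,
                 objective_at_star = abs(star$mean),
                 mean_at_star = star$mean,
                 sd_at_star = star$sd,
                 trace = trace,
                 transform = star$transform,
                 registration_per_tau = re_register,
                 method = method),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> tau* = %.6g (|mean| = %.4f mm, SD = %.4f mm; %s, %d evaluations)\n",
              x$tau_star, x$objective_at_star, x$sd_at_star, x$method,
              nrow(x$trace)))
  invisible(x)
}
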