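#' Register and compare a test mesh against a gold mesh (one report)
#'
#' The end-to-end pairwise comparison behind the workflow tables: landmark
#' alignment (when a landmark file is given) followed by trimmed-ICP
#' refinement, then full-field signed deviation statistics. The report
#' carries every parameter and seed needed to reproduce it bit-identically.
#'
#' @param test_path,gold_path mesh files (`.stl`/`.ply`).
#' @param landmarks_path optional plain-text landmark file
#'   (see [read_landmarks()]); identity initialisation when absent.
#' @param roi optional [roi_spec()] restricting the comparison to the
#'   mating surfaces of the test mesh.
#' @param icp an [icp_params()].
#' @param sample_count deviation-field sample count.
#' @param seed integer seed.
#' @param skip_icp only use the landmark (or identity) alignment.
#' @param out_json,out_ply optional output paths for the JSON report and the
#'   colour-mappable deviation PLY.
#' @return A `comparison_report` list: `pair` (test/gold ids), `stats`,
#'   `transform`, `icp` (convergence info), `parameters`, `version`.
#' @export
compare_pair <- function(test_path, gold_path, landmarks_path = NULL,
                         roi = NULL, icp = icp_params(),
                         sample_count = 20000L, seed = 1L,
                         skip_icp = FALSE, out_json = NULL, out_ply = NULL) {
  test <- read_mesh(test_path)
  gold <- read_mesh(gold_path)
  init <- if (!is.null(landmarks_path))
    landmark_register(read_landmarks(landmarks_path)) else rigid_transform()
  if (skip_icp) {
    transform <- init
    fit <- NULL
  } else {
    fit <- icp_refine(test, gold, init = init, params = icp)
    transform <- fit$transform
  }
  aligned <- apply_transform(test, transform)
  field <- compare_surfaces(aligned, gold, roi = roi,
                            sample_count = sample_count, seed = seed)
  st <- deviation_stats(field)
  report <- list(
    pair = list(test = basename(test_path), gold = basename(gold_path)),
    stats = list(mean_mm = st$mean, sd_mm = st$sd, n = st$n,
                 bins = list(breaks_mm = st$breaks, counts = st$counts),
                 rendered = format_deviation_stats(st)),
    transform = transform_to_list(transform),
    icp = if (is.null(fit)) NULL else
      list(converged = fit$converged, iterations = fit$iterations,
           rms_mm = fit$rms, rms_trimmed_mm = fit$rms_trimmed),
    parameters = list(sample_count = sample_count, seed = seed,
                      landmarks = if (is.null(landmarks_path)) NULL else
                        basename(landmarks_path),
                      roi = !is.null(roi),
                      icp = if (skip_icp) NULL else unclass(icp)),
    version = as.character(utils::packageVersion("guidefit")))
  class(report) <- "comparison_report"
  if (!is.null(out_json)) write_report_json(report, out_json)
  if (!is.null(out_ply)) write_deviation_ply(field, out_ply)
  report
}

transform_to_list <- function(tf) {
  list(rotation = as.numeric(t(tf$rotation)),  # row-major, 9 values
       translation = as.numeric(tf$translation))
}

list_to_transform <- function(l) {
  rigid_transform(matrix(as.numeric(l$rotation), 3, 3, byrow = TRUE),
                  as.numeric(l$translation))
}

#' Write / read a rigid transform as JSON
#'
#' Stored as 9 row-major rotation values plus 3 translation values (mm).
#' @param transform a [rigid_transform()].
#' @param path JSON file path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  list_to_transform(jsonlite::read_json(path, simplifyVector = TRUE))
}

write_report_json <- function(report, path, timestamp = TRUE) {
  out <- unclass(report)
  if (timestamp)
    out$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the complete phantom calibration study
#'
#' Desk-scale stand-in for the clinical workflow: generates the synthetic
#' CT + optical pair of a [phantom_spec()], writes the phantom artefacts
#' (ground-truth STL + PLY, CT volume as NRRD, spec sidecar JSON including
#' the true pose and seed), derives landmarks from ground-truth
#' correspondences (with a small seeded jitter emulating manual picking),
#' runs [optimize_threshold()] against the optical gold standard, and
#' reports the deviation statistics at a low / optimal / high threshold
#' triple — the structure of the smaller / comparable / greater comparison.
#' Everything is seeded, and reports are byte-stable apart from timestamps.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @param spacing CT voxel spacing (mm).
#' @param bracket threshold search bracket (intensity units); default
#'   `bg + c(0.2, 0.8) * (fg - bg)`.
#' @param icp an [icp_params()]; default seeds derive from the phantom seed.
#' @param sample_count deviation-field sample count.
#' @param landmark_count number of synthetic landmark pairs.
#' @param landmark_jitter_sd SD (mm) of the manual-picking jitter.
#' @param write_timestamp include a timestamp field in the JSON reports.
#' @return (invisibly) a list with `result` (a `threshold_result`), `table`
#'   (the low/optimal/high data frame), `paths` of all written artefacts.
#' @export
run_phantom_study <- function(spec = phantom_spec(), out_dir,
                              spacing = 0.3, bracket = NULL,
                              icp = NULL, sample_count = 20000L,
                              landmark_count = 6L, landmark_jitter_sd = 0.1,
                              write_timestamp = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(bracket))
    bracket <- spec$bg_intensity + c(0.2, 0.8) *
      (spec$fg_intensity - spec$bg_intensity)
  if (is.null(icp)) icp <- icp_params(seed = spec$seed + 2L)

  pair <- make_phantom_pair(spec, spacing = spacing)
  paths <- list(
    truth_stl = file.path(out_dir, "phantom_truth.stl"),
    optical_ply = file.path(out_dir, "phantom_optical.ply"),
    ct_nrrd = file.path(out_dir, "phantom_ct.nrrd"),
    sidecar = file.path(out_dir, "phantom_spec.json"),
    landmarks = file.path(out_dir, "landmarks.txt"),
    result = file.path(out_dir, "result.json"))
  write_mesh(pair$mesh, paths$truth_stl)
  write_mesh(pair$optical, paths$optical_ply)
  write_volume(pair$ct, paths$ct_nrrd)

  sidecar <- spec
  sidecar$true_pose <- transform_to_list(spec$true_pose)
  jsonlite::write_json(unclass(sidecar), paths$sidecar, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)

  # ground-truth landmark correspondences with manual-picking jitter
  lm <- withr::with_seed(spec$seed + 3L, {
    vi <- sample.int(nrow(pair$mesh$vertices), landmark_count)
    src <- pair$mesh$vertices[vi, , drop = FALSE]
    tgt <- apply_transform(src, spec$true_pose) +
      matrix(stats::rnorm(3 * landmark_count, sd = landmark_jitter_sd),
             landmark_count, 3)
    landmark_set(src, tgt)
  })
  write_landmarks(lm, paths$landmarks)
  init <- landmark_register(lm)

  result <- optimize_threshold(pair$ct, pair$optical, bracket = bracket,
                               init = init, icp = icp,
                               sample_count = sample_count,
                               seed = spec$seed + 4L)

  # low / optimal / high threshold triple (bracket ends vs tau*)
  triple <- data.frame(
    label = c("low", "optimal", "high"),
    tau = c(bracket[1], result$tau_star, bracket[2]))
  rows <- lapply(triple$tau, function(tau) {
    r <- deviation_objective(pair$ct, tau, pair$optical,
                             fixed_transform = result$transform,
                             sample_count = sample_count,
                             seed = spec$seed + 4L)
    data.frame(mean_mm = r$mean, sd_mm = r$sd)
  })
  table <- cbind(triple, do.call(rbind, rows))

  out <- list(
    spec_seed = spec$seed,
    bracket = bracket,
    tau_star = result$tau_star,
    objective_at_star_mm = result$objective_at_star,
    mean_at_star_mm = result$mean_at_star,
    sd_at_star_mm = result$sd_at_star,
    method = result$method,
    registration = transform_to_list(result$transform),
    trace = result$trace,
    comparison_table = table,
    parameters = list(spacing = spacing, sample_count = sample_count,
                      landmark_count = landmark_count,
                      landmark_jitter_sd = landmark_jitter_sd,
                      icp = unclass(icp)),
    version = as.character(utils::packageVersion("guidefit")))
  if (write_timestamp) out$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(out, paths$result, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "columns")
  invisible(list(result = result, table = table, paths = paths))
}
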