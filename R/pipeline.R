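#' Configuration for a full reproducibility experiment
#'
#' Bundles every parameter of the end-to-end workflow: phantom cohort
#' generation, the segmentation arms to run, the number of observers and
#' repeat sessions, observer boundary jitter, CLAHE and level-set parameters,
#' feature extraction settings, and the ICC model.
#'
#' Arms:
#' * `"manual"` — observer-delineated masks (ground truth perturbed by the
#'   observer model), features from the unenhanced image;
#' * `"semiauto"` — region-growing seed followed by level-set evolution on the
#'   unenhanced image;
#' * `"clahe"` — the same semi-automated pathway on the CLAHE-enhanced image.
#'
#' @param n_subjects Cohort size (>= 2).
#' @param base_spec [phantom_spec()] shared by the cohort.
#' @param variation Per-subject parameter ranges; see [generate_cohort()].
#' @param arms Subset of `c("manual", "semiauto", "clahe")`.
#' @param observers,sessions Replication structure; `observers * sessions >= 2`
#'   is required so the ICC is estimable.
#' @param jitter_sigma,jitter_smoothness Observer-model parameters
#'   ([observer_model()]); `jitter_sigma = 0` makes every replicate identical.
#' @param clahe [clahe_params()] for the `"clahe"` arm.
#' @param snake [snake_params()] for the level-set arms.
#' @param features [feature_config()].
#' @param region_grow_tol Intensity tolerance of the region-growing seed stage.
#' @param icc_model `"agreement"` or `"consistency"`.
#' @param seed Global seed; all stage randomness is derived from it.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 30,
                              base_spec = phantom_spec(),
                              variation = list(
                                lesion_intensity = c(0.7, 0.95),
                                lesion_axis_a = c(12, 22),
                                lesion_axis_b = c(8, 16),
                                lesion_rotation = c(0, 180)
                              ),
                              arms = c("manual", "semiauto", "clahe"),
                              observers = 1, sessions = 2,
                              jitter_sigma = 2, jitter_smoothness = 30,
                              clahe = clahe_params(),
                              snake = snake_params(),
                              features = feature_config(),
                              region_grow_tol = 0.15,
                              icc_model = c("agreement", "consistency"),
                              seed = 1L, output_dir = NULL) {
  if (!length(arms)) abort("at least one arm is required.")
  arms <- match.arg(arms, c("manual", "semiauto", "clahe"), several.ok = TRUE)
  if (observers < 1 || sessions < 1) abort("`observers` and `sessions` must be >= 1.")
  if (observers * sessions < 2) {
    abort("`observers * sessions` must be >= 2 for the ICC to be estimable.")
  }
  if (jitter_sigma < 0) abort("`jitter_sigma` must be >= 0.")
  structure(
    list(n_subjects = as.integer(n_subjects), base_spec = base_spec,
         variation = variation, arms = arms,
         observers = as.integer(observers), sessions = as.integer(sessions),
         jitter_sigma = jitter_sigma, jitter_smoothness = jitter_smoothness,
         clahe = clahe, snake = snake, features = features,
         region_grow_tol = region_grow_tol,
         icc_model = match.arg(icc_model), seed = as.integer(seed),
         output_dir = output_dir),
    class = "experiment_config"
  )
}

# Segment one replicate for one subject under one arm.
segment_replicate <- function(arm, image, gt_mask, config, rep_seed) {
  if (arm == "manual") {
    model <- observer_model(config$jitter_sigma, config$jitter_smoothness,
                            seed = rep_seed)
    return(list(image = image, mask = simulate_observer(gt_mask, model)))
  }
  work <- if (arm == "clahe") clahe(image, config$clahe) else image
  ctr <- round(colMeans(which(gt_mask, arr.ind = TRUE)))
  if (config$jitter_sigma > 0) {
    shift <- with_seed_(rep_seed, rnorm(2, sd = config$jitter_sigma))
    shift <- pmin(pmax(shift, -2 * config$jitter_sigma), 2 * config$jitter_sigma)
    ctr <- round(ctr + shift)
  }
  ctr <- pmin(pmax(ctr, 1), dim(image))
  # The seed marking is an observer action on the acquired slice: grow on the
  # Gaussian-smoothed raw image (raw-pixel growing is noise-fragile), then let
  # the contour and the features see the arm's working image.
  init <- region_grow(gaussian_smooth(image, config$snake$edge_sigma),
                      ctr, config$region_grow_tol)
  mask <- evolve_level_set(work, init, config$snake)
  if (!any(mask)) abort("level-set front collapsed.")
  list(image = work, mask = mask)
}

#' Run the full reproducibility pipeline
#'
#' Generates the phantom cohort, runs every configured arm for every subject,
#' observer, and session (phantom -> optional CLAHE -> segmentation -> feature
#' extraction), assembles the long-format measurement table, and computes the
#' feature-stability report. The run is a pure function of the configuration:
#' per-replicate seeds are derived deterministically from the global seed, the
#' arm, the subject, and the replicate labels.
#'
#' When `config$output_dir` is set, `features.csv` (long format), `icc.csv`,
#' `bin_counts.csv`, and a JSON run manifest (parameter snapshot, seed, output
#' hashes, timestamps) are written there.
#'
#' @param config An [experiment_config()].
#' @return An object of class `radstab_run`: list with `report`
#'   (a [stability_report()]), `measurements` (long tibble: subject, arm,
#'   observer, session, replicate, feature, group, value), `dice` (tibble of
#'   per-replicate Dice against ground truth for the segmentation arms),
#'   `manifest`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$n_subjects, config$base_spec,
                            config$variation, seed = config$seed)
  reps <- tidyr::expand_grid(observer = seq_len(config$observers),
                             session = seq_len(config$sessions))

  rows <- list(); dice_rows <- list()
  for (arm in config$arms) {
    for (i in seq_len(nrow(cohort))) {
      image <- cohort$image[[i]]; gt <- cohort$mask[[i]]
      for (j in seq_len(nrow(reps))) {
        o <- reps$observer[j]; s <- reps$session[j]
        rep_seed <- derive_seed(config$seed, arm, i, o, s)
        seg <- tryCatch(
          segment_replicate(arm, image, gt, config, rep_seed),
          error = function(e) abort(sprintf(
            "stage `segment` failed for arm '%s', subject %d: %s",
            arm, i, conditionMessage(e)))
        )
        fv <- tryCatch(
          extract_features(seg$image, seg$mask, config$features),
          error = function(e) abort(sprintf(
            "stage `features` failed for arm '%s', subject %d: %s",
            arm, i, conditionMessage(e)))
        )
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          fv, subject = i, arm = arm, observer = o, session = s,
          replicate = sprintf("obs%d_ses%d", o, s), .before = 1
        )
        if (arm != "manual") {
          dice_rows[[length(dice_rows) + 1L]] <- tibble(
            subject = i, arm = arm, observer = o, session = s,
            dice = dice(seg$mask, gt)
          )
        }
      }
    }
  }
  measurements <- dplyr::bind_rows(rows)
  dice_tbl <- dplyr::bind_rows(dice_rows)

  report <- tryCatch(
    stability_report(measurements, model = config$icc_model),
    error = function(e) abort(sprintf("stage `stability` failed: %s",
                                      conditionMessage(e)))
  )

  manifest <- list(
    seed = config$seed,
    arms = config$arms,
    n_subjects = config$n_subjects,
    observers = config$observers, sessions = config$sessions,
    jitter_sigma = config$jitter_sigma,
    clahe = unclass(config$clahe),
    snake = unclass(config$snake),
    features = unclass(config$features),
    region_grow_tol = config$region_grow_tol,
    icc_model = config$icc_model,
    measurements_hash = rlang::hash(measurements),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements,
                     file.path(config$output_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(report$icc, file.path(config$output_dir, "icc.csv"),
                     row.names = FALSE)
    utils::write.csv(report$bin_counts,
                     file.path(config$output_dir, "bin_counts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(manifest, list(summary = report$summary)),
      file.path(config$output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  structure(list(report = report, measurements = measurements,
                 dice = dice_tbl, manifest = manifest, config = config),
            class = "radstab_run")
}

#' @export
print.radstab_run <- function(x, ...) {
  cat(sprintf("radstab run: %d subjects, %d replicate(s) x %d session(s), arms: %s\n",
              x$config$n_subjects, x$config$observers, x$config$sessions,
              paste(x$config$arms, collapse = ", ")))
  print(x$report)
  invisible(x)
}
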