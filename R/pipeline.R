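#' End-to-end run configuration
#'
#' Bundles everything one full analysis run needs: the mode (synthetic
#' simulation or real annotation tables on disk), stage toggles, the module
#' configurations, and the global seed. The resolved configuration and its
#' hash are embedded in the run report so any run can be reproduced exactly.
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"real"` (load tables).
#' @param out_dir Output directory for tables and the report; `NULL` keeps
#'   everything in memory.
#' @param stages Character subset of
#'   `c("simulate", "score", "fit_stats", "classify")`; later stages that
#'   depend on skipped ones are skipped too.
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param classifier A [classifier_config()].
#' @param annotations_path,gold_path,images_dir Input locations (real mode).
#' @param mapping Optional column mapping for [read_annotations()].
#' @param seed Global seed; overrides `cohort$seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), out_dir = NULL,
                       stages = c("simulate", "score", "fit_stats", "classify"),
                       cohort = cohort_config(), classifier = classifier_config(),
                       annotations_path = NULL, gold_path = NULL,
                       images_dir = NULL, mapping = NULL, seed = 1) {
  mode <- match.arg(mode)
  stages <- match.arg(stages, c("simulate", "score", "fit_stats", "classify"),
                      several.ok = TRUE)
  if (mode == "real" && (is.null(annotations_path) || is.null(gold_path)))
    stop("real mode needs annotations_path and gold_path")
  cohort$seed <- seed
  structure(list(mode = mode, out_dir = out_dir, stages = stages,
                 cohort = cohort, classifier = classifier,
                 annotations_path = annotations_path, gold_path = gold_path,
                 images_dir = images_dir, mapping = mapping, seed = seed),
            class = "run_config")
}

stage_log <- function(report, stage, msg) {
  entry <- paste0("[", stage, "] ", msg)
  message(entry)
  report$log <- c(report$log, entry)
  report
}

#' Run the full annotation-quality pipeline
#'
#' Executes the enabled stages in order: simulate (synthetic mode) or load
#' (real mode), score against the gold standard, fit the statistical models
#' (group comparison of F_mean, log-time fatigue regression, per-image BLUP
#' regression, time-accuracy correlation), and train/evaluate per-participant
#' classifiers with their group F-test. Incomplete participants are filtered
#' once, at load, with logged row counts. Any stage failure aborts with the
#' stage name.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` with sections `data`, `scores`,
#'   `stats`, `classifier`, plus `config`, `config_hash`, `seed`, `log`.
#'   When `config$out_dir` is set, tables and a JSON report are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = unclass(config), config_hash = config_hash(config),
                 seed = config$seed, log = character())
  cohort <- NULL; annotations <- NULL; gold <- NULL; images <- NULL

  if (config$mode == "synthetic") {
    if (!"simulate" %in% config$stages)
      stop("stage 'simulate' is required in synthetic mode")
    cohort <- tryCatch(generate_cohort(config$cohort),
                       error = function(e) stop("stage 'simulate' failed: ",
                                                conditionMessage(e)))
    annotations <- cohort$annotations; gold <- cohort$gold; images <- cohort$images
    report <- stage_log(report, "simulate",
                        paste0(length(cohort$profiles), " participants, ",
                               config$cohort$n_images, " images, ",
                               nrow(annotations), " boxes"))
  } else {
    annotations <- tryCatch(
      read_annotations(config$annotations_path, config$mapping),
      error = function(e) stop("stage 'load' failed: ", conditionMessage(e)))
    gold <- tryCatch(read_gold(config$gold_path),
                     error = function(e) stop("stage 'load' failed: ",
                                              conditionMessage(e)))
    n0 <- nrow(annotations)
    annotations <- suppressMessages(filter_complete_participants(annotations))
    report <- stage_log(report, "load",
                        paste0(n0, " rows read, ", nrow(annotations),
                               " kept after completeness filter (",
                               length(attr(annotations, "dropped")),
                               " participants dropped)"))
    if (!is.null(config$images_dir) && "classify" %in% config$stages) {
      files <- list.files(config$images_dir, pattern = "\\.png$",
                          full.names = TRUE)
      images <- stats::setNames(lapply(files, read_scene_png),
                                sub("\\.png$", "", basename(files)))
    }
  }
  report$data <- list(n_participants = length(unique(annotations$participant_id)),
                      n_images = length(unique(annotations$image_id)),
                      n_boxes = nrow(annotations),
                      groups = table(unique(annotations[c("participant_id",
                                                          "group")])$group))

  scores <- NULL
  if ("score" %in% config$stages) {
    scores <- tryCatch(score_dataset(annotations, gold),
                       error = function(e) stop("stage 'score' failed: ",
                                                conditionMessage(e)))
    report$scores <- list(
      group_f_mean = tapply(scores$image_scores$f_mean,
                            scores$image_scores$group, mean),
      median_time = stats::median(scores$image_scores$time_seconds),
      n_boxes_scored = nrow(scores$box_scores))
    report <- stage_log(report, "score",
                        paste0(nrow(scores$box_scores), " boxes scored over ",
                               nrow(scores$image_scores), " participant-images"))
  }

  if ("fit_stats" %in% config$stages) {
    if (is.null(scores)) stop("stage 'fit_stats' requires stage 'score'")
    fm <- tryCatch(fit_fmean_model(scores),
                   error = function(e) stop("stage 'fit_stats' failed: ",
                                            conditionMessage(e)))
    tm <- tryCatch(fit_time_model(annotations),
                   error = function(e) stop("stage 'fit_stats' failed: ",
                                            conditionMessage(e)))
    blup_reg <- regress_blups(extract_blups(tm, "image"),
                              extract_blups(fm, "image"))
    blup_reg$fit <- NULL
    corr <- time_accuracy_correlation(scores)
    report$stats <- list(
      fmean_omnibus = fm$omnibus,
      fmean_contrasts = fm$contrasts,          # Table-1-style layout
      fmean_varcomp = fm$varcomp,
      time_slopes = tm$slopes,                 # Table-2-style layout
      time_interactions = tm$interaction_contrasts,
      blup_regression = blup_reg,
      blup_scatter = merge(extract_blups(tm, "image"),
                           extract_blups(fm, "image"), by = "id",
                           suffixes = c("_time", "_fmean")),
      time_accuracy = corr,
      df_method = fm$meta$df_method)
    report <- stage_log(report, "fit_stats",
                        sprintf("omnibus group F = %.3f (p = %.3g)",
                                fm$omnibus$F, fm$omnibus$p))
  }

  if ("classify" %in% config$stages) {
    if (is.null(images))
      stop("stage 'classify' failed: no images available (synthetic cohort or images_dir required)")
    cl <- tryCatch(evaluate_cohort(annotations, images, gold,
                                   config = config$classifier,
                                   seed = config$seed),
                   error = function(e) stop("stage 'classify' failed: ",
                                            conditionMessage(e)))
    ftest <- anova_classifier_performance(cl$results)
    report$classifier <- list(results = cl$results,
                              group_means = cl$group_means,
                              overall_mean = mean(cl$results$performance),
                              expert_performance =
                                if (!is.null(cl$expert)) cl$expert$performance else NULL,
                              f_test = ftest[c("F", "df1", "df2", "p")])
    report <- stage_log(report, "classify",
                        sprintf("mean performance %.4f over %d participants",
                                mean(cl$results$performance), nrow(cl$results)))
  }

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_annotations(annotations, file.path(config$out_dir, "annotations.csv"))
    write_gold(gold, file.path(config$out_dir, "gold.csv"))
    if (!is.null(scores)) write_scores(scores, file.path(config$out_dir, "scores"))
    jsonlite::write_json(serialize_report(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

# report without model objects / raw tables, suitable for JSON
serialize_report <- function(report) {
  r <- strip_classes(unclass(report))
  if (!is.null(r$data$groups)) r$data$groups <- as.list(r$data$groups)
  if (!is.null(r$scores$group_f_mean))
    r$scores$group_f_mean <- as.list(r$scores$group_f_mean)
  if (!is.null(r$classifier$group_means))
    r$classifier$group_means <- as.list(r$classifier$group_means)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("crowdbox run report (seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
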