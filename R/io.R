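ANNOTATION_COLS <- c("participant_id", "group", "image_id", "question_index",
                     "box_id", "x_min", "y_min", "width", "height",
                     "time_seconds")
GOLD_COLS <- c("image_id", "gold_box_id", "x_min", "y_min", "width", "height",
               "difficulty")

report_offenders <- function(bad, what) {
  if (!any(bad)) return(invisible())
  rows <- utils::head(which(bad), 10)
  stop(sum(bad), " row(s) with ", what, "; first offending data row(s): ",
       paste(rows, collapse = ", "))
}

#' Read and validate an annotation table
#'
#' Reads the canonical per-box annotation CSV (header
#' `participant_id,group,image_id,question_index,box_id,x_min,y_min,width,height,time_seconds`).
#' Real-data exports with other column names can be mapped onto the canonical
#' dialect by passing `mapping`, a named character vector
#' `c(canonical_name = "name_in_file", ...)`. Validation is strict: missing
#' columns, non-numeric coordinates, and non-positive extents are errors
#' naming the offending rows.
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector mapping canonical column
#'   names to the column names used in the file.
#' @return A data.frame in the canonical annotation dialect.
#' @export
read_annotations <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    miss <- setdiff(unname(mapping), names(df))
    if (length(miss))
      stop("mapping refers to column(s) absent from the file: ",
           paste(miss, collapse = ", "))
    for (canon in names(mapping)) names(df)[names(df) == mapping[[canon]]] <- canon
  }
  miss <- setdiff(ANNOTATION_COLS, names(df))
  if (length(miss))
    stop("annotation table lacks required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[ANNOTATION_COLS]
  for (col in c("question_index", "box_id", "x_min", "y_min", "width",
                "height", "time_seconds")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    report_offenders(is.na(v) & !is.na(df[[col]]), paste0("non-numeric ", col))
    report_offenders(is.na(df[[col]]), paste0("missing ", col))
    df[[col]] <- v
  }
  report_offenders(df$width <= 0 | df$height <= 0,
                   "non-positive box width/height")
  report_offenders(df$x_min < 0 | df$y_min < 0, "negative box origin")
  df
}

#' Write an annotation table
#' @param table Canonical annotation data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  stopifnot(all(ANNOTATION_COLS %in% names(table)))
  utils::write.csv(table[ANNOTATION_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a gold-standard box table
#'
#' Header `image_id,gold_box_id,x_min,y_min,width,height,difficulty` with
#' `difficulty` in `{easy, hard}`.
#'
#' @inheritParams read_annotations
#' @return A data.frame in the canonical gold dialect.
#' @export
read_gold <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping))
    for (canon in names(mapping)) names(df)[names(df) == mapping[[canon]]] <- canon
  miss <- setdiff(GOLD_COLS, names(df))
  if (length(miss))
    stop("gold table lacks required column(s): ", paste(miss, collapse = ", "))
  df <- df[GOLD_COLS]
  for (col in c("gold_box_id", "x_min", "y_min", "width", "height")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    report_offenders(is.na(v), paste0("non-numeric ", col))
    df[[col]] <- v
  }
  report_offenders(df$width <= 0 | df$height <= 0,
                   "non-positive gold box extent")
  report_offenders(!df$difficulty %in% c("easy", "hard"),
                   "difficulty outside {easy, hard}")
  df
}

#' @rdname read_gold
#' @param table Canonical gold data.frame.
#' @param path Output CSV path.
#' @export
write_gold <- function(table, path) {
  stopifnot(all(GOLD_COLS %in% names(table)))
  utils::write.csv(table[GOLD_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and re-read score tables
#'
#' Scores are written as two CSVs under a common stem: `<stem>_boxes.csv`
#' (per-box match results) and `<stem>_images.csv` (per participant-image
#' `F_mean` rows).
#'
#' @param scores A `crowd_scores` object from [score_dataset()].
#' @param stem Output path stem.
#' @return The two file paths, invisibly.
#' @export
write_scores <- function(scores, stem) {
  stopifnot(inherits(scores, "crowd_scores"))
  paths <- paste0(stem, c("_boxes.csv", "_images.csv"))
  utils::write.csv(scores$box_scores, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(scores$image_scores, paths[2], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @rdname write_scores
#' @export
read_scores <- function(stem) {
  structure(list(
    box_scores = utils::read.csv(paste0(stem, "_boxes.csv"), stringsAsFactors = FALSE),
    image_scores = utils::read.csv(paste0(stem, "_images.csv"), stringsAsFactors = FALSE)),
    class = "crowd_scores")
}

#' Write a generated cohort to disk
#'
#' Writes `images/<image_id>.png`, `gold.csv`, `annotations.csv` and
#' `config.json` under `dir`.
#'
#' @param cohort A `crowd_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param images Whether to write the PNG scenes.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, images = TRUE) {
  stopifnot(inherits(cohort, "crowd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (images) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (id in names(cohort$images))
      write_scene_png(cohort$images[[id]], file.path(img_dir, paste0(id, ".png")))
  }
  write_gold(cohort$gold, file.path(dir, "gold.csv"))
  write_annotations(cohort$annotations, file.path(dir, "annotations.csv"))
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Drop participants who did not annotate every image
#'
#' The study analysed only participants who completed the full task; this
#' filter applies the same rule once, at load time, and reports how many
#' participants and rows were removed.
#'
#' @param annotations Canonical annotation table.
#' @param n_images Number of images constituting a complete run; defaults to
#'   the maximum number of distinct images any participant annotated.
#' @return The filtered annotation table, with attribute `dropped`
#'   (participant ids removed).
#' @export
filter_complete_participants <- function(annotations, n_images = NULL) {
  done <- tapply(annotations$image_id, annotations$participant_id,
                 function(x) length(unique(x)))
  if (is.null(n_images)) n_images <- max(done)
  incomplete <- names(done)[done < n_images]
  out <- annotations[!annotations$participant_id %in% incomplete, ]
  if (length(incomplete))
    message("dropped ", length(incomplete), " incomplete participant(s) (",
            nrow(annotations) - nrow(out), " rows)")
  attr(out, "dropped") <- incomplete
  out
}

strip_classes <- function(x) {
  if (is.list(x)) x <- lapply(x, strip_classes)
  if (!is.data.frame(x)) attr(x, "class") <- NULL
  x
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(strip_classes(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
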