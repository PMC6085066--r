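boxes_to_df <- function(boxes, id_col) {
  if (is.data.frame(boxes)) {
    df <- boxes
    if (!id_col %in% names(df)) df[[id_col]] <- seq_len(nrow(df))
    need <- c("x_min", "y_min", "width", "height")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("box table lacks column(s): ", paste(miss, collapse = ", "))
    return(df[c(id_col, need)])
  }
  if (inherits(boxes, "crowd_box")) boxes <- list(boxes)
  df <- as.data.frame(do.call(rbind, lapply(boxes, function(b) unclass(as_box(b)))))
  df[[id_col]] <- seq_len(nrow(df))
  df[c(id_col, "x_min", "y_min", "width", "height")]
}

#' Match participant boxes to gold-standard boxes and score them
#'
#' Each participant-drawn box is independently assigned to the gold-standard
#' box that maximises F1 over all gold boxes in the image (ties broken by the
#' smaller gold-box id). When two or more participant boxes are assigned to
#' the same gold box, only the one with the highest F1 keeps its precision,
#' recall and F1; the others are zeroed (`zeroed = TRUE`), with ties broken
#' in favour of the earlier-drawn (lower id) box. Zeroed boxes are not
#' re-assigned to other gold boxes: matching is a single pass.
#'
#' Degenerate participant boxes (non-positive width or height) are scored
#' `(0, 0, 0)` with a warning rather than rejected, so one malformed box
#' cannot abort a cohort run.
#'
#' @param participant_boxes Participant boxes: a data.frame with columns
#'   `x_min`, `y_min`, `width`, `height` (and optionally `box_id`), or a list
#'   of [box()] objects. May be empty.
#' @param gold_boxes Gold boxes in the same form (id column `gold_box_id`);
#'   must contain at least one box.
#' @return A data.frame with one row per participant box: `box_id`,
#'   `gold_box_id`, `precision`, `recall`, `f1`, `zeroed`.
#' @examples
#' g <- data.frame(gold_box_id = 1, x_min = 0, y_min = 0, width = 10, height = 10)
#' p <- data.frame(box_id = 1:2, x_min = 0, y_min = 0, width = c(10, 20), height = 10)
#' match_boxes(p, g) # box 2 argmaxes to the same gold box and is zeroed
#' @export
match_boxes <- function(participant_boxes, gold_boxes) {
  gold <- boxes_to_df(gold_boxes, "gold_box_id")
  if (nrow(gold) == 0L)
    stop("image has no gold-standard boxes; cannot score annotations")
  if (any(gold$width <= 0 | gold$height <= 0))
    stop("degenerate gold box (non-positive extent) in gold table")
  part <- boxes_to_df(participant_boxes, "box_id")
  n <- nrow(part)
  out <- data.frame(box_id = part$box_id,
                    gold_box_id = rep(gold$gold_box_id[1], n),
                    precision = numeric(n), recall = numeric(n),
                    f1 = numeric(n), zeroed = logical(n))
  if (n == 0L) return(out)

  degenerate <- part$width <= 0 | part$height <= 0
  if (any(degenerate))
    warning(sum(degenerate), " degenerate participant box(es) scored (0, 0, 0)")

  for (i in seq_len(nrow(part))) {
    if (degenerate[i]) { out$gold_box_id[i] <- NA; next }
    prf <- prf_against_gold(part$x_min[i], part$y_min[i],
                            part$width[i], part$height[i], gold)
    best <- which(prf[, "f1"] == max(prf[, "f1"]))
    best <- best[which.min(gold$gold_box_id[best])]
    out$gold_box_id[i] <- gold$gold_box_id[best]
    out$precision[i] <- prf[best, "precision"]
    out$recall[i]    <- prf[best, "recall"]
    out$f1[i]        <- prf[best, "f1"]
  }

  # conflict rule: one keeper per gold box, the rest zeroed
  for (g in unique(out$gold_box_id[!is.na(out$gold_box_id)])) {
    idx <- which(!is.na(out$gold_box_id) & out$gold_box_id == g)
    if (length(idx) < 2L) next
    keep <- idx[out$f1[idx] == max(out$f1[idx])]
    keep <- keep[which.min(out$box_id[keep])]
    losers <- setdiff(idx, keep)
    out$precision[losers] <- 0
    out$recall[losers] <- 0
    out$f1[losers] <- 0
    out$zeroed[losers] <- TRUE
  }
  out
}

#' Average F1 of one participant on one image
#'
#' The arithmetic mean of the per-box F1 values of a single participant on a
#' single image, conflict-zeroed boxes included. This is the per
#' participant-image response used by the group-comparison mixed model.
#'
#' @param results A data.frame as returned by [match_boxes()]; at least one row.
#' @return A single number in `[0, 1]`.
#' @export
f_mean <- function(results) {
  if (!is.data.frame(results) || !"f1" %in% names(results))
    stop("`results` must be a match-result data.frame with an `f1` column")
  if (nrow(results) == 0L)
    stop("cannot average an empty set of match results; >= 1 box is required")
  mean(results$f1)
}

#' Score a full annotation table against a gold table
#'
#' Runs [match_boxes()] for every (participant, image) pair in the annotation
#' table and aggregates per-image [f_mean()] scores. Every participant box
#' keeps its match result so that the precision/recall density structure can
#' be analysed per group.
#'
#' @param annotations Annotation table: one row per participant-drawn box with
#'   columns `participant_id`, `group`, `image_id`, `question_index`,
#'   `box_id`, `x_min`, `y_min`, `width`, `height`, `time_seconds`.
#' @param gold Gold table: one row per gold box with columns `image_id`,
#'   `gold_box_id`, `x_min`, `y_min`, `width`, `height` (and optionally
#'   `difficulty`).
#' @return An object of class `crowd_scores`: a list with `box_scores`
#'   (per-box match results joined with annotation metadata) and
#'   `image_scores` (one row per participant-image with `f_mean`, `n_boxes`,
#'   `question_index` and `time_seconds`).
#' @export
score_dataset <- function(annotations, gold) {
  stopifnot(is.data.frame(annotations), is.data.frame(gold))
  unknown <- setdiff(unique(annotations$image_id), unique(gold$image_id))
  if (length(unknown))
    stop("annotation table references image id(s) absent from the gold table: ",
         paste(utils::head(unknown, 10), collapse = ", "))

  if (nrow(annotations) == 0L) {
    empty_box <- data.frame(participant_id = character(), group = character(),
                            image_id = character(), question_index = integer(),
                            box_id = integer(), gold_box_id = integer(),
                            precision = numeric(), recall = numeric(),
                            f1 = numeric(), zeroed = logical(),
                            time_seconds = numeric())
    empty_img <- data.frame(participant_id = character(), group = character(),
                            image_id = character(), question_index = integer(),
                            f_mean = numeric(), n_boxes = integer(),
                            time_seconds = numeric())
    return(structure(list(box_scores = empty_box, image_scores = empty_img),
                     class = "crowd_scores"))
  }

  gold_by_image <- split(gold, gold$image_id)
  ann_split <- split(annotations,
                     list(annotations$participant_id, annotations$image_id),
                     drop = TRUE)
  box_rows <- vector("list", length(ann_split))
  img_rows <- vector("list", length(ann_split))
  for (k in seq_along(ann_split)) {
    a <- ann_split[[k]]
    m <- match_boxes(a[c("box_id", "x_min", "y_min", "width", "height")],
                     gold_by_image[[as.character(a$image_id[1])]])
    box_rows[[k]] <- data.frame(participant_id = a$participant_id,
                                group = a$group,
                                image_id = a$image_id,
                                question_index = a$question_index,
                                m,
                                time_seconds = a$time_seconds)
    img_rows[[k]] <- data.frame(participant_id = a$participant_id[1],
                                group = a$group[1],
                                image_id = a$image_id[1],
                                question_index = a$question_index[1],
                                f_mean = mean(m$f1),
                                n_boxes = nrow(m),
                                time_seconds = a$time_seconds[1])
  }
  box_scores <- do.call(rbind, box_rows)
  image_scores <- do.call(rbind, img_rows)
  ord <- order(image_scores$participant_id, image_scores$question_index)
  image_scores <- image_scores[ord, ]
  rownames(box_scores) <- rownames(image_scores) <- NULL
  structure(list(box_scores = box_scores, image_scores = image_scores),
            class = "crowd_scores")
}

#' @export
print.crowd_scores <- function(x, ...) {
  cat("crowd_scores:", nrow(x$box_scores), "scored boxes across",
      nrow(x$image_scores), "participant-image pairs\n")
  cat("  mean F_mean:", round(mean(x$image_scores$f_mean), 4), "\n")
  invisible(x)
}
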