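#' Axis-aligned box in pixel coordinates
#'
#' Boxes use the raster convention: origin at the top-left corner, x growing
#' rightwards (columns), y growing downwards (rows), 0-based coordinates, and
#' half-open intervals `[x_min, x_min + width) x [y_min, y_min + height)`.
#' Under this convention intersection arithmetic is exact in integers and the
#' area of an integer box equals its pixel count.
#'
#' @param x_min,y_min Top-left corner, in pixels (>= 0).
#' @param width,height Extents in pixels; must be strictly positive.
#' @return An object of class `crowd_box`: a named numeric vector with
#'   elements `x_min`, `y_min`, `width`, `height`.
#' @examples
#' b <- box(0, 0, 10, 10)
#' box_area(b)
#' @export
box <- function(x_min, y_min, width, height) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         width = as.numeric(width), height = as.numeric(height))
  if (anyNA(b)) stop("box coordinates must be non-missing numerics")
  if (b[["x_min"]] < 0 || b[["y_min"]] < 0)
    stop("box origin must be non-negative, got (", b[["x_min"]], ", ", b[["y_min"]], ")")
  if (b[["width"]] <= 0 || b[["height"]] <= 0)
    stop("degenerate box: width and height must be strictly positive, got ",
         b[["width"]], " x ", b[["height"]])
  class(b) <- "crowd_box"
  b
}

as_box <- function(x) {
  if (inherits(x, "crowd_box")) return(x)
  if (is.list(x) || (is.numeric(x) && !is.null(names(x))))
    return(box(x[["x_min"]], x[["y_min"]], x[["width"]], x[["height"]]))
  if (is.numeric(x) && length(x) == 4L) return(box(x[1], x[2], x[3], x[4]))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"), " as a box")
}

#' @rdname box
#' @param b A `crowd_box` (or coercible object).
#' @export
box_area <- function(b) {
  b <- as_box(b)
  unname(b[["width"]] * b[["height"]])
}

#' Intersection area of two boxes
#'
#' Area of overlap between two axis-aligned boxes in the same image frame,
#' in squared pixels. Zero when the boxes are disjoint. Symmetric in its
#' arguments and never larger than the smaller box.
#'
#' @param a,b Boxes (see [box()]).
#' @return Intersection area in pixels^2.
#' @examples
#' intersection_area(box(0, 0, 10, 10), box(5, 5, 10, 10)) # 25
#' @export
intersection_area <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ox <- min(a[["x_min"]] + a[["width"]],  b[["x_min"]] + b[["width"]])  -
        max(a[["x_min"]], b[["x_min"]])
  oy <- min(a[["y_min"]] + a[["height"]], b[["y_min"]] + b[["height"]]) -
        max(a[["y_min"]], b[["y_min"]])
  max(0, ox) * max(0, oy)
}

#' Precision, recall and F1 of a participant box against a gold box
#'
#' With `PB` the participant-box area, `GB` the gold-box area and `IB` their
#' intersection area, precision is `IB/PB`, recall is `IB/GB`, and F1 is the
#' harmonic mean `2*Pr*Rc/(Pr+Rc)`, defined as 0 when both rates are 0
#' (disjoint boxes). All three lie in `[0, 1]`: 0 when the boxes fail to
#' overlap, 1 only for identical boxes.
#'
#' @param participant,gold Boxes (see [box()]).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @examples
#' precision_recall_f1(box(0, 0, 20, 10), box(0, 0, 10, 10)) # 0.5, 1, 2/3
#' @export
precision_recall_f1 <- function(participant, gold) {
  participant <- as_box(participant); gold <- as_box(gold)
  ib <- intersection_area(participant, gold)
  pr <- ib / box_area(participant)
  rc <- ib / box_area(gold)
  f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  c(precision = pr, recall = rc, f1 = f1)
}

# Vectorised Pr/Rc/F1 of one participant box row against a gold-box
# data.frame; returns a matrix with one row per gold box.
prf_against_gold <- function(px, py, pw, ph, gold) {
  ox <- pmin(px + pw, gold$x_min + gold$width) - pmax(px, gold$x_min)
  oy <- pmin(py + ph, gold$y_min + gold$height) - pmax(py, gold$y_min)
  ib <- pmax(0, ox) * pmax(0, oy)
  pr <- ib / (pw * ph)
  rc <- ib / (gold$width * gold$height)
  f1 <- ifelse(pr + rc == 0, 0, 2 * pr * rc / (pr + rc))
  cbind(precision = pr, recall = rc, f1 = f1)
}
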