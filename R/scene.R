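#' Scene specification for the synthetic image generator
#'
#' Describes one synthetic field image: raster dimensions, the number of
#' tassel-like foreground objects, and a difficulty class. Hard scenes pack
#' their tassels into a smaller central region (so overlaps among foreground
#' tassels are more frequent) and add tassel-like background clutter that
#' carries no gold box, mimicking field photos where background plants must
#' be ignored.
#'
#' @param width,height Image dimensions in pixels (>= 64).
#' @param n_tassels Number of foreground tassels (>= 1).
#' @param difficulty `"easy"` or `"hard"`.
#' @param stem_frac Stem length as a fraction of image height (range).
#' @param n_branches Range of branch counts per tassel.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 256, height = 256, n_tassels = 4,
                       difficulty = c("easy", "hard"),
                       stem_frac = c(0.18, 0.30), n_branches = c(3L, 6L)) {
  difficulty <- match.arg(difficulty)
  stopifnot(width >= 64, height >= 64, n_tassels >= 1)
  if (n_tassels > floor(width * height / 1024))
    stop("impossible placement: ", n_tassels, " tassels cannot fit in a ",
         width, "x", height, " image")
  structure(list(width = width, height = height, n_tassels = n_tassels,
                 difficulty = difficulty, stem_frac = stem_frac,
                 n_branches = n_branches),
            class = "scene_spec")
}

# Rasterize one tassel: a slightly tilted stem with curved branches near the
# top, stamped with a 3x3 brush. Returns an n x 2 matrix of (row, col) pixel
# indices, 1-based, possibly out of bounds (caller translates into frame).
draw_tassel_pixels <- function(spec) {
  h <- spec$height; w <- spec$width
  len <- stats::runif(1, spec$stem_frac[1], spec$stem_frac[2]) * h
  tilt <- stats::rnorm(1, 0, 0.12)
  t <- seq(0, len, by = 0.5)
  sx <- sin(tilt) * t
  sy <- -t
  pts <- cbind(sx, sy)
  nb <- sample(seq(spec$n_branches[1], spec$n_branches[2]), 1)
  for (b in seq_len(nb)) {
    at <- stats::runif(1, 0.45, 1) * len           # attach on upper stem
    ang <- sample(c(-1, 1), 1) * stats::runif(1, 0.35, 1.1)
    blen <- stats::runif(1, 0.25, 0.55) * len
    bt <- seq(0, blen, by = 0.5)
    curve <- 0.004 * bt^2 * sample(c(-1, 1), 1)
    bx <- sin(tilt) * at + sin(ang) * bt + cos(ang) * curve
    by <- -at - cos(ang) * bt + sin(ang) * curve
    pts <- rbind(pts, cbind(bx, by))
  }
  px <- round(pts[, 1]); py <- round(pts[, 2])
  # 3x3 brush for thickness
  off <- expand.grid(dr = -1:1, dc = -1:1)
  rows <- as.vector(outer(py, off$dr, `+`))
  cols <- as.vector(outer(px, off$dc, `+`))
  unique(cbind(row = rows, col = cols))
}

#' Generate a synthetic tassel scene
#'
#' Renders a grayscale field-like image containing `n_tassels` branched,
#' elongated foreground blobs (statistical stand-ins for maize tassels, not
#' botanical renderings) over textured background noise, and returns one
#' binary mask per tassel. Foreground pixels are brighter than background on
#' average, so the tassel class is learnable from intensity texture.
#' Deterministic given `seed`.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed for this scene.
#' @return A list with `image` (height x width matrix in `[0, 1]`), `masks`
#'   (list of logical matrices, one per tassel, all pixels inside the frame),
#'   and `spec`.
#' @export
generate_scene <- function(spec, seed) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  h <- spec$height; w <- spec$width
  hard <- spec$difficulty == "hard"
  # hard scenes confine anchors to a central band -> more overlap
  shrink <- if (hard) 0.30 else 0.05
  masks <- vector("list", spec$n_tassels)
  for (i in seq_len(spec$n_tassels)) {
    px <- draw_tassel_pixels(spec)
    # translate the blob so that it fits fully inside the (shrunken) frame
    rlo <- min(px[, "row"]); rhi <- max(px[, "row"])
    clo <- min(px[, "col"]); chi <- max(px[, "col"])
    rmar <- floor(shrink * h / 2); cmar <- floor(shrink * w / 2)
    r0 <- sample(seq(1 + rmar - rlo, h - rmar - rhi), 1)
    c0 <- sample(seq(1 + cmar - clo, w - cmar - chi), 1)
    m <- matrix(FALSE, h, w)
    m[cbind(px[, "row"] + r0, px[, "col"] + c0)] <- TRUE
    masks[[i]] <- m
  }
  bg_rows <- matrix(seq(0, 0.08, length.out = h), h, w)           # low-freq shading
  image <- 0.33 + bg_rows + matrix(stats::rnorm(h * w, 0, 0.05), h, w)
  if (hard) {
    # background clutter: faint tassel-like marks with no gold box
    for (j in seq_len(spec$n_tassels)) {
      px <- draw_tassel_pixels(spec)
      r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
      rr <- px[, "row"] + r0; cc <- px[, "col"] + c0
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      image[cbind(rr[ok], cc[ok])] <- image[cbind(rr[ok], cc[ok])] + 0.12
    }
  }
  fg <- Reduce(`|`, masks)
  image[fg] <- 0.72 + stats::rnorm(sum(fg), 0, 0.06)
  image[image < 0] <- 0; image[image > 1] <- 1
  list(image = image, masks = masks, spec = spec)
}

#' Minimum bounding box of a binary mask
#'
#' The smallest axis-aligned box containing every foreground pixel of the
#' mask: each of its four edges touches at least one foreground pixel. This
#' is the gold-standard construction used to score participant boxes.
#' Coordinates follow the raster convention of [box()] (0-based, half-open),
#' so a single foreground pixel at matrix position (row 8, col 6) yields the
#' unit box `(5, 7, 1, 1)`.
#'
#' @param mask A logical (or 0/1) matrix; must contain >= 1 foreground pixel.
#' @return A [box()].
#' @export
min_bounding_box <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box")
  rlo <- min(idx[, 1]); rhi <- max(idx[, 1])
  clo <- min(idx[, 2]); chi <- max(idx[, 2])
  box(x_min = clo - 1, y_min = rlo - 1,
      width = chi - clo + 1, height = rhi - rlo + 1)
}

# count of overlapping mask pairs in one scene (bounding-box overlap)
count_overlapping_pairs <- function(scene) {
  bbs <- lapply(scene$masks, min_bounding_box)
  n <- length(bbs)
  if (n < 2) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (intersection_area(bbs[[i]], bbs[[j]]) > 0) cnt <- cnt + 1L
  cnt
}

#' Write a scene image as an 8-bit RGB PNG
#'
#' @param image A matrix in `[0, 1]` as produced by [generate_scene()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(image, path) {
  arr <- array(rep(image, 3), dim = c(nrow(image), ncol(image), 3))
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a scene PNG back as a grayscale matrix
#'
#' @param path PNG file path.
#' @return A matrix in `[0, 1]`.
#' @export
read_scene_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1] else arr
}
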