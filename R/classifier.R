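#' Classifier configuration
#'
#' Parameters of the bag-of-visual-words + SVM pipeline. Crops are resized
#' to a square canonical size; dense patches are taken on a regular grid and
#' described by their raw intensity values (brightness and texture both
#' carry signal in the synthetic imagery); the codebook is a k-means
#' clustering of patch descriptors; crops are encoded as normalized
#' codeword-frequency histograms and classified with a linear-kernel SVM.
#'
#' @param K Vocabulary size (number of codewords).
#' @param canonical Canonical square crop size, pixels.
#' @param patch Patch side, pixels.
#' @param stride Patch grid stride, pixels.
#' @param cost SVM cost parameter (linear kernel).
#' @param n_negatives Size of the constant negative training set.
#' @param n_test_pos,n_test_neg Test-set sizes (tassel / non-tassel crops).
#' @param max_descriptors Cap on descriptors sampled for vocabulary building.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(K = 100, canonical = 32, patch = 8, stride = 4,
                              cost = 1, n_negatives = 600,
                              n_test_pos = 600, n_test_neg = 600,
                              max_descriptors = 20000) {
  stopifnot(K >= 2, canonical >= patch, patch >= 2, stride >= 1)
  structure(list(K = K, canonical = canonical, patch = patch, stride = stride,
                 cost = cost, n_negatives = n_negatives,
                 n_test_pos = n_test_pos, n_test_neg = n_test_neg,
                 max_descriptors = max_descriptors),
            class = "classifier_config")
}

#' Cut a box out of an image and resize it to the canonical size
#'
#' Boxes extending past the image edge are clipped (with a warning); boxes
#' fully outside the image are dropped (`NULL`, with a warning). Resizing is
#' bilinear.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param b A [box()] (or coercible).
#' @param canonical Output side length, pixels.
#' @return A `canonical x canonical` matrix, or `NULL` for a box fully
#'   outside the image.
#' @export
crop_box <- function(image, b, canonical = 32) {
  b <- as_box(b)
  h <- nrow(image); w <- ncol(image)
  r1 <- floor(b[["y_min"]]) + 1; r2 <- ceiling(b[["y_min"]] + b[["height"]])
  c1 <- floor(b[["x_min"]]) + 1; c2 <- ceiling(b[["x_min"]] + b[["width"]])
  if (r1 > h || c1 > w || r2 < 1 || c2 < 1) {
    warning("box fully outside the image; crop dropped")
    return(NULL)
  }
  if (r1 < 1 || c1 < 1 || r2 > h || c2 > w)
    warning("box extends past the image edge; clipped")
  crop <- image[max(r1, 1):min(r2, h), max(c1, 1):min(c2, w), drop = FALSE]
  if (any(dim(crop) != canonical))
    crop <- EBImage::imageData(EBImage::resize(EBImage::Image(crop),
                                               w = canonical, h = canonical))
  crop
}

# dense patch descriptors: raw intensities of patch x patch windows on a
# stride grid; one row per patch
extract_descriptors <- function(crop, patch = 8, stride = 4) {
  n <- nrow(crop)
  pos <- seq(1, n - patch + 1, by = stride)
  desc <- matrix(0, length(pos)^2, patch * patch)
  k <- 0L
  for (r in pos) for (c in pos) {
    k <- k + 1L
    desc[k, ] <- as.vector(crop[r:(r + patch - 1), c:(c + patch - 1)])
  }
  desc
}

#' Bundle positive and negative crops into a training or test set
#'
#' @param positives,negatives Lists of canonical-size crop matrices.
#' @param provenance Where the positives came from: a participant id or
#'   `"gold"`.
#' @return A list of class `crop_set`.
#' @export
crop_set <- function(positives, negatives, provenance = "gold") {
  structure(list(positives = positives, negatives = negatives,
                 provenance = provenance),
            class = "crop_set")
}

#' Sample non-tassel crops from a set of scenes
#'
#' Draws boxes uniformly over the images, matched in size to randomly chosen
#' gold boxes, and keeps only boxes with zero intersection with every gold
#' box of their image (gold boxes contain the tassel masks, so such crops
#' contain no tassel). Used both for the constant negative training set and
#' for the non-tassel half of the test set.
#'
#' @param images Named list of grayscale matrices.
#' @param gold Gold table covering those images.
#' @param n Number of crops wanted.
#' @param seed Integer seed.
#' @param canonical Canonical crop size.
#' @param max_tries Rejection-sampling cap.
#' @return A list of `n` crop matrices.
#' @export
sample_negative_crops <- function(images, gold, n, seed, canonical = 32,
                                  max_tries = 50 * n) {
  set.seed(seed)
  ids <- names(images)
  gold_by_image <- split(gold, gold$image_id)
  out <- vector("list", n)
  k <- 0L; tries <- 0L
  while (k < n && tries < max_tries) {
    tries <- tries + 1L
    id <- sample(ids, 1)
    img <- images[[id]]
    g <- gold_by_image[[id]]
    tmpl <- g[sample.int(nrow(g), 1), ]
    w <- min(tmpl$width, ncol(img)); h <- min(tmpl$height, nrow(img))
    x <- stats::runif(1, 0, ncol(img) - w)
    y <- stats::runif(1, 0, nrow(img) - h)
    cand <- box(x, y, w, h)
    hits <- prf_against_gold(x, y, w, h, g)
    if (any(hits[, "f1"] > 0)) next
    k <- k + 1L
    out[[k]] <- crop_box(img, cand, canonical)
  }
  if (k < n)
    stop("could only sample ", k, " of ", n,
         " negative crops; scenes may be too crowded")
  out
}

#' Crop a participant's (or the expert's) boxes into a positive set
#'
#' Builds the per-participant training set: every box that participant drew,
#' cropped from its image and resized to the canonical size, as the positive
#' class, together with the shared constant negative set passed through
#' unchanged.
#'
#' @param annotations Annotation rows of a single participant (or gold-table
#'   rows for an expert set, any table with `image_id` and box coordinates).
#' @param images Named list of grayscale matrices.
#' @param negatives List of negative crops, shared across participants.
#' @param canonical Canonical crop size.
#' @return A [crop_set()].
#' @export
build_training_set <- function(annotations, images, negatives, canonical = 32) {
  stopifnot(length(negatives) >= 1)
  prov <- if ("participant_id" %in% names(annotations) && nrow(annotations) > 0)
    as.character(annotations$participant_id[1]) else "gold"
  pos <- vector("list", nrow(annotations))
  keep <- logical(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    cr <- crop_box(images[[as.character(a$image_id)]],
                   c(x_min = a$x_min, y_min = a$y_min,
                     width = a$width, height = a$height),
                   canonical)
    if (!is.null(cr)) { pos[[i]] <- cr; keep[i] <- TRUE }
  }
  crop_set(pos[keep], negatives, provenance = prov)
}

#' Learn a visual-word codebook from crops
#'
#' Samples patch descriptors across the supplied crops (capped at
#' `max_descriptors`) and clusters them with k-means into `K` centroids.
#' Deterministic given `seed`.
#'
#' @param crops List of canonical-size crop matrices.
#' @param K Vocabulary size.
#' @param seed Integer seed.
#' @param config A [classifier_config()] supplying patch geometry.
#' @return A list of class `feature_vocabulary` with `codebook`
#'   (`K x patch^2` matrix), `K`, and the patch geometry.
#' @export
build_vocabulary <- function(crops, K, seed, config = classifier_config(K = K)) {
  desc <- do.call(rbind, lapply(crops, extract_descriptors,
                                patch = config$patch, stride = config$stride))
  set.seed(seed)
  if (nrow(desc) > config$max_descriptors)
    desc <- desc[sample.int(nrow(desc), config$max_descriptors), ]
  if (nrow(unique(desc)) < K)
    stop("only ", nrow(unique(desc)), " distinct descriptors available; ",
         "reduce K below ", K)
  # fixed Lloyd iteration budget: a codebook does not need exact convergence
  km <- suppressWarnings(stats::kmeans(desc, centers = K, iter.max = 50,
                                       nstart = 1, algorithm = "Lloyd"))
  structure(list(codebook = km$centers, K = K,
                 patch = config$patch, stride = config$stride),
            class = "feature_vocabulary")
}

#' Encode a crop as a codeword-frequency vector
#'
#' Assigns every patch descriptor of the crop to its nearest codeword
#' (Euclidean distance) and returns the normalized histogram of assignments:
#' a nonnegative vector of length `K` summing to 1.
#'
#' @param crop Canonical-size crop matrix.
#' @param vocab A `feature_vocabulary` from [build_vocabulary()].
#' @return Numeric vector of length `vocab$K`.
#' @export
encode <- function(crop, vocab) {
  stopifnot(inherits(vocab, "feature_vocabulary"))
  desc <- extract_descriptors(crop, vocab$patch, vocab$stride)
  cb <- vocab$codebook
  # squared distances via ||d||^2 - 2 d.c + ||c||^2; the ||d||^2 term is
  # constant per row and can be dropped for the argmin
  d2 <- -2 * desc %*% t(cb)
  d2 <- sweep(d2, 2, rowSums(cb^2), `+`)
  nearest <- max.col(-d2, ties.method = "first")
  tabulate(nearest, nbins = vocab$K) / nrow(desc)
}

encode_set <- function(crops, vocab) {
  t(vapply(crops, encode, numeric(vocab$K), vocab = vocab))
}

#' Train a linear SVM on a crop set and evaluate it on a test set
#'
#' Encodes the training crops with the vocabulary (built from the training
#' crops when `vocab` is `NULL`), fits a linear-kernel support-vector
#' classifier, and evaluates on the test crops. Performance is the mean of
#' the true positive rate and the true negative rate.
#'
#' @param train,test [crop_set()]s; the test set must contain both classes.
#' @param vocab Optional `feature_vocabulary`; built from `train` if `NULL`.
#' @param config A [classifier_config()].
#' @param seed Integer seed (vocabulary sampling and SVM).
#' @return A list of class `classifier_result`: `provenance`, `tpr`, `tnr`,
#'   `performance`, confusion counts (`tp`, `fn`, `tn`, `fp`), and `vocab`.
#' @export
train_and_evaluate <- function(train, test, vocab = NULL,
                               config = classifier_config(), seed = 1) {
  stopifnot(inherits(train, "crop_set"), inherits(test, "crop_set"))
  if (length(train$positives) == 0L || length(train$negatives) == 0L)
    stop("training set must contain both classes")
  if (length(test$positives) == 0L || length(test$negatives) == 0L)
    stop("test set must contain both classes")
  if (is.null(vocab))
    vocab <- build_vocabulary(c(train$positives, train$negatives),
                              K = config$K, seed = seed, config = config)
  x <- rbind(encode_set(train$positives, vocab),
             encode_set(train$negatives, vocab))
  y <- factor(rep(c("tassel", "background"),
                  c(length(train$positives), length(train$negatives))),
              levels = c("background", "tassel"))
  set.seed(seed)
  model <- e1071::svm(x, y, kernel = "linear", cost = config$cost, scale = FALSE)
  pred_pos <- stats::predict(model, encode_set(test$positives, vocab))
  pred_neg <- stats::predict(model, encode_set(test$negatives, vocab))
  tp <- sum(pred_pos == "tassel"); fn <- length(pred_pos) - tp
  tn <- sum(pred_neg == "background"); fp <- length(pred_neg) - tn
  tpr <- tp / (tp + fn); tnr <- tn / (tn + fp)
  structure(list(provenance = train$provenance, tpr = tpr, tnr = tnr,
                 performance = (tpr + tnr) / 2,
                 tp = tp, fn = fn, tn = tn, fp = fp, vocab = vocab),
            class = "classifier_result")
}

#' Train and evaluate one classifier per participant
#'
#' Builds each participant's positive set from their own boxes, shares one
#' constant negative training set across all participants, trains a
#' bag-of-features + linear SVM classifier per participant, and evaluates
#' all of them on one common test set of tassel and non-tassel crops drawn
#' from freshly generated scenes (never seen during training). Optionally
#' adds an expert row trained on the gold boxes themselves.
#'
#' @param annotations Canonical annotation table (all participants).
#' @param images Named list of grayscale training-scene matrices.
#' @param gold Gold table for those scenes.
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @param include_expert Add a `"gold"`-provenance row trained on gold boxes.
#' @param test_scenes Optional list with `images` and `gold` for the test
#'   set; generated internally (same scene geometry as `images`) when `NULL`.
#' @return A list with `results` (data.frame: `participant_id`, `group`,
#'   `tpr`, `tnr`, `performance`), `group_means`, and `expert`
#'   (a `classifier_result` or `NULL`).
#' @export
evaluate_cohort <- function(annotations, images, gold,
                            config = classifier_config(), seed = 1,
                            include_expert = TRUE, test_scenes = NULL) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  if (is.null(test_scenes)) {
    per_scene <- max(1, round(nrow(gold) / length(images)))
    n_test_img <- max(2L, ceiling(config$n_test_pos / per_scene))
    t_images <- list(); t_gold <- list()
    for (i in seq_len(n_test_img)) {
      sc <- generate_scene(scene_spec(w, h, n_tassels = per_scene),
                           seed = seed + 7000L + i)
      id <- sprintf("test%03d", i)
      t_images[[id]] <- sc$image
      bbs <- lapply(sc$masks, min_bounding_box)
      t_gold[[i]] <- data.frame(image_id = id, gold_box_id = seq_along(bbs),
                                do.call(rbind, lapply(bbs, unclass)),
                                difficulty = "easy")
    }
    test_scenes <- list(images = t_images, gold = do.call(rbind, t_gold))
  }
  tg <- test_scenes$gold
  n_pos <- min(config$n_test_pos, nrow(tg))
  set.seed(seed + 11L)
  tg <- tg[sample.int(nrow(tg), n_pos), ]
  test_pos <- lapply(seq_len(nrow(tg)), function(i)
    crop_box(test_scenes$images[[as.character(tg$image_id[i])]], tg[i, ],
             config$canonical))
  test_neg <- sample_negative_crops(test_scenes$images, test_scenes$gold,
                                    config$n_test_neg, seed = seed + 13L,
                                    canonical = config$canonical)
  test_set <- crop_set(test_pos, test_neg, provenance = "test")

  negatives <- sample_negative_crops(images, gold, config$n_negatives,
                                     seed = seed + 17L,
                                     canonical = config$canonical)

  parts <- unique(annotations[c("participant_id", "group")])
  rows <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    pid <- parts$participant_id[i]
    ts <- build_training_set(annotations[annotations$participant_id == pid, ],
                             images, negatives, config$canonical)
    res <- train_and_evaluate(ts, test_set, config = config, seed = seed + i)
    rows[[i]] <- data.frame(participant_id = pid, group = parts$group[i],
                            tpr = res$tpr, tnr = res$tnr,
                            performance = res$performance)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  expert <- NULL
  if (include_expert) {
    ets <- build_training_set(gold, images, negatives, config$canonical)
    expert <- train_and_evaluate(ets, test_set, config = config, seed = seed)
  }
  list(results = results,
       group_means = tapply(results$performance, results$group, mean),
       expert = expert)
}
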