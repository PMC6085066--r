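# Independent oracles and fixture builders, computed from first principles
# (no calls into the matching code they are used to check).

# Pr/Rc/F1 of two boxes by direct interval arithmetic
oracle_prf <- function(p, g) {
  ox <- max(0, min(p$x_min + p$width, g$x_min + g$width) - max(p$x_min, g$x_min))
  oy <- max(0, min(p$y_min + p$height, g$y_min + g$height) - max(p$y_min, g$y_min))
  ib <- ox * oy
  pr <- ib / (p$width * p$height)
  rc <- ib / (g$width * g$height)
  f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  c(precision = pr, recall = rc, f1 = f1)
}

# intersection area by counting unit pixels of a discrete grid (integer boxes)
oracle_pixel_intersection <- function(a, b, grid = 64) {
  xs <- 0:(grid - 1); ys <- 0:(grid - 1)
  inside <- function(bx, x, y)
    x >= bx$x_min & x < bx$x_min + bx$width & y >= bx$y_min & y < bx$y_min + bx$height
  cnt <- 0
  for (y in ys) cnt <- cnt + sum(inside(a, xs, y) & inside(b, xs, y))
  cnt
}

# literal transcription of the matching rule: argmax-F1 assignment per
# participant box (ties -> smaller gold id), then per gold box keep the
# highest-F1 claimant (ties -> lower box id) and zero the rest
oracle_match <- function(part, gold) {
  n <- nrow(part)
  res <- data.frame(box_id = part$box_id, gold_box_id = NA_real_,
                    precision = 0, recall = 0, f1 = 0, zeroed = FALSE)
  for (i in seq_len(n)) {
    best <- NULL
    for (j in seq_len(nrow(gold))) {
      prf <- oracle_prf(part[i, ], gold[j, ])
      if (is.null(best) || prf[["f1"]] > best$f1 + 1e-12 ||
          (abs(prf[["f1"]] - best$f1) <= 1e-12 && gold$gold_box_id[j] < best$gid)) {
        best <- list(f1 = prf[["f1"]], gid = gold$gold_box_id[j],
                     pr = prf[["precision"]], rc = prf[["recall"]])
      }
    }
    res$gold_box_id[i] <- best$gid
    res$precision[i] <- best$pr; res$recall[i] <- best$rc; res$f1[i] <- best$f1
  }
  for (g in unique(res$gold_box_id)) {
    idx <- which(res$gold_box_id == g)
    if (length(idx) < 2) next
    keep <- idx[res$f1[idx] == max(res$f1[idx])]
    keep <- keep[which.min(res$box_id[keep])]
    losers <- setdiff(idx, keep)
    res$precision[losers] <- 0; res$recall[losers] <- 0; res$f1[losers] <- 0
    res$zeroed[losers] <- TRUE
  }
  res
}

# random integer boxes inside a 30x30 frame
random_box_df <- function(n, id_col) {
  df <- data.frame(x_min = sample(0:20, n, replace = TRUE),
                   y_min = sample(0:20, n, replace = TRUE),
                   width = sample(1:10, n, replace = TRUE),
                   height = sample(1:10, n, replace = TRUE))
  df[[id_col]] <- seq_len(n)
  df
}

# small cohort used by several tests; shrunk relative to the package
# defaults so the whole suite stays fast
tiny_cohort_config <- function(seed = 1, ...) {
  cohort_config(group_sizes = c(master = 3, nonmaster = 3, credit = 3),
                n_images = 10, image_width = 128, image_height = 128,
                n_tassels_easy = 3, n_tassels_hard = 5, seed = seed, ...)
}

# flat-texture crops: trivially separable two-class problem
flat_crop <- function(level, size = 32, noise = 0.02) {
  matrix(level + stats::rnorm(size * size, 0, noise), size, size)
}

# directly simulated per participant-image score table (no images involved):
# used for null simulations of the statistical tests
simulate_score_table <- function(n_per_group = 3, n_images = 20,
                                 group_means = c(master = 0.75, nonmaster = 0.75,
                                                 credit = 0.75),
                                 participant_sd = 0.05, image_sd = 0.04,
                                 resid_sd = 0.08) {
  groups <- names(group_means)
  img_eff <- stats::rnorm(n_images, 0, image_sd)
  rows <- list()
  for (g in groups) for (p in seq_len(n_per_group)) {
    pid <- paste0(g, p)
    p_eff <- stats::rnorm(1, 0, participant_sd)
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = pid, group = g,
      image_id = sprintf("img%02d", seq_len(n_images)),
      question_index = seq_len(n_images),
      f_mean = group_means[[g]] + p_eff + img_eff +
        stats::rnorm(n_images, 0, resid_sd),
      n_boxes = 1L,
      time_seconds = exp(stats::rnorm(n_images, log(25), 0.4)))
  }
  do.call(rbind, rows)
}
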