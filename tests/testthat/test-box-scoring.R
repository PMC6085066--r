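test_that("intersection area matches closed form and pixel-count oracle", {
  expect_equal(intersection_area(box(0, 0, 10, 10), box(0, 0, 10, 10)), 100)
  expect_equal(intersection_area(box(0, 0, 10, 10), box(20, 20, 5, 5)), 0)
  # frozen from the pixel-rasterization oracle over a discrete grid
  expect_equal(intersection_area(box(0, 0, 10, 10), box(5, 5, 10, 10)), 25)
  expect_equal(oracle_pixel_intersection(list(x_min = 0, y_min = 0, width = 10, height = 10),
                                         list(x_min = 5, y_min = 5, width = 10, height = 10)),
               25)
  set.seed(41)
  for (i in 1:25) {
    a <- random_box_df(1, "box_id"); b <- random_box_df(1, "box_id")
    got <- intersection_area(box(a$x_min, a$y_min, a$width, a$height),
                             box(b$x_min, b$y_min, b$width, b$height))
    expect_equal(got, oracle_pixel_intersection(a, b))
    expect_equal(got, intersection_area(box(b$x_min, b$y_min, b$width, b$height),
                                        box(a$x_min, a$y_min, a$width, a$height)))
    expect_lte(got, min(a$width * a$height, b$width * b$height))
  }
})

test_that("degenerate boxes are rejected at construction", {
  expect_error(box(0, 0, 0, 10), "degenerate")
  expect_error(box(0, 0, 5, -1), "degenerate")
  expect_error(box(-1, 0, 5, 5), "non-negative")
})

test_that("precision/recall/F1 hit their printed extremes and area arithmetic", {
  expect_equal(precision_recall_f1(box(0, 0, 10, 10), box(0, 0, 10, 10)),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(precision_recall_f1(box(50, 50, 5, 5), box(0, 0, 10, 10)),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(box(0, 0, 20, 10), box(0, 0, 10, 10)),
               c(precision = 0.5, recall = 1, f1 = 2 / 3))
})

test_that("enclosing participant boxes have perfect recall, imperfect precision", {
  set.seed(42)
  for (i in 1:20) {
    g <- random_box_df(1, "gold_box_id")
    grow <- sample(1:5, 2, replace = TRUE)
    p <- box(max(0, g$x_min - grow[1]), max(0, g$y_min - grow[2]),
             g$width + grow[1] + sample(0:3, 1), g$height + grow[2] + sample(0:3, 1))
    prf <- precision_recall_f1(p, box(g$x_min, g$y_min, g$width, g$height))
    expect_equal(prf[["recall"]], 1)
    expect_lt(prf[["precision"]], 1)
  }
})

test_that("scores are invariant to uniform rescaling of all coordinates", {
  set.seed(43)
  for (k in c(0.5, 3, 17.5)) {
    p <- random_box_df(1, "box_id"); g <- random_box_df(1, "gold_box_id")
    a <- precision_recall_f1(box(p$x_min, p$y_min, p$width, p$height),
                             box(g$x_min, g$y_min, g$width, g$height))
    b <- precision_recall_f1(box(k * p$x_min, k * p$y_min, k * p$width, k * p$height),
                             box(k * g$x_min, k * g$y_min, k * g$width, k * g$height))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("match_boxes applies argmax assignment and the conflict zeroing rule", {
  g <- data.frame(gold_box_id = 1, x_min = 0, y_min = 0, width = 10, height = 10)
  # unique matching keeps the pair's scores
  one <- match_boxes(data.frame(box_id = 1, x_min = 2, y_min = 2, width = 10, height = 10), g)
  expect_equal(one$f1, oracle_prf(list(x_min = 2, y_min = 2, width = 10, height = 10),
                                  list(x_min = 0, y_min = 0, width = 10, height = 10))[["f1"]])
  expect_false(one$zeroed)
  # two claimants of the same gold box: the lower-F1 one is zeroed, not re-matched
  p <- data.frame(box_id = 1:2, x_min = 0, y_min = 0, width = c(10, 20), height = 10)
  m <- match_boxes(p, g)
  expect_equal(m$f1, c(1, 0))
  expect_equal(m$precision, c(1, 0))
  expect_equal(m$zeroed, c(FALSE, TRUE))
  # disjoint from every gold box: matched with zero scores, not an error
  far <- match_boxes(data.frame(box_id = 1, x_min = 50, y_min = 50, width = 5, height = 5), g)
  expect_equal(far$f1, 0)
  # empty participant set is allowed, empty gold set is not
  expect_equal(nrow(match_boxes(data.frame(box_id = integer(), x_min = numeric(),
                                           y_min = numeric(), width = numeric(),
                                           height = numeric()), g)), 0)
  expect_error(match_boxes(p, g[0, ]), "no gold")
})

test_that("match_boxes agrees with the literal brute-force rule on random instances", {
  set.seed(7)
  for (i in 1:300) {
    part <- random_box_df(sample(1:4, 1), "box_id")
    gold <- random_box_df(sample(1:4, 1), "gold_box_id")
    got <- match_boxes(part, gold)
    want <- oracle_match(part, gold)
    expect_equal(got$gold_box_id, want$gold_box_id)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$zeroed, want$zeroed)
    expect_true(all(got$f1 >= 0 & got$f1 <= 1))
    expect_true(all(got$precision >= 0 & got$precision <= 1 &
                    got$recall >= 0 & got$recall <= 1))
  }
})

test_that("degenerate participant boxes are zero-scored with a warning, not fatal", {
  g <- data.frame(gold_box_id = 1, x_min = 0, y_min = 0, width = 10, height = 10)
  p <- data.frame(box_id = 1:2, x_min = 0, y_min = 0, width = c(10, 0), height = 10)
  expect_warning(m <- match_boxes(p, g), "degenerate")
  expect_equal(m$f1, c(1, 0))
})

test_that("f_mean averages F1 values with zeroed boxes included", {
  expect_equal(f_mean(data.frame(f1 = 1)), 1)
  expect_equal(f_mean(data.frame(f1 = c(1, 0.5))), 0.75)
  g <- data.frame(gold_box_id = 1, x_min = 0, y_min = 0, width = 10, height = 10)
  p <- data.frame(box_id = 1:2, x_min = 0, y_min = 0, width = c(20, 10), height = 10)
  m <- match_boxes(p, g)  # the 2/3 box is zeroed because the exact box wins
  expect_equal(f_mean(m), 1 / 2)
  expect_error(f_mean(data.frame(f1 = numeric())), ">= 1 box")
})

test_that("score_dataset scores every participant-image pair and keeps box rows", {
  gold <- data.frame(image_id = rep(c("a", "b"), each = 1), gold_box_id = 1,
                     x_min = 0, y_min = 0, width = 10, height = 10,
                     difficulty = "easy")
  ann <- expand.grid(participant_id = c("p1", "p2"), image_id = c("a", "b"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(ann, group = "master", question_index = 1, box_id = 1,
                    x_min = 0, y_min = 0, width = 10, height = 10,
                    time_seconds = 5)
  sc <- score_dataset(ann, gold)
  expect_s3_class(sc, "crowd_scores")
  expect_equal(nrow(sc$image_scores), 4)
  expect_equal(sc$image_scores$f_mean, rep(1, 4))
  expect_equal(nrow(sc$box_scores), 4)
  # empty annotation table -> empty score table
  empty <- score_dataset(ann[0, ], gold)
  expect_equal(nrow(empty$image_scores), 0)
  # unknown image ids are reported
  bad <- ann; bad$image_id[1] <- "zz"
  expect_error(score_dataset(bad, gold), "zz")
})

test_that("score_dataset matches a straight-line reimplementation on a jittered cohort", {
  coh <- generate_cohort(tiny_cohort_config(seed = 5))
  sc <- score_dataset(coh$annotations, coh$gold)
  expect_equal(nrow(sc$image_scores), 9 * 10)
  expect_true(all(sc$image_scores$f_mean >= 0 & sc$image_scores$f_mean <= 1))
  # recompute a handful of pairs independently
  set.seed(9)
  pick <- sample(nrow(sc$image_scores), 10)
  for (k in pick) {
    row <- sc$image_scores[k, ]
    a <- coh$annotations[coh$annotations$participant_id == row$participant_id &
                         coh$annotations$image_id == row$image_id, ]
    g <- coh$gold[coh$gold$image_id == row$image_id, ]
    expect_equal(row$f_mean, mean(oracle_match(a, g)$f1), tolerance = 1e-12)
    expect_equal(row$n_boxes, nrow(a))
  }
})
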