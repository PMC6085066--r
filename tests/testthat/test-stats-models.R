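make_times <- function(fatigue, groups = c("master", "master", "credit", "credit"),
                       noise_sd = 0, n_q = 30, seed = 1) {
  g <- data.frame(gold_box_id = 1, x_min = 10, y_min = 10, width = 20, height = 20)
  rows <- list()
  for (p in seq_along(groups)) {
    prof <- annotator_profile(paste0("p", p), groups[p], fatigue_rate = fatigue,
                              time_noise_sd = noise_sd, jitter_sd = 0,
                              miss_rate = 0, spurious_rate = 0,
                              base_log_time = log(20) + 0.1 * p)
    for (q in seq_len(n_q)) {
      sim <- simulate_annotation(prof, g, q, seed = seed + q * 100 + p)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = paste0("p", p), group = groups[p],
        image_id = sprintf("img%02d", q), question_index = q, box_id = 1,
        x_min = 0, y_min = 0, width = 1, height = 1,
        time_seconds = sim$time_seconds)
    }
  }
  do.call(rbind, rows)
}

test_that("noise-free fatigue times recover exp(slope) equal to the decay factor", {
  tm <- suppressWarnings(fit_time_model(make_times(0.99)))
  expect_equal(tm$slopes$exp_estimate, rep(0.99, 2), tolerance = 1e-3)
  expect_equal(tm$meta$log_base, "natural")
})

test_that("constant times give a zero slope and unit multiplicative factor", {
  ann <- make_times(1.0)
  tm <- suppressWarnings(fit_time_model(ann))
  expect_equal(tm$slopes$estimate, rep(0, 2), tolerance = 1e-6)
  expect_equal(tm$slopes$exp_estimate, rep(1, 2), tolerance = 1e-6)
})

test_that("nonpositive times are dropped with a warning, not modelled", {
  ann <- make_times(0.99, noise_sd = 0.1)
  ann$time_seconds[3] <- 0
  expect_warning(tm <- suppressMessages(fit_time_model(ann)), "non-positive")
  expect_equal(nrow(tm$slopes), 2)
})

test_that("equal decay in all groups leaves interaction contrasts non-significant", {
  hits <- 0L
  for (s in 1:8) {
    ann <- make_times(0.99, groups = c("master", "master", "credit", "credit"),
                      noise_sd = 0.3, seed = 7000 * s)
    tm <- suppressWarnings(fit_time_model(ann))
    hits <- hits + any(tm$interaction_contrasts$p < 0.05)
  }
  expect_lte(hits, 2)
})

test_that("group F_mean model recovers a configured group gap on one cohort", {
  set.seed(101)
  sc <- simulate_score_table(n_per_group = 6, n_images = 30,
                             group_means = c(master = 0.80, nonmaster = 0.81,
                                             credit = 0.70))
  fm <- fit_fmean_model(sc)
  mc <- fm$contrasts[fm$contrasts$contrast == "master - credit", ]
  expect_lt(abs(mc$estimate - 0.10), 2.5 * mc$se)
  expect_lt(fm$omnibus$p, 0.05)
  # reference ordering: master first
  expect_equal(fm$contrasts$contrast[1], "master - nonmaster")
})

test_that("balanced duplication of participants leaves fixed effects unchanged", {
  set.seed(202)
  sc <- simulate_score_table(n_per_group = 4, n_images = 15)
  dup <- sc
  dup$participant_id <- paste0(dup$participant_id, "_copy")
  both <- rbind(sc, dup)
  f1 <- fit_fmean_model(sc)
  f2 <- fit_fmean_model(both)
  expect_equal(f1$contrasts$estimate, f2$contrasts$estimate, tolerance = 1e-6)
})

test_that("deficient designs are rejected with the component named", {
  set.seed(303)
  sc <- simulate_score_table(n_per_group = 3, n_images = 10)
  expect_error(fit_fmean_model(sc[sc$group == "master", ]), ">= 2 groups")
  one_img <- sc[sc$image_id == "img01", ]
  expect_error(fit_fmean_model(one_img), ">= 2 images")
  solo <- sc[sc$participant_id != "master1", ]
  solo <- solo[!(solo$participant_id %in% c("master2")), ]
  expect_error(fit_fmean_model(solo), ">= 2 participants")
})

test_that("BLUPs identify a planted easy image and shrink toward zero", {
  for (s in 1:3) {
    set.seed(400 + s)
    sc <- simulate_score_table(n_per_group = 4, n_images = 12)
    sc$f_mean <- sc$f_mean + 0.2 * (sc$image_id == "img07")
    fm <- fit_fmean_model(sc)
    bl <- extract_blups(fm, "image")
    expect_equal(bl$id[which.max(bl$blup)], "img07")
    expect_lt(abs(mean(bl$blup)), 0.02)
    # shrinkage: BLUP spread no larger than raw per-image mean spread
    raw <- tapply(sc$f_mean, sc$image_id, mean)
    expect_lte(stats::var(bl$blup), stats::var(as.numeric(raw)))
    # shrinkage preserves the raw-mean ordering in this balanced design
    expect_equal(order(bl$blup[match(names(raw), bl$id)]), order(as.numeric(raw)))
  }
  expect_error(extract_blups(list(blups = list(image = NULL)), "image"),
               "no random effect")
})

test_that("regressing one BLUP set on another reproduces exact linear structure", {
  tb <- data.frame(id = sprintf("img%02d", 1:10), blup = seq(-0.5, 0.5, length.out = 10))
  fb <- tb; fb$blup <- 2 * tb$blup
  r <- suppressWarnings(regress_blups(tb, fb))  # exact fit warns about summary
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$adj_r_squared, 1, tolerance = 1e-9)
  expect_error(regress_blups(tb[1:2, ], fb[1:2, ]), ">= 3 images")
  # independent BLUPs: slope centred on zero
  set.seed(11)
  slopes <- replicate(60, {
    a <- data.frame(id = 1:20, blup = rnorm(20))
    b <- data.frame(id = 1:20, blup = rnorm(20))
    regress_blups(a, b)$slope
  })
  expect_lt(abs(mean(slopes)), 0.08)
})

test_that("time-accuracy correlation reports raw and residual versions per group", {
  set.seed(55)
  sc <- simulate_score_table(n_per_group = 4, n_images = 15)
  # accuracy independent of time by construction
  ta <- time_accuracy_correlation(sc)
  expect_setequal(unique(ta$version), c("raw", "residual"))
  expect_true(all(abs(ta$estimate) < 0.35))
  # perfect monotone coupling, noise-free
  sc2 <- sc
  sc2$f_mean <- 0.1 * log(sc2$time_seconds) + 0.4
  ta2 <- time_accuracy_correlation(sc2)
  expect_equal(ta2$estimate[ta2$version == "raw"], rep(1, 3), tolerance = 1e-9)
  expect_error(time_accuracy_correlation(sc[sc$time_seconds < 0, ]), "no participant-image rows")
})

test_that("a simulated slow-but-careful cohort shows a positive residual correlation", {
  pos <- 0L
  for (s in 1:5) {
    coh <- generate_cohort(tiny_cohort_config(seed = 800 + s,
                                              time_accuracy_coupling = 0.05))
    sc <- score_dataset(coh$annotations, coh$gold)
    ta <- time_accuracy_correlation(sc)
    pos <- pos + all(ta$estimate[ta$version == "residual"] > 0)
  }
  expect_gte(pos, 4)
})

test_that("classifier performance F-test behaves at its extremes", {
  perf <- data.frame(participant_id = paste0("p", 1:9),
                     group = rep(c("master", "nonmaster", "credit"), each = 3),
                     performance = 0.88)
  eq <- anova_classifier_performance(perf)
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  # one group shifted by five standard deviations
  set.seed(66)
  perf2 <- perf
  perf2$performance <- rnorm(9, 0.88, 0.01)
  perf2$performance[perf2$group == "credit"] <-
    rnorm(3, 0.88 + 5 * 0.01, 0.01)
  expect_lt(anova_classifier_performance(perf2)$p, 0.001)
  expect_error(anova_classifier_performance(perf[perf$group == "master", ]),
               ">= 2 groups")
  expect_error(anova_classifier_performance(perf[c(1, 4:9), ]), ">= 2 participants")
})
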