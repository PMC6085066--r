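#' Generative profile of a simulated crowd annotator
#'
#' Collects the parameters that govern how a simulated worker draws boxes and
#' how long they take. Workers tend to draw boxes that enclose the gold
#' standard box ("to make sure the whole tassel is covered"), which the model
#' expresses as a multiplicative dilation of the gold extents; jitter
#' perturbs the box centre; misses and spurious boxes are Bernoulli/Poisson
#' events; completion times are lognormal with a multiplicative per-question
#' fatigue factor.
#'
#' For a centred enclosing box dilated by factor `d` in both dimensions,
#' precision is `1/d^2`, recall is 1 and therefore `F1 = 2/(1 + d^2)`. The
#' simulator uses this closed form to translate a target F1 into a dilation,
#' which makes additive accuracy drift exact on the F scale (before jitter).
#'
#' @param participant_id Identifier.
#' @param group Group label, one of `"master"`, `"nonmaster"`, `"credit"`.
#' @param dilation_bias Box enlargement factor (>= 1).
#' @param jitter_sd Centre jitter, pixels.
#' @param miss_rate Probability of skipping a tassel.
#' @param spurious_rate Expected spurious boxes per image (Poisson mean).
#' @param base_log_time Intercept of log completion time (log seconds).
#' @param fatigue_rate Multiplicative per-question time factor (about 0.99:
#'   each successive question takes about 1% less time).
#' @param accuracy_drift Additive per-question drift in target F1 (<= 0,
#'   magnitude around 1e-3).
#' @param time_noise_sd Residual sd of log time.
#' @param skill_sd The participant-level sd this profile was drawn with
#'   (bookkeeping; 0 for hand-built profiles).
#' @return A list of class `annotator_profile`.
#' @export
annotator_profile <- function(participant_id, group = "master",
                              dilation_bias = 1.2, jitter_sd = 1.5,
                              miss_rate = 0.03, spurious_rate = 0.15,
                              base_log_time = log(27), fatigue_rate = 0.99,
                              accuracy_drift = -3e-4, time_noise_sd = 0.45,
                              skill_sd = 0) {
  if (dilation_bias < 1) { warning("dilation_bias < 1 clamped to 1"); dilation_bias <- 1 }
  miss_rate <- min(max(miss_rate, 0), 1)
  spurious_rate <- max(spurious_rate, 0)
  if (fatigue_rate <= 0) { warning("fatigue_rate <= 0 clamped to 0.5"); fatigue_rate <- 0.5 }
  structure(list(participant_id = participant_id, group = group,
                 dilation_bias = dilation_bias, jitter_sd = jitter_sd,
                 miss_rate = miss_rate, spurious_rate = spurious_rate,
                 base_log_time = base_log_time, fatigue_rate = fatigue_rate,
                 accuracy_drift = accuracy_drift, time_noise_sd = time_noise_sd,
                 skill_sd = skill_sd),
            class = "annotator_profile")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# place a (w x h) box with centre (cx, cy) inside a W x H frame
place_box <- function(cx, cy, w, h, W, H) {
  w <- min(w, W); h <- min(h, H)
  x <- clamp(cx - w / 2, 0, W - w)
  y <- clamp(cy - h / 2, 0, H - h)
  c(x_min = x, y_min = y, width = w, height = h)
}

#' Simulate one participant annotating one image
#'
#' For each gold box that is not missed, emits a participant box whose centre
#' is jittered by `jitter_sd` and whose extents are dilated towards the
#' profile's target F1 (adjusted by per-question accuracy drift and the image
#' shift `f_shift`). Adds `Poisson(spurious_rate)` spurious boxes placed
#' uniformly. At least one box is always emitted (the task required at least
#' one box per image): when everything would be missed, one gold box is
#' annotated anyway. Completion time is lognormal:
#' `exp(base_log_time + log(fatigue_rate) * (question_index - 1) +
#' time_shift + noise)`.
#'
#' @param profile An [annotator_profile()].
#' @param gold Gold boxes for the image (data.frame or list of [box()]).
#' @param question_index 1-based position of this image in the participant's
#'   (randomised) ordering.
#' @param seed Integer seed for this call.
#' @param image_width,image_height Frame bounds for box placement.
#' @param f_shift Additive image-level shift on the target F1 scale.
#' @param time_shift Additive image-level shift on the log-time scale.
#' @return A list with `boxes` (data.frame `box_id`, `x_min`, `y_min`,
#'   `width`, `height`) and `time_seconds`.
#' @export
simulate_annotation <- function(profile, gold, question_index, seed,
                                image_width = 256, image_height = 256,
                                f_shift = 0, time_shift = 0) {
  stopifnot(inherits(profile, "annotator_profile"))
  gold <- boxes_to_df(gold, "gold_box_id")
  if (nrow(gold) == 0L) stop("simulate_annotation needs >= 1 gold box")
  set.seed(seed)

  f_base <- 2 / (1 + profile$dilation_bias^2)
  f_target <- clamp(f_base + profile$accuracy_drift * (question_index - 1) + f_shift,
                    0.05, 1)
  d <- sqrt(2 / f_target - 1)

  hit <- stats::runif(nrow(gold)) >= profile$miss_rate
  if (!any(hit)) hit[sample.int(nrow(gold), 1)] <- TRUE   # >= 1 box per image

  rows <- list()
  for (i in which(hit)) {
    cx <- gold$x_min[i] + gold$width[i] / 2 + stats::rnorm(1, 0, profile$jitter_sd)
    cy <- gold$y_min[i] + gold$height[i] / 2 + stats::rnorm(1, 0, profile$jitter_sd)
    rows[[length(rows) + 1L]] <-
      place_box(cx, cy, gold$width[i] * d, gold$height[i] * d,
                image_width, image_height)
  }
  n_sp <- stats::rpois(1, profile$spurious_rate)
  for (s in seq_len(n_sp)) {
    tmpl <- gold[sample.int(nrow(gold), 1), ]
    w <- tmpl$width * stats::runif(1, 0.7, 1.3)
    h <- tmpl$height * stats::runif(1, 0.7, 1.3)
    rows[[length(rows) + 1L]] <-
      place_box(stats::runif(1, 0, image_width), stats::runif(1, 0, image_height),
                w, h, image_width, image_height)
  }
  boxes <- as.data.frame(do.call(rbind, rows))
  boxes <- data.frame(box_id = seq_len(nrow(boxes)),
                      round(boxes[c("x_min", "y_min", "width", "height")], 2))

  lt <- profile$base_log_time +
    log(profile$fatigue_rate) * (question_index - 1) + time_shift +
    stats::rnorm(1, 0, profile$time_noise_sd)
  list(boxes = boxes, time_seconds = round(exp(lt), 3))
}

#' Configuration of a simulated annotation cohort
#'
#' Defaults mirror the structure of the crowdsourcing study the package
#' models: three groups (49 Master MTurk workers, 51 non-Master MTurk
#' workers, 26 course-credit students who completed the task), 80 images half
#' of which are "hard", group mean-F targets separated by 0.10 between the
#' course-credit and MTurk groups, per-group fatigue factors near 0.99, and
#' group log-time intercepts set to the log of each group's median completion
#' time. A single global `seed` fans out into per-image and per-participant
#' substreams, so cohorts are reproducible while streams stay independent.
#'
#' @param group_sizes Named integer vector of participants per group.
#' @param n_images Number of images each participant annotates.
#' @param image_width,image_height Scene dimensions, pixels.
#' @param n_tassels_easy,n_tassels_hard Foreground tassels per scene.
#' @param prop_hard Fraction of hard images.
#' @param group_f_targets Named group mean F1 targets.
#' @param fatigue_factors Named per-group multiplicative time decay per question.
#' @param accuracy_drift Named per-group additive F drift per question.
#' @param group_median_times Named group median completion times, seconds.
#' @param skill_sd Participant-level sd of the F target.
#' @param image_f_sd Image-level sd of the F target.
#' @param time_participant_sd,time_image_sd,time_noise_sd Log-time variance
#'   components (participant, image, residual).
#' @param jitter_sd,miss_rate,spurious_rate Annotator noise parameters
#'   shared across groups.
#' @param time_accuracy_coupling Additive shift of target F per residual
#'   log-time sd: positive values make slower answers slightly more accurate.
#' @param seed Global seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(master = 49, nonmaster = 51, credit = 26),
                          n_images = 80,
                          image_width = 256, image_height = 256,
                          n_tassels_easy = 4, n_tassels_hard = 8,
                          prop_hard = 0.5,
                          group_f_targets = c(master = 0.80, nonmaster = 0.81, credit = 0.70),
                          fatigue_factors = c(master = 0.9896, nonmaster = 0.9893, credit = 0.9883),
                          accuracy_drift = c(master = -8e-5, nonmaster = -2.7e-4, credit = -9.5e-4),
                          group_median_times = c(master = 30.02, nonmaster = 29.40, credit = 16.86),
                          skill_sd = 0.05, image_f_sd = 0.04,
                          time_participant_sd = 0.35, time_image_sd = 0.25,
                          time_noise_sd = 0.45,
                          jitter_sd = 1.5, miss_rate = 0.03, spurious_rate = 0.15,
                          time_accuracy_coupling = 0.02,
                          seed = 1) {
  groups <- names(group_sizes)
  stopifnot(!is.null(groups), length(groups) >= 1,
            all(groups %in% names(group_f_targets)),
            all(groups %in% names(fatigue_factors)),
            all(groups %in% names(accuracy_drift)),
            all(groups %in% names(group_median_times)),
            n_images >= 1, all(group_sizes >= 1))
  structure(list(group_sizes = group_sizes, n_images = n_images,
                 image_width = image_width, image_height = image_height,
                 n_tassels_easy = n_tassels_easy, n_tassels_hard = n_tassels_hard,
                 prop_hard = prop_hard,
                 group_f_targets = group_f_targets,
                 fatigue_factors = fatigue_factors,
                 accuracy_drift = accuracy_drift,
                 group_median_times = group_median_times,
                 skill_sd = skill_sd, image_f_sd = image_f_sd,
                 time_participant_sd = time_participant_sd,
                 time_image_sd = time_image_sd, time_noise_sd = time_noise_sd,
                 jitter_sd = jitter_sd, miss_rate = miss_rate,
                 spurious_rate = spurious_rate,
                 time_accuracy_coupling = time_accuracy_coupling,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a full synthetic annotation cohort
#'
#' Renders the scenes, derives gold-standard minimum bounding boxes from the
#' tassel masks, draws per-participant annotator profiles from the group
#' parameters, and simulates every participant annotating every image in an
#' independently randomised order. Identical configurations and seeds yield
#' identical outputs.
#'
#' @param config A [cohort_config()].
#' @return A list of class `crowd_cohort` with elements `images` (named list
#'   of grayscale matrices), `gold` (gold table, one row per gold box, with
#'   `difficulty`), `annotations` (annotation table, one row per drawn box),
#'   `profiles` (list of [annotator_profile()]s), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_img <- config$n_images
  image_ids <- sprintf("img%03d", seq_len(n_img))
  n_hard <- round(config$prop_hard * n_img)
  difficulty <- sample(c(rep("hard", n_hard), rep("easy", n_img - n_hard)))
  scene_seeds <- sample.int(2^31 - 2, n_img)
  f_img <- stats::rnorm(n_img, 0, config$image_f_sd)
  t_img <- stats::rnorm(n_img, 0, config$time_image_sd)

  images <- stats::setNames(vector("list", n_img), image_ids)
  gold_rows <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    nt <- if (difficulty[i] == "hard") config$n_tassels_hard else config$n_tassels_easy
    sc <- generate_scene(scene_spec(config$image_width, config$image_height,
                                    n_tassels = nt, difficulty = difficulty[i]),
                         seed = scene_seeds[i])
    images[[i]] <- sc$image
    bbs <- lapply(sc$masks, min_bounding_box)
    gold_rows[[i]] <- data.frame(image_id = image_ids[i],
                                 gold_box_id = seq_along(bbs),
                                 do.call(rbind, lapply(bbs, unclass)),
                                 difficulty = difficulty[i])
  }
  gold <- do.call(rbind, gold_rows)
  rownames(gold) <- NULL

  groups <- names(config$group_sizes)
  set.seed(config$seed + 1L)
  profiles <- list()
  for (g in groups) {
    for (k in seq_len(config$group_sizes[[g]])) {
      f_p <- clamp(config$group_f_targets[[g]] + stats::rnorm(1, 0, config$skill_sd),
                   0.2, 0.98)
      profiles[[length(profiles) + 1L]] <- annotator_profile(
        participant_id = sprintf("%s%03d", g, k), group = g,
        dilation_bias = sqrt(2 / f_p - 1),
        jitter_sd = config$jitter_sd, miss_rate = config$miss_rate,
        spurious_rate = config$spurious_rate,
        base_log_time = log(config$group_median_times[[g]]) +
          stats::rnorm(1, 0, config$time_participant_sd),
        fatigue_rate = config$fatigue_factors[[g]],
        accuracy_drift = config$accuracy_drift[[g]],
        time_noise_sd = 0,                       # residual drawn here, see below
        skill_sd = config$skill_sd)
    }
  }
  part_seeds <- sample.int(2^28, length(profiles))

  gold_by_image <- split(gold, gold$image_id)
  ann <- vector("list", length(profiles) * n_img)
  k <- 0L
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    set.seed(part_seeds[p])
    ord <- sample.int(n_img)                       # this participant's image order
    z <- stats::rnorm(n_img, 0, config$time_noise_sd)
    call_seeds <- sample.int(2^28, n_img)
    for (q in seq_len(n_img)) {
      i <- ord[q]
      zstd <- if (config$time_noise_sd > 0) z[q] / config$time_noise_sd else 0
      sim <- simulate_annotation(
        prof, gold_by_image[[image_ids[i]]], question_index = q,
        seed = call_seeds[q],
        image_width = config$image_width, image_height = config$image_height,
        f_shift = f_img[i] + config$time_accuracy_coupling * zstd,
        time_shift = t_img[i] + z[q])
      k <- k + 1L
      ann[[k]] <- data.frame(participant_id = prof$participant_id,
                             group = prof$group,
                             image_id = image_ids[i],
                             question_index = q,
                             sim$boxes,
                             time_seconds = sim$time_seconds)
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  structure(list(images = images, gold = gold, annotations = annotations,
                 profiles = profiles, config = config),
            class = "crowd_cohort")
}

#' @export
print.crowd_cohort <- function(x, ...) {
  cat("crowd_cohort:", length(x$profiles), "participants x",
      x$config$n_images, "images;", nrow(x$annotations), "boxes drawn\n")
  invisible(x)
}
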