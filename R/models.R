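GROUP_LEVELS <- c("master", "nonmaster", "credit")

group_factor <- function(g) {
  lev <- intersect(GROUP_LEVELS, unique(g))
  if (!length(lev)) lev <- sort(unique(g))      # non-canonical labels: alphabetical
  factor(g, levels = c(lev, setdiff(sort(unique(g)), lev)))
}

check_design <- function(df) {
  tab <- table(unique(df[c("participant_id", "group")])$group)
  tab <- tab[tab > 0]
  if (length(tab) < 2)
    stop("deficient design: need >= 2 groups, got ", length(tab))
  if (any(tab < 2))
    stop("deficient design: every group needs >= 2 participants; ",
         paste(names(tab)[tab < 2], collapse = ", "), " has fewer")
  if (length(unique(df$image_id)) < 2)
    stop("deficient design: need >= 2 images to separate the image random effect")
  invisible()
}

blup_table <- function(re, effect) {
  data.frame(id = rownames(re), blup = re[, "(Intercept)"], row.names = NULL,
             effect = effect, stringsAsFactors = FALSE)
}

#' Mixed-model comparison of annotation accuracy among groups
#'
#' Fits the linear mixed-effects model
#' `F_mean ~ group + (1 | participant) + (1 | image)` by REML, with the
#' Master-MTurk group as the reference level. Participants are nested within
#' groups (each participant id belongs to exactly one group, so the plain
#' participant intercept is the nested effect). Returns the omnibus group
#' F-test, all three pairwise group contrasts (unadjusted, as in the study's
#' presentation), variance components, and per-image / per-participant BLUPs.
#' Degrees of freedom use the Satterthwaite approximation.
#'
#' @param scores A `crowd_scores` object or the `image_scores` data.frame
#'   (columns `participant_id`, `group`, `image_id`, `f_mean`).
#' @return A list of class `fmean_fit`: `model`, `omnibus`
#'   (`F`, `df1`, `df2`, `p`), `contrasts` (estimate/SE/df/p per group pair),
#'   `varcomp`, `blups` (list with `image` and `participant` tables), and
#'   `meta` (df method).
#' @export
fit_fmean_model <- function(scores) {
  df <- if (inherits(scores, "crowd_scores")) scores$image_scores else scores
  stopifnot(all(c("participant_id", "group", "image_id", "f_mean") %in% names(df)))
  check_design(df)
  df$group <- group_factor(df$group)
  fit <- lmerTest::lmer(f_mean ~ group + (1 | participant_id) + (1 | image_id),
                        data = df, REML = TRUE)
  aov <- stats::anova(fit)  # Satterthwaite type III
  em <- emmeans::emmeans(fit, ~group, lmer.df = "satterthwaite")
  ctr <- as.data.frame(summary(emmeans::contrast(em, "pairwise", adjust = "none"),
                               infer = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)
  list(model = fit,
       omnibus = list(F = aov[["F value"]][1], df1 = aov[["NumDF"]][1],
                      df2 = aov[["DenDF"]][1], p = aov[["Pr(>F)"]][1]),
       contrasts = data.frame(contrast = ctr$contrast, estimate = ctr$estimate,
                              se = ctr$SE, df = ctr$df, p = ctr$p.value),
       varcomp = vc[c("grp", "var1", "vcov", "sdcor")],
       blups = list(image = blup_table(re$image_id, "image"),
                    participant = blup_table(re$participant_id, "participant")),
       meta = list(df_method = "satterthwaite", reml = TRUE)) |>
    structure(class = "fmean_fit")
}

#' Mixed-model fatigue regression on log completion time
#'
#' Fits `log(time) ~ group * question_index + (1 | participant) + (1 | image)`
#' by REML, where `question_index` enters centred at the first question
#' (index - 1) so intercepts are first-question log times. Reports per-group
#' slopes on the log scale together with their exponential (the per-question
#' multiplicative time factor: exp(slope) near 0.99 means each successive
#' question takes about 1% less time), and the pairwise interaction
#' contrasts between group slopes. Rows with non-positive times are dropped
#' with a warning.
#'
#' @param annotations Canonical annotation table (per-box rows; times are
#'   per participant-image and are deduplicated internally), or a
#'   per-image data.frame with columns `participant_id`, `group`,
#'   `image_id`, `question_index`, `time_seconds`.
#' @return A list of class `time_fit`: `model`, `slopes` (per group:
#'   estimate, exp_estimate, SE, df, p), `interaction_contrasts`, `varcomp`,
#'   `blups`, `meta`.
#' @export
fit_time_model <- function(annotations) {
  need <- c("participant_id", "group", "image_id", "question_index", "time_seconds")
  stopifnot(all(need %in% names(annotations)))
  df <- unique(annotations[need])
  bad <- !(df$time_seconds > 0)
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with non-positive completion time")
    df <- df[!bad, ]
  }
  check_design(df)
  df$group <- group_factor(df$group)
  df$qidx <- df$question_index - 1
  df$log_time <- log(df$time_seconds)
  fit <- lmerTest::lmer(log_time ~ group * qidx + (1 | participant_id) + (1 | image_id),
                        data = df, REML = TRUE)
  tr <- emmeans::emtrends(fit, ~group, var = "qidx", lmer.df = "satterthwaite")
  sl <- as.data.frame(summary(tr, infer = TRUE))
  ic <- as.data.frame(summary(emmeans::contrast(tr, "pairwise", adjust = "none"),
                              infer = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)
  list(model = fit,
       slopes = data.frame(group = sl$group, estimate = sl$qidx.trend,
                           exp_estimate = exp(sl$qidx.trend), se = sl$SE,
                           df = sl$df, p = sl$p.value),
       interaction_contrasts = data.frame(contrast = ic$contrast,
                                          estimate = ic$estimate, se = ic$SE,
                                          df = ic$df, p = ic$p.value),
       varcomp = vc[c("grp", "var1", "vcov", "sdcor")],
       blups = list(image = blup_table(re$image_id, "image"),
                    participant = blup_table(re$participant_id, "participant")),
       meta = list(df_method = "satterthwaite", reml = TRUE,
                   log_base = "natural")) |>
    structure(class = "time_fit")
}

#' Extract BLUPs of a random effect from a fitted model
#'
#' Best linear unbiased predictors (conditional modes) of the requested
#' random effect — one shrunken prediction per image or per participant.
#' Their mean is approximately zero.
#'
#' @param fit An `fmean_fit` or `time_fit`.
#' @param effect `"image"` or `"participant"`.
#' @return A data.frame with columns `id` and `blup`.
#' @export
extract_blups <- function(fit, effect = c("image", "participant")) {
  effect <- match.arg(effect)
  if (!is.list(fit) || is.null(fit$blups))
    stop("`fit` must be a fitted crowdbox model object")
  if (is.null(fit$blups[[effect]]))
    stop("fit has no random effect named '", effect, "'")
  fit$blups[[effect]][c("id", "blup")]
}

#' Regress accuracy BLUPs on time BLUPs across images
#'
#' Ordinary least squares of the per-image accuracy (F_mean) BLUPs on the
#' per-image log-time BLUPs: a positive slope means images that take longer
#' also tend to be annotated more accurately.
#'
#' @param time_blups,fmean_blups Data.frames with columns `id`, `blup`
#'   covering the same image ids (from [extract_blups()]).
#' @return A list with `slope`, `se`, `p`, `adj_r_squared`, `n`, and the
#'   underlying `lm` fit.
#' @export
regress_blups <- function(time_blups, fmean_blups) {
  m <- merge(time_blups, fmean_blups, by = "id", suffixes = c("_time", "_fmean"))
  if (nrow(m) < 3) stop("need >= 3 images with BLUPs in both models, got ", nrow(m))
  fit <- stats::lm(blup_fmean ~ blup_time, data = m)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       se = s$coefficients[2, "Std. Error"],
       p = s$coefficients[2, "Pr(>|t|)"],
       adj_r_squared = s$adj.r.squared,
       n = nrow(m), fit = fit)
}

#' Within-group association between completion time and accuracy
#'
#' For each group, correlates log completion time with F_mean across
#' participant-image pairs. Two versions are reported side by side: `raw`
#' (plain Pearson correlation) and `residual` (correlation after removing
#' participant and image means from both variables, i.e. the within-cell
#' association not explained by who annotated or which image it was).
#'
#' @param scores A `crowd_scores` object or its `image_scores` table (must
#'   carry `time_seconds`; [score_dataset()] propagates it).
#' @return A data.frame with one row per group x version: `group`, `version`,
#'   `estimate`, `p`, `n`.
#' @export
time_accuracy_correlation <- function(scores) {
  df <- if (inherits(scores, "crowd_scores")) scores$image_scores else scores
  need <- c("participant_id", "group", "image_id", "f_mean", "time_seconds")
  stopifnot(all(need %in% names(df)))
  df <- df[df$time_seconds > 0, ]
  if (nrow(df) == 0L) stop("no participant-image rows with positive times to correlate")
  df$log_time <- log(df$time_seconds)
  out <- list()
  for (g in unique(df$group)) {
    d <- df[df$group == g, ]
    ct_raw <- stats::cor.test(d$log_time, d$f_mean)
    rt <- stats::resid(stats::lm(log_time ~ factor(participant_id) + factor(image_id), d))
    rf <- stats::resid(stats::lm(f_mean ~ factor(participant_id) + factor(image_id), d))
    ct_res <- if (stats::sd(rt) > 0 && stats::sd(rf) > 0)
      stats::cor.test(rt, rf) else list(estimate = NA_real_, p.value = NA_real_)
    out[[g]] <- data.frame(group = g,
                           version = c("raw", "residual"),
                           estimate = c(unname(ct_raw$estimate),
                                        unname(ct_res$estimate)),
                           p = c(ct_raw$p.value, ct_res$p.value),
                           n = nrow(d))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way F-test on per-participant classifier performances
#'
#' Fixed-effects linear model `performance ~ group` with its omnibus F-test:
#' one performance value per participant, testing whether classifiers trained
#' from different groups' annotations perform differently on average.
#'
#' @param perf Data.frame with columns `participant_id`, `group`,
#'   `performance` (one row per participant).
#' @return A list with `F`, `df1`, `df2`, `p`, `group_means`, and the `lm` fit.
#' @export
anova_classifier_performance <- function(perf) {
  stopifnot(all(c("participant_id", "group", "performance") %in% names(perf)))
  tab <- table(perf$group)
  tab <- tab[tab > 0]
  if (length(tab) < 2)
    stop("need >= 2 groups for the F-test, got ", length(tab))
  if (any(tab < 2))
    stop("every group needs >= 2 participants; ",
         paste(names(tab)[tab < 2], collapse = ", "), " has fewer")
  perf$group <- group_factor(perf$group)
  fit <- stats::lm(performance ~ group, data = perf)
  av <- suppressWarnings(stats::anova(fit))  # degenerate perfect fits handled below
  Fval <- av[["F value"]][1]
  pval <- av[["Pr(>F)"]][1]
  if (stats::var(perf$performance) < 1e-20) { Fval <- 0; pval <- 1 }  # constant response
  list(F = Fval, df1 = av[["Df"]][1], df2 = av[["Df"]][2], p = pval,
       group_means = tapply(perf$performance, perf$group, mean),
       fit = fit)
}
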