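---
title: "Scoring, simulating and modelling crowdsourced bounding-box annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, simulating and modelling crowdsourced bounding-box annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdbox)
```

# The problem

Training an image classifier to find maize tassels (or any object of
interest) needs a large labelled set of bounding boxes. Crowdsourcing can
produce such labels quickly and cheaply, but raises two questions that
`crowdbox` is built to answer quantitatively:

1. **How good are the crowd's boxes**, measured against an expert's
   gold-standard *minimum bounding boxes*, and do worker groups (paid
   marketplace workers with or without a quality tier, students working for
   course credit) differ?
2. **Does annotation quality matter downstream** — do classifiers trained on
   different workers' boxes perform differently?

The package provides the scoring statistic, a synthetic cohort simulator so
every stage is testable without any external download, the mixed-effects
analyses, and the per-participant classifier pipeline.

# The scoring statistic

For a participant box with area $PB$ and a gold box with area $GB$, with
intersection area $IB$:

$$\mathrm{Pr} = IB/PB, \qquad \mathrm{Rc} = IB/GB, \qquad
F_1 = \frac{2\,\mathrm{Pr}\,\mathrm{Rc}}{\mathrm{Pr}+\mathrm{Rc}},$$

with $F_1 = 0$ when the boxes are disjoint (the $\mathrm{Pr}=\mathrm{Rc}=0$
limit). Each participant box is matched to the gold box maximising $F_1$
within its image. When several participant boxes claim the same gold box,
only the highest-$F_1$ claimant keeps its scores; the others are zeroed and
are **not** re-matched (a single assignment pass — the literal rule, also the
rule our brute-force test oracle transcribes). Per participant and image,
the mean of the box $F_1$ values (zeroed boxes included) is $F_{mean}$, the
response of the statistical analyses.

Numerical conventions: boxes are `(x_min, y_min, width, height)` in pixels,
origin top-left, 0-based, half-open intervals, so integer-box intersections
are exact pixel counts. Ties in the argmax go to the smaller gold-box id;
ties among conflicting claimants go to the earlier-drawn box. Both
tie-breaks are deterministic and order-independent. Degenerate (zero-extent)
participant boxes in loaded data are scored $(0,0,0)$ with a warning rather
than rejected, so one malformed row cannot abort a cohort run; the readers,
in contrast, reject such rows loudly, because a file you are still free to
fix should fail fast.

```{r scoring}
precision_recall_f1(participant = box(0, 0, 20, 10), gold = box(0, 0, 10, 10))
```

# What the simulator emulates

`generate_cohort()` produces the full data structure of a crowdsourcing
study: rendered scenes, gold boxes derived as minimum bounding boxes of the
tassel masks, and per-box annotation records with completion times.

**Scenes.** Tassels are elongated, branched blobs (a statistical stand-in,
not a botanical rendering) brighter on average than the textured background,
so the tassel class is learnable by the downstream classifier. `hard`
scenes pack tassels into a central band (more overlap) and add faint
background clutter without gold boxes, emulating background plants that
annotators were told to ignore.

**Annotators.** The generative model is the minimal one able to reproduce
the empirical patterns the analyses look for:

* *Enclosure bias*: each annotated box is the gold box dilated by a factor
  $d \ge 1$ in both dimensions and jittered at the centre
  (`jitter_sd`, default 1.5 px). For a centred enclosing box,
  $\mathrm{Rc}=1$, $\mathrm{Pr}=1/d^2$ and $F_1 = 2/(1+d^2)$; the simulator
  inverts this closed form to hit a target $F_1$, which makes group effects
  and accuracy drift additive and exact on the $F$ scale before jitter.
  This reproduces the hallmark of real crowd boxes: perfect recall is far
  more common than perfect precision.
* *Misses and spurious boxes*: Bernoulli misses (default rate 0.03) and
  Poisson spurious boxes (default mean 0.15 per image), with at least one
  box always drawn (the task design forced one). These defaults are
  placeholders exposed in the configuration, not estimates — the source
  study does not report per-group miss/spurious rates.
* *Times*: lognormal, $\log t = \mu_p + \log(\phi_g)(q-1) + b_i +
  \varepsilon$, with participant intercepts $\mu_p$ (sd 0.35 around the
  group's log median time), image effects $b_i$ (sd 0.25), residual sd 0.45,
  and per-group fatigue factors $\phi_g$ defaulting to 0.9896 / 0.9893 /
  0.9883 — each successive question about 1% faster.
* *Slow-but-careful coupling*: the standardized residual of log time also
  shifts the target $F$ by `time_accuracy_coupling` (default +0.02 per sd),
  giving the slight positive within-cell time–accuracy correlation the
  analyses probe for.

**Cohort structure.** Defaults mirror the modelled study: groups of 49
Master MTurk / 51 non-Master MTurk / 26 course-credit participants who all
complete 80 images (half hard), image order randomised independently per
participant, group mean-$F$ targets 0.80 / 0.81 / 0.70 (a 0.10 gap between
course-credit and the marketplace groups), participant-skill sd 0.05 and
image-effect sd 0.04 on the $F$ scale. A single seed fans out into
per-image and per-participant substreams; identical configuration and seed
give byte-identical CSV output.

What the simulator does **not** emulate: real field-photo appearance
(illumination, occlusion, camera noise), annotator-specific box styles
beyond dilation+jitter, heavy-tailed break-taking times (the lognormal has
no 15,000-second outliers), or group differences in miss/spurious behaviour.
Passing tests on synthetic cohorts therefore validate the *pipeline
mechanics and estimator calibration*, not claims about any particular human
population.

# The statistical models

`fit_fmean_model()` fits
$F_{mean} \sim \text{group} + (1\,|\,\text{participant}) + (1\,|\,\text{image})$
by REML (participants are nested within groups; unique ids make the plain
intercept the nested effect), reporting the omnibus group F-test, all three
pairwise contrasts without multiplicity adjustment (matching the
presentation convention of the modelled study), variance components and
BLUPs. `fit_time_model()` fits
$\log t \sim \text{group} \times (q-1) + (1\,|\,\text{participant}) +
(1\,|\,\text{image})$ and reports per-group slopes with
$\exp(\hat\beta)$ — the per-question multiplicative time factor — plus the
pairwise slope (interaction) contrasts. The natural log is used throughout.

Degrees of freedom use the **Satterthwaite** approximation (via `lmerTest`
and `emmeans`). The original analysis this package models used
Kenward–Roger in SAS; contrast estimates are identical, only the p-value
tails differ slightly, and the choice is recorded in each fit's `meta`.
Incomplete participants are removed once, at load time
(`filter_complete_participants()`), with logged counts.

`extract_blups()` returns the conditional modes of the image or participant
effects — shrunken per-level predictions summing to approximately zero.
`regress_blups()` regresses the per-image accuracy BLUPs on the log-time
BLUPs by OLS (slope, p, adjusted $R^2$): a positive slope means
longer-taking images are annotated more accurately.
`time_accuracy_correlation()` reports the within-group time–accuracy
association twice — raw, and on residuals after removing participant and
image means — because the two answer different questions (the source study
does not state which conditioning it used, so both are shown side by side).

# The classifier

Each participant's boxes become their positive training crops; a constant
negative set (default 600 crops, sampled to have zero intersection with any
gold box and size-matched to gold boxes) is shared by everyone. Crops are
resized bilinearly to 32×32; dense 8×8 patches at stride 4 are described by
their raw intensities; a codebook of K = 100 centroids (k-means with a fixed
Lloyd iteration budget — a codebook does not need exact convergence) turns
each crop into a normalized codeword-frequency histogram; a linear-kernel
SVM (C = 1) separates tassel from background crops. Performance is
$(\mathrm{TPR}+\mathrm{TNR})/2$ on a held-out test set of tassel and
non-tassel crops from freshly generated scenes (default 600 + 600).
`anova_classifier_performance()` then applies a one-way fixed-effects F-test
to the one-per-participant performances.

The original study names only "bag-of-features" with an SVM; patch
geometry, vocabulary size, kernel and crop preprocessing are undocumented
there, so these defaults are this package's own declared choices, scaled to
the synthetic imagery (small blobs with far fewer distinct textures than
field photographs), and all are exposed in `classifier_config()`. On clean
synthetic scenes the task is nearly separable and performances saturate
near 1; the degradation tests therefore use heavily corrupted annotator
profiles rather than expecting the specific mid-0.88 performances real
field data produce.

# Test and verification scale

The package's statistical checks run at deliberately reduced sizes chosen to
give stable verdicts: parameter recovery uses 20 replicate cohorts of 9
participants × 20 images on 128-px scenes (95% intervals must cover the
configured 0.10 group gap and the 0.99 fatigue factor in at least 95% of
replicates; in the recovery cohorts the per-question accuracy drift is held
equal across groups so that the configured gap *is* the marginal truth);
type-I calibration uses 500 null replicates each for the omnibus group test
and the classifier F-test (rejection rate 5% ± 2 percentage points,
comfortably inside binomial noise at that replicate count); matching
correctness is checked against a literal brute-force transcription of the
assignment-and-zeroing rule on 1,000 random instances of up to 4×4 boxes.

# Known limitations

* The simulator's group effects act through a single mechanism (dilation);
  real groups likely differ in several behaviours at once.
* BLUP-based image-difficulty analysis assumes the balanced
  everyone-annotates-everything design; unbalanced real data will still fit
  but shrinkage comparisons in the tests assume balance.
* The bag-of-features defaults are tuned for 32×32 synthetic crops; real
  field imagery would warrant larger crops, gradient-based descriptors and
  a larger vocabulary.
* Real-data mode expects the canonical CSV dialect or a column mapping; it
  has been exercised on synthetic fixtures only.
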