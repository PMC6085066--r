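# crowdbox

Quality analysis of crowdsourced bounding-box annotations for plant
phenotyping, and a test of whether that quality matters downstream.

When untrained workers draw bounding boxes around objects — here, maize
tassels in field images — two questions decide whether crowdsourcing can
replace expert labelling: how close are the crowd's boxes to an expert's
gold-standard *minimum bounding boxes*, and do classifiers trained on
different workers' boxes actually perform differently? `crowdbox`
implements the full analysis pipeline for both questions, plus a synthetic
cohort simulator so every stage is testable without downloading anything.

## The statistic at the core

For a participant box of area *PB* and a gold box of area *GB* with
intersection area *IB*:

    Pr = IB / PB        Rc = IB / GB        F1 = 2·Pr·Rc / (Pr + Rc)

Each participant box is matched to the gold box maximising F1 within its
image. If several participant boxes claim the same gold box, only the
highest-F1 claimant keeps its scores; the rest are zeroed (and not
re-matched). The per participant-image mean of box F1 values, **F_mean**,
feeds a linear mixed model

    F_mean ~ group + (1 | participant) + (1 | image)

with pairwise group contrasts, a log-time fatigue regression
`log t ~ group × question_index + (1 | participant) + (1 | image)` whose
exponentiated slope is the per-question multiplicative time factor, and a
per-image BLUP analysis relating image difficulty in time to difficulty in
accuracy. Per-participant boxes also train bag-of-visual-words + linear-SVM
tassel classifiers, evaluated as (TPR + TNR) / 2 and compared across groups
with a one-way F-test.

## Worked example

```r
library(crowdbox)

# score one participant box that encloses its gold box
precision_recall_f1(participant = box(2, 0, 24, 12), gold = box(4, 2, 18, 9))
#> precision    recall        f1
#>    0.5625    1.0000    0.7200

# simulate a reduced cohort: 3 groups x 4 participants, 20 images
cfg <- cohort_config(group_sizes = c(master = 4, nonmaster = 4, credit = 4),
                     n_images = 20, image_width = 128, image_height = 128,
                     n_tassels_easy = 3, n_tassels_hard = 5, seed = 42)
coh <- generate_cohort(cfg)
sc  <- score_dataset(coh$annotations, coh$gold)
tapply(sc$image_scores$f_mean, sc$image_scores$group, mean)
#>  credit  master nonmaster
#>  0.6253  0.7303    0.7565

fm <- fit_fmean_model(sc)
fm$contrasts
#>             contrast estimate     se df      p
#> 1 master - nonmaster  -0.0262 0.0335  9 0.4542
#> 2    master - credit   0.1050 0.0335  9 0.0120
#> 3 nonmaster - credit   0.1312 0.0335  9 0.0035

tm <- fit_time_model(coh$annotations)
tm$slopes
#>       group estimate exp_estimate      se    df      p
#> 1    master -0.02665       0.9737 0.00853 211.9 0.0020
#> 2 nonmaster -0.01250       0.9876 0.00857 212.4 0.1460
#> 3    credit -0.00200       0.9980 0.00864 213.5 0.8169
```

The group means and contrasts recover the simulated structure: the
course-credit group was configured 0.10 below the two MTurk-style groups
(estimated gaps 0.105 and 0.131, both significant), while the MTurk-style
groups do not differ (p = 0.45). The `exp_estimate` column is the
multiplicative change in completion time per question — values near 0.99
mean each successive image is annotated about 1% faster (here the cohort's
per-group factors wander around their configured values because this
example uses only 4 participants per group).

`run_pipeline(run_config(...))` chains all stages — simulate → score →
fit-stats → classify — and writes tables plus a JSON report embedding the
resolved configuration and seed; see the vignette in `vignettes/` for the
full model description, simulator assumptions and parameter meanings.

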