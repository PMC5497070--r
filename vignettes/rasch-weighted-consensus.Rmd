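---
title: "Rasch-weighted consensus scoring of crowdsourced diagnostic labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch-weighted consensus scoring of crowdsourced diagnostic labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschcrowd)
```

## The problem

Crowdsourced grading of medical images — for example, classifying retinal
fundus photographs as *normal* or *abnormal* for diabetic retinopathy
screening — collects many cheap, noisy binary votes per image from an
anonymous pool of workers. The simplest consensus, majority vote (MV),
treats every grader as equally reliable. Graders are not equally reliable,
and images are not equally hard: an aggregation rule that knows which
workers tend to be right can recover a more accurate consensus from the
same votes.

`raschcrowd` implements a two-stage weighting scheme:

1. **Calibrate workers** on a training set of items with known gold labels,
   using the dichotomous Rasch model, and
2. **Weight each worker's vote** on held-out items by the exponentiated
   ability measure, summing signed weighted votes into a continuous
   consensus score that can be thresholded at a clinically chosen operating
   point.

## The model

Each graded (worker $i$, item $n$) pair is scored 1 if the worker's binary
classification matched the gold label and 0 otherwise, giving a sparse
correctness matrix. The Rasch model puts a single *measure* (in log-odds
units, logits) on each worker and each item:

$$
P_{ni} \;=\; \Pr(\text{worker } i \text{ grades item } n \text{ correctly})
\;=\; \frac{e^{B_n - D_i}}{1 + e^{B_n - D_i}},
$$

where $B_n$ is the item measure (higher = easier to grade correctly) and
$D_i$ the worker measure (lower = more skilled; the most skilled workers
sit at negative measures). The likelihood depends on the parameters only
through the differences $B_n - D_i$, so a common shift of all measures is
unidentified; a centering constraint fixes it (see below).

The per-worker vote weight is the negative exponentiated measure,

$$ w_i = e^{-D_i}, $$

interpretable as the odds that worker $i$ correctly classifies an item of
average difficulty ($B_n = 0$). Votes on a test item are recoded
$c_i = +1$ (abnormal) or $-1$ (normal) and summed,

$$ S_n = \sum_i w_i\, c_i, $$

with $S_n \ge 0$ read as abnormal at the natural zero cut-off; ties go to
abnormal, the conservative direction for screening. The continuous $S_n$
also feeds a univariate logistic calibration and an exhaustive cut-point
search, so the operating point can trade sensitivity against specificity
explicitly.

## Estimation

`fit_rasch()` performs joint maximum-likelihood estimation (JMLE) by
alternating exact per-facet Newton solves of the marginal-score estimating
equations: given the item measures, each worker's measure solves
$\sum_n P_{ni} = r_i$ (its observed number correct), and symmetrically for
items. Because the joint log-likelihood is concave in all measures, this is
coordinate ascent and converges monotonically. Convergence is declared when
both the largest measure update and the largest expected-minus-observed
marginal fall below `tol` (default 0.005; units are logits and score points
respectively), with `max_iter` sweeps (default 200) as a cap.
Missing cells simply contribute nothing to the likelihood: task assignment
in these marketplaces does not depend on image content, so missingness is
taken as ignorable.

**Extreme scores.** A worker with a perfect or zero marginal (likewise an
item everyone got right or wrong) has no finite MLE. Such entities are set
aside iteratively — removing an extreme item can make a remaining worker's
score extreme — the non-extreme core is fitted, and each set-aside entity's
measure is then solved from its own marginal equation with the extreme
marginal pulled in by `extreme_score_adjust` score points (default 0.3, the
convention of the measurement software family this estimator mirrors).
Applying the adjustment inside the joint iteration instead would make the
worker-side and item-side targets mutually inconsistent (they would no
longer sum to the same total), which manifests as a convergence stall;
separating the extreme entities avoids that while reporting them honestly
via the `*_extreme` flags.

**Centering.** The default constraint is `worker_mean_zero`. A
median-centered variant (`worker_median_zero`) and item-mean centering are
available; the choice shifts every measure by a constant, which cancels in
weight *ratios* but not in raw weights, so any saved fit records the mode.
The final shift is applied to both facets at once, leaving all fitted
probabilities untouched.

**Bias.** JMLE measures are biased away from zero when a worker has few
grades (the classic finite-test-length bias). The package documents rather
than corrects this: the downstream weights are monotone in the measures and
the weighted score is used for *ranking* items, for which the bias is
largely inconsequential; the sparse-worker filter (below) removes the worst
cases.

## Cleaning rules

Three cleaning conventions precede fitting, matching standard practice for
multi-batch crowdsourced grading:

- **Dichotomization**: ordinal source grades 0–3 collapse to
  normal (0–1) / abnormal (2–3); `dichotomize()` is the single point of
  truth for the rule.
- **Deduplication**: repeated grades of one item by one worker keep the
  *earliest* submission (`order_index`), since later views are contaminated
  by prior exposure. Ties fall back to input order.
- **Sparse-worker filter**: workers with fewer than `min_grades` (default
  10) distinct graded items *within the training set* are removed from the
  training matrix only — their test-set votes are kept and receive the
  neutral weight 1.0 when `impute_missing = TRUE`, because an unknown
  worker is best treated as average rather than discarded.

## Evaluation

Abnormal is the positive class everywhere; prevalence is always taken from
the gold labels. `auroc()` computes the empirical ROC and the Mann–Whitney
AUROC (ties counted ½) with a DeLong 95% CI, and `compare_auroc()` the
paired DeLong test for two score sets on the same items, reported as a 1-df
chi-square. These standard computations are delegated to the `pROC`
package; the test suite verifies them against an independent
$O(n^2)$ concordant-pair oracle and a 500-replicate CI coverage simulation.
`select_cutpoint()` sweeps all midpoint cut-offs (plus $\pm\infty$) under
three criteria — maximize percent correct, guarantee a minimum sensitivity,
or a minimum specificity — and reports the confusion summary and
$(\text{sens}+\text{spec})/2$, the AUROC of the dichotomized rule.
`jackknife_auroc()` refits the Rasch model with each item held out
(warm-started from the full fit), scores the held-out item with the
refitted weights, and computes the AUROC over held-out scores; replicates
that fail to converge are flagged and fall back to full-data weights.

## The simulator

`simulate_crowd()` generates crowds with the structure the method assumes:
gold labels Bernoulli(`prevalence`, default 0.42), worker measures
$D \sim N(0, \texttt{ability\_sd}^2)$, item measures
$B \sim N(\texttt{mean\_easiness}, \texttt{difficulty\_sd}^2)$, and each
response correct with probability $P_{ni}$ — a correct response reproduces
the gold label, an incorrect one flips it. Defaults mirror a 1200-image,
10-grades-per-item batch from a pool of 300 workers, with
`ability_sd = 1.0` and `difficulty_sd = 1.5` (the spreads used throughout
the recovery tests). `assignment = "heavy_tail"` draws worker participation
from a Zipf-like distribution to mimic marketplaces where a few workers do
most tasks and many do exactly one.

`mean_easiness` deserves a note. At its default 0 the *average worker is
exactly at chance* on the average item, which makes majority vote
uninformative and flatters any weighting scheme. Real screening crowds are
better than chance (median per-worker accuracy around 65%), which
corresponds to `mean_easiness` ≈ 0.6 logits ($\mathrm{logit}(0.65)$); the
package's own end-to-end demonstrations use that value so that the weighted
rule is compared against a *competent* majority vote.

What the simulator does **not** model, and what passing tests therefore do
not establish about real data: batch effects between grading rounds,
asymmetric error rates across classes (an incorrect response here is always
a label flip), worker learning or fatigue over time, and any dependence of
assignment on image content. Parameter-recovery and benchmark results
transfer to real crowds only insofar as those assumptions are tolerable.

## Numerical choices and edge cases

- Convergence: `tol` 0.005 logits / score points, `max_iter` 200; inner
  Newton steps are capped at 1 logit for stability.
- Weight truncation uses linear-interpolation empirical percentiles (R's
  type 7) at the 1st/99th centiles on the **odds** scale (after
  exponentiation), clamping rather than dropping outlying workers.
- Candidate cut-offs are midpoints between adjacent distinct scores plus
  $\pm\infty$, avoiding ambiguity exactly at observed values; the decision
  rule is `score >= cutoff`, consistent with the $S \ge 0$ convention.
- Tie-breaks: `max_correct` prefers higher sensitivity then lower cut-off;
  item difficulty ranking breaks ties by item id; deduplication by input
  order.
- Degenerate inputs: one-class gold sets yield `NA` rates (never 0);
  identical score vectors make the paired DeLong test "not applicable"
  (chi-square 0, p 1 when the curves coincide); complete separation in the
  logistic calibration is flagged while the raw-score ROC remains valid;
  a worker or item whose cells all face a single partner is listed in
  `flat_entities`.

## Problem sizes used in the shipped checks

The package's own verification uses: parameter recovery at 300 workers ×
600 items with ~25 grades/item; the MV-vs-weighted benchmark at 1200 items,
300 workers, 10 grades/item over 100 replicates plus one pooled 2400-item
replicate; jackknife agreement at 300 items × 100 workers × 20 grades/item;
and exhaustive oracles (grid-search likelihood maximization up to 6×6
matrices, pair-count AUROC up to n = 50). These sizes were chosen as the
smallest at which the asymptotic claims being checked are expected to hold
comfortably.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_items = 400, n_workers = 150, grades_per_item = 15,
                  ability_sd = 1, mean_easiness = 0.6, seed = 42)
bundle <- simulate_crowd(cfg)

split <- split_items(bundle$truth$item_id, 0.5, seed = 43)
train <- filter_sparse_workers(
  bundle$records[bundle$records$item_id %in% split$train_items, ],
  split$train_items, min_grades = 10)

fit <- fit_rasch(build_correctness_matrix(train, bundle$truth))
weights <- weights_from_fit(fit)

test <- bundle$records[bundle$records$item_id %in% split$test_items, ]
cons <- consensus_table(test, weights, impute_missing = TRUE)
gold <- setNames(bundle$truth$gold, bundle$truth$item_id)[cons$item_id]

auroc(setNames(cons$weighted_score, cons$item_id), gold)
compare_auroc(setNames(cons$weighted_score, cons$item_id),
              setNames(2 * cons$n_abnormal_votes - cons$n_votes, cons$item_id),
              gold)
select_cutpoint(setNames(cons$weighted_score, cons$item_id), gold,
                "min_sensitivity", target = 90)
```

## Known limitations

- JMLE bias for short response strings is documented, not corrected.
- The estimator fits the dichotomous Rasch model only: no polytomous
  models, no infit/outfit statistics, no differential item functioning,
  and no conditional or marginal ML alternatives.
- No early-stopping ("on the fly") consensus and no joint
  truth-and-ability estimation of the Dawid–Skene type: gold labels are
  required for the training items.
- Exact measure values depend on the centering mode and the extreme-score
  convention; comparisons across fits should use one recorded
  configuration.
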