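---
title: "Validating automated verbal autopsy methods: models, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating automated verbal autopsy methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vavalid)
```

## The problem

In populations without routine medical certification of death, the cause
of death is often inferred from a *verbal autopsy* (VA): a structured
interview of the deceased's household about signs, symptoms and events
preceding death, together with an open narrative. `vavalid` implements
the major families of automated VA cause-assignment methods and, just as
importantly, the validation protocol needed to compare them fairly. Both
halves matter: naive validation designs let a method look good merely by
reproducing the cause composition of its training data.

A VA dataset here is a flat table — one row per death, one binary column
per item (structured questionnaire items and dichotomous free-text token
indicators), a per-death age module tag, and, for labeled data, a
gold-standard cause. Items reflecting household recall of health care
experience (HCE) — medical-history questions, recalled diagnoses — are
flagged in the item metadata so every analysis can be run with and
without them; the "without" condition approximates populations with
little access to care.

## The methods

**Tariff.** For item $i$ and cause $j$, with endorsement rate $x_{ij}$
(the fraction of cause-$j$ training deaths answering "yes" to item $i$),
the tariff is a robust z-score across causes:

$$T_{ij} = \frac{x_{ij} - \mathrm{median}_{j'}\, x_{ij'}}{\mathrm{IQR}_{j'}\, x_{ij'}}$$

with percentiles by linear interpolation and an IQR floor of 0.001 (an
item with no cross-cause spread carries tariff 0, not 0/0). Only
statistically significant tariffs are used: each item-cause tariff is
recomputed on bootstrap resamples of the training deaths (within cause)
and kept only when the two-sided 95% percentile interval excludes zero.
The bootstrap-interval rule is this package's explicit operationalization
of "statistically significant"; `n_boot` and `alpha` are exposed. A
death's score against cause $j$ sums that cause's kept tariffs (at most
`max_items = 40`, by absolute value) over endorsed items. Because raw
score scales differ across causes, assignment is by *rank against a
uniform-cause reference pool*: `pool_per_cause = 100` training deaths are
resampled per cause and scored, and each test death is assigned the cause
for which its score ranks best within the pool — this also removes any
leakage of the training composition into the prediction, the very
artifact the split design is built to suppress.

**Joint-posterior naive Bayes (InterVA-style).** Given a
conditional-probability matrix $P_{ij} = \Pr(\text{yes to } i \mid
\text{cause } j)$ — expert-supplied via CSV or fitted from data — the
posterior over all causes at once is, under conditional independence of
items,

$$\Pr(j \mid \mathbf{x}) \propto \pi_j \prod_i P_{ij}^{x_i} (1 - P_{ij})^{1 - x_i},$$

optionally on a restricted item set and with an indeterminate threshold
(default 0, i.e. always assign, so CSMF comparisons need no
indeterminate-redistribution rule; nonzero thresholds report
indeterminate mass separately). Fitted conditionals use additive
smoothing, $(k + s)/(n_j + 2s)$ with $s = 1$, so no single item can veto
a cause.

**Symptom-pattern classifier (SSP-style).** One-vs-rest rather than
joint: for each cause $j$ the two-class posterior of $j$ against a
composite complement whose conditionals are the prior-weighted mixture of
the other causes' profiles, computed on a random subset of
`subset_size = 16` items and averaged over `n_draws = 100` subsets.
Small subsets bound how much conditional dependence any one product term
assumes — the mechanism by which the method "takes symptom clustering
into account" — and the mixture weighting is the probabilistically
coherent definition of the complement class. With the full item set and
one draw, the two-cause case reduces exactly to the joint posterior (a
tested identity). The subset pool defaults to the tariff-significant
items when a tariff fit is supplied, reflecting the coupling of the
symptom-pattern method to tariff output; without one, all items are used.

**Direct estimation (King-Lu-style).** No individual assignment: for a
subset $S$ of items, the test-set distribution $b$ of the $2^{|S|}$
symptom profiles satisfies $b = A f$ in expectation, where $A$ holds the
cause-conditional profile distributions estimated from training data and
$f$ is the test CSMF. `estimate_csmf_direct()` solves $A f = b$ by least
squares *on the simplex* ($f \ge 0$, $\sum f = 1$, imposed at the
quadratic-programming solver rather than by post-hoc clipping, which
biases small fractions), for `n_subsets = 300` random subsets of
`subset_size = 8` items, and averages the solutions (a trimmed-mean
option exists for robustness to occasional degenerate subsets). Whether
the original analyses averaged solutions or stacked equations is not
documented; averaging is the declared behavior here. Profile tables must
stay dense, which is why the subset size is small; the method's known
degradation as the cause list grows at fixed information is asserted as
a monotone comparison in the test suite.

## The validation design

`generate_splits()` produces train/test pairs in which (1) each cause's
deaths are randomly partitioned into a train fraction
(`train_frac = 0.75`) and a test pool, so train and test share no
deaths; (2) a target composition is drawn from a flat Dirichlet over the
simplex (`alpha = 1`, configurable) independently of the data; (3) the
test set is built by multinomial draws at the target composition,
sampling with replacement within cause from the pool — required to hit
arbitrary compositions from a finite pool. Causes with an empty pool
have their target mass renormalized over the available causes and are
logged per split. The protocol scale is 500 splits; desk-scale runs use
50. The paper trail for each experiment is a JSON manifest from which
any split is bit-reproducible given the source data and seed: all
randomness flows from one root integer through named substreams
(`child_seed()`).

Because the per-cause partition keeps a fixed fraction, the train
composition is essentially constant across splits while the test target
varies freely — the two are uncorrelated by construction, which the test
suite checks empirically across 500 splits.

## Metrics

Individual-level: per-cause sensitivity and specificity (undefined
denominators reported as missing, never 0), chance-corrected concordance

$$\mathrm{CCC}_j = \frac{\frac{TP_j}{TP_j + FN_j} - \frac{1}{N}}{1 - \frac{1}{N}},$$

whose overall value is the *unweighted* mean over causes with a defined
value (treating causes equally; weights are not otherwise specified by
convention), and Cohen's kappa. Population-level: CSMF accuracy

$$1 - \frac{\sum_j |\mathrm{CSMF}_j^{\text{true}} - \mathrm{CSMF}_j^{\text{pred}}|}{2\,(1 - \min_j \mathrm{CSMF}_j^{\text{true}})} \in [0, 1],$$

per-cause regression of estimated on true CSMF across splits (slope,
intercept, RMSE — 1/0/0 for a perfect estimator), and mean absolute
error. Cross-split summaries report the median with a 95%
percentile-bootstrap interval of the median (`n_boot = 1000`) —
uncertainty of the summary, not the spread of the split distribution;
the construction is configurable. Reports render CCC and kappa as
percentages and CSMF accuracy as a fraction. Head-to-head tables give
each split's best method one unit of credit, shared equally under exact
ties, so fractional counts appear and per-condition credit sums to the
number of compared splits. Direct-estimation methods produce no
individual assignments, so CCC and kappa are not computed for them.

## The synthetic generator, and what passing tests do not show

`make_cause_profiles()` gives each cause a distinct block of signal
items endorsed with probability `base + signal * (1 - base)` against a
background rate `base`, flags `n_hce` items as HCE and a trailing block
as free-text tokens; `simulate_deaths()` draws causes i.i.d. from a CSMF
and items as independent Bernoulli draws given cause. Defaults mirror an
adult-module scale (34 causes, ~100 structured + ~50 token items,
`signal = 0.8`, `base = 0.05` — a background endorsement rate and
signal-to-background contrast typical of symptom checklists). Items are
*independent given cause*, matching the naive-Bayes assumption: that
makes enumeration oracles exact and limits (`signal = 1, base = 0`
perfectly separable; `signal = 0` uninformative) analytic. It also means
passing tests say nothing about robustness to correlated symptoms,
site or cultural response styles, or recall effects in real VA data —
those require evaluation on a real gold-standard dataset, for which the
package's CSV dialect and the same harness apply unchanged.

## Numerical and design choices

- Likelihood products run in the log domain (with ~150 items direct
  products underflow); expert matrices containing exact 0/1 entries are
  honored, and a death whose likelihood vanishes under every cause is
  indeterminate.
- Ties in tariff rank assignment break toward the lowest cause index and
  are counted (`n_ties`); argmax ties elsewhere break the same way.
- The constrained solve adds a 1e-9 ridge to keep the quadratic program
  positive definite when profile columns collide; failed subsets are
  skipped and counted, and estimation errors only if every subset fails.
- Missing item responses are imputed as non-endorsement (items are
  dichotomous endorsements); the sentinel code is configurable at read
  time.
- Tokenization is deterministic and explicit — lowercase, strip
  punctuation, drop tokens under 3 characters and stop-words — since the
  upstream tool family is not otherwise pinned down.
- Method failures on a split are excluded for that method with a logged
  reason; a 500-split run never dies at split 499.

## Problem sizes used by the shipped tests

The test suite and acceptance checks run at desk scale, chosen so the
full suite completes in well under a minute while keeping every
statistical tolerance comfortably wide: generator data of 2–10 causes,
9–40 items and 150–2000 deaths; 50-split experiments for protocol
properties (500 splits for the split-design invariants, which are cheap
because splits are index manifests); 100 bootstrap resamples for tariff
significance inside experiments (the function default is 500);
enumeration oracles at ≤ 3 causes and ≤ 10 items cover all 1024
profiles exhaustively. Scaling the same calls to the 500-split,
34-cause protocol is a matter of configuration, not code.

## Worked example

```{r, eval = FALSE}
prof <- make_cause_profiles(n_causes = 8, n_items = 40, signal = 0.8,
                            base = 0.05, n_hce = 8, n_text = 10, seed = 1)
truth <- withr::with_seed(2, draw_target_csmf(8, causes = prof$causes))
ds <- simulate_deaths(prof, truth, 2000, seed = 3)

ex <- run_experiment(ds,
  methods = list(method_tariff(), method_interva(), method_ssp(),
                 method_kinglu()),
  n_splits = 50, seed = 4)
summary(ex)
head_to_head(ex)
csmf_regression_table(ex)
```

## Known limitations

- No site- or age-stratified metrics, no ICD coding, no physician-review
  workflow, and no published expert probability base ships with the
  package (one can be supplied as CSV).
- The generator's optional realism ends at conditional independence;
  correlated-symptom generation would be the natural extension for
  probing one-vs-rest versus joint posteriors under model misspecification.
- Uncertainty intervals summarize median uncertainty only; full split
  distributions are available in the tidy per-split output for any other
  summary.
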