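---
title: "Methods: multimodal fusion, evolutionary splitting and attention MIL"
author: "oncofusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal fusion, evolutionary splitting and attention MIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncofusion)
```

# Scope

`oncofusion` implements a complete multimodal machine-learning analysis
for head-and-neck-cancer-style cohorts: per-modality encoding of patient
records into multimodal vectors (early fusion), evolutionary selection of
class-balanced in-distribution and out-of-distribution train/test splits,
SMOTE + Random Forest outcome prediction over three split regimes,
gated-attention multiple instance learning (MIL) over multi-source
instance-embedding bags, and Kaplan–Meier / Wilcoxon–Mann–Whitney
survival statistics. Because real clinical cohorts of this kind are
access-restricted, the package ships a seeded synthetic-cohort generator
that emulates the statistical structure those analyses assume; every
pipeline stage is exercised and tested against it.

# The data model

One JSON array, one object per patient: demographics (sex, age at
diagnosis, smoking status), pathology (primary site, grading, pT/pN
stage, six tri-state flags such as lymphatic invasion and HPV status), a
blood panel (per-parameter value, unit, group), ICD-10 code lists,
tissue-microarray (TMA) CD3/CD8 cell densities in tumor center and
invasion front (cells/mm²), and an event timeline expressed in days
since initial diagnosis (day 0). Missing values are JSON `null`; an
absent key is equivalent. When a death day is present it defines the end
of follow-up. The machine-readable data dictionary ships at
`cohortSchemaPath()`.

# Multimodal patient vectors

Encoding rules per modality:

* **Clinical/pathological** — binary flags map to {0, 1, missing}; pT
  and pN stages map to consecutive ordinal labels via shipped decision
  tables (pTis→0 … pT4b→6; pN0→0, pN1→1, pN2a/b/c→2, pN3→3 —
  monotone in severity, configurable); nominal features (sex, smoking,
  site, grading) become integer labels expanded one-hot at assembly.
  One-hot expansion keeps all observed levels (no reference-level drop):
  tree models are unaffected and cosine geometry stays symmetric.
* **Blood** — raw values of the hematology panel (the complete blood
  count; 8 parameters by default). Parameters from other groups (CRP,
  electrolytes, renal) are excluded by design.
* **ICD** — bag-of-words over the literal first four characters of each
  code (`"C32.0"` → `"C32."`, i.e. the category level); prefixes carried
  by fewer than 3 patients are dropped; the vocabulary is sorted
  lexicographically.
* **TMA** — the four CD3/CD8 densities as numeric features.

Imputation replaces missing categorical/binary entries by the
per-feature mode and numeric/ordinal entries by the mean; ordinal and
numeric columns are then z-scored. Zero-variance columns are left at 0
after centering. Completeness flags (all required modalities present)
are recorded **before** imputation; the genetic algorithm only optimizes
over complete-vector patients and assigns the rest to training.

Two fitting regimes exist deliberately: `assembleVectors()` fits the
encoder on the whole cohort (the variant used for visualization and for
defining splits), while `fitPredict()` refits the encoder — including
the ICD vocabulary, observed one-hot levels, imputation values and
z-scoring statistics — on training patients only, so that no information
from held-out patients leaks into model evaluation. The
leakage audit test perturbs a test patient arbitrarily and verifies the
fitted pipeline and all other test scores are unchanged.

`project2D()` provides the 2-D map of the cohort: classical metric
multidimensional scaling of the pairwise cosine-distance matrix with
each axis min-max rescaled to [0, 1]. Classical MDS was chosen as the
package's projection because it is deterministic, parameter-free and
respects the same cosine geometry the splitter optimizes; it does not
attempt the local-neighborhood emphasis of nonlinear embeddings, and the
package's claims never depend on the projection.

# Evolutionary dataset splitting

A split is a binary mask over eligible patients with exactly
N = round(0.2 · n) test entries. Two fitness functions are maximized,
both penalized by class imbalance:

* **In-distribution**: the sum over test points of the cosine distance
  to their nearest *other* test point. Maximizing nearest-neighbor
  distances spreads the test set evenly across the data — a
  space-filling, representative sample.
* **Out-of-distribution**: the sum of cosine distances over all test
  pairs. This objective concentrates on points that are far from the
  bulk *and* mutually dissimilar — genuine distributional outliers.

The penalty is α·Σₖ|dₖ − dₖ,all| over the C = 2 outcome classes
(recurrence, survival status), where dₖ is the positive fraction among
labeled test patients and dₖ,all overall; patients with a missing
outcome are excluded from the penalty but remain splittable. The default
α scales the penalty to the magnitude of the distance sum — N for
in-distribution, N(N−1)/2 for out-of-distribution — so balance competes
meaningfully in both modes.

The GA uses fixed-cardinality genomes: tournament selection (size 3)
with 1% elitism, one-point crossover followed by cardinality repair
(random bit swaps), and inversion mutation, which reverses a random
segment and therefore preserves cardinality; the expected number of
inversion events per genome is one (per-bit rate 1/n). Termination is
stagnation-based (default 50 generations without improvement) with a
hard cap. The documented population default is 10,000; the package's own
tests use a few hundred genomes because their optimization problems are
small. Nearest-neighbor ties break toward the lowest patient index, and
a zero-norm vector has cosine distance 1 to anything by convention.

Initialization is memetic by default (`greedyInit = TRUE`): one genome
is constructed greedily for the mode's distance objective (farthest-pair
start, then best-marginal additions), refined by a randomized
improving-swap pass on the full penalized fitness, and injected with a
few mutated copies into the otherwise random population. The warm start
matters on larger cohorts: the balance penalty is steep, so an
unbalanced greedy optimum would otherwise be eliminated by selection
before the GA can repair it. `exhaustiveSplitOracle()` provides the
brute-force optimum on enumerable instances (ties broken toward the
lexicographically smallest mask); the test suite verifies the GA attains
it across both modes on 40 random instances.

# Outcome prediction over three split regimes

Labels: *recurrence* — positive if recurrence within 1095 days (three
years at day resolution, no leap handling); negative if no recurrence,
no death within three years, and at least three years of follow-up;
anything else (late recurrence, early death, short follow-up) is
excluded, since it satisfies neither class definition. *Survival* —
positive for deaths with tumor-specific or unknown cause, negative for
patients alive at last follow-up, excluded for non-tumor-specific
deaths.

`fitPredict()` runs the leakage-safe pipeline: encoder fit on train,
SMOTE oversampling of the training minority class (k = 5 nearest
minority neighbors, interpolation with uniform weights, automatic k
reduction near singleton classes), then a probability Random Forest (500
trees, √p features per split, unlimited depth). `evaluateProtocol()`
repeats train/evaluate five times per split × task with derived seeds,
averages ROC curves threshold-wise on a 101-point FPR grid, and reports
mean ± sd AUC. The three regimes are the two GA splits plus a site
holdout (`siteHoldoutSplit()`), whose held-out site is a parameter — the
package does not hard-code a particular anatomical site.

# The synthetic cohort

The generator (`generateCohort()`) draws, per patient, demographic
marginals (80% male, median age 61 ± 11 years, 72% ever-smokers), a
primary site from a five-site mix, and four latent factors: stage
severity, blood anomaly, immune infiltration, comorbidity burden. Sites
shift the latents and the outcome intercept (`siteConfounding`, default
1 SD): oropharyngeal disease is largely HPV-driven, immunologically hot
and has better prognosis; hypopharyngeal disease is the reverse.
Observed features derive from the latents: stages by monotone binning,
a 12-parameter blood panel, log-normal CD3/CD8 densities, and per-site
ICD-10 codes plus comorbidity codes (with deliberately rare codes so the
minimum-support filter has something to drop).

Outcomes follow a logistic model whose log-odds signal is deliberately
**distributed across modalities** (stage 1.2, blood 1.0, immune −1.2,
ICD burden 0.9 per latent SD) so that early fusion beats any single
modality by construction. Three structures make the split regimes
behave like real cohorts:

* **Effect modification** — immune infiltration is strongly protective
  in HPV-positive disease and weakly otherwise, and in the oropharynx
  the anatomical stage, blood and comorbidity effects carry little
  prognostic weight. A model trained without oropharyngeal patients
  therefore ranks them poorly: the site holdout is genuinely hard, not
  merely differently calibrated.
* **Rare deranged-panel syndromes** — a small fraction of patients
  (default 7%) carries one of three mutually opposing panel-derangement
  signatures (hyperproliferative, macrocytic-anemic, pancytopenic),
  shifted by ≈4 cohort SDs. These patients are far from the bulk and
  from each other's groups in cosine geometry — exactly what the
  out-of-distribution objective seeks.
* **Panel-anomaly signal attenuation** — each patient's planted signal
  is scaled by a logistic function of the root-mean-square cohort
  z-score of the measured panel: as a panel becomes anomalous, tumor
  biology is replaced by elevated, individually unpredictable acute-risk
  heterogeneity (`frailty`, `anomalyRisk`). Outcomes of deranged
  patients are thus near coin flips at elevated prevalence, which is
  what makes out-of-distribution test sets measurably harder than
  representative ones.

Event days follow geometric waiting times consistent with event status;
deaths end follow-up; recurrences are only reported when observed within
follow-up. `injectMissingness()` blanks eligible fields at configured
rates (outcome fields and IDs never); `plantOutliers()` shifts numeric
features of chosen patients by a multiple of the per-feature spread with
random signs, providing ground truth for outlier-capture checks. All
randomness derives from one seed through documented named sub-streams,
so modules are independently reproducible.

What the generator does **not** emulate: realistic ICD-10 epidemiology,
correlated missingness patterns, measurement batch effects, informative
censoring, or pixel-level image content. Passing tests therefore show
that the pipeline recovers structure it is designed to recover under
controlled conditions — not that any particular clinical performance
level would be attained on real data.

# Attention MIL over multimodal bags

A bag is one patient's set of instance embeddings — by default 64
whole-slide-image (WSI) instances (a stand-in for sparse patch sampling)
plus 32 tiles per TMA core × 2 cores per requested stain, with embedding
dimension 64. The synthetic embedding source draws background instances
from a standard Gaussian and shifts a planted fraction (10%) of the
instances of positive patients by 3 units along a fixed per-source
direction. With `signalAssignment = "split"`, each positive patient
carries signal in exactly one of the signal sources, so single-source
bags are informative for only part of the positives — complementary
modalities by construction.

The model is two-layer gated attention — a_i = w⊤(tanh(V h_i) ⊙
σ(U h_i)), hidden size 32 — with softmax pooling and a logistic bag
classifier, trained by Adam on the bag cross-entropy plus a clustering
loss: an instance-level head on the gated representation receives
pseudo-labels from the attention ranking (top-k of positive bags →
positive; their bottom-k and the top-k of negative bags → negative,
k = 8). Three numerical choices matter and are defaults for a reason:
class-balanced bag weighting (prevents majority-class collapse on
imbalanced cohorts), L2 weight decay 0.03 on the attention backbone
*and* the bag classifier (an unregularized bag head turns the model into
plain mean pooling and the attention never learns), and 3 random
restarts selected by final training loss. Attention is permutation
equivariant by construction, weights sum to one per bag, and
`modalityAttentionSummary()` aggregates weights by source tag without
per-source renormalization. Bag labels for survival use the MIL-specific
three-year rule: deaths within three years are the deceased class,
deaths after three years are force-labeled alive, and patients alive
with under three years of observation are removed. A multi-class
(e.g. site-localization) label option can be emulated by supplying
custom labels; the shipped trainer is binary.

# Survival statistics

`kmEstimate()` computes the product-limit estimator with right-censoring
(deaths precede censorings at tied times) and a Greenwood variance band
on the log scale, delegating the arithmetic to the survival package;
`survivalAt()` is the right-continuous step lookup, flagging queries
beyond the last observed time as extrapolated. `mwuTest()` implements
the Wilcoxon–Mann–Whitney U with midrank ties; for total n ≤ 12 the
two-sided p-value is computed by exhaustive enumeration of all group
assignments, otherwise by normal approximation with tie and continuity
correction — the suite cross-checks both branches against
`stats::wilcox.test` and against each other.

# Problem sizes and test design

The shipped checks run the GA-versus-oracle comparison on 40 instances
of 10–12 patients, class balance and outlier capture at n = 200, the
three-split and fusion evaluations at n = 600 with 5 repeats, and MIL on
200 bags (10 master seeds for the orderings). These sizes were chosen so
the full pipeline — including 30 MIL trainings — completes comfortably
on a single CPU while leaving the stochastic criteria enough replication
to be stable. Larger cohorts can be generated freely; nothing in the
implementation is specific to these sizes.

# Known limitations

* The MIL trainer is plain R; it is sized for hundreds of bags with
  hundreds of instances, not for cohort-scale gigapixel pipelines.
* Real embedding sources (foundation-model tile encoders) are consumed
  through the `embedSource` hook but none ships with the package.
* The splitter's penalty handles two binary targets additively;
  multi-label stratification beyond that and Pareto-style
  multi-objective splitting are out of scope.
* Cox models, log-rank tests and competing-risk analyses are out of
  scope; the survival module covers the product-limit estimator and the
  rank-sum comparison only.
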