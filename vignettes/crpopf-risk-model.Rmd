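---
title: "A discrete Bayes model for preoperative CR-POPF risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete Bayes model for preoperative CR-POPF risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfrisk)
```

## The clinical problem

Clinically relevant postoperative pancreatic fistula (CR-POPF, ISGPS grade
B or C) complicates roughly a third of pancreaticoduodenectomies and drives
most of the procedure's morbidity. The dominant anatomical determinant is
gland texture: a soft pancreas with preserved exocrine function and a
non-dilated main pancreatic duct (MPD) leaks; a fibrotic gland with a
dilated duct does not. Texture itself is only known intraoperatively, but
its radiological surrogate — the **MPD index**, duct diameter divided by
parenchymal thickness, both in mm on preoperative CT — is available before
the incision, as are nutritional and anthropometric markers (BMI, visceral
fat area, PNI, CONUT, albumin) and history (diabetes, biliary drainage,
sarcopenia, diagnosis).

`popfrisk` implements a preoperative risk model over fourteen such
candidate markers: each marker is dichotomized at a clinical cut-off, a
**discrete Bayes classifier** is fitted over the resulting cells, the
optimal marker combination is found by exhaustive search inside a
**leave-one-out wrapper**, and the final model is stratified by
preoperative diagnosis — pancreatic ductal adenocarcinoma (PDAC) is scored
by the MPD index alone, all other diagnoses by MPD index plus BMI. The
stratification reflects physiology: exocrine function is usually already
impaired in PDAC, so the duct/parenchyma geometry carries the signal alone,
while in non-PDAC disease body habitus adds information.

## The classifier

With $k$ dichotomized markers the feature space has $2^k$ cells. For class
$c \in \{\text{POPF}^+, \text{POPF}^-\}$ with $n_c$ training samples, of
which $n_{c,\text{cell}}$ fall in a cell,

$$\hat P(\text{cell} \mid c) = \frac{n_{c,\text{cell}} + \alpha}
{n_c + \alpha\,2^k}, \qquad
\hat\pi_c = n_c / n,$$

and a profile is classified by the larger of
$\hat\pi_c\,\hat P(\text{cell}\mid c)$. This is the *full joint-cell*
estimate, not a naive-Bayes factorization: with $k \le 3$ there are at most
8 cells, well supported by strata of 80–100 patients, and the fitted model
is literally a decision table one can print and audit
(`decision_table()`).

Numerical choices that matter:

* **Smoothing.** The default is $\alpha = 1$ (Laplace). Inside
  leave-one-out folds, cells routinely go empty; a zero-probability cell
  would make posteriors degenerate. $\alpha = 0$ gives maximum-likelihood
  estimates, under which the rule provably reduces to comparing raw
  per-class counts in the sample's cell — the form used by the
  hand-checked test fixtures.
* **Ties predict positive.** A missed fistula is costlier than an
  unnecessary precaution, so an exact posterior tie fails toward
  sensitivity. Ties are not exotic here: cell counts are small integers
  and tied prior-weighted likelihoods occur in real folds.
* **Exact tie arithmetic.** Decisions compare cross-multiplied integer
  scores, never quotients of floating divisions, so a tie that is exact in
  rational arithmetic is exact in code. (The test suite checks the
  classifier against a brute-force joint-table rule on hundreds of random
  small cohorts; the first implementation failed those checks purely
  through one-ulp rounding of tied scores.)
* **Sufficiency.** At $\alpha = 0$ a marker that is constant across the
  training data changes no posterior. With smoothing this holds only
  approximately (the $2^k$ in the denominator changes), a deliberate trade
  of exact sufficiency for fold robustness.
* **Priors** are empirical class frequencies; a uniform-prior mode exists
  for sensitivity analyses.

## The wrapper selection

For each of the $N$ training samples in turn: hold it out, fit the
classifier for *every* candidate combination of the requested size on the
remaining $N-1$, score each combination by its **re-substitution
estimate** (classify the same $N-1$ samples), and keep the combination
with maximal sensitivity among those with specificity $\ge 50\%$ (or
maximal F1 under the alternative criterion). The most frequently selected
combination across the $N$ folds wins. Sizes 1–3 are searched; by default
each size runs in its own pass so per-size winners can be tabulated side
by side, and a cumulative mode lets sizes compete directly (ties break
toward fewer markers, then lexicographically — determinism everywhere, no
randomness in selection).

Two honesty notes. First, re-substitution is optimistic; the package
therefore also reports the held-out leave-one-out estimate of any fixed
combination (`loo_holdout_estimate()`), and the gap between the two is
visible in `analysis/02_select_markers.R`. Second, when no combination
meets the specificity floor in a fold, that fold falls back to the F1
criterion and is flagged in the fold log rather than silently dropped.

The engine precomputes per-combination cell indices and count arrays and
updates them by single-sample decrements, so a full 180-fold run over all
1–3-marker subsets of 14 candidates (469 combinations, ~84 000 classifier
fits) takes well under a second; the suite cross-checks it fold-by-fold
against naive refitting.

## The synthetic cohorts

No public patient-level data exist for this problem, so the generator is a
first-class, tested component that encodes the cohort structure the
analysis assumes:

* 180 patients, 47% PDAC, overall CR-POPF prevalence ≈ 33%; marker
  marginals log-normal around the reported medians (BMI 22.3, MPD index
  0.33, thickness 13 mm, PNI 47.7, …) and category frequencies (59% male,
  34% diabetic, 42% drained, 53% sarcopenic).
* Outcomes are drawn from the **discretized cell** of the planted risk
  markers, so the discrete Bayes classifier is the true model and exact
  recovery properties are available.
* Derived markers are generated consistently from raw inputs: the MPD
  index is duct size / thickness of the stored values, BMI is
  weight / height², PNI and CONUT come from the stored labs — the
  record-level invariants hold bit-exactly, and a written CSV re-reads
  losslessly (doubles are serialized with shortest round-trip precision).

The per-cell risks of the default configuration were solved analytically
from the reported training operating points. For PDAC (sens 0.87, spec
0.81, PPV 0.50, NPV 0.97) this forces stratum prevalence ≈ 0.179,
$P(\text{index} < 0.3) \approx 0.31$, and cell risks 0.50 / 0.034. Note
the value 0.50 *exactly*: a PPV of 50% literally says the flagged group is
a coin flip, so the positive cell sits on the decision boundary and only
the tie rule makes the implied rule decisive. For non-PDAC (sens 0.84,
spec 0.57, PPV 0.63 at prevalence 0.466) the solved cell risks over
(index bin, BMI bin) are 0.576 / 0.85 / 0.197 / 0.55 — positive in three
cells, negative only for (high index, low BMI).

Three separation levels share this structure:

* `"calibrated"` — the solved risks above. Finite cohorts of n = 180 drawn from
  it are *deliberately* marginal: two of the positive cells sit near risk
  0.5, so single training draws can flip them, and selection at realistic
  effect sizes is noisy. That is a feature — it reproduces the ambiguity
  real cohorts of this size have.
* `"strong"` — the same planted decision structure with every cell pushed
  to 0.9 / 0.05. Used for recovery and convergence experiments, where the
  question is "does the machinery find what was planted", not "how hard is
  the clinical problem".
* `"none"` — every cell at the background prevalence, the negative
  control. Under pure noise most folds tie at sensitivity zero and the
  deterministic tie-break concentrates wins on the alphabetically first
  marker, so the meaningful control property — tested — is that the
  *planted* combinations are not recovered, not that winners are uniform.

What the generator does **not** emulate: correlations among noise markers
(age, albumin, PNI and friends are sampled independently), measurement
error in CT-derived quantities, site effects between hospitals, and any
continuous dose–response within a cell (outcomes depend on values only
through their bins). Passing tests therefore show the *procedure* is
correct and recoverable under its own assumptions; they cannot show the
published cut-offs are optimal for real patients.

## Fixed design points

* Dichotomization sends a value **equal to the cut-off to the upper bin**;
  male sex and PDAC code as 1.
* Cut-offs: age 65, BMI 25, VFA 100, PNI 45, MPD size 3 mm, MPD index 0.3,
  CONUT ≥ 3. Albumin (3.5 g/dL — the hypoalbuminemia threshold) and
  parenchymal thickness (13 mm — the training median) are this package's
  choices: neither marker carries a published cut-off, and neither appears
  in any winning combination.
* PNI uses Onodera's form, $10 \times \text{albumin} + 0.005 \times
  \text{lymphocytes}$; CONUT uses the standard albumin/lymphocyte/
  cholesterol bands. Only the CONUT ≥ 3 dichotomy reaches the classifier.
* Missing marker values are errors, never imputed; cohorts are
  complete-case by construction.
* The final model's marker sets and cut-offs are fixed (they are the
  published artifact); the risk *direction* is always learned from the
  training data. Rediscovery from scratch is available via
  `loo_select()`.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 200 random small cohorts
(n ≤ 50, k ≤ 3) for the brute-force equivalence check; 50 replicates of
n = 200 strongly separated cohorts for recovery; one n = 20 000 cohort for
marginal/conditional calibration and for convergence of the fitted model
to the implied operating point within three binomial standard errors.
These sizes give comfortable statistical margins for every asserted
property while keeping a full run in minutes.

## Limitations

The validation performance of the published model is reproduced here from
its printed confusion matrices, and the synthetic experiments show the
pipeline recovers planted structure; neither substitutes for external
validation on real cohorts. Training-set selection tables are not
reproducible without the original hospital data and are not asserted
anywhere. The classifier's cells are unordered — it cannot exploit
monotone dose–response across cut-offs — and with k = 3 and ~90 patients
per stratum the per-cell counts are already small, which is why sizes
above 3 are not searched.
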