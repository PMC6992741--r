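---
title: "Methods: integrating miRNA-target predictors into one meta-classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating miRNA-target predictors into one meta-classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeta)
```

## The problem

Dozens of tools predict whether a microRNA silences a given mRNA, and they
disagree often enough to confuse anyone who runs more than one of them.
Each tool sees a different slice of the evidence: duplex free energies,
seed-match classes, conservation, site accessibility, alignment scores,
learned probabilities. `mirmeta` treats those heterogeneous outputs as the
*input features* of a second-level classifier: a soft-margin SVM trained on
a fixed-order numeric encoding of eleven established predictors' results
(RNA22, RNAhybrid, TargetScan, PITA, miRanda, RNAduplex, microT-CDS,
STarMirDB, PACCMIT-CDS, MBSTAR, TarPmiR). The package does not run those
tools; it consumes their outputs through a long-format interchange table
(`mirna_id, target_id, tool, field, value`), so any upstream pipeline that
can produce a TSV can feed it.

## The evaluation panel and the CHL index

Binary evaluation starts from the four outcome counts TP, FN, FP, TN and
the usual ratios: sensitivity $Sn = TP/(TP+FN)$, specificity
$Sp = TN/(TN+FP)$, accuracy, precision, the F1 score and the Matthews
correlation coefficient (MCC). Accuracy and F1 both fall to the accuracy
paradox on imbalanced data; MCC resists it but rewards degenerate
all-negative predictors with respectable scores when negatives dominate.
The panel therefore also carries the CHL index, the harmonic mean of
accuracy, normalized MCC ($MCC' = (MCC+1)/2$) and F1:

$$ CHL \;=\; 3\,\frac{Acc \cdot MCC' \cdot F_1}
        {Acc \cdot MCC' \;+\; MCC' \cdot F_1 \;+\; F_1 \cdot Acc} $$

Sitting between F1 (positive-focused) and MCC (symmetric), it weights the
positive class — the scientific object of interest in target prediction —
without ignoring the negatives.

Degenerate cases are handled with two distinct conventions, matching how
published benchmark tables print them:

* **MCC with a zero denominator is 0.** An all-negative or all-positive
  predictor has an undefined MCC ratio; the panel reports 0, the value MCC
  approaches for uninformative predictors.
* **Precision, F1 and CHL are undefined (`NA`, printed `"null"`)** when no
  positive call was made (`TP + FP = 0`). They are not zero: the quantity
  has no value, and reports say so explicitly.

Values are carried at full precision; only report writers round, half away
from zero, to 4 decimals — the convention of the published tables the
package can verify (`verify_panel_identities()`). Because printed tables
round their own inputs, a cell recomputed from other printed cells can
legitimately differ by one unit in the fourth decimal; the verifier's
default tolerance is exactly that one printed ulp, and anything beyond it
is flagged as a genuine inconsistency (the shipped fixture contains one
such typo, in an MCC cell whose row's CHL confirms the printed MCC').

`counts_from_rates()` inverts printed Sn/Sp back to integer counts for
known class sizes; ties (a rate exactly between two counts) resolve to the
larger count — an arbitrary but fixed convention.

## Energy-stratified training sets

Curated interaction databases contain positives only. The builder derives
labelled training sets from binding free energy (kcal/mol, more negative =
more stable), on the premise that a miRNA's most stable recorded pairs are
its most trustworthy positives and its least stable ones behave like
negatives for training purposes. This is a *stability convention*, not
biological truth, and the documentation of `build_training_set()` says so.

* **trA** — per miRNA: most stable pair (positive) + most unstable pair
  (negative); 2 records per miRNA.
* **trB** — the two most stable vs the two most unstable; 4 per miRNA.
* **trC** — the extremes plus the two unused candidates nearest the
  per-miRNA *median* energy, the more stable of which joins the positive
  half. "Mid-range" has no canonical definition; nearest-the-median with
  ties to the more stable candidate is this package's documented heuristic.
* **trR** — a seeded uniform random sample, as a baseline.

When a miRNA has too few candidates to fill its quota (e.g. a single
recorded target), the deficit is filled with the next most extreme unused
pairs from other miRNAs, in deterministic order, keeping totals at exactly
2 (trA) or 4 (trB/trC) records per miRNA whenever the table allows. With
2,588 miRNAs this reproduces the reference sizes 5,176 and 10,352.

Negatives beyond the stability convention come from
`generate_negatives_by_permutation()`: uniform draws from (miRNA x gene
universe) minus the known positives — the standard mock-negative
construction. `enforce_pn_ratio()` subsamples to an exact P/N ratio; 1:1
is the default, the ratio that proved best for this design.

## Feature encoding

`default_registry()` defines the feature vector: 83 dimensions across six
categories (energy, scoring function, evolution evidence, binding type,
sequence property, structure). Six encoding kinds cover everything the
eleven tools emit:

* continuous scores/energies copied as numerics;
* binary flags (conservation, seed match, m/e motif, and each tool's own
  binding call);
* binding positions normalized by target length into [0, 1] — including
  the position-only tools PITA and MBSTAR, for which no range information
  exists and a normalized scalar is this package's choice of encoding;
* one-hot groups for miRanda's 4 score/conservation classes and
  STarMirDB's 6 region/seed classes;
* the 7-dimensional seed-type indicator. The canonical seven are
  configurable; the shipped default (8mer, 7mer-m8, 7mer-A1, 6mer,
  offset-6mer, CDS-seed, seedless) covers the classes commonly reported by
  seed-aware tools, ordered strongest first;
* nucleotide composition (A/C/G/U fractions and AU content) of the bound
  target subsequence, computed from each site-reporting tool's
  coordinates. Coordinates are 1-based inclusive on the target, 5'→3'.

**Missing is zero.** A pair with no record from a tool contributes 0 in
every dimension sourced from that tool. This keeps sparse tool coverage
from invalidating pairs and matches how the upstream encoding handles
absent predictions. The zero is imputation, not information: a model can
in principle confuse "tool silent" with "tool reported zero", which is why
each tool's binary call is also a feature. The registry is a config
artifact (YAML round-trip via `read_registry()`/`write_registry()`), so
registry size is whatever the config defines; the shipped default covers
every feature family above, not any particular historical layout.

## Feature selection: mRMR (MIQ) + IFS

Ranking uses minimum-redundancy-maximum-relevance under the quotient
scheme: the first feature maximizes mutual information with the label;
each later feature maximizes relevance divided by mean MI with the
already-selected set. Choices the literature leaves open, fixed here:

* MI is the plug-in estimator in bits after equal-frequency discretization
  into 10 bins (binary/indicator columns bypass binning). Equal-frequency
  is robust to the heavy tails of score distributions; 10 bins is the
  usual bias/variance compromise at the sample sizes involved.
* The redundancy denominator is floored at $\varepsilon = 2^{-20}$ bits,
  since selected sets can contain zero-MI pairs.
* All ties break lexicographically by feature name, making the ranking a
  pure function of the data.

One subtlety of MIQ worth knowing: if a feature equals the label exactly,
every other informative feature has relevance = redundancy (all its label
information *is* label information), so quotients collapse toward 1 and
ordering among them is tie-breaking, not signal. With realistic (noisy)
features the quotient behaves as intended, and the test suite pins the
ranking to an exhaustive greedy oracle on small matrices.

Incremental feature selection then evaluates every prefix of the ranking
by k-fold cross-validated CHL (one fixed seeded fold assignment reused
across prefixes) and keeps the *smallest* prefix attaining the curve's
maximum. Prefixes where training fails or the pooled CHL is undefined are
excluded from the argmax rather than treated as zero.

## The meta-classifier

Features are min-max scaled to [0, 1] with parameters learned on the
training fold only and clipped on application. The SVM is `e1071::svm`
(libsvm) with RBF kernel, cost 1 and `gamma = 1/n_features` — the standard
defaults, deliberately not grid-searched so that every reported number is
exactly reproducible from a seed. The decision rule is the classifier's
sign; no probability calibration.

Cross-validation uses stratified folds (per-fold class counts within one
record of global proportions) and **pools** the out-of-fold confusion
counts into a single panel instead of averaging per-fold metrics: pooling
keeps the panel defined even when a small fold happens to be degenerate,
and the pooled counts identity (`sum of fold counts = total`) is asserted
in the tests.

`evaluate_tool_panel()` scores any upstream tool's raw calls on the same
truth, with an explicit missing-prediction policy. The default,
`missing_as_negative`, counts unpredicted pairs as non-binding calls; the
alternative `exclude_missing` drops them, which can flatter a low-coverage
tool by silently shrinking its denominator — the distortion that makes
MCC comparisons across tools with different coverage misleading. Both
policies are reportable side by side.

## The synthetic study generator

The generator exists so the entire pipeline runs and is testable offline.
It emulates:

* ground-truth interactions: each of `n_mirnas` miRNAs gets
  `targets_per_mirna` true targets from a shared gene universe, plus
  permutation negatives (default: as many as positives);
* a two-component Gaussian energy model, default −25 ± 3 kcal/mol for
  interacting and −12 ± 3 for non-interacting pairs: overlapping unimodal
  components, the interacting one more stable, in the physically plausible
  range for miRNA:mRNA duplexes;
* per-tool outputs: each tool covers a Bernoulli fraction of pairs
  (default 0.9) and calls covered pairs per its sensitivity/specificity.
  The default per-tool operating points are spread to mimic the field —
  strong sequence/ML tools near 0.95/0.9, conservative tools near
  0.1–0.3 sensitivity with 0.97–0.99 specificity, energy tools in
  between. Score payloads are drawn from two overlapping distributions
  conditioned on the emitted call, so continuous features carry graded
  signal beyond the binary call;
* random RNA sequences at configurable GC content with in-bounds binding
  sites.

What it does **not** emulate: real sequence composition and homology,
correlated errors between tools that share methodology (simulated tools
err independently given the truth), energy-dependent tool behaviour, and
database biases. Passing tests on synthetic data therefore demonstrate
that the machinery is correct and that integration beats single tools
*when tools carry independent signal* — the integration premise — not
that any particular accuracy will be attained on biological data.

Every operation derives its RNG stream from the config seed plus a fixed
offset, so a study is bit-reproducible from one integer.

## Problem sizes and numerical choices in the shipped tests

The test suite and the acceptance script run the full pipeline at 50
miRNAs x 20 targets (100 trA records, 83 features, 10-fold CV with IFS
over all 83 prefixes), which completes in well under a minute on one
core; property suites over seeds (feature recovery, integration-vs-best
tool, data-quality monotonicity) use 30 x 8 studies with 5-fold CV, 10
seeds each. Structural checks of the builders run at the full reference
scale of 2,588 miRNAs. These sizes are the package's chosen trade-off
between statistical resolution and a test suite that stays fast enough to
run on every change.

## Known limitations

* The stability-convention labels of trA/trB/trC inherit whatever biases
  the input energies carry; the builder never validates energies against
  structure predictions.
* The MIQ quotient is scale-free but estimator-dependent; a different
  discretization changes rankings near ties.
* `missing_as_negative` conflates "not covered" with "predicted
  non-binding" by design; when coverage is the quantity of interest,
  evaluate both policies.
* The SVM defaults favour reproducibility over squeezing out the last
  percent; `svm_config()` exposes kernel, cost and gamma for tuning.
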