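---
title: "Methods: hierarchical PLS-DA annotation of EI mass spectra"
author: "eimsCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical PLS-DA annotation of EI mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eimsCascade)
```

## The problem

Novel synthetic cannabinoids appear on the illicit market faster than
reference standards can be produced, so a seized sample's GC--MS
spectrum often matches nothing in any library.  The spectra are still
informative: electron ionization fragments a synthetic cannabinoid at
predictable bonds, and the fragment masses betray its structural
moieties --- the *core* (indole, indazole, azaindole or
naphthoylpyrrole), the *head* (e.g. naphthyl) and the *tail* (e.g.
4-fluorobenzyl "FUB" or 5-fluoropentyl).  An indole core produces an
ion at nominal *m/z* 144 and an indazole or azaindole core at 145; a
naphthyl head gives 127 and 155; a FUB tail gives 109 and 252; a
5-fluoropentyl tail coupled to an indole or indazole/azaindole core
gives 232 or 233; classical (THC-related tricyclic) cannabinoids show
the familiar 41/69/73/91/175/231/260 pattern.

`eimsCascade` turns this fragment chemistry into a *hierarchical
system of binary classifiers*.  Rather than one multiclass model, a
cascade of seven two-class PLS-DA models asks a sequence of simple
questions, each trained only on the compounds that can reach it:

1. **cannabinoid vs other drug** (the root; all compounds);
2. **classical vs synthetic cannabinoid** (cannabinoids only);
3. **naphthoylpyrrole core vs the rest** (synthetics only; a positive
   terminates its branch);
4. **indole vs indazole/azaindole core**;
5. **naphthyl head vs other heads**;
6. **FUB tail vs other tails**;
7. **5F-pentyl tail vs other tails** (6 and 7 are independent
   siblings --- a compound may be negative for both).

A query spectrum is routed down this tree and emerges with a
structural annotation: *other drug*, *classical cannabinoid*, or
*synthetic cannabinoid* plus core/head/tail calls, together with every
executed node's discrimination score and threshold.

## Preprocessing

Spectra are (in this order) **base-peak normalized** to 100 --- so the
base peak is defined on the full spectrum before anything is discarded
--- then **cropped** to *m/z* 40--300 (inclusive) and **binned** to
unit mass by round-half-up of *m/z*, giving a 261-channel intensity
vector.  Both crop bounds are configurable; 40--300 is the default
because low-mass fragments below 40 are generic and masses above 300
are rare in this compound space.  Peaks rounding to the same integer
are summed, never averaged.  Each classifier then **autoscales** its
own training block (mean 0, variance 1 per channel, n−1 denominator);
channels with standard deviation below 1e−12 are dropped, and the mask
and scaling parameters are stored so prediction data are transformed
identically.  Autoscaling gives every channel equal a-priori weight,
which is what lets minor diagnostic fragments compete with base peaks
--- at the price of amplifying rarely-occupied channels, the main
failure mode discussed under *Limitations*.

## The PLS-DA model

Each node codes its classes +1/−1 and fits a univariate-response
partial least squares regression by NIPALS: per component, the weight
vector is the normalized covariance `X'y`, scores and loadings follow,
and both blocks are deflated.  For a single response NIPALS and SIMPLS
give identical models, so the algorithm choice is immaterial; NIPALS
is used and recorded.  The regression vector is
`B = W (P'W)^{-1} q`, and predictions are affine in the raw
(autoscaled) channels.  Latent-variable counts per node default to 3,
2, 3, 2, 2, 1, 2 in the node order above; the 5F-pentyl node's count
is not pinned by any published setting and defaults to 2, configurable
like the rest.  If the response is fitted exactly before the requested
number of components, the fit truncates to the achieved number rather
than failing --- small noiseless training sets reach this routinely.

Component signs are fixed by forcing each component's
largest-magnitude loading positive, so score plots and the
`lv_weights()` fragment-interpretation report are reproducible.

**Decision threshold.**  The boundary between the two classes is
placed where two Gaussians fitted to the class-wise training scores
(equal priors) have equal density --- the Bayes crossing.  When either
class variance collapses below 1e−12, or no crossing lies strictly
between the class means, the midpoint of the class means is used; with
several admissible crossings the one nearest that midpoint wins.  A
score exactly at the threshold is classified *positive* (documented
tie rule).  The Gaussian-crossing rule is fully specified,
deterministic, and reduces to the intuitive midpoint for symmetric
well-separated classes.

## Cross-validation

All cross-validation uses **venetian blinds**: sample *i* (0-based, in
dataset order) goes to fold `i mod k`, with `k = 10` splits by
default.  The assignment is deterministic and depends only on `(n, k,
order)`; no stratification or reordering is applied (the simulated
datasets interleave classes by construction, and because the splitter
honors input order, sorting the input spectra by class before training
achieves stratified folds when that is wanted).  Node-level
CV re-estimates scaling, PLS fit and threshold inside every fold, with
the variable mask held fixed.

## Genetic-algorithm variable selection

Most of the 261 channels carry no class information, and PLS will
happily spread small weights over them.  Every node except
classical-vs-synthetic therefore runs a genetic algorithm over binary
channel masks before the final fit (for the classical-vs-synthetic
split, variable selection is disabled by default: the classical class
shows many peaks across the whole range and selection was found to
hurt external prediction --- over-selection discards channels that
matter for unseen compounds).

The GA uses a population of 64 chromosomes, window width 1 (one gene
per channel), per-gene mutation probability 0.005, initial inclusion
probability 0.3, double-point crossover, tournament selection of size
2, elitism of 1, and at most 50 generations.  **Fitness** is the
venetian-blinds RMSECV of the PLS-DA discrimination score against the
±1 coding, on the masked channels; an empty mask scores `+Inf`.

Two safeguards address over-selection:

* **Parsimony banding.**  RMSECV values within a 2% relative band are
  treated as ties and ranked by variable count, smaller first --- a
  one-standard-error-style rule.  Without it, once a population
  reaches the RMSECV floor (common: many masks cross-validate almost
  perfectly) selection pressure vanishes and the mask drifts at its
  random initialization density, retaining dozens of noise channels
  whose autoscaled values are unstable on new data.  With banding, the
  search keeps pruning channels that only fit fold noise while real
  fitness differences (>2%) still dominate.
* **Stall-based early stopping and a final guard.**  Where the
  original workflow monitored GA runs by hand to stop before
  overfitting, the package stops automatically when the incumbent has
  not improved for 10 generations (configurable, `Inf` disables), and
  if the final mask cross-validates worse than the full channel set
  the model falls back to all variables with a warning.

Given the data, configuration and seed, the whole search is exactly
reproducible; `fitness_history` records the best-so-far RMSECV (a
non-increasing curve, guaranteed by elitism) and the population mean
per generation.

## Figures of merit

Node performance is reported as the five standard binary figures:
accuracy, true positive rate TP/(TP+FN), true negative rate
TN/(TN+FP), F1 = 2TP/(2TP+FP+FN), and Matthews correlation
coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with MCC defined as 0 when any factor under the radical vanishes,
while TPR/TNR raise an explicit error when their class is absent.
`evaluate_bundle()` lays these out as one row per node per evaluation
set (calibration / cross-validation / external validation), with
misclassified compound ids attached.  Reported tables round half-up to
4 decimals; note that published MCC values in this field are sometimes
truncated rather than rounded, so automated comparisons should allow
5e−4.

## The synthetic spectrum generator

Because curated spectral libraries cannot be redistributed, the
package ships a generator (`generate_dataset()`) that emulates
unit-mass EI spectra from the diagnostic fragment tables above.
Twelve compound classes cover every cascade node: six synthetic
cannabinoid classes (indole/naphthyl/pentyl "JWH-like", indole + 5F,
indazole + FUB, indazole + naphthyl, azaindole + 5F, naphthoylpyrrole
core), classical cannabinoids, and five non-cannabinoid classes
(fentanyl-, cathinone-, tryptamine-, phenethylamine- and opioid-like)
built from their literature fragment sets.  Core and tail stay
chemically coherent: a fluorinated tail couples to the 232/233 core
fragment, a plain pentyl tail to 214/215.

Defaults (all configurable in `sim_config()`):

* **36 training and 8 test compounds per class** (432 / 96 spectra),
  matching the scale of the curated libraries this workflow targets;
  train and test ids are disjoint.
* **Intensity jitter**: multiplicative log-normal, σ = 0.25 --- about
  ±25% one-sigma variation, a plausible inter-instrument spread.
* **Peak dropout**: each characteristic peak other than the class base
  peak is missing with probability 0.05.
* **Noise peaks**: 15 per spectrum at unoccupied channels, uniform
  intensity up to 20 (base peak = 100).  Noise never lands on the
  compound's own characteristic channels, but may coincide with
  *another* class's diagnostic channel --- the realistic confusion
  mode (a stray peak at 232 mimics a 5F tail).

Characteristic-peak mean intensities are synthetic choices, not
measurements; they give diagnostic peaks relative abundances of
roughly 35--100.  The generator makes no attempt at physical
fragmentation simulation, isotope patterns, adducts, class imbalance,
or correlated intensities between fragments of one cleavage event.
Consequently, passing the synthetic end-to-end checks demonstrates
that the pipeline's machinery (preprocessing, selection, fitting,
thresholding, routing, evaluation) is correct and robust to this noise
model --- it does *not* certify performance on real library spectra,
whose intensity structure is richer.

With jitter, dropout and noise all zero the twelve classes are
linearly separable in the binned space by construction, so a correct
implementation must reach MCC 1.0 at every node on held-out data; the
test suite asserts exactly that, and asserts held-out MCC ≥ 0.9 per
node under the default noise regime.

## Numerical choices and degenerate inputs

* Nominal-mass assignment is round-half-up (`floor(x + 0.5)`), never
  banker's rounding; ties are summed.
* Zero-variance channels are dropped (not epsilon-padded) and the drop
  mask is stored with the model.
* `fit_pls` requires `1 ≤ n_lv ≤ min(n−1, p)` and a non-constant
  response; exhaustion of the deflated blocks truncates the component
  count.
* The GA's RMSECV treats a PLS failure inside a fold (e.g. a mask with
  no covariance left) as fitness `+Inf`.
* Thresholding falls back to the class-mean midpoint under variance
  collapse, and warns when the two score distributions are identical.
* A node with fewer than 4 training samples in either class is skipped
  with a warning; routing marks any annotation that needed a skipped
  node as *partial*.
* Bundles serialize to JSON (`jsonlite::serializeJSON`) with full
  numeric precision; identical training inputs give byte-identical
  bundle files, and no timestamps are embedded.

## Problem sizes used by the automated checks

The test suite and the acceptance script run entirely on generated
data: the cascade checks use the generator defaults (432 training / 96
test spectra); the PLS--least-squares oracle uses 20 random 12×5
problems; the Ward-clustering oracle compares 100 random problems of
up to 8 points against exhaustive minimum-variance merges; the GA
recovery check plants 3 informative channels among 261 (n = 60) and
repeats the search over 20 seeds.  These sizes were chosen to exercise
every code path at the scale the method targets while keeping a full
run in the minutes range on a single core.

## Known limitations

* Autoscaling amplifies sparsely occupied channels; with small
  training cohorts this is the dominant error source, and it is the
  reason variable selection (with the parsimony rule) matters.
* The decision threshold assumes roughly Gaussian class score
  distributions; heavily multimodal classes would be served poorly.
* The cascade takes hard decisions at every node --- scores are
  reported but not propagated as probabilities, and an early wrong
  turn cannot be recovered downstream.
* Binary nodes never abstain: a compound class absent from training
  (e.g. a new core group) will be forced into the nearest existing
  label.
* The generator's fidelity claims are limited to "sufficient
  statistical structure to exercise the pipeline"; real intensity
  distributions of library spectra are not modeled.
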