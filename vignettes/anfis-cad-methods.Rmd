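---
title: "Neuro-fuzzy classification and guideline trees for thyroid nodules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-fuzzy classification and guideline trees for thyroid nodules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfiscad)
```

## The problem and the method in brief

Ultrasound risk stratification of thyroid nodules (the TIRADS family of
guidelines) rates a handful of sonographic features to decide which nodules
need fine-needle aspiration biopsy. `anfiscad` implements a computer-aided
alternative that uses a much wider 27-sign coding of the sonographic
appearance: a first-order Takagi–Sugeno fuzzy inference system (ANFIS) is
trained to map the coded signs to a malignancy score, and a Gini decision
tree over the same signs is grown, prepruned, and exported as a
human-readable risk-stratification flowchart.

The training method of interest is a real-coded genetic algorithm (GA) over
the full ANFIS parameter vector; gradient backpropagation (BP) and the
classical hybrid least-squares/gradient scheme (HB) are included as
comparators, all minimizing the same root-mean-square error (RMSE) between
the continuous model output and the 0/1 histopathology label
(benign = 0, malignant = 1).

## The ANFIS model

Each of the `n_rules` fuzzy rules (default 10) owns one Gaussian membership
function per input dimension, a consequent coefficient vector and a bias.
For input $x \in \mathbb{R}^d$:

$$w_i = \prod_{j=1}^{d} \exp\!\left(-\frac{(x_j - c_{ij})^2}{2\sigma_{ij}^2}\right),
\qquad \bar w_i = \frac{w_i}{\sum_k w_k},
\qquad \hat y = \sum_i \bar w_i\,(p_i^\top x + r_i).$$

A nodule is called malignant when $\hat y \ge 0.5$; the boundary goes to
malignant, the conservative choice for a cancer screen.

**Why one membership function per rule rather than a grid partition.** A
grid partition with 10 membership functions per input would generate
$10^{27}$ rules for the 27-sign model — combinatorially impossible, and
inconsistent with the sizes of the three models actually optimized, which
are 820, 400 and 250 free parameters for 27, 13 and 8 inputs. Those counts
are reproduced exactly by a cluster-style rule base of 10 rules, each with
one Gaussian per input: $2 d \cdot 10$ premise parameters plus
$(d + 1) \cdot 10$ consequent parameters. `parameter_count()` implements
this arithmetic and the test suite pins all three values. The rule count is
configurable; 10 is the default throughout.

**Input scaling.** Raw sub-feature codes (and the two continuous signs,
nodule size P1 and the diameter ratio P10) are min–max scaled to $[0,1]$
per dimension using training-set extrema. The extrema travel with the model
so test data are mapped identically — Gaussian premises need commensurate
axes. Dimensions that are constant in training map to 0.5.

**Numerical guards.** Premise spreads are clamped to
$\sigma \ge 10^{-3}$ (on the scaled axis) everywhere a model is built or
decoded, so memberships never collapse to a point mass. Rule strengths are
accumulated in log space and shifted by the row maximum before
exponentiation, so the normalization $\bar w$ is well defined even when all
raw strengths underflow (e.g. inputs far outside the training range).
Conditional signs that do not apply to a nodule are coded 0, below every
defined sub-feature code.

## Fuzzy c-means initialization

All trainers start from the same model built by `anfis_init()`:

1. Bezdek fuzzy c-means on the scaled inputs, fuzzifier $m = 2$, tolerance
   $10^{-5}$, at most 200 iterations, initial partition drawn from seeded
   uniform randoms normalized row-wise. The alternating updates make the
   objective non-increasing; the per-iteration trace is kept and asserted in
   tests. Zero distances are floored at $10^{-12}$ so the membership update
   is always defined.
2. Rule $i$ takes cluster center $i$ as premise centers, and the fuzzily
   weighted spread
   $\sigma_{ij} = \sqrt{\sum_k u_{ki}^m (x_{kj} - c_{ij})^2 / \sum_k u_{ki}^m}$
   (clamped to the floor) as premise spreads.
3. Consequents are set by one global ridge least-squares solve
   ($\lambda = 10^{-8}$, the same step the hybrid trainer uses), so the
   starting model is consequent-optimal given its premises.

The fuzzifier, tolerance and spread formula are this package's documented
defaults; they are the standard choices where the method description is
silent.

## The three trainers

**Genetic algorithm** (`train_ga`). The encoded parameter vector is the
chromosome; fitness is training RMSE. Defaults are the study settings:
100 generations, population 50, crossover rate 0.4, mutation rate 0.15, one
elite. The unstated operators are filled with standard real-coded practice:
tournament-2 selection; whole-arithmetic crossover
($\beta p_1 + (1-\beta) p_2$ and its complement, $\beta \sim U(0,1)$),
applied to a fraction `crossover_rate` of parent pairs; per-gene Gaussian
mutation with sd equal to 10% of the gene range. Gene bounds — centers in
$[-0.25, 1.25]$, spreads in $[10^{-3}, 2]$, consequents in $[-10, 10]$ —
are enforced by clipping the offspring of crossover and mutation. The
initial population is the FCM-initialized template plus mutation-scale
Gaussian perturbations of it, deliberately *not* clipped: the least-squares
consequents of an ill-conditioned rule design can legitimately exceed the
search bounds, and elitism must be able to preserve that consequent-optimal
start (clipping the template can degrade its RMSE by an order of
magnitude). The bounds therefore delimit where the GA *searches*, not what
it may *inherit*. Elitism makes the best-fitness trace non-increasing,
which is asserted every generation in tests. Stopping is by iteration count
only.

**Backpropagation** (`train_bp`). Full-batch gradient descent on the RMSE
over all parameters with classical momentum
($v \leftarrow \mu v - \eta \nabla E$, $\theta \leftarrow \theta + v$),
defaults $\eta = 0.2$, $\mu = 0.4$, 100 epochs. Gradients are analytic
through the five layers and are checked against central finite differences
to $10^{-5}$ relative error. Two behaviors are worth knowing: (i) because
the objective is a *root* mean square — a norm — its gradient magnitude does
not vanish at the minimum, so fixed-step descent settles into an
oscillation whose radius scales with the learning rate; reduce $\eta$ when
you need a tight fit on a well-conditioned problem. (ii) From a strongly
ill-conditioned least-squares start (consequents in the hundreds, as the
27-sign synthetic cohort produces), fixed-step BP can oscillate at a large
RMSE — the instability that motivates both the hybrid scheme and the GA. A
guard aborts with a diagnostic if the RMSE exceeds $10^6$.

**Hybrid** (`train_hybrid`). Each epoch solves all consequents exactly by
ridge least squares on the design matrix whose row $k$ concatenates
$\bar w_{ik} [x_k, 1]$ over rules, then takes one BP momentum step on the
premise parameters only; a final least-squares pass leaves the returned
model consequent-optimal. The least-squares step is verified in tests
against brute-force numeric minimization over the consequents.

## Evaluation protocol

Malignant is the positive class. Accuracy, sensitivity and specificity are
reported as percentages; an undefined ratio (a test set without one class)
is reported as `NaN` with a warning, never silently zeroed. Four splitting
schemes are provided: 70/30 and 80/20 holdouts and 5-/10-fold cross
validation, all stratified by default — with 28.6% benign prevalence an
unstratified small test set can be degenerate. K-fold metrics pool the
test-fold confusion counts (bias-free for sensitivity and specificity with
unequal fold compositions); `per_fold = TRUE` switches to averaging
per-fold percentages for comparison. Report tables round half-up to two
decimals. `aggregate_mean()` averages metric rows the way the published
per-classifier summary averages its twelve scheme-by-signset experiments;
the test suite reproduces all four published summary rows from the shipped
benchmark grid (`reference_metrics()`).

## The guideline tree

A CART-style binary tree with Gini impurity $1 - \sum_k p_k^2$. Candidate
thresholds are midpoints between consecutive observed values of each sign —
coded sub-features are treated as ordinal numerics, matching how branch
numbers reference the code table. Ties are broken toward the lowest sign
index, then the lowest threshold, making growth fully deterministic.
`best_split()` is verified against exhaustive search on small tables.

Growth is best-first: the frontier leaf whose best split has the largest
*node-fraction-weighted* impurity decrease
($\frac{n_{node}}{n_{root}} \Delta_{Gini}$) is expanded first. The
weighting is the CART convention and has two consequences we rely on: a
7-split prepruning budget is spent where it reduces impurity most, and sign
importances (the summed weighted decreases per sign) add up exactly to the
tree's total impurity reduction, a conservation law asserted in tests.
Unbudgeted growth continues until every leaf is pure or admits no
positive-decrease split. Leaves carry the majority class with ties to
malignant. There is no minimum leaf size and no postpruning. The fitted
tree exports as an indented text flowchart phrased in sub-feature code sets
and as a Graphviz DOT document.

`rank_signs()` ranks all 27 signs by importance from the unpruned tree;
`top_signs(ranking, 13)` reproduces the reduced-input workflow in which the
13 highest-ranked signs are re-modeled. Which signs land in the top 13 is
data-dependent, so the package takes sign subsets as explicit arguments
rather than hard-coding any list.

## The synthetic cohort generator

The clinical cohort behind the published numbers (398 nodules, 284
malignant / 114 benign) is not publicly deposited, so the package ships a
seeded generator, `generate_nodules()`, whose defaults emulate the
documented study conditions: the exact class sizes, the full 27-sign coding
schema, and class-conditional enrichment of the high-risk sub-features
(solid composition, marked hypoechogenicity, taller-than-wide shape,
irregular edges, punctate calcification, capsule interruption, suspicious
or metastatic lymph nodes, and the rest of the consensus list). One knob,
`risk_lift` $\in [0,1]$ (default 0.8), sets how strongly high-risk codes
concentrate in malignant nodules: each ordinal sign is drawn from
$(1-\text{lift}) \cdot \text{Unif(codes)} + \text{lift} \cdot
\text{Unif(high-risk codes)}$ for malignant nodules and with the lift
routed to the complement for benign ones, so `risk_lift = 0` makes every
sign independent of the label. Signs with no consensus risk direction are
uniform in both classes.

Invented conveniences, flagged as such: nodule size P1 is log-normal
(median 12 mm, 0.5 log-units spread, both classes — size carries no signal
here, matching its "no consensus" status); the diameter ratio P10 is
normal(0.85, 0.15) benign versus normal(1.05, 0.15) malignant. Conditional
signs are gated minimally: P7/P8 apply only when P6 shows any
calcification or microechogenicity, P9 only under incomplete peripheral
calcification (P6 codes 8 or 10), P12–P14 only when a capsule relationship
exists (P11 ≠ 1), and P19 only when the composition has a cystic component
(P2 codes 2–8); gated-off signs are coded 0.

**What passing tests do and do not show.** Generated signs are
conditionally independent given the class; real sonographic signs are
correlated (a spiculated margin co-occurs with hypoechogenicity), and real
code distributions are far from uniform. Tests on this generator therefore
validate the *machinery* — training dynamics, protocol arithmetic, tree
growth — and the qualitative ordering of methods, not clinical performance.
Metrics on synthetic cohorts at `risk_lift = 0.8` tend to run higher than
the published clinical values because independent enriched signs are an
easier problem than correlated clinical data.

## Problem sizes used by the test suite

The suite exercises the full study conditions where the claim demands it
and small instances elsewhere: the 10-fold GA evaluation runs on a default
synthetic cohort (398 nodules, 27 signs, 10 rules, GA at 100/50/0.4/0.15);
the parameter-recovery benchmark uses a 1-input, 2-rule generating model
with 200 points; the monotonicity-in-`risk_lift` check averages three
seeded 70/30 holdouts with a reduced GA budget (30 generations, population
30), which is ample to expose the ordering; oracle-equivalence checks use
instances of at most 3 rules and 30 samples where exhaustive or numeric
optimization is exact.

## Known limitations

* The BP trainer is faithful to fixed-step momentum descent and inherits
  its brittleness from ill-conditioned starts; it is a comparator, not the
  recommended trainer.
* The least-squares consequent solve uses a fixed tiny ridge
  ($10^{-8}$); on nearly collinear rule designs it returns large, genuinely
  loss-optimal coefficients that overfit — visible as a gap between
  resubstitution and held-out metrics.
* The guideline tree treats codes as ordered; a categorical-subset split
  (and postpruning) is out of scope.
* No ROC/AUC, calibration or confidence intervals — the protocol reports
  the three percentage metrics only.
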