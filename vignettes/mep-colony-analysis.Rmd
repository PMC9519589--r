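---
title: "Modeling MEP colony dynamics from single-cell tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling MEP colony dynamics from single-cell tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meptrace)
```

## The system and the questions

Bipotent megakaryocytic–erythroid progenitors (MEPs) plated singly in
semisolid colony-forming-unit (CFU) culture grow clones whose cells divide,
move, die, commit to the megakaryocytic (Mk) or erythroid (E) lineage, and —
for the Mk side — terminally mature by endomitosis. Long-term time-lapse
imaging with in-situ lineage-marker staining, followed by supervised cell
tracking, turns each colony into a rooted binary lineage tree with per-frame
positions and endpoint marker calls per cell. `meptrace` takes that tracking
output (a tab-separated track table, optionally with a CTC-style lineage
file) and answers, per colony and per cohort:

* which cells were bipotent, E-destined, Mk-destined, or already committed;
* how division outcomes (symmetric expansion, asymmetric maintenance,
  exhaustion) distribute over generations;
* how motile each cell state is;
* whether behavioral phenotype alone predicts state (PCA + clustering);
* how the probability of each division outcome changes with generation — a
  nonhomogeneous Markov chain with exhaustion absorbing.

A seeded colony simulator generates track files with known ground truth so
that every stage is testable without any imaging data.

## Fate inference by back-propagation

Leaves are identified from endpoint evidence: CD41 marks Mk; bright CD71 or
CD235a marks E (bright CD71 is usable days before CD235a becomes
detectable); endomitosis is terminal Mk maturation and counts as Mk even
without a marker. Every internal cell is then labeled from the set of
lineages among its identified descendant leaves: both lineages means the
cell was upstream of both Mk and E progeny (bipotent); one lineage means
lineage-destined; none means indeterminate. Cells carrying both an Mk and an
E marker are contradictory evidence: they are labeled indeterminate and
reported, never dropped silently. Trees grown from sorted unipotent ErP/MkP
controls are labeled committed throughout; a sorted-MEP tree whose progeny
are all one lineage is labeled lineage-destined, not reclassified as a
sorting error — single-lineage colonies from true bipotent cells are an
expected outcome of early exhaustion.

Two caveats follow directly from the definition. First, the labels are
*realized-fate* labels: a bipotent cell whose exhaustion division happened
to produce two E daughters is — correctly, by this rule — labeled E-destined.
Second, inference degrades with censoring: a bipotent branch cut by the
movie end looks single-lineage or indeterminate. Exact statements about
label fidelity are therefore made on *fully marker-resolved* cells (every
descendant leaf carries evidence; see `fully_resolved_cells()`), where the
test suite verifies exact agreement with simulator ground truth.

Division outcomes follow from daughter labels: two bipotent daughters =
expansion; one = maintenance (toward E or Mk by the committed daughter); none
= exhaustion, the absorbing outcome. Divisions touching an indeterminate
cell are excluded and tallied, and every kinetics table carries that tally.

## Generation and censoring conventions

The plated cell is generation 1 and a division is indexed by the generation
of the dividing cell, so divisions occur at generations 1..13 when 13
generations are tracked. Cells ending in `lost` or `movie_end` are censored:
excluded from death-rate numerators and denominators by default (a flag
includes them), excluded from exhaustion calls, and terminating division
sequences with a censoring flag. Death rates are pooled over colonies by
default with a per-movie option, since the original figure's denominators
are not fully specified.

## Motility metrics

Per cell, over its lifetime trajectory: total distance (sum of per-frame
Euclidean steps), diffusion distance (straight line, first to last
position), directionality (total over diffusion, `NaN` when the net
displacement is zero; such cells are excluded from clustering and counted),
and peak velocity (largest per-interval displacement over that interval's
actual duration). The acquisition schedule is deliberately non-uniform (one
frame in the unimaged first 24 h, 2-h frames to 60 h, 10-min frames after),
so peak velocity always uses each frame pair's true time difference and no
smoothing is applied. All metrics are invariant to rotation and translation
and are checked against an independently coded brute-force oracle at
1e-9 relative tolerance.

Note one sampling property: the measured path length of a diffusive cell
grows with the frame rate (finer sampling resolves more of the path), so
total distance and peak velocity are only comparable between cells imaged at
the same schedule phase. The clustering benchmark cohorts therefore use a
uniform frame interval.

## Behavioral phenotype clustering

Features are peak velocity, total distance, lifespan and directionality,
z-scored (they differ by orders of magnitude in units). PCA
(`stats::prcomp`) is used for reporting and visualization; clustering runs
in the standardized feature space, not on PC scores, for scale consistency
— an option the reader can revisit by clustering the exported scores. The
number of clusters is chosen by cutting a Ward-linkage dendrogram at
k = 2..8 and maximizing the mean silhouette width (`cluster::silhouette`),
deterministically; k-means (best of 25 seeded restarts) partitions the
cells; the report is the state-by-cluster count table with row percentages
(each state's row sums to 100%, matching the "84% of ErPs in cluster 2"
style of statement) and the predominant cluster per state.

A methodological caution established by the package's own synthetic
benchmarks: on trajectory-derived features the silhouette criterion is
genuinely unstable between k = 2 and k = 3. Two structural reasons: (i) the
features are multiplicative in the motility scale, so after z-scoring the
most motile state's within-cluster spread is commensurate with the gaps
separating the less motile states; (ii) the directionality of a pure
isotropic random walk is a ratio with an inverse-Rayleigh tail — its
variance is infinite, so a few extreme values dominate the standardization.
Persistent (drifting) motion removes the second pathology, which is why the
benchmark cohorts give committed states a modest drift; even so, the k = 3
claim is asserted as the modal choice over replicate cohorts, and for real
analyses we recommend fixing `k` explicitly (the package exposes it
everywhere) rather than trusting the automatic choice.

## The nonhomogeneous Markov fate model

Each bipotent division at generation g has outcome
o ∈ {expansion, maintenance_E, maintenance_Mk, exhaustion} with multinomial
logit probabilities

  P(o = j | from-state i, g) = softmax_j( α_ij + β_ij · log g ),

expansion being the reference category (η = 0). The log-generation covariate
is the discrete-time counterpart of a Weibull log-hazard, which is linear in
log time — natural here because exhaustion is a "time to failure";
β = 0 recovers the homogeneous chain. Exhaustion is absorbing: it never
appears as a from-state and simulated chains stop there. Time is the
discrete generation index, not clock hours: the predictions of interest are
per-generation outcome probabilities for 13 generations, and clock time is
recorded but unused by the model.

The from-state of a division is the outcome of the division that created the
dividing cell (`start` for the plated cell). The default model gives every
from-state its own coefficients; `shared = TRUE` fits the reduced,
from-state-independent model in which the outcome distribution depends on
generation only — the two are nested and comparable by likelihood ratio,
which is how the memoryless description can be tested rather than assumed.

The likelihood unit is the division event, not the root-to-exhaustion path:
expansion branches share prefixes, and a per-path likelihood would count
shared events twice. Sequence extraction (`extract_division_sequences()`)
is still provided for path-level descriptives and for the simulator.
Censored terminals contribute no outcome factor.

Estimation is Newton iteration from zero-initialized parameters with the
analytic gradient and Hessian; the multinomial-logit log-likelihood is
concave, so full Newton steps (with step halving, and a 1e-8 ridge on the
Hessian solve for directions left unidentified by the design, e.g. a
from-state observed at a single generation) converge in a handful of
iterations to a gradient norm below 1e-8. The covariance is the inverse
observed information. Outcomes never observed for some from-state drive
coefficients to the boundary and are flagged; total separation is flagged as
making intervals unreliable. Confidence intervals for predicted
probabilities use the delta method through the softmax by default, clamped
to [0, 1]; a seeded parametric bootstrap (outcomes redrawn at the observed
design, model refitted, percentile intervals) is available and agrees with
the delta intervals away from boundaries. Simulation-based checks in the
test suite verify ±0.05 parameter recovery at 500 sequences, ≈95% interval
coverage over 200 replicates, 5% ± 3% type-I error of the homogeneity
likelihood-ratio test and >0.9 power under strong generation dependence.

Two derived quantities: `first_division_exhaustion()` computes the expected
exhaustion probability at the first observed division if plated cells are an
equal mixture of generational ages 1..G (the arithmetic mean of the
per-generation exhaustion probabilities, G = 13 by default) — the model's
explanation for single-lineage colonies in static assays; and
`homogeneity_test()` formalizes the choice of a nonhomogeneous over a
homogeneous chain.

## The synthetic colony generator

`synthetic_config()` encodes the study conditions as defaults: lognormal
cycle times with means 15.8 h (bipotent), 15.5 h (E-destined), 25.5 h
(Mk-destined), 10.2 h (ErP), 35.7 h (MkP) and CV 0.3 (the source data give
means only; lognormal guarantees positivity and a realistic right tail);
15.7% of plated cells dying before progeny; per-cycle death probabilities
of 1–3% elsewhere, E-destined death from generation 6; a 2:1 E:Mk
commitment bias (π_E = 2/3); Mk-destined self-renewal for on average 2.5,
at most 5, committed generations before endomitosis; committed-E tracking
lost to crowding after 7 committed generations; marker onset CD71-bright
before CD235a; the three-phase acquisition schedule; and a first division
landing between 24 and 48 h (a fixed 24 h seeding delay plus one cycle).
Motility is a Gaussian random walk with state-dependent step scale ordered
MkP > bipotent > ErP, plus an optional per-state persistent drift
(default 0). Division outcomes are drawn from a `mep_markov` parameter
object; the default has expansion dominant in early generations and
exhaustion dominant late.

Exhaustion daughters follow one of two rules, because the source
definitions genuinely conflict: `mixed_pair` (always one E + one Mk, the
literal outcome-class definition) and the default `independent_draws` (two
independent π_E draws), which is the only rule that produces E-only and
Mk-only colonies from true bipotent roots and therefore reproduces the
observed colony-type spectrum. Under `independent_draws`, note that the
*observed* committed-daughter E fraction estimated from classified
divisions sits below π_E: same-lineage exhaustion pairs make their parent
look lineage-destined, so those divisions drop out of the classified
universe and the surviving exhaustion events are exactly mixed pairs. This
is a property of the estimator under the realized-fate definition, not a
bug, and disappears under `mixed_pair`.

Condition variants (`condition_variant()`) encode cytokine withdrawal
qualitatively: without TPO or EPO, death multiplies (×2 per-cycle, ×1.5 for
root death), cycles lengthen (×1.25 without TPO, ×1.1 without EPO), the
outcome model shifts toward earlier exhaustion (+0.7 on the exhaustion
intercept), and without EPO CD235a onset is suppressed; π_E is unchanged in
both, reflecting survival/self-renewal roles rather than fate instruction.
The magnitudes are free parameters chosen once to reproduce the qualitative
directions; the source quantifies directions, not effect sizes.

The generator emits exactly the track/CTC formats the readers consume, plus
per-cell ground truth with two truth columns: the hidden state and the
realized-fate label (computed by an independent bottom-up pass inside the
simulator), which is the right reference for label-inference fidelity under
`independent_draws`.

What the simulator does *not* emulate: pixel-level imaging and segmentation
error, spatially correlated motion and crowding mechanics, continuous
marker intensities (calls are binary at onset times), and cell-cycle
correlations between relatives. Passing tests on simulated data therefore
validate the analysis logic and its statistical calibration, not the
upstream tracking.

## Problem sizes and numerical choices

Test and acceptance runs scale the simulation down: cohorts of 100–250
colonies, movies of 120–400 h, a 2-h (or 1-h) late frame interval instead
of 10 min, and committed-E depth 2–4 instead of 7. These choices keep the
suite fast while preserving every generative mechanism; the full-schedule
defaults remain the package defaults. Where an exact-identity check needs
its stated precondition (no death, full marker resolution, all chains
exhausting inside the tracked range), the test constructs precisely that
configuration rather than loosening the assertion. Estimates of cycle-time
means from simulated cohorts window on birth time (birth earlier than the
movie end minus three mean cycles) so that end-of-movie truncation cannot
bias complete-cycle averages.

Ties in k selection go to the smaller k; k-means uses 25 restarts under a
fixed seed; the Newton fit is deterministic; all simulator randomness flows
from a single mandatory seed, and dataset files are byte-reproducible from
(config, seed).

## Known limitations

* Fate labels are realized-fate calls; hidden bipotency that never
  manifests is unknowable from marker evidence, and all fidelity guarantees
  are conditional on full marker resolution.
* The Markov model conditions on observed divisions; death and censoring
  remove events rather than entering the likelihood as competing risks.
* The automatic k selection should be treated as advisory on trajectory
  features (see above); fix k for confirmatory analyses.
* Newick export targets interchange and round-tripping; bracket comments
  carry labels and are ignored (not preserved) by some standard readers.
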