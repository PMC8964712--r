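---
title: "Transient brain-state analysis of power envelopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient brain-state analysis of power envelopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envhmm)
```

## The scientific problem

Resting-state electrophysiological activity is not stationary: band-limited
power envelopes switch among a small set of recurring spatial patterns on a
100--200 ms timescale. `envhmm` models these transient states with a
Gaussian-observation hidden Markov model (HMM) fitted to power envelopes
that have been standardized, concatenated across subjects and sessions, and
reduced by PCA whitening. Decoding the single most probable state sequence
(Viterbi) enforces the defining constraint that exactly one state is active
at every sample. Downstream, each state is summarized by four temporal
parameters per subject and session --- mean life time (MLT), fractional
occupancy (FO), mean interval length (MIL) and number of occurrences (NO)
--- and by a spatial map of partial correlations between its activation
course and the parcel envelopes. A companion behavioural module scores
finger-tapping performance, and a statistics module runs the non-parametric
battery relating state dynamics to motor performance before and after
learning.

## The model

Observations $y_t \in \mathbb{R}^d$ (component space, after whitening) are
modelled as

$$ y_t \mid s_t = k \sim \mathcal{N}(\mu_k, \Sigma_k), \qquad
   P(s_t = j \mid s_{t-1} = i) = A_{ij}, $$

with $K$ states, free means and full covariances, a row-stochastic
transition matrix $A$ and an initial distribution. Because envelopes are
standardized before fitting, states are distinguished chiefly by their
covariance structure, with means capturing residual level differences; the
richer free-mean model nests the covariance-only one.

Fitting is maximum-likelihood expectation-maximization (Baum--Welch) with
scaled forward--backward recursions. Inference details that matter:

* **Restarts and selection.** The EM is restarted `n_restarts` times
  (default 10) and the restart with the highest final log-likelihood is
  kept. This likelihood-based selection stands in for the variational
  free-energy criterion used by variational-Bayes HMM toolboxes: both pick
  the best run of a local optimizer, and every quantity this package
  reports (decoded paths, temporal parameters, transition structure) is a
  function of the selected parameters, not of the selection score itself.
* **Initialization.** Each restart initializes from a k-means clustering of
  a random 10\,000-observation subsample (restart $r$ seeded with
  `seed + r - 1`), with cluster means as state means, within-cluster
  covariances as state covariances and a sticky (0.9 self-transition)
  uniform transition matrix. Initializations built from per-sample random
  responsibilities were rejected: on long concatenations they place every
  initial state mean at the global data mean, which is an exact saddle
  point of the EM objective and can stall all restarts.
* **Numerical safeguards.** Each M-step adds a ridge of
  $10^{-6} \times \mathrm{mean}(\mathrm{diag}\,\Sigma_k)$ to every
  covariance, preventing collapse on short runs. The forward pass is
  scaled per sample; log densities are computed via Cholesky
  factorization. EM stops when the relative log-likelihood gain falls
  below `tol` ($10^{-6}$) after at least `min_iter` (10) iterations, or at
  `max_iter` (500); the minimum iteration count keeps the relative-gain
  test from firing during the slow early phase of symmetry breaking.
* **Determinism.** Viterbi ties are broken toward the lower state index,
  and the PCA sign convention (largest-magnitude loading positive) fixes
  the component basis, so identical inputs give bit-identical outputs.

## Preprocessing

The canonical path from raw oscillatory signals to HMM observations is:

1. `hilbert_envelope()` --- zero-phase (forward--backward) Butterworth
   band-pass, 4--30 Hz by default, then the analytic-signal amplitude.
   Zero-phase filtering introduces no group delay, so decoded state
   timings stay aligned with behaviourally meaningful time.
2. `moving_window_downsample()` --- left-aligned moving-window averages,
   100 ms windows sliding every 25 ms (75% overlap), so 1 kHz input yields
   an effective 40 Hz envelope rate. Windows are half-open with trailing
   partial windows discarded, giving exactly
   $\lfloor (N - W)/S \rfloor + 1$ outputs. The moving average is itself a
   low-pass operation and is the single canonical smoothing step.
3. `standardize_concatenate()` --- per recording (subject $\times$
   session): demean each parcel channel and divide all channels by one
   global standard deviation, then concatenate in time with a segment
   table recording provenance. Normalizing per recording (rather than
   once over the full concatenation, which would also be defensible)
   prevents between-subject amplitude differences from dominating state
   assignment.
4. `pca_whiten()` --- project onto the leading principal components
   (default 40) scaled to unit variance. Rank-deficient requests are
   reduced with a warning, never silently.

## Temporal parameters and state maps

`viterbi_decode()` returns mutually exclusive labels, which
`metrics_by_segment()` de-concatenates along the segment table before
computing, per subject, session and state:

* **MLT** --- mean duration of maximal runs of activation (seconds);
* **FO** --- fraction of samples active (sums to 1 over states);
* **MIL** --- mean duration of gaps strictly between consecutive visits
  (edges excluded; undefined, reported as `NA`, with fewer than two
  visits);
* **NO** --- number of visits.

Runs are cut at segment boundaries: a visit cannot span two recordings
that were merely concatenated. Undefined values propagate as explicit
missing markers; the statistical layer deletes them pairwise and reports
the effective $n$ per test.

Partial-correlation maps correlate each state's binary course with each
parcel's (standardized, parcel-space) envelope while controlling for the
other states' courses. Because the $K$ courses sum to one, the controlling
set must drop one course; the convention is fixed (drop the last course,
or the first when mapping the last state itself). The choice of dropped
course genuinely changes the conditioned-on set --- with exclusive binary
courses only $K-1$ independent activation signals exist --- so the
convention is recorded in the pipeline log, and the map of the
last (dropped) state should be read as the complement of the others.
Positive map values mean increased envelope power during visits. Maps are
computed on the full concatenation by default (states are defined at the
group level); because `partial_correlation_map()` is agnostic to sample
provenance, per-session maps are obtained by passing the samples of one
session, selected via the segment table. `map_display_threshold()`
implements the usual figure convention of masking values below a fraction
(60% by default) of each state's maximum absolute correlation.

## Behavioural indices

The finger-tapping task presents the cyclic 5-element sequence 4--1--3--2--4
in 30-s blocks (20 learning blocks, 2 post-interval test blocks). The
block score (`gpi()`) is correct presses per second, where a press is
correct iff it continues the cyclic sequence from the previous correct
press; the first correct press of a block may start at any cycle position,
as the task is continuous and blocks have no stated anchor. The exact
functional form of the original speed--accuracy composite is not public,
so the scoring hook is pluggable (`score` argument); every downstream
index depends only on GPI ratios and orderings. From block scores:
BL = mean of learning blocks 2--3 (block 1 is excluded for habituation,
but remains eligible for BMP), BMP = mean of the two best learning blocks,
LI = $100\,(\mathrm{BMP}-\mathrm{BL})/\mathrm{BL}$, and
BE = $100\,(\mathrm{best\ test} - \mathrm{BMP})/\mathrm{BMP}$.

## Statistics

* `paired_wilcoxon()` uses the classic signed-rank convention: zero
  differences discarded, average ranks for ties, $W$ = sum of positive
  ranks; exact p (signed-rank distribution) for $n \le 15$ without ties,
  otherwise a normal approximation with continuity and tie corrections.
* `spearman()` is the Pearson correlation of average ranks with the
  $t_{n-2}$ approximation for the two-sided p.
* Family corrections follow the exclusivity argument: with $K$ mutually
  exclusive states, $K-1$ courses are independent, so the state-wise
  family factor is $K-1$ (7 for $K=8$); the temporal-parameter family
  factor is 4; the full family is $4(K-1) = 28$. Corrected p-values are
  always $\min(1, p \times \mathrm{factor})$ with the factor reported in
  the output, never implicit.
* `compare_dependent_correlations()` tests equality of two dependent
  Spearman correlations by a subject-level bootstrap of the difference
  (assumption-light, valid for rank correlations; no standard closed form
  covers this dependent design). The two-sided p doubles the smaller tail
  of the bootstrap distribution around zero with the usual $+1$
  correction; measured type-I error at $n = 27$, 1000 resamples, is about
  0.03--0.06 at nominal 0.05.
* No automatic outlier exclusion is applied to state temporal parameters;
  extreme values are the user's call to investigate (the batteries report
  per-test $n$ so exclusions are visible).

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code that produces the study
conditions the analysis expects: 27 subjects by default, two 5-min
resting sessions at 40 Hz, 20 parcels, K = 8 states with distinct
low-rank-plus-diagonal covariances, geometric dwell times with a 150 ms
mean (inside the 100--200 ms transient range), plus finger-tapping logs.
Specific modelling choices:

* **Envelope positivity.** Observations are drawn in a latent Gaussian
  space and mapped through a softplus, since envelopes are non-negative
  amplitude signals while the downstream model is Gaussian after
  standardization. The default baseline (5 latent units) keeps the
  softplus near-linear, so planted covariances survive the transform to
  within a few percent. The softplus-Gaussian choice is a pragmatic
  stand-in, not a claim about the physics of band-limited amplitudes.
* **Dwell times are geometric** (first-order Markov), matching the HMM
  assumption and making parameter recovery well-posed.
* **Between-subject variation** shifts each subject's self-transition
  probabilities on the logit scale (SD 0.3 for the behaviourally coupled
  state, 0.1 elsewhere), and rows are renormalized by rescaling
  off-diagonal mass.
* **Behavioural coupling** uses a Gaussian copula on subject-level latent
  scores: the copula correlation $2\sin(\pi\rho_s/6)$ targets the Spearman
  correlation $\rho_s$ directly, which is the quantity the statistical
  layer estimates. The default $\rho_s = -0.5$ emulates the negative
  MLT--performance association typical of frontal/sensorimotor transient
  states; validation suites plant $+0.6$.
* **The planted learning effect** reduces the effect state's
  self-transition probability in the post session only (default state 1,
  size 0 unless requested), which jointly lowers MLT and FO, raises MIL
  and lowers NO --- the signature of a state visited less often and more
  briefly. A reduction of 0.15 from the 0.833 baseline moves group-mean
  FO by about 0.056, the regime the detection suites exercise.
* **The tapping generator** shrinks inter-press intervals and error
  probability exponentially across blocks toward skill-determined
  asymptotes (start 0.5 s and 25% error; asymptotes 0.40--0.25 s and
  10--4% depending on skill; lognormal interval jitter, SD 0.15), with a
  3% interval speed-up at the post-interval test blocks to model the
  offline boost. On an error the intended sequence position does not
  advance, modelling immediate correction. These rates were chosen once
  to give realistic block scores (2--4 correct presses/s) and learning
  curves that asymptote within 20 blocks.

What the generator does *not* emulate: sensor-space acquisition, head
movement or artifacts, non-geometric dwell distributions,
amplitude-envelope autocorrelation within a state beyond state switching,
or any spatial geometry of real parcellations. Passing recovery tests on
these cohorts therefore demonstrates the correctness of the estimation
machinery under the model's own assumptions, not robustness to every
violation real recordings exhibit.

## Problem sizes used in the validation suites

The bundled suites fit K = 4 states to cohorts of 27 subjects, two 300-s
sessions at 40 Hz and 20 parcels (648\,000 concatenated samples), with 2
restarts per fit and 3 independent cohorts --- sizes chosen so a full
recovery study completes in a few minutes on one CPU while retaining the
full per-subject session structure. Coupling recovery uses 200-subject
cohorts on ground-truth chains (no envelope synthesis) over 20 seeds;
effect detection uses 20 cohorts of 27 subjects; bootstrap calibration
uses 500 replicates of 1000 resamples.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  sim = simulation_config(n_subjects = 12, n_states = 3, n_parcels = 6,
                          session_duration = 120, effect_state = 2,
                          effect_size = 0.25, coupling_rho = -0.9,
                          subject_sd = 0.6, seed = 21),
  n_states = 3, n_restarts = 2, seed = 21)
res <- run_full_analysis(cfg, out_dir = "run1")
subset(res$prepost, parameter == "FO")
subset(res$brain_behaviour, session == "pre" & parameter == "MLT_s")
```

## Known limitations

* Inference is maximum-likelihood EM, not variational Bayes; there is no
  posterior over the state count, and K is a configuration input (no
  model-order search).
* The GPI functional form is a stated convention (correct presses per
  second), pluggable but not identical to the unpublished original.
* Partial-correlation maps depend mildly on the dropped-course
  convention; only $K-1$ maps are truly independent.
* The pre/post transition-matrix comparison is descriptive (difference
  matrices with the correction convention); no inferential test is
  defined for it.
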