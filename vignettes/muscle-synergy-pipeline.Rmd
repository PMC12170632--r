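---
title: "Extracting and comparing muscle synergies with emgsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and comparing muscle synergies with emgsynergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsynergy)
```

## The problem

During explosive overhead movements such as the badminton forehand overhead
smash, the central nervous system coordinates many shoulder muscles at once.
The muscle-synergy hypothesis holds that this coordination is modular: a small
number of fixed, nonnegative muscle weightings (synergies) are recruited by
shared time-varying activation coefficients. `emgsynergy` implements the full
analysis chain used to test this idea with two complementary data sources —
surface-EMG recordings and activations predicted by a musculoskeletal model —
and to quantify how well the two agree.

The model is non-negative matrix factorization (NMF): an activation matrix
$M \in \mathbb{R}_{\ge 0}^{m \times t}$ (muscles $\times$ time) is approximated
as $M \approx WC$ with $W \in \mathbb{R}_{\ge 0}^{m \times k}$ (synergy weight
vectors) and $C \in \mathbb{R}_{\ge 0}^{k \times t}$ (activation coefficients),
minimizing the Frobenius reconstruction error $\lVert M - WC \rVert_F$.

## Signal conditioning

`preprocess_emg()` applies the standard surface-EMG chain:

1. zero-phase 4th-order Butterworth band-pass, 20–450 Hz (removes drift and
   high-frequency noise while keeping the physiological band);
2. zero-phase Butterworth notch at 50 Hz with 1 Hz bandwidth (power-line
   interference; Q = 50);
3. full-wave rectification followed by a zero-phase 20 Hz low-pass (the
   linear envelope; comparable to a 25 ms moving average);
4. optional division by the muscle's maximum voluntary isometric contraction
   (MVIC) reference;
5. cubic-spline resampling of the movement window onto 101 samples, i.e. the
   0–100% normalized cycle.

All filters run forward–backward (`signal::filtfilt`), which cancels phase
delay at the cost of doubling the effective filter order — peak timing is
preserved to within a sample or two, which matters when coefficients are
interpreted against movement phases. Movement onset/offset indices are caller
supplied (segmenting by racquet kinematics is outside this package's scope);
the default is the full trial. 101 points were chosen so that both endpoints
of the 0–100% cycle are represented. MVIC values are inputs, not computed:
no MVIC protocol is modelled here. A signal-to-noise screen
(`snr_estimate()`) flags trials whose active-versus-baseline power ratio
falls below 20 dB.

## NMF with multiplicative updates

`nmf_decompose()` implements Lee–Seung multiplicative updates for the
Frobenius objective. Protocol defaults: at most 100 iterations per run,
convergence declared when the relative objective change falls below
$10^{-6}$, 50 random restarts, best (lowest-error) restart kept. Numerical
choices worth knowing:

* **Initialization.** $W$ and $C$ start elementwise Uniform(0, 1] scaled by
  $2\sqrt{\bar m / k}$ (so the initial product matches the data's mean
  magnitude). Restart seeds derive deterministically from the master seed.
* **Zero guard.** Denominators carry $\varepsilon = 10^{-12}$; update fixed
  points are unchanged for positive factors.
* **Monitored quantity.** Convergence is judged on the relative change of the
  Frobenius error itself, evaluated after each full (C then W) update pair.
  The objective is non-increasing at every iteration — the test suite asserts
  this on every run it performs.
* **Scale convention.** NMF is scale-ambiguous per component;
  `normalize_synergies()` fixes columns of $W$ to unit Euclidean norm and
  moves the scale into $C$, leaving $WC$ untouched.
* **Iteration cap.** The 100-iteration budget is treated as a cap alongside
  the tolerance, not a fixed count. Near-exact factorizations of noiseless
  low-rank data benefit from a deeper budget; the parameter-recovery tests
  use `max_iter = 2000` for that reason.

The multiplicative-update inner loop is compiled (RcppArmadillo), with a
pure-R reference implementation kept in the package and checked for exact
agreement in the tests.

Whether synergies should be extracted per trial, per subject (trials
concatenated along time), or pooled across subjects is genuinely open; the
package exposes all three (any set of trials can be concatenated with shared
labels) and the cohort pipeline defaults to per-subject concatenation, which
stabilizes the factorization without blurring inter-subject differences.

## Choosing the number of synergies

`vaf_curve()` fits every candidate $k$ and `select_order()` applies a
conjunctive multi-criterion rule — the selected order is the smallest $k$
such that:

* global VAF $> 0.90$, where global VAF $= 1 - \lVert M - \hat M \rVert_F^2 /
  \lVert M \rVert_F^2$ (uncentered);
* every defined per-muscle (local) VAF $> 0.75$ (rowwise uncentered VAF;
  zero-activity muscles are undefined and excluded rather than failing the
  rule);
* adding the $(k{+}1)$-th synergy improves global VAF by fewer than 5
  percentage points ("slope" criterion). At the largest tested $k$ the
  improvement is unobservable and the criterion is treated as satisfied, so
  the rule degrades gracefully at the range boundary.

The three criteria are applied conjunctively (all must hold); whether the
original multi-criterion formulation was conjunctive or majority-vote is not
stated anywhere authoritative, and conjunction is the stricter, more
conservative reading. If no $k$ qualifies, the largest tested $k$ is returned
with `selected = FALSE` rather than an error.

Two cross-validation views complement the rule. `leave_one_out_vaf()`
extracts $W$ from $n-1$ concatenated trials, fits the held-out trial's
coefficients by nonnegative least squares (per time sample, $W$ fixed), and
reports the generalization gap $\Delta\mathrm{VAF}$ (held-out minus
within-sample). `split_half_consistency()` repeatedly divides trials into
random halves, extracts synergies independently from each half, matches
components, and summarizes matched cosine similarities together with an
ICC/SEM consistency index. Split-half results are advisory — they are
reported, not gated on, since no numeric threshold for them is established.
Both halves of a split share one extraction seed, so duplicated halves score
exactly 1.

## The toy static-optimization stage

The model modality in a real study comes from a musculoskeletal simulation:
inverse kinematics and dynamics followed by static optimization. This package
implements the static-optimization stage itself at desk scale
(`solve_frame()`, `simulate_model_activations()`): at each time sample,
activations minimize $\sum_i a_i^2$ subject to joint moment equilibrium
$\sum_i r_{ij} F_i(a_i) = M_j$ and bounds $0 \le a_i \le 1$. Forces use a
rigid-tendon, nominal-length Hill model, $F_i = a_i F_{0,i}
\cos(\text{pennation}_i)$, with force–length and force–velocity factors fixed
at 1 by default (hooks accept multiplicative factors up to 1.8). With linear
$F_i(a_i)$ the problem is a strictly convex quadratic program with a unique
solution (ties impossible); the package solves it by an active-set QP and
verifies the equilibrium residual below $10^{-6}$. Infeasible frames abort
with the offending joint and moment shortfall.

`hill_muscle_params()` ships the published Hill-type parameter table of the
upper-extremity model verbatim — including its internally inconsistent length
scales (trapezius fiber lengths around 0.1 versus deltoid around 10 under one
"cm" heading), which are therefore labelled units-as-printed; only peak force
and pennation enter the toy computation. `default_joint_task()` is a
two-joint (elevation, internal rotation), 15-muscle task whose hand-authored
signed moment arms make the three functional muscle groups the efficient
actuators of three phase-specific moment demands; muscles without a published
counterpart carry synthetic parameters at plausible magnitudes and are marked
as such. Inverse kinematics/dynamics, forward-dynamics verification and
subject-specific scaling are out of scope.

## Comparing decompositions

`compare_decompositions()` quantifies agreement between an EMG-derived and a
model-derived synergy set:

* **Matching.** Components are paired one-to-one to maximize total
  scalar-product similarity of weight columns; the assignment is exhaustive
  over permutations up to 8 components (guaranteed optimal) and greedy
  beyond.
* **Weights.** Matched weight vectors are scored by the scalar product
  (normalized dot product), which lies in $[0, 1]$ for nonnegative inputs and
  reaches 1 only for parallel vectors.
* **Coefficients.** Matched coefficient rows are scored by Pearson's $r$.
* **Per muscle.** Each muscle's weight profile across matched synergies (its
  row of $W$) is scored by the scalar product between the two sets. The
  published per-muscle similarity is not defined precisely anywhere, so an
  alternative definition — Pearson correlation of the muscle's reconstructed
  signals — is available via `per_muscle_method = "reconstruction"`.

## Reliability metrics

For repeated scalar measurements (for example per-trial joint angles),
`reliability_report()` computes per-subject coefficients of variation
(sample SD over mean, in percent), ICC(3,1), and the standard error of
measurement $\mathrm{SEM} = \mathrm{SD}\sqrt{1 - \mathrm{ICC}}$, with
acceptability flags at CV $< 10\%$ and ICC $> 0.80$. The ICC is the two-way
mixed-effects, single-measure, *consistency* form,
$(\mathrm{BMS} - \mathrm{EMS}) / (\mathrm{BMS} + (k-1)\mathrm{EMS})$; the
"(3,1)" label alone does not distinguish consistency from absolute agreement,
and consistency is the conventional choice for trial-to-trial stability. The
SD entering the SEM is the between-subject SD of subject means.

## The synthetic cohort generator

No data accompany the study this pipeline is designed around, so the package
ships a generator (`synth_config()`, `generate_cohort()`) whose defaults *are*
the study conditions: 15 labelled shoulder muscles, 20 subjects, 5 trials per
subject per modality, 101-sample cycles, 20 dB SNR, three ground-truth
synergies. Ground-truth weights are dominated by three functional groups —
scapular stabilizers (upper/middle/lower trapezius, serratus anterior),
anterior power generators (pectoralis regions, anterior deltoid, biceps), and
posterior decelerators (middle/posterior deltoid, infraspinatus, latissimus,
triceps heads) — with the dominant group's mean weight at least twice the
rest. Coefficients are raised Gaussian bumps centred at 20%, 50% and 80% of
the cycle, mirroring the preparation/impact/follow-through phase ordering;
each bump occupies about 15% of the cycle (`envelope_width`).

Per-trial variation enters as lognormal gains (sdlog 0.1) on each synergy's
coefficient — trial-to-trial amplitude variability is not documented
anywhere, so this value is an explicit stand-in. Noise is zero-mean Gaussian,
scaled so the pre-clipping SNR equals the configured value exactly, then the
matrix is clipped at zero. Subjects differ by 5% multiplicative weight jitter
(renormalized). The model modality carries an additional 10% multiplicative
weight perturbation drawn once per subject, so a subject's model trials
differ *systematically* from their EMG trials — attributing the modality gap
to weightings rather than coefficients matches where real EMG-versus-model
discrepancies concentrate.

What the generator does **not** emulate: raw interference EMG (trials are
generated directly as envelopes), marker or racquet kinematics, muscle-
specific noise structure, electrode crosstalk, or the magnitude of real
EMG-versus-model disagreement — a 10% multiplicative weight perturbation
moves weight-vector cosines only to about 0.995, far milder than the 0.8–0.9
range typical of real comparisons. Passing tests on this generator therefore
demonstrate the pipeline's correctness and calibration, not that real data
would be this clean. Kinematic scalars are generated per subject and trial
with between-/within-subject variances set from a target ICC, so the
population ICC(3,1) is controllable in closed form; defaults reproduce
published calibration values (e.g. shoulder abduction 45.2°, CV ≈ 3.2%,
ICC 0.92).

## Problem sizes and runtime choices

The package's own validation uses desk-scale problems: the default cohort (20
subjects × 5 trials × 2 modalities, candidate orders 1–6, 50 restarts) runs
in about a minute; the parameter-recovery study (3 true orders × 3 SNR levels
× 50 replicates, single-subject cohorts, 10 restarts) in a few minutes.
Restart counts below the 50-restart protocol default are used only where a
study repeats the factorization many times; recovery rates are insensitive to
this choice on these problem sizes.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(synth = synth_config(seed = 42), seed = 1)
res <- run_pipeline(cfg)
res
tidy(res$per_subject$order_selection[[1]])
autoplot(res$per_subject$order_selection[[1]])
```

## Known limitations

* NMF is non-convex; best-of-restarts mitigates but does not eliminate local
  optima, and global VAF is only guaranteed non-decreasing in $k$ up to
  restart noise (tested at tolerance $10^{-6}$).
* Overlapping coefficient bumps leave a sliver of rotational freedom in exact
  factorizations, so even noiseless recovery of ground-truth weights
  saturates around cosine 0.98–0.99 per column rather than exactly 1.
* The static-optimization stage is a toy: rigid tendon, nominal fiber length,
  two joints, hand-authored moment arms. It generates equilibrium-consistent
  activations for testing the comparison machinery; it is not a
  musculoskeletal simulation.
* Group-level inferential statistics (MANOVA, chi-square, post-hoc tests) are
  out of scope; the package stops at per-subject metrics and their summaries.
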