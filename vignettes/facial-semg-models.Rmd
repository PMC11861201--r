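---
title: "Muscle synergies and keypoint displacement models for facial sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergies and keypoint displacement models for facial sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model overview

`facemotor` analyses multichannel facial surface electromyography (sEMG)
recorded while a person performs the six basic facial expressions (anger,
disgust, fear, happiness, sadness, surprise), and couples two analyses:

1. **Expression recognition.** Seven facial muscles — inner and outer
   frontalis (IF, OF), corrugator supercilii (CS), levator labii
   superioris alaeque nasi (LLSAN), zygomaticus major (ZM), depressor
   anguli oris (DAO) and mentalis (Me) — are reduced to a small set of
   *muscle synergies* by non-negative matrix factorisation (NMF),
   `U ≈ Ws C`, where `U` (muscles × time) holds MVC-normalised envelopes,
   `Ws` the synergy weights and `C` their time-varying activations.
   Sliding-window features (RMS, variance, mean absolute value,
   integrated EMG) of either `C` (synergy mode) or `U` (per-muscle mode)
   feed a 100-tree random forest that labels each window with an
   expression.
2. **Keypoint displacement estimation.** Five facial keypoints (inner
   eyebrow, outer eyebrow, nose, mouth corner, chin) are modelled as
   spring equilibria between a linear skin spring (stiffness `KH`, fixed
   at 100 N/m) and one or two muscle springs whose stiffness
   `k0 + k1 u` and rest length `l0 + l1 u` depend on activation `u`
   (the Mykin muscle model). The single-muscle equilibrium is
   `Δl = (k0 + k1 u)(l0 + l1 u) / (KH + k0 + k1 u)`; double-muscle
   systems (inner eyebrow ← IF+CS, mouth corner ← ZM+DAO) add projection
   coefficients `a_i` and geometry factors `λ_i`:
   `Δl = Σ a_i(k0_i + k1_i u_i)(l0_i + l1_i u_i) / (KH + Σ a_i λ_i (k0_i + k1_i u_i))`.
   Three estimators are compared: the spring model alone (SMSM), a
   multivariate linear regression `ΔL = W_LRM U` (LRM), and the hybrid
   SMSM-LRM `ΔL = W · Δl_SMSM`, a 5×5 linear recombination of the
   per-point spring outputs that captures skin coupling between
   keypoints.

## Preprocessing assumptions

Raw sEMG is band-pass filtered 20–450 Hz, rectified, divided per channel
by its maximum-voluntary-contraction (MVC) value, low-pass filtered at
2 Hz into a linear envelope, and clipped at zero. Keypoint trajectories
arrive at the 25 Hz video rate; envelopes are aligned to them by
nearest-tick selection every 40 ms (the 2 Hz envelope is band-limited far
below the 12.5 Hz output Nyquist, so plain selection loses nothing).
One second of data on each side of every neutral↔expression transition
is discarded (electrode-friction artifacts concentrate there), and
"reordered trials" are assembled by drawing one repetition of each
expression (with 3 s of preceding neutral context) from each
single-expression trial.

Numerical choices a practitioner should know:

* Both filters are zero-phase 4th-order Butterworth designs (the filter
  family and order are our defaults; zero-phase filtering avoids lag
  between sEMG envelopes and video). Zero-phase filtering is applied
  with odd-reflection end padding so edge transients decay inside the
  padding rather than distorting segment ends.
* The MVC profile is the per-channel maximum of the *2 Hz-smoothed*
  rectified MVC task, not the raw rectified peak — robust to
  single-sample spikes.
* Envelope undershoot after zero-phase filtering is clipped at 0 to
  satisfy NMF's non-negativity.
* Segment times are half-open intervals `[start, end)` in seconds.

## Synergy extraction

NMF minimises the Frobenius residual with a HALS/coordinate-descent
solver over multiple seeded random restarts (default 10), keeping the
best restart. Synergy columns are normalised to unit Euclidean norm
(activations rescaled compensatingly) so cosine comparisons across
participants are well defined, and ordered by activation energy. The
number of synergies is the smallest rank whose variance accounted for
(VAF, the global Frobenius form
`100(1 − ‖U − WsC‖²_F / ‖U‖²_F)`) reaches 90% — the common criterion in
the synergy literature; whether a per-muscle-averaged VAF was meant is
ambiguous in parts of the literature, and the global form is our
documented choice. Synergies are extracted per participant, never
pooled, from the video-rate envelopes (information-free downsampling of
a 2 Hz-band-limited signal), and activations are re-projected at the
full 1024 Hz rate by non-negative least squares with `Ws` fixed before
feature extraction.

## Classification

Features use a window of `R = 125` samples at 1024 Hz (~122 ms; 150 ms
is the nominal design figure — the sample count is what enters the
formulas, and both are configurable) with a 40 ms step matched to the
video frame period. Windows are label-pure: they never straddle a
segment boundary. Variance uses the population (1/R) normalisation, so
`RMS² = VAR + mean²` holds exactly and `IEMG = R × MAV`. The pooled
split takes 10 of the 12 reordered trials per participant for training
and 2 for testing; the random forest uses 100 trees and otherwise
default parameters, without class weighting (neutral windows are
over-represented by design, matching the task structure).
Classification is per window; no majority-vote smoothing is applied.

## Fitting the displacement models

All three estimators minimise the mean squared displacement error over
the five keypoints jointly, at 25 Hz, on the same 10/2 trial split as
the classifier. The spring parameters (and the hybrid's `W`) are
optimised by full-batch Adam (step size 1e-3, default moment decays,
18,000 epochs — step size is our documented default, configurable), with:

* `k0`, `k1` kept positive by a soft-plus reparameterisation; `KH` fixed
  at 100 N/m, never fitted; displacement units absorb any stiffness/pixel
  unit mismatch.
* `a_i` and `λ_i` unconstrained in sign (projection and geometry factors
  may oppose the skin-force direction); a hinge penalty keeps the
  double-system denominator above 1% of `KH` over the activation range.
* λ initialisation follows the anatomical agonist/antagonist convention
  of the fixed wiring (elevator positive, depressor negative).
* The LRM is solved in closed form (exact least squares) by default; an
  Adam path exists for parity and for the convexity diagnostics.
* 5-fold cross-validation over training trials; the fold model with the
  lowest validation MSE is the selected model (no refit), mirroring the
  training protocol of the displacement study.

The product `(k0 + k1 u)(l0 + l1 u)` is invariant under reciprocal
rescaling of its two factors, so individual spring constants are not
identifiable; all quality statements are about predicted displacements
(R² on the 0–100 scale and RMSE normalised by the per-keypoint max–min
range of the true data; per-keypoint normalisation is our choice and is
configurable), never about recovered constants. Model comparison across
participants uses one-way ANOVA plus Tukey's HSD on both metrics.

## The synthetic study

Because the underlying human recordings are not publicly released, the
package ships a seeded generator that emulates their statistical
structure; it is first-class, tested code and defines the default study
conditions:

* 10 participants × 6 trials (one expression each) × 12 repetitions;
  5 s neutral / 5 s expression cycles with a 1 s neutral tail (132 s
  trials); MVC task of five 40 s trials (4 s neutral / 4 s action,
  each action driving a designated muscle subset at the participant's
  maximum expression-task amplitude).
* Three ground-truth synergies: CS+LLSAN+DAO, IF+OF+DAO+Me, ZM+DAO —
  with anger, surprise and happiness as single-synergy expressions
  (amplitude 0.8 MVC), sadness 1+2, fear 2+3 (0.5 each) and disgust
  1+2+3. Each participant perturbs the synergy matrix (sd 0.05,
  renormalised) and every repetition draws log-normal amplitude jitter
  (sdlog 0.1).
* Raw-like sEMG is a 20–450 Hz band-limited Gaussian carrier
  amplitude-modulated by the muscle envelope, with signal-dependent
  noise (sd = 0.1 × envelope), baseline noise (sd = 2% of the mean MVC
  amplitude) and 5% crosstalk mixing. Trapezoidal activations rise and
  fall in 0.5 s, so the 1 s transition trim removes exactly the
  non-stationary part.
* Keypoints are the spring-equilibrium displacements of the noise-free
  normalised envelopes, multiplied by a non-trivial cross-point coupling
  matrix (identity plus 0.1–0.2 couplings between anatomically adjacent
  points), plus Gaussian tracking noise (sd 2e-4 displacement units,
  about 4% of a typical peak displacement — displacement units are
  arbitrary since every evaluation metric is scale-free).

One RNG stream per participant and purpose (amplitudes, synergy
perturbation, jitters, carriers, keypoint noise) derives from the master
seed, so every participant and stage is independently reproducible.

What the generator does **not** emulate: video pixels and tracking
failures, electrode lift-off or motion artifacts beyond white and
signal-dependent noise, muscle fatigue, asymmetric expressions, or
non-stationary carrier spectra. Passing tests therefore demonstrate
correctness of the pipeline and attainability of the reported accuracy
levels *under the stated generative assumptions*, not performance on
real recordings.

## Problem sizes used by the tests and the acceptance script

The acceptance script runs the full default study (10 participants,
12 repetitions; 18,000-epoch hybrid fits with 5-fold CV). The test
suite mirrors the same checks with the full study for rank selection,
classification and the hybrid-model accuracy, and uses deliberately
smaller replicates elsewhere (1–2 participants, 2–4 repetitions,
6,000-epoch fits) for properties that hold at any scale — seed
stability, model ordering, recovery from clean data. The clean-data
recovery tests double as convergence checks for the shorter runs: a
6,000-epoch fit already reaches a prediction error within 2% of the
displacement range on noiseless data at those problem sizes.

## Known limitations

* The spring equilibria are static; transition dynamics (velocity-
  dependent skin damping) are out of scope, as is 2-D displacement
  modelling — each keypoint's displacement is the signed scalar
  projection onto its dominant motion axis (elevation-positive for
  eyebrow/nose/chin, ZM-pull-positive for the mouth corner).
* At `u = 0` the single-muscle equilibrium gives
  `Δl = k0 l0 / (KH + k0)`, which is non-zero unless `l0 = 0`; the
  generator and the default initialisation use `l0 = 0` so the neutral
  pose has zero displacement by construction.
* NMF residuals carry discriminative information, so per-muscle
  classification can outperform synergy classification slightly; the
  package exposes both modes through one code path.
* The inverse problem (desired displacements → activations) is not
  implemented.
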