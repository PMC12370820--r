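---
title: "Normative mapping of intracranial EEG band power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative mapping of intracranial EEG band power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Intracranial EEG (icEEG) is recorded from people with epilepsy during
presurgical evaluation. Channels that are judged non-pathological — outside
lesions, outside the seizure onset zone, not subsequently resected — can be
pooled across many subjects to describe what "normal" brain activity looks
like region by region: a normative map. Because no single hospital implants
every brain region densely, such maps are necessarily multi-centre, and the
recording hospital then becomes a nuisance variable that can rival or exceed
the biological effects of interest (age, sex). `iceegnorm` implements the
full chain from raw multichannel voltage segments to hospital-aware
normative models and per-subject deviation scores, together with a
synthetic-data module that generates every input with known ground truth so
each stage is testable.

## Signal chain

A 70 s interictal segment is selected at least two hours from any annotated
ictal event (earliest valid window on a 1 s search grid, clearance measured
to the nearest interval edge). Channels are screened with three documented
heuristics — peak-to-peak range below 1 µV ("flat"), robust z of the channel
SD above 5 ("amplitude outlier"), and 50/60 Hz Welch density exceeding 3×
its ±2.5–7.5 Hz flanks ("line noise"). These are deliberately simple,
configurable stand-ins for the visual-plus-algorithmic inspection that a
clinical team would perform; they catch gross failures, not subtle
artefacts or epileptiform transients.

Retained channels are band-pass filtered 0.5–80 Hz with a 4th-order
Butterworth band-pass applied forward–backward (zero phase). The segment is
odd-reflection padded by 6/`low` seconds before filtering so the low
corner's start-up transient never reaches the data. Signals are then
resampled to 200 Hz by rational-rate polyphase FIR resampling (zero-stuff,
Hamming-windowed `fir1` low-pass at the smaller Nyquist with 20 taps per
branch, group-delay compensated, decimate); passband content below ~0.9 of
the new Nyquist is preserved to well within 2%. A common average reference
subtracts the across-channel mean of the retained channels at every sample.

Power spectral density uses Welch's method with a 2 s Hann window and 1 s
overlap, density scaling (µV²/Hz) on the resulting 0.5 Hz grid. Band powers
integrate the density by rectangle rule over δ 1–4, θ 4–8, α 8–13, β 13–30
and γ 30–77.5 Hz, excluding 47.5–52.5 and 57.5–62.5 Hz from γ to avoid both
mains frequencies. A grid bin belongs to a band iff its centre frequency
lies in the half-open interval `[lower, upper)`, and exclusions apply the
same rule, so shared edges (e.g. 4 Hz) are counted exactly once. Because the
five values are subsequently L1-normalised, any constant bandwidth factor
cancels; the integral (not the per-Hz average) is the logged choice.

Relative band power (RBP) is the vector of log10 band powers divided by
their sum. This is only a convex weighting when the five logs share a sign,
which holds when all band powers sit on the same side of 1 µV²; referential
icEEG in µV comfortably satisfies the positive regime, where a band with
more power receives a larger component. Mixed-sign logs raise an error
asking for a unit rescale rather than silently producing non-convex
weights.

## Localisation and the normative table

Contacts are assigned to the region owning the nearest grey-matter voxel
centre (Euclidean, mm), excluded beyond 5 mm, with deterministic
lexicographic tie-breaking (region id, then voxel index). Distances are to
voxel centres; no registration is performed — contacts and parcellation
must already share a space. Clinically flagged contacts (lesion, SOZ,
resected) are excluded with set-union reasons.

Within subject and region, contact RBP vectors are averaged per band (the
mean of unit-sum vectors is unit-sum). Six subcortical regions — pallidum,
thalamus, accumbens, both hemispheres — are dropped for their chronically
low sampling, reducing the standard 82-region atlas to 76. Mirroring then
collapses homologous left/right regions to 38, roughly doubling per-region
sample sizes; a bilaterally implanted subject contributes one row per
mirrored region. The collapse rule is the per-band arithmetic mean by
default (symmetric, consistent with contact averaging) with left- or
right-priority selection available; the choice is recorded in the table
header. Re-mirroring a mirrored table is an error, not a second collapse.

## The mixed model

For each band, `RBP ~ fixed effects + (1 | hospital)`: a linear
mixed model with a hospital random intercept, fixed-effect candidates
{∅, age, sex, age+sex}, age in raw years (uncentred), sex coded
0 = female / 1 = male. Estimation profiles the likelihood down to one
dimension: writing λ = σ²ᵤ/σ²ₑ, the marginal covariance is
σ²ₑ(I + λJ) block-diagonal over hospitals, so for fixed λ the GLS
coefficients and σ²ₑ have closed forms and the profiled ML or REML
criterion is minimised over λ ≥ 0 by golden-section search after a coarse
log-spaced bracket. This makes every fit a few milliseconds, which in turn
makes dense grid-search likelihood oracles and large simulation studies
cheap. REML supplies reported coefficients and variance components; ML
refits supply AIC, BIC and likelihood-ratio tests (REML likelihoods of
models with different fixed effects are not comparable, and `lrt()`
refuses them). BLUPs of the hospital offsets are the shrunken per-hospital
mean residuals λn_h/(1+λn_h)·r̄_h.

A fit is flagged singular when λ̂ < 1e-4 or a single hospital makes the
split unidentifiable (the ratio is then pinned at the boundary, which also
reduces the fit to OLS exactly). Under a truly zero hospital variance the
estimate lands on the boundary with probability ≈ 1/2 (the classic
boundary mixture), so roughly half of such fits are flagged — the package's
flag agrees fit-for-fit with `lme4::isSingular` in testing.

Variance is decomposed as ICC = σ²ᵤ/(σ²ᵤ+σ²ₑ) (hospital share) and marginal
R² = var(Xβ̂)/(var(Xβ̂)+σ²ᵤ+σ²ₑ) (fixed-effect share). Because the
denominator includes the residual variance it changes between models, so
R²m values of nested models are not additive.

Profile confidence intervals for fixed effects profile the ML deviance over
one coefficient (its column moved to the offset; remaining coefficients and
both variance components re-optimised per trial value), locating the
χ²₁ cutoff by root finding within ±10 Wald SEs to tolerance 1e-6, with a
Wald fallback recorded per side if the deviance never crosses the cutoff in
range. The intervals reproduce `lme4::confint` to ~1e-4 relative.

Model selection fits all four candidates and declares agreement when the
AIC-best and BIC-best model coincide and equal the unique model whose every
term has a CI excluding zero and an LRT p < 0.05 when added last, with no
further term significant. When metrics split, the simplest of the top
contenders is retained and the decision trace records the tie-break. An
age×sex interaction is deliberately not in the default candidate set.

The regional map fits the age model by REML per mirrored region, keeping
every fit (including singular ones) with b̂_age, SE, CI, CI-contains-zero
and singular flags, ordered by sample size; regions under `min_roi_n = 10`
rows are reported unfitted with a reason.

## Deviation scoring

A new subject has no hospital in the model, so the prediction uses the
population line (hospital offset at its prior mean, zero) and the residual
is standardised by the model residual SD. That matches "deviation from the
regression line"; it also means that when the hospital variance is large,
out-of-sample scores over-disperse (SD > 1) because the unknown hospital
offset is part of the residual. The alternative denominator
√(σ²ᵤ+σ²ₑ) is exposed as an option for that regime. Singular regions are
scored with the raw residual only and flagged; scores are ranked by |z| and
flagged beyond a configurable threshold (default 2).

## The synthetic-data module

The cohort generator draws exactly the model the pipeline fits: per band,
RBP = β₀ + b_age·age + b_sex·male + u_hospital + ε, bands independent, no
sum-to-one constraint (the modelling layer never uses one). Defaults
emulate a 15-hospital, ~500-subject cohort, ages 4–66, equal sex split:
age slopes (−6.1, −0.8, +4.1, +2.9, −0.2)×1e-4 RBP/year across
δ/θ/α/β/γ, sex offsets zero except small θ/γ offsets (3e-3), residual SD
0.024 and hospital-intercept SDs calibrated so the hospital ICC spans
~5–30% across bands while age explains at most ~8% of variance — the
regime a multi-centre icEEG cohort of this size exhibits. Implantation is
independent Bernoulli per subject × region with heterogeneous
probabilities (middle temporal 0.8 down to frontal pole 0.075), emulating
the clinical bias towards temporal coverage.

The recording generator synthesises a 1/f^χ background (frequency-domain
shaping of Gaussian noise, band-limited to 0.5–80 Hz, χ = 1 by default,
100 µV² total so band powers stay above 1 µV²) plus one fixed-amplitude
random-phase sinusoid per band, amplitudes solved in closed form so the
analytic band powers are proportional to the requested targets; the
analytic powers are attached to the segment as the oracle. The default
target profile (0.34/0.25/0.18/0.13/0.10) is monotone delta-dominant, both
realistic for resting icEEG and separated enough that the planted ordering
survives common-average referencing, which mixes ~1/√n_ch of the other
channels' oscillations into each channel.

What the generator does *not* emulate — epileptiform transients, sleep
architecture, aperiodic-component drift, electrode-type differences,
non-Gaussian artefacts, spatial correlation between neighbouring contacts
— bounds what passing tests show: they validate the estimators and the
pipeline's arithmetic under the stated model, not robustness to every
clinical recording pathology.

All generators are pure functions of (parameters, seed) and restore the
global RNG state.

## Numerical and design choices

- Band edges shared between bands resolve upward (4 Hz is θ); γ
  exclusions use the same half-open rule.
- The Butterworth band-pass is `butter(4, c(low, high))` (8 poles)
  applied forward–backward. Its skirts roll off at ~4 poles per side:
  a 95 Hz tone at fs = 512 is attenuated ~14–16 dB, which is the
  attainable figure for this design and the bound the tests assert.
- Welch windows are detrended (constant) per window; one-window segments
  reduce exactly to the Hann periodogram.
- λ is optimised on [0, 1e4] with a log-spaced bracket; the boundary
  λ = 0 is always compared against the interior optimum.
- Aliased fixed-effect columns (e.g. a constant-zero sex column in an
  all-female cohort) get `NA` coefficients with a warning, `lm()`-style,
  so degenerate nested comparisons yield an LRT statistic of exactly 0.
- EDF I/O is a minimal 16-bit implementation (fixed-layout ASCII header,
  little-endian int16 records, per-channel physical calibration); its
  round-trip error is bounded by one quantisation step and it refuses
  mixed sampling rates and EDF+ annotations.

## Problem sizes

The test-suite and acceptance studies use cohorts of 15 hospitals × 33
subjects (whole-brain analyses), 100 replicates per intraclass-correlation
setting for slope recovery and profile-CI coverage, 1000 null replicates
for LRT calibration at 10 × 30, 100 replicates per scenario for selection
consistency, and 20-replicate matched designs (n = 50 vs 400) for the
SE-versus-sample-size comparison; DSP checks use 50-channel, 70 s segments
at 512 Hz. These sizes give Monte-Carlo standard errors comfortably inside
the asserted tolerances while the whole suite runs in a few minutes.

## Limitations

Only linear age trajectories are modelled (no quadratic or spline terms),
one random intercept (no random slopes, no subject-level random effect
across regions), no cross-band joint modelling, and no harmonisation beyond
the hospital intercept. Channel screening approximates, rather than
reproduces, expert artefact review. The deviation score is a descriptive
normative comparison; no claim is made about seizure-onset-zone
localisation accuracy.
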