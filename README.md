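# iceegnorm

Normative mapping of intracranial EEG (icEEG) relative band power across
age, sex and recording hospital.

icEEG normative maps pool presumed-healthy channels from many epilepsy
surgery patients to describe regional "normal" brain activity. Such
cohorts are unavoidably multi-centre, and the recording hospital is a
strong nuisance variable. This package is for researchers building or
auditing such maps: it implements the complete chain from raw referential
voltage segments to hospital-aware normative models and per-subject
deviation scores, plus a synthetic-data module that generates every input
from a known ground truth so the whole chain is testable.

## The model

Per contact, relative band power is the L1-normalised log power vector

RBP(b) = log10 P(b) / Σ_b' log10 P(b'),  b ∈ {δ 1–4, θ 4–8, α 8–13,
β 13–30, γ 30–77.5 Hz} (γ excludes 47.5–52.5 and 57.5–62.5 Hz mains
windows), with P(b) the Welch-integrated band power (2 s Hann window,
1 s overlap, 200 Hz, common average reference, 0.5–80 Hz zero-phase
band-pass).

Per band and region, the normative model is a random-intercept linear
mixed model

RBP ~ β₀ + b_age·Age + b_sex·Sex + u_Hospital + ε,
u ~ N(0, σ²ᵤ), ε ~ N(0, σ²ₑ),

with fixed-effect structure chosen among {null, age, sex, age+sex} by
AIC/BIC, 95% profiled confidence intervals and likelihood-ratio tests.
Hospital effects are summarised by the intraclass correlation
ICC = σ²ᵤ/(σ²ᵤ+σ²ₑ); fixed effects by the marginal
R²m = var(Xβ̂)/(var(Xβ̂)+σ²ᵤ+σ²ₑ). Estimation is by closed-form GLS
profiling over the variance ratio (REML for reported estimates, ML for
information criteria and tests), reproducing `lme4` to numerical
precision while staying cheap enough for large simulation studies.

## Worked example

Simulate a 15-hospital, ~500-subject cohort from the generative model and
fit the age model to the alpha band at the whole-brain level:

```r
library(iceegnorm)
p   <- simulation_params(rois = data.frame(roi = "whole_brain", prob = 1),
                         seed = 3)
tab <- simulate_cohort(p)$table
fit <- fit_lmm(tab, "alpha", fixed = "age", method = "REML")
fit
#> <lmm_fit> RBP(alpha) ~ age + (1|hospital)  [REML, n=495, H=15]
#>          (Intercept)      age
#> estimate    0.179435 0.000473
#> se          0.002412 0.000060
#> sigma2_u=0 sigma2_e=0.000584 ICC=0.000 R2m=0.111 logLik=1126.81 [singular]
profile_ci(fit, "age")
#>        lower        upper
#> 0.0003545486 0.0005906306
```

The estimated slope (+4.7×10⁻⁴ RBP/year) recovers the planted alpha-band
value (+4.1×10⁻⁴) within its confidence interval; this particular draw
happens to put the hospital variance on the boundary, so the fit is
flagged singular. The full analysis narrative lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R        # parcellation, EDF demo subjects, cohort
Rscript analysis/02_extract_rbp.R     # signal chain -> RBP per contact
Rscript analysis/03_build_table.R     # localise, exclude, aggregate, mirror
Rscript analysis/04_fit_normative.R   # model selection, ICC/R2m, regional map
Rscript analysis/05_score_deviation.R # score an out-of-sample subject
```

Stage 4 prints, for the default simulated cohort (seed 2026):

```
delta  optimal model: age      (metrics split (AIC: age+sex, BIC: age, CI/LRT: age); simpler contender 'age' retained)
theta  optimal model: age+sex  (all metrics agree)
alpha  optimal model: age      (all metrics agree)
beta   optimal model: age      (all metrics agree)
gamma  optimal model: sex      (metrics split (AIC: age+sex, BIC: sex, CI/LRT: sex); simpler contender 'sex' retained)

whole-brain age slopes (x 1e-4 RBP/year, 95% profile CI):
  band b_age_x1e4 ci_lo_x1e4 ci_hi_x1e4 se_x1e4 singular
 delta     -6.144     -6.506   -5.78259   0.185    FALSE
 theta     -0.701     -1.061   -0.33997   0.184    FALSE
 alpha      3.890      3.524    4.25540   0.187    FALSE
  beta      3.171      2.815    3.52699   0.182    FALSE
 gamma     -0.355     -0.713    0.00313   0.183    FALSE
```

i.e. decreasing slow-band and increasing α/β relative power with age, a
band-specific optimal model, and a γ interval containing zero — with
every number traceable to the generator's parameters. Stage 5 scores a
subject planted 2.5 residual SDs high in hippocampal alpha; that
region-band pair is the single flagged deviation (z = 2.58).

Tables are written under `results/` as TSV with provenance headers.

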