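---
title: "Methods: validating activity questionnaires against wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating activity questionnaires against wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelq)
```

`accelq` implements the analysis pipeline of a questionnaire validation
study: a wrist-worn tri-axial accelerometer supplies the objective
reference for time spent at different physical activity intensities, a
MET-based questionnaire supplies the self-report, and a suite of
agreement statistics quantifies validity (between methods) and
reproducibility (within method, between measurement occasions). This
vignette documents the models, conventions and numerical choices, and
what the synthetic-data generator does and does not emulate.

## 1. From raw acceleration to minute epochs

The device samples acceleration $(x, y, z)$ in g units at $K$ samples/s
(40 Hz in the motivating protocol). The per-minute summary is the
gravity-subtracted signal vector magnitude,

$$
E \;=\; \frac{80}{K}\sum_{\text{minute}}
  \bigl|\sqrt{x^2 + y^2 + z^2} - g\bigr| \quad [\text{g·min}],
$$

with $g = 1.00$ by default and the sum running over the minute's $60K$
samples. The $80/K$ factor expresses every recording on a common
80 samples/s reference scale: the per-second mean deviation
$\frac{1}{60K}\sum|\cdot|$ times 60 (minute epoch) times $2$ at
$K = 40$. Two properties pin this normalisation down and are enforced by
tests: doubling every sample's deviation from $g$ doubles every epoch,
and the same physical signal represented at 40 and at 80 samples/s
yields identical epochs. As a magnitude anchor, sitting-scale deviations
of about 0.02 g give $2 \times 2400 \times 0.02 \approx 96$ g·min,
consistent with observed sitting epochs near 105 g·min.

Epochs are aligned to wall-clock minute boundaries; samples before the
first whole minute are dropped. Timestamps are taken at face value — no
resampling or gap interpolation. A minute with missing samples is
incomplete, a day containing any incomplete minute is incomplete, and a
participant series that cannot supply the requested number of complete
midnight-to-midnight days (1440 epochs each, starting at the first
midnight at or after the series start) is rejected outright. This
all-or-nothing rule matches the inclusion criteria of wear-time
protocols, which exclude participants rather than impute partial days.

## 2. Calibration and cut points

Each calibration activity (sitting, standing, walking at 3.2, 4.8 and
6.4 km/h; compendium MET values 1.5, 1.8, 2.5, 3.3, 5.0) is performed
for five minutes; the middle three minutes are averaged to avoid
transition artefacts. Ordinary least squares of steady-state SVM_gs on
MET gives the calibration line — on the packaged activity means,
$\text{SVM\_gs} = 529\,\text{MET} - 627$ after integer rounding, which
is the display convention; coefficients are kept at full precision
internally. Under a balanced design (every activity on every device)
fitting per-activity means reproduces the same line as fitting all
individual observations, which is why the five packaged means suffice.

Cut points are the line's values at MET 1.5, 3 and 6 — evaluation on the
fitted line at fixed MET, not inversion of a MET-on-SVM_gs regression —
clamped at 0 because SVM_gs is nonnegative (the packaged line never
triggers the clamp for MET ≥ 1.5, but synthetic models may). The MET
thresholds are configurable parameters with those defaults.

Boundary conventions, used identically for epochs, questionnaire items
and diary entries: sedentary strictly below the MET-1.5 boundary, light
below the MET-3 boundary, moderate from 3 to 6 *inclusive*, vigorous
strictly above 6; MVPA is everything at or above MET 3. So a MET of
exactly 1.5 is light, and exactly 3 or 6 is moderate.

## 3. Daily summaries and non-wear correction

A complete day's 1440 epochs are counted into category minutes, which
sum to 1440 by construction. Diary-recorded non-wear activities
(e.g. swimming, when the device must be removed) register as sedentary
on the device, so each diary entry with MET strictly above 1.5 moves its
duration from the sedentary category into the category of its MET value;
entries at or below 1.5 MET would move time within sedentary and are
ignored. The correction operates on daily category totals, not on epoch
streams — the correction is defined as a category-time transfer, and no
epoch-level placement of the non-wear interval is needed for any
downstream statistic. If an entry exceeds the available sedentary time,
the deficit is drawn from LPA with a warning; this degenerate case has
no protocol-defined behaviour, and the chosen rule preserves the
1440-minute budget, which every operation in the module maintains as an
invariant. Multi-period averaging weights all days equally (a 12-day
mean over two 6-day periods), identical to period-then-grand averaging
when periods are balanced — which the complete-data inclusion rule
guarantees.

## 4. Questionnaire scoring

Activity items carry compendium MET values; reported hours/day
accumulate into category minutes through the same MET boundaries. The
instrument's predefined frequency-by-duration answer grids are not part
of the package contract: the scorer accepts already-resolved hours/day
per item, and the packaged catalogue of ~19 items with representative
MET values is a fixture convention covering the usual domains (four
occupational activity levels, transportation, leisure, sports including
water and winter sports that accelerometers miss, sleep). Sleep is
classified by its MET value like any other item (0.95 → sedentary).
Screening logic: non-working respondents skip occupation and
transportation items; leisure and sport items are asked only if selected
in screening; sleep is always asked.

The 24-h-adjusted total MET-h is
$\sum_i \text{hours}_i \times \text{MET}_i + (24 - \sum_i \text{hours}_i)
\times 2.0$: missing time is added, and over-reported time subtracted,
at MET 2.0 — the assumed average of unreported time, between quiet
sitting (≈1.5) and light self-care or slow walking (≈2.5). The
adjustment is applied globally, not per domain; the instrument gives no
basis for attributing the gap to a specific domain.

## 5. Agreement statistics

* **Spearman correlation** is computed as the Pearson correlation of
  mid-ranks (average ranks for ties). Confidence intervals use the
  percentile bootstrap with participant-level (pairwise) resampling,
  2000 resamples by default, and an explicit seed; the percentile method
  was chosen over BCa or normal approximations as the simplest method
  consistent with "the bootstrap", and its empirical coverage is itself
  checked by simulation (94% at the default study conditions).
* **Bland–Altman**: differences are questionnaire minus reference, so
  over-reporting appears as a positive mean difference; limits of
  agreement are the mean difference ± 2 SD of the differences — exactly
  2, not 1.96, following the convention of the motivating analysis. By
  Chebyshev the limits contain at least 75% of points for any input, and
  about 95% under normal differences.
* **Weighted kappa** is computed on quartiles: each series is cut at its
  *own* quartiles (each method's distribution defines its classes;
  values equal to a cut fall into the lower quartile) into four ordinal
  classes. Weights are linear, $w_{ij} = 1 - |i - j|/3$, by default —
  the weight scheme is otherwise a free choice, and quadratic weights
  are available. The p-value is the large-sample normal test of
  $\kappa = 0$ using the Fleiss–Cohen–Everitt null variance. The
  same-quartile and same-or-adjacent-quartile percentages are reported
  alongside.
* **ICC** is the one-way random-effects ICC(1,1) from ANOVA mean
  squares, $(MS_B - MS_W)/(MS_B + MS_W)$ for two replicates, with the
  standard F-based confidence interval. Two-way forms (which separate a
  systematic occasion effect) are intentionally out of scope.

The report builder assembles per-category descriptives for each
method and occasion, validity statistics of the first questionnaire
admission against the accelerometer two-period average, weighted kappa
for MPA/VPA/MVPA, and per-method ICCs — the layout of a validation
paper's results tables — plus per-category Bland–Altman point sets for
plotting. All randomness is confined to the bootstrap and controlled by
its seed.

## 6. The synthetic cohort generator

The generator's defaults are the study conditions of the motivating
design: 148 participants, two 6-day accelerometer periods, two
questionnaire admissions; accelerometer moderate time averaging
46 (SD 27) min/day and vigorous time 3 (SD 6) min/day; questionnaire
over-reporting factors 2.6 (MPA) and 6.5 (VPA), the ratios of the
questionnaire to accelerometer means in the motivating cohort;
between-method Spearman targets 0.19/0.27/0.54 for the sedentary share,
MPA and VPA; test-retest ICC targets 0.78 (accelerometer) and 0.67
(questionnaire, mid-range of its per-category reliability).

Construction, per participant $i$ and component
$v \in \{\text{MPA}, \text{VPA}, \text{sedentary share}\}$:

1. A latent propensity $a_{iv} \sim N(0,1)$ per method, with the
   questionnaire's propensity tied to the accelerometer's through a
   Gaussian copula parameter $r_v$.
2. Occasion replicates follow a one-way random-effects structure on the
   latent scale,
   $L_{ivt} = \sqrt{\rho^*_v}\,a_{iv} + \sqrt{1-\rho^*_v}\,\varepsilon_{ivt}$.
3. Observed MPA and VPA minutes are shifted lognormals of the latent,
   matched to the target mean/SD/shift; the sedentary share of non-MVPA
   time is a logit-normal. LPA is the remainder, so the 1440-minute
   budget holds identically for every record, and questionnaire
   over-reporting multiplies the whole observed scale (mean, SD and
   shift), preserving ranks.

Two calibrations make the targets exact rather than approximate. For
the ICC, the lognormal transform deflates latent-scale correlation, so
the latent replicate correlation is solved in closed form from the
observed-scale moment ICC:
$\rho^* = \log\!\bigl(1 + \rho\,(e^{\sigma^2}-1)\bigr)/\sigma^2$ with
$\sigma$ the component's log-scale SD. For the Spearman, bivariate
normal latents give $\rho_S = \tfrac{6}{\pi}\arcsin(\rho_P/2)$, and the
accelerometer's two-period average attenuates the person-level signal by
$\sqrt{\rho^* + (1-\rho^*)/2}$; the copula parameter inverts both. One
approximation remains: the two-period average of lognormals is treated
as rank-equivalent to the average latent. The multiplicative residual is
independent of the average latent and contributes under 1% of its
variance at the default noise levels, so the induced Spearman error is
far below the generator's ±0.05 calibration check (200 cohorts at the
defaults recover the VPA target 0.54 with mean 0.539 and the MPA ICC
target 0.78 with mean 0.773).

Known limitations, stated so that passing tests are read correctly. The
moment-matched ICC is exact in population moments per directly generated
component; on the heavily skewed VPA scale (CV = 2) the finite-sample
ANOVA estimator is dominated by the shared extremes and sits well above
the moment ICC, so ICC calibration is demonstrated on the milder MPA
scale. Derived categories (MVPA, LPA, the combined sedentary-to-light
block) inherit *emergent* correlations rather than targeted ones. MPA
and VPA propensities are independent across components within a
participant. The raw-signal generator synthesises deviation magnitudes
directly (gamma-distributed around the calibration line's expectation,
orientation uniform on the sphere, shape 4 by default giving ≈1%
epoch-level noise); it makes no attempt at biomechanically realistic
waveforms, which is sufficient because every downstream computation
consumes only $|$magnitude$-g|$. None of this emulates real-world
failure modes — device non-wear that goes undiaried, seasonal
variability between the questionnaire's recall window and the wear
period, or the accelerometer's blindness to cycling and swimming — so
agreement recovered on synthetic cohorts demonstrates correctness of the
statistical machinery, not validity of any particular instrument.

## 7. Problem sizes used in the checks

The packaged checks run 200 synthetic cohorts of 148 participants for
the stochastic recovery of the Spearman and ICC targets with 2000-fold
bootstraps, 100 random minutes against the brute-force epoch oracle,
and 1000 randomized inputs for the budget-conservation sweep — sizes at
which the Monte-Carlo error of every checked mean is an order of
magnitude below its tolerance.
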