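---
title: "Validating a GC-FID caffeine assay: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a GC-FID caffeine assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caffval)
```

caffval implements a complete single-laboratory validation workflow for
quantifying caffeine in coffee grains by gas chromatography with
flame-ionisation detection (GC-FID), without an internal standard. This
vignette explains the statistical models behind each stage, the parameters
that matter and their defaults, what the synthetic-data generator does and
does not emulate, and the design decisions that were genuinely open.

## The measurement model

A 0.5 g portion of homogenised grains is extracted into 10 mL, so every
mg/L of caffeine in the final extract corresponds to 20 mg/kg
(`extract_to_sample()`); 1 %w/w equals 10 000 mg/kg exactly. The detector
is modelled as linear in concentration over 10–1000 mg/L:

$$A = b\,c + a + \varepsilon,$$

with peak area $A$, slope $b$, intercept $a$, and a multiplicative
injection error of relative standard deviation `injection_cv` (default 2 %,
a typical split-injection repeatability when no internal standard corrects
for volume variation). The calibration is fit by unweighted ordinary least
squares (`fit_calibration()`); a 1/x weighting is available but off by
default because the validated range is only two orders of magnitude and the
reference workflow used the unweighted fit.

Detection and quantification limits come from the intercept's standard
error, not the residual SD:

$$\mathrm{LOD} = 3.3\,\frac{SE(a)}{b}, \qquad
  \mathrm{LOQ} = 10\,\frac{SE(a)}{b},$$

so LOQ/LOD is structurally 10/3.3. Matrix effects are tested by comparing
the external-standard and standard-addition slopes with
$t = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}$ on $n_1 + n_2 - 4$ degrees of
freedom (Welch–Satterthwaite available via `df_method = "welch"`). Unknowns
are quantified by inverse prediction with the standard
$s_{x_0}$ formula; responses outside the calibrated range are flagged, not
rejected, because real extracts can exceed the range and the flag should
propagate to the report rather than abort a batch.

## Precision, Horwitz and HORRAT

Fortified samples at spikes of 0.5, 1.0 and 2.0 %w/w above a 1.3 %w/w
background are measured in triplicate on each of two days. Repeatability
and reproducibility are separated by one-way ANOVA with day as the factor:

$$\mathrm{RSD}_r = 100\,\frac{\sqrt{MS_w}}{\bar{y}}, \qquad
  \mathrm{RSD}_R = 100\,\frac{\sqrt{MS_w + s_B^2}}{\bar{y}},
  \quad s_B^2 = \max\!\left(\frac{MS_B - MS_w}{n_{\mathrm{per\,day}}}, 0\right).$$

The truncation at zero keeps $\mathrm{RSD}_R \ge \mathrm{RSD}_r$ by
construction. The ANOVA route was chosen over a pooled naive SD because the
2-day × 3-replicate design is exactly what variance components describe.

Observed RSDs are judged against the Horwitz function,
$\mathrm{PRSD}_R = 2^{\,1 - 0.5\log_{10} c}$ percent at mass fraction $c$,
with repeatability predicted through the empirical rule $r = 0.66R$. The
HORRAT ratio (observed/predicted) must be strictly below 2 on both bases.
The Horwitz concentration argument uses the **total** analyte content
(background + spike), the standard HORRAT convention; a spike-only basis is
exposed (`horwitz_basis = "spike"`) because fortified-study reporting is
sometimes read that way — at these contents both bases pass comfortably.
Thompson's low-concentration modification (flat 22 % below ~120 ppb) is not
implemented: caffeine in coffee sits four orders of magnitude above that
regime.

Recovery is computed per replicate as
$100\,(y_{\mathrm{total}} - y_{\mathrm{bg}})/\mathrm{spike}$, with the
background estimated from unspiked replicates of the same study (an
external value can be supplied). A level passes when the mean lies in
80–120 %. Note that a spike-only recovery inherits the *total*-content
measurement noise divided by the (smaller) spike, so its replicate SD is
several times the RSD of the underlying measurements at the 0.5 %w/w
level; summaries based on recovery SDs are therefore much noisier at low
spikes than the content RSDs themselves.

## The uncertainty budget

Five independent relative components combine by root-sum-of-squares into
$u_c$, expanded with $k = 2$ (≈95 % confidence):

* `u_mass`, `u_volume`: balance and glassware tolerances converted by the
  rectangular rule (÷√3), the volume term RSS'd with a rectangular thermal
  expansion term. Defaults (0.5 mg on 0.5 g; 0.02 mL on 10 mL; ±4 °C with
  water's 2.1 × 10⁻⁴ /°C) contribute well under 1 % of the budget.
* `u_calibration`: the relative inverse-prediction SD at the working
  concentration, smallest at the calibration centroid — one reason the
  calibrated range is centred near typical sample extracts.
* `u_bias`: by default $\sqrt{(100 - \overline{\mathrm{rec}})^2 +
  SE(\mathrm{rec})^2}$. Eurachem practice admits several variants (bias
  treated as corrected, leaving only its SE; or as a rectangular limit);
  both are selectable because the choice is genuinely conventional, and it
  materially changes low-spike budgets where the recovery estimate is noisy.
* `u_precision`: the reproducibility RSD, unchanged.

A sixth optional component (`stock_standard`) covers the purity/assay
uncertainty of the stock calibrant, default 0. Since any subset of
components gives an expanded uncertainty no larger than the full budget,
subset budgets are useful as lower-bound cross-checks against externally
reported totals.

## Internal quality control

A fortified control sample (the 1.0 %w/w spike) is analysed after every
five runs. The Shewhart chart uses the classical multiples — warning at
±2σ, action at ±3σ — estimated from a baseline of 20 points by default
(the conventional number for establishing limits; 8 is the hard minimum).
The system is declared in control when at most 5 % of evaluated points
exceed the warning limits and none exceeds the action limits, evaluated
over the full monitored series rather than a moving window. A run of ≥7
consecutive points on one side of the centre is reported as an advisory
trend flag only; no further Westgard rules are applied because the
acceptance criterion is the two-rule verdict above.

## The synthetic-data generator

All inputs are simulated with known ground truth so that every downstream
estimator can be tested as a parameter-recovery problem:

* **Chromatograms** — a Gaussian analyte peak (σ = 0.02 min at 7.5 min) on
  white Gaussian baseline noise, sampled at 25 Hz. Area, not shape, carries
  the quantitative information, so peak asymmetry, co-eluting matrix peaks
  and detector saturation are deliberately not modelled; passing tests say
  nothing about resolving overlapped peaks.
* **Validation studies** — measured content
  $(\mathrm{bg} + \rho_l\,\mathrm{spike}_l)(1 + \delta_{ld})(1 +
  \varepsilon_{ldr})$ with Gaussian day effects $\delta$ and replicate
  effects $\varepsilon$ on the relative scale, truncated at zero. A
  multiplicative (CV-based) error model was chosen because all precision
  figures of merit are %RSDs. Default CVs are per level: within-day
  4.1/2.5/2.0 %, with between-day components
  $\sqrt{\mathrm{RSD}_R^2 - \mathrm{RSD}_r^2}$ = 1.85/2.30/0.92 % so the
  total reproducibility is 4.5/3.4/2.2 %; default true recoveries are
  93.5/96.7/102.0 %.
* **QC series** — i.i.d. Gaussian around the control value with optional
  injected shifts recorded as ground truth.

One global seed drives everything; each stage derives its own substream so
stages can be regenerated independently and a fixed configuration yields a
bit-identical report.

## Numerical choices

* Baseline estimation is a morphological opening — centred rolling minimum
  then rolling maximum over a 0.5 min window (O(n) prefix/suffix extrema) —
  followed by a rolling mean. On a noise-free monotone drift this recovers
  the baseline exactly away from the record ends (edge replication biases
  the estimate within about one window of either end); under noise the opening tracks the lower envelope,
  so accuracy is a few noise SDs, which is immaterial at chromatographic
  signal-to-noise ratios (peak heights here are ~10⁵ × the noise SD).
* Integration is the trapezoid rule (robust on irregular sampling; Simpson
  buys nothing at 25 Hz), with negative baseline-subtracted samples clipped
  at zero so areas are non-negative. On a dense Gaussian the quadrature
  error is below 0.5 %, and because the same small relative error applies
  to every calibration level it cancels through the fit: the noise-free
  pipeline inverts injected concentrations to better than 0.1 %.
* Retention-time matching uses a ±0.1 min tolerance; equidistant candidates
  resolve toward the larger area, since the analyte is the dominant peak.
* Perfect fits (zero residuals) are legal inputs throughout: slope
  comparison then substitutes a machine-epsilon SE floor (with a warning)
  so identical slopes give t = 0 instead of 0/0.

## Problem sizes used in the tests

The simulation-based checks run at sizes chosen to put Monte-Carlo error
well below the tolerances being asserted while staying desk-scale: 400
replicate traces for the area model, 2000 replicate studies (each 3 levels
× 2 days × 3 replicates) for recovery and precision recovery, 10⁴
replicates for the slope-test type-I error and the QC false-alarm rate, and
a 3000-draw parametric bootstrap as the oracle for the calibration
uncertainty.

## Known limitations

* The generator produces ideal Gaussian peaks; the signal-processing chain
  is validated for area recovery, not for overlapped-peak deconvolution or
  retention-index drift.
* Back-extraction is treated as volume-preserving; partition losses are
  absorbed into the recovery bias rather than modelled chemically.
* The intake arithmetic takes the per-cup coffee mass (80 mg) verbatim from
  the consumption scenario it reproduces; the figure is far below a real
  brewed serving, so treat the default intake numbers as a worked example,
  not an exposure assessment.
* Expanded uncertainties from a single simulated study are themselves
  noisy at the lowest spike (the recovery-bias component divides
  total-content noise by a 0.5 %w/w spike); comparisons against externally
  reported budgets should use the deterministic bias+precision subsets as
  lower bounds.
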