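---
title: "Quantitative DCE-MRI response assessment: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DCE-MRI response assessment: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfutex)
```

perfutex implements the complete quantitative chain used to assess tumour
response to neoadjuvant chemoradiotherapy from dynamic contrast-enhanced
(DCE) MRI: baseline T1 mapping, conversion of signal to contrast-agent
concentration, extended Tofts pharmacokinetic mapping, 3D co-occurrence
texture of the parameter maps, and a biomarker statistics stage (group
screening, redundancy filtering, logistic modelling, ROC and DeLong
comparisons). Because clinical DCE data of this kind are rarely shareable,
the package also ships a phantom generator that synthesizes whole cohorts
with known ground truth; every stage of the pipeline is validated against
it. This vignette explains the models, the tunable parameters, and the
design decisions that were genuinely open.

## Signal model and relaxometry

The dynamic series is modelled as a spoiled gradient echo (SPGR) in steady
state,

$$ S = M_0 \sin\alpha \, \frac{1 - E}{1 - E\cos\alpha},
   \qquad E = e^{-TR/T_1}, $$

with default protocol constants TR/TE = 3.9/1.4 ms, dynamic flip angle
$\alpha$ = 12°, 40 frames at 6 s spacing (240 s), 5 mm slices, and two
pre-contrast frames before a 0.1 mmol/kg gadolinium bolus at 2 mL/s.

Baseline T1 (`vfa_t1_fit()`) uses the variable-flip-angle method: the SPGR
equation linearizes as $S/\sin\alpha = E \cdot S/\tan\alpha + M_0(1-E)$, so
an ordinary per-voxel regression of $S/\sin\alpha$ on $S/\tan\alpha$ yields
$E$ and hence T1. Default angles are 3°–15° in 3° steps; voxels whose slope
falls outside $(0,1)$ are flagged invalid rather than propagated. The fit is
scale-invariant: rescaling all volumes rescales $M_0$ and leaves T1
untouched.

Concentration conversion assumes fast water exchange,
$1/T_1(t) = 1/T_{10} + r_1 C(t)$, with relaxivity $r_1$ = 4.3 s⁻¹mM⁻¹ by
default (a configuration constant typical of gadodiamide at 3 T, not a
measured value). Two conversions are provided:

* **linear** (the default, mirroring common perfusion software):
  $C(t) = (S(t)-S_0)/(S_0\, r_1\, T_{10})$ with $S_0$ the mean of the
  pre-contrast frames;
* **exact**: closed-form inversion of the SPGR ratio $S(t)/S_0$ for
  $T_1(t)$.

A point worth knowing before trusting linear-mode outputs quantitatively:
the linear reduction assumes signal proportional to $1/T_1$, which requires
the $E\cos\alpha$ term of the SPGR denominator to be negligible. At a
12° flip angle with TR = 3.9 ms and T1 ≈ 1 s it is not:
$d\ln S/dR_1 \approx 0.85\,T_{10}$, so the linear conversion systematically
*underestimates* concentration by roughly 15% even for small enhancements,
and Ktrans inherits a bias of similar size (20–25% on phantoms, partly
cancelling through the AIF, which is scaled by the same mechanism at the
blood T1). The package therefore runs its quantitative recovery checks with
the exact inversion and keeps linear mode as the fidelity-to-practice
default. Negative concentrations from noise are retained, not clipped, so
noise statistics stay unbiased (an optional clip flag exists).

## Arterial input and kinetic model

The arterial input function is taken from an aorta mask as the mean blood
concentration curve divided by $1-\mathrm{Hct}$ (default hematocrit 0.42),
because the Tofts model is driven by *plasma* concentration. Whether
clinical software applies this correction is often undocumented; it can be
disabled by passing `hematocrit = 0`.

Tissue kinetics follow the extended Tofts model,

$$ C_t(t) = v_p\,C_p(t) + K^{trans}\!\int_0^t C_p(\tau)\,
   e^{-k_{ep}(t-\tau)}\,d\tau, \qquad v_e = K^{trans}/k_{ep}, $$

evaluated by causal trapezoidal quadrature on the acquisition grid (rates
are reported per minute; integration runs in seconds). `fit_voxel()` solves
the bounded nonlinear least-squares problem in $(K^{trans}, k_{ep}, v_p)$
with a Levenberg–Marquardt solver, initialized from the linear matrix
formulation of the model equations
($C_t = a_1\int C_p + a_2\int C_t + a_3 C_p$), which is itself exposed as a
fast mode. Bounds are $K^{trans}\in[0,5]$ min⁻¹, $k_{ep}\in(0,10]$ min⁻¹,
$v_p\in[0,0.5]$; solver failure or a bound hit sets `fit_ok = FALSE` — never
a silent zero. No per-voxel bolus-arrival time is fitted: at 6 s resolution
that problem is ill-posed, so onset is inherited from the AIF.

## Texture features

Texture is computed on a parameter map (Ktrans by default) restricted to the
lesion: min–max quantization into 32 gray levels, a single 3D co-occurrence
matrix pooled over the 13 unique voxel-neighbour directions at distance 1,
counted symmetrically and normalized, then seven classical features (energy,
entropy, inertia, correlation, cluster shade, cluster prominence, inverse
difference moment). Entropy uses log base 2. Pooling directions into one
matrix (rather than averaging per-direction features) follows the convention
of several radiomics engines; levels, distance, symmetry and log base are
all configurable. The GLCM engine is verified against a brute-force
pair-enumeration oracle on small grids.

## Phantom generator

The generator defines the conditions the pipeline is tested under:

* **Acquisition** — the protocol constants above.
* **AIF** — a closed-form population curve: zero before bolus arrival
  (at the end of the baseline frames, 12 s), then a smooth rise
  ($1-e^{-6\tau}$, $\tau$ in minutes, modelling a 2 mL/s injector bolus)
  multiplying the classical biexponential plasma decay
  ($3.99\,e^{-0.144\tau} + 4.78\,e^{-0.0111\tau}$ kg/L, scaled by the
  0.1 mmol/kg dose). At 6 s sampling its trapezoidal integral matches a
  0.1 s fine-grid quadrature within 0.2%.
* **Lesion kinetics** — each lesion draws a lesion-level mean from its
  response class's truncated-normal distribution (complete response CR,
  post-treatment: Ktrans 0.117 ± 0.065 min⁻¹, ve 0.130 ± 0.094; partial
  response PR: 0.299 ± 0.231, 0.322 ± 0.204; corresponding pre-treatment
  moments for the first visit; vp of a few tenths of a percent). The
  truncation bounds keep parameters physical, and the normal's location is
  adjusted so the *truncated* mean still equals the class mean — the
  generator is unbiased for the condition it encodes. Pre- and post-visit
  draws are independent; the implied change-score dispersions are consistent
  with the class moments of the changes.
* **Heterogeneity** — voxel values modulate the lesion mean by a bounded,
  mean-one multiplicative random field (a Gaussian random field mapped
  through a symmetric beta quantile). Flatter marginals and weaker
  neighbour correlation both raise co-occurrence entropy. Pre-treatment
  lesions of both classes share one texture regime (smooth, peaked
  marginal), so pre-treatment texture does not separate the classes; after
  treatment CR lesions roughen mildly and PR lesions markedly, so map
  entropy rises in both classes and is higher in PR, at an effect size
  comparable to the kinetic markers'. (A heavier-tailed amplitude alone
  does *not* achieve this: min–max quantization compresses skewed
  histograms into few bins and can lower entropy, which is why the
  mechanism is correlation- and shape-based.) Absolute entropy magnitudes
  depend on lesion size and quantization depth and are not matched, only
  the class ordering and separation. One induced artefact is worth knowing:
  a single roughness axis makes *all* roughness-sensitive co-occurrence
  features (inertia, correlation, IDM, cluster prominence) co-vary with
  entropy, so on image-level phantom cohorts these features also separate
  the classes post-treatment, whereas real cohorts may single out entropy.
* **Tissue constants** — T1(0) of 1.0 s for tissue and 1.6 s for blood
  (typical 3 T values), M0 = 1000, additive Gaussian signal noise with SD
  2% of the baseline signal by default (high-SNR magnitude MRI is
  approximately Gaussian); aorta voxels carry whole-blood concentration
  $(1-\mathrm{Hct})\,C_p$.

`make_cohort()` writes per patient and visit a 4D dynamic NIfTI, a 4D
multi-flip-angle baseline file, lesion and aorta masks, and a CSV manifest
with the true lesion-level parameters. A lesion-level shortcut,
`simulate_feature_table()`, draws per-patient ROI summaries (and entropy)
directly from the class moments, skipping image synthesis; it is the
workhorse for replicate-level statistics, where hundreds of cohorts are
needed. Default problem sizes — 9×9×5 lesion blocks (~120 voxels), 16+16
patients per cohort, 200 replicates for Monte-Carlo fractions — were chosen
as the smallest sizes at which the phantom's class conditions are stable.

What the phantom does *not* emulate: breathing motion (masks are assumed
co-registered, as after registration), B1 inhomogeneity, slice profiles,
k-space sampling, Rician noise floors at low SNR, partial-volume and inflow
effects in the aorta, and any correlation between kinetic and texture
markers beyond what the shared lesion mean induces. Passing tests therefore
demonstrate correctness of the estimation and statistics chain under its own
model assumptions, not robustness to those real-world effects.

## Statistics stage

`run_full_analysis()` mirrors a standard biomarker workflow on the
per-patient pre/post/change table:

1. **Screening** — two-sided Mann–Whitney U per feature between response
   classes (exact null for pooled n ≤ 12 without ties, otherwise normal
   approximation with tie and continuity corrections). No multiplicity
   correction is applied by default, matching common practice in small
   exploratory studies; the screening is explicitly exploratory.
2. **Redundancy filter** — candidates with p < 0.05 are ordered by ascending
   p and greedily retained unless |Spearman ρ| ≥ 0.6 against an
   already-retained feature. The survivor rule (keep the smaller-p member)
   is a design choice; the threshold 0.6 is the conventional cut.
3. **Model** — maximum-likelihood logistic regression of class on the
   retained features, CR as the positive class. Wald statistics
   $(\beta/SE)^2$, odds ratios $e^\beta$ and 95% CIs
   $e^{\beta \pm 1.96\,SE}$ are pure functions of the coefficient table.
   With 32 subjects and three predictors, quasi-separation is a real
   possibility; it is detected and flagged, never silently dropped.
4. **ROC** — AUC by the rank formulation (half credit for ties; equal to
   the Mann–Whitney U divided by $n_1 n_2$), DeLong 95% CI, and the cutoff
   maximizing Youden's J with ties broken toward higher sensitivity. Marker
   direction is folded so single-marker AUCs are ≥ 0.5.
5. **Model comparison** — post-only, change-only and combined variants are
   fitted on the significant set and compared pairwise by the paired DeLong
   test. Inside the test both curves use a fixed common direction; choosing
   directions per curve from the data inflates the type-I error, which is
   visible in null calibration simulations.

A reference coefficient set for the post-treatment model
(`response_model_preset()`) ships with the package: logit P(CR) =
26.772 − 17.010 Ktrans_post − 15.854 ve_post − 3.235 entropy_post. All three
coefficients are negative — lower residual permeability, smaller
extravascular volume fraction and lower map entropy after treatment all
favour complete response — so the predicted probability is monotone
decreasing in each marker.

## Numerical and degenerate-input policy

* Convolution and cumulative integrals use trapezoidal rules on the
  sampling grid; the boxcar-AIF closed form is reproduced within 1% at 6 s
  spacing.
* All-zero or non-finite voxel curves yield `fit_ok = FALSE` (all-zero gives
  Ktrans = 0 with `fit_ok = TRUE`, since that is the exact answer); ROI
  summaries average over `fit_ok` voxels only and error loudly when none
  remain.
* Constant maps quantize to a single level; a constant region has entropy 0
  and energy 1; GLCM correlation is reported missing when a marginal is
  degenerate.
* Constant pooled samples give Mann–Whitney p = 1 with a warning; identical
  score vectors give DeLong p = 1 with a warning.
* Seeds: every stochastic entry point takes an explicit integer seed and
  restores the caller's RNG state, so generator calls are reproducible and
  side-effect free.

## Known limitations

* The linear conversion's shallow-angle scale bias (above) is inherent to
  that reduction, not a bug; quantitative use should prefer
  `conversion = "exact"`.
* ROI-mean recovery degrades when many voxels hit parameter bounds; the
  generator keeps voxel kinetics inside the fit bounds, real data need not.
* Absolute texture magnitudes depend on quantization depth, lesion size and
  co-occurrence conventions and are not comparable across software; only
  within-study contrasts are meaningful.
* The statistics stage fits and evaluates in-sample, as small single-centre
  studies typically do; reported AUCs are optimistic and no cross-validation
  is attempted.
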