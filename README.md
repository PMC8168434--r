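# perfutex

Quantitative DCE-MRI analysis of tumour response to neoadjuvant
chemoradiotherapy, for imaging scientists who need the full chain from raw
dynamic signal to response biomarkers in one tested package:

* **Relaxometry** — variable-flip-angle baseline T1 mapping from the
  linearized SPGR relation, and signal-to-concentration conversion (the
  standard linear reduction `C = (S − S₀)/(S₀ r₁ T₁₀)`, or exact closed-form
  SPGR inversion).
* **Pharmacokinetics** — voxelwise extended Tofts model
  `Cₜ(t) = vₚ Cₚ(t) + Ktrans ∫₀ᵗ Cₚ(τ) e^(−kep (t−τ)) dτ`, fitted by bounded
  Levenberg–Marquardt with a linear least-squares initialization, yielding
  Ktrans, Kep, ve = Ktrans/Kep and vp maps.
* **Texture** — 3D gray-level co-occurrence matrices of the parameter maps
  (32 levels, 13 pooled directions, symmetric) and the seven classical
  features: energy, entropy, inertia, correlation, cluster shade, cluster
  prominence, inverse difference moment.
* **Statistics** — per-patient pre/post/change feature tables, Mann–Whitney
  screening, greedy Spearman redundancy filtering (|ρ| ≥ 0.6), logistic
  response modelling with Wald/OR/CI reporting, ROC with Youden-optimal
  cutoffs, and paired DeLong model comparisons.
* **Phantom cohorts** — a synthetic DCE-MRI generator (population AIF,
  class-conditional lesion kinetics and heterogeneity, NIfTI output with a
  ground-truth manifest) so the entire pipeline is testable end to end
  without patient data.

See `vignettes/dce-response-pipeline.Rmd` for the models, assumptions and
design decisions in detail.

## Worked example

Simulate a small cohort, process it end to end, and run the statistics
stage:

```r
library(perfutex)

res <- run_all(out_dir = tempfile("demo"), simulate = TRUE,
               n_cr = 16, n_pr = 16, seed = 2, conversion = "exact")
print(res$report)
```

```
Response-biomarker analysis report
  33 features screened, 10 significant at p < 0.05
  retained after Spearman filter: ve_change, correlation_post, idm_post 
  combined model AUC 0.973
    ve_change        AUC 0.871
    correlation_post AUC 0.820
    idm_post         AUC 0.793
  DeLong model comparisons:
    post_vs_change           p = 0.1128
    post_vs_change_post      p = 1.0000
    change_vs_change_post    p = 0.1128
```

The screening finds post-treatment and change markers separating complete
from partial responders while pre-treatment features stay null, the
redundancy filter reduces them to a small uncorrelated set, the combined
logistic model's AUC exceeds each single marker's, and the DeLong
comparisons find no significant difference between the post/change model
variants (the post-plus-change variant quasi-separates in-sample at
n = 32, collapsing its comparison to p = 1) — the qualitative signature
this kind of response study reports.
(Which individual markers survive the filter varies from cohort to cohort
at n = 16 + 16; over many replicates the post-treatment Ktrans, ve and
entropy dominate.) The shipped reference model is available as a preset:

```r
preset <- response_model_preset()
predict_prob(preset, data.frame(ktrans_post = 0.117, ve_post = 0.130,
                                entropy_post = 6.084))
#> [1] 0.9543083
```

A post-treatment lesion at the complete-response class means gets a 95%
predicted probability of complete response.

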