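# opilearn

Surgical data science toolkit for analysing registries of robotic
ventral hernia repairs (RVHR) described by **objective performance
indicators (OPIs)** — event-based measures of operator behaviour
(head-in-console events, clutch use, energy activation, ...) logged by
the robotic platform. It is written for surgical-education and
clinical-performance researchers who want to ask, on a longitudinal
single-surgeon case series:

1. **Do OPIs predict case complexity?** Case complexity is a three-level
   label (minor / moderate / major) assigned from patient and hernia
   characteristics. An iterative model competition (random forest,
   gradient boosting, decision tree, SVM, k-NN, multinomial logistic)
   predicts the label from OPI-only, clinical-only and combined
   covariate sets; variants are selected by stratified five-fold
   cross-validated F1 (support-weighted harmonic mean of precision and
   recall), and winners are explained by per-class SHAP rankings.
2. **Do OPIs trace the surgeon's learning curve?** Cases are binned by
   month of operation; all (case, OPI) rows are embedded jointly by
   t-SNE into 2-D, components are averaged per (bin, OPI) into points
   `p_{i,j|t}`, and consecutive bins are compared by the weighted
   Euclidean distance

   ```
   d_{t,t+1} = sqrt( (w_{t+1,t} / c_{t+1}) * sum_{n in (i,j)} (p_{n|t+1} - p_{n|t})^2 )
   ```

   with `w` the day gap between the bins' last case days and `c` the
   later bin's case volume, smoothed with a Savitzky-Golay filter
   (window 5, order 2), per OPI representation group (count, rate,
   normalised duration).
3. **When does the surgeon become an Expert?** Dispersion traces of the
   per-OPI displacement vectors — the leading eigenvalue of their 2×2
   second-moment matrix and their origin-anchored convex-hull area —
   are fitted with exponential decays `f(x) = a·exp(-b·x) + c`; bins
   with `f(t) > E[f]` are labelled Novice, the rest Expert, the
   transition being the first Expert bin. The OPI-only models are then
   re-run separately on the Novice and Expert phases.

Since registries of this kind are not publicly deposited, the package
includes a **synthetic cohort generator** that reproduces the published
marginals of such a registry (complexity mix 38.7/45.5/15.8%, an
exclusion rate of 93/561 for concurrent procedures, Table-style patient
covariates) and plants a known skill dynamic — per-case OPI noise
decaying with the primary surgeon's cumulative experience,
`sigma(n) = sigma_inf + (sigma0 - sigma_inf)·exp(-n/tau)` — together
with a ground-truth sidecar, so every pipeline stage is testable
against a known answer. See the methods vignette
(`vignettes/opi-skill-analysis.Rmd`) for the model, its assumptions and
all numerical choices.

## Worked example

```r
library(opilearn)

# a scaled synthetic registry: 96 months, ~310 cases, 6 OPI event types
cfg   <- cohort_config(seed = 1, cases_per_month = 3.2, n_opi = 6, tau = 16)
sim   <- generate_cohort(cfg)
cases <- filter_cohort(sim$cases)          # concurrent-procedure exclusion

# complexity models on two covariate sets
grid <- model_grid(seed = 1)
rep_clin <- run_competition(encode_features(cases, "clinical_only"), grid)
rep_opi  <- run_competition(encode_features(cases, "opi_only"), grid)
rep_clin$winner$cv_f1; rep_opi$winner$cv_f1

# learning curves and skill segmentation
curves <- build_curves(cases, n_iter = 350, seed = 0)
early_late_contrast(curves)$pooled
att <- cases[cases$primary_surgeon_role == "attending", ]
seg <- segment_cases(att, seed = 0, n_iter = 350)
seg$transition_date
```

Output from this exact script (seed 1):

```
[1] 0.7653643
[1] 0.5046888
[1] 2.466095
[1] "2015-12-17"
```

Read: clinical covariates predict complexity far better than OPIs
(CV F1 ~0.77 vs ~0.50 — OPIs alone are poor
complexity predictors), early bins moved roughly 2.5 times
more than late bins in the embedded OPI space (the learning curve falls
and flattens), and the fitted decay places the Novice-to-Expert
transition at 2015-12-17.

The same analysis, end to end with all artifacts, is scripted under
`analysis/` (run `Rscript analysis/01_simulate.R` ...
`analysis/05_report.R` from the repository root; outputs land in
`results/`), or in one call via `run_all(pipeline_config(...))`.

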