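# The model competition predicting 3-level case complexity from each
# covariate set, the attending/trainee sensitivity split, and SHAP
# rankings of the winners.
source("analysis/00_common.R")

cases <- read_cohort(file.path(RESULTS_DIR, "cohort_filtered.csv"))
grid <- model_grid(seed = ROOT_SEED)

reports <- lapply(c(opi_only = "opi_only",
                    clinical_only = "clinical_only",
                    combined = "combined"), function(s) {
  rep <- run_competition(encode_features(cases, s), grid)
  cat(sprintf("%-14s winner %-14s CV F1 %.3f\n", s, rep$winner$family,
              rep$winner$cv_f1))
  rep
})

roles <- run_subset_comparison(cases, subset_by_role, grid,
                               feature_set = "opi_only")
for (r in roles)
  cat(sprintf("OPI-only, %-14s winner %-14s CV F1 %.3f\n",
              r$subset_label, r$winner$family, r$winner$cv_f1))

f1_tab <- do.call(rbind, lapply(c(reports, roles), function(r)
  data.frame(feature_set = r$feature_set, subset = r$subset_label,
             winner = r$winner$family, cv_f1 = r$winner$cv_f1)))
readr::write_csv(f1_tab, file.path(RESULTS_DIR, "model_f1_summary.csv"))

for (s in c("clinical_only", "opi_only")) {
  rk <- rank_shap(reports[[s]], nsim = 15, explain_n = 80,
                  seed = ROOT_SEED)
  df <- do.call(rbind, lapply(names(rk), function(cl)
    cbind(data.frame(class = cl), rk[[cl]])))
  readr::write_csv(df, file.path(RESULTS_DIR,
                                 sprintf("shap_%s.csv", s)))
  cat(sprintf("top SHAP covariates (%s): %s\n", s,
              paste(unique(unlist(lapply(rk, function(d)
                d$feature[1:3]))), collapse = ", ")))
}

cat(sprintf("clinical-minus-OPI winner F1 gap: %.3f\n",
            reports$clinical_only$winner$cv_f1 -
              reports$opi_only$winner$cv_f1))
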