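# The OPI learning curves: joint t-SNE embedding of monthly bins,
# weighted Euclidean distances between consecutive bins, Savitzky-Golay
# smoothing, per representation group.
source("analysis/00_common.R")
suppressMessages(library(ggplot2))

cases <- read_cohort(file.path(RESULTS_DIR, "cohort_filtered.csv"))

curves <- build_curves(cases, n_iter = 350, seed = 0)
df <- curves_to_df(curves)
readr::write_csv(df, file.path(RESULTS_DIR, "learning_curves.csv"))

contrast <- early_late_contrast(curves)
cat("early/late smoothed-distance ratios:\n")
print(round(contrast$per_group, 2))
cat(sprintf("pooled ratio: %.2f (values > 1 mean early cases moved more)\n",
            contrast$pooled))

trend <- movement_trend_test(curves$groups$count, seed = 1)
cat(sprintf("weight-corrected movement trend (count group): p = %.3f\n",
            trend$p_value))

p <- ggplot(df, aes(t, smoothed_d)) +
  geom_line(aes(y = raw_d), colour = "grey70", linewidth = 0.3) +
  geom_line(colour = "steelblue") +
  facet_wrap(~group, scales = "free_y", ncol = 1) +
  labs(x = "monthly bin", y = "weighted Euclidean distance",
       title = "OPI learning curves (raw and smoothed)") +
  theme_minimal()
ggsave(file.path(RESULTS_DIR, "learning_curves.png"), p,
       width = 7, height = 8, dpi = 150)
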