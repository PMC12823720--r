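# Collect the artifacts written by the earlier drivers into one
# human-readable summary.
source("analysis/00_common.R")

lines <- c("# Analysis summary", "")

f1p <- file.path(RESULTS_DIR, "model_f1_summary.csv")
if (file.exists(f1p)) {
  f1 <- readr::read_csv(f1p, show_col_types = FALSE)
  lines <- c(lines, "## Complexity model winners", "",
             sprintf("- %s / %s: %s, CV F1 %.3f",
                     f1$feature_set, f1$subset, f1$winner, f1$cv_f1), "")
}
cp <- file.path(RESULTS_DIR, "learning_curves.csv")
if (file.exists(cp)) {
  d <- readr::read_csv(cp, show_col_types = FALSE)
  rat <- vapply(split(d, d$group), function(g) {
    k <- min(10, floor(nrow(g) / 2))
    mean(g$smoothed_d[1:k]) / mean(tail(g$smoothed_d, k))
  }, numeric(1))
  lines <- c(lines, "## Learning curves", "",
             sprintf("- %s: early/late ratio %.2f", names(rat), rat), "")
}
sp <- file.path(RESULTS_DIR, "segmentation.json")
if (file.exists(sp)) {
  seg <- jsonlite::read_json(sp, simplifyVector = TRUE)
  lines <- c(lines, "## Skill segmentation", "",
             sprintf("- transition bin %d on %s (eigen %d / hull %d)%s",
                     seg$transition_t, seg$transition_date,
                     seg$transition_eigen, seg$transition_hull,
                     if (isTRUE(seg$disagreement)) ", traces disagree"
                     else ", traces agree"))
}
writeLines(lines, file.path(RESULTS_DIR, "summary.md"))
cat(lines, sep = "\n")
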