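# Novice/Expert segmentation of the attending surgeon's timeline from
# decay fits to the displacement dispersion traces, and the OPI-only
# model competition re-run on the two phases.
source("analysis/00_common.R")

cases <- read_cohort(file.path(RESULTS_DIR, "cohort_filtered.csv"))
att <- cases[cases$primary_surgeon_role == "attending", ]

seg <- segment_cases(att, seed = 0, n_iter = 350)
cat(sprintf("eigen transition bin %d, hull transition bin %d%s\n",
            seg$transition_eigen, seg$transition_hull,
            if (seg$disagreement) " (traces disagree; later bin used)"
            else " (traces agree)"))
cat(sprintf("combined transition: bin %d, date %s\n", seg$transition_t,
            seg$transition_date))

jsonlite::write_json(
  list(transition_eigen = seg$transition_eigen,
       transition_hull = seg$transition_hull,
       transition_t = seg$transition_t,
       transition_date = as.character(seg$transition_date),
       disagreement = seg$disagreement,
       eigen = list(t = seg$eigen$t, value = seg$eigen$value,
                    fitted = seg$eigen$fitted, params = seg$eigen$params,
                    labels = seg$eigen$labels),
       hull = list(t = seg$hull$t, value = seg$hull$value,
                   fitted = seg$hull$fitted, params = seg$hull$params,
                   labels = seg$hull$labels)),
  file.path(RESULTS_DIR, "segmentation.json"),
  auto_unbox = TRUE, digits = NA)

grid <- model_grid(seed = ROOT_SEED)
post <- rerun_after_segmentation(cases, seg, grid)
for (r in post)
  cat(sprintf("post-segmentation %-7s winner %-14s CV F1 %.3f\n",
              r$subset_label, r$winner$family, r$winner$cv_f1))

readr::write_csv(
  do.call(rbind, lapply(post, function(r)
    data.frame(phase = r$subset_label, winner = r$winner$family,
               cv_f1 = r$winner$cv_f1))),
  file.path(RESULTS_DIR, "post_segmentation_f1.csv"))
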