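# Shared settings for the analysis drivers. Run the scripts from the
# repository root in numeric order; each writes its outputs under
# results/.
suppressMessages(library(opilearn))

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

ROOT_SEED <- as.integer(Sys.getenv("OPILEARN_SEED", "1"))

# Analysis profile: the registry's 96-month span with monthly volume, OPI
# count and experience decay constant scaled down proportionally (the
# methods vignette motivates the scaling).
analysis_config <- cohort_config(seed = ROOT_SEED, cases_per_month = 3.2,
                                 n_opi = 6, tau = 16)
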