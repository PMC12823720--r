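# End-to-end orchestration: simulate (or load) -> exclusion filter ->
# encode -> model competitions (three feature sets; attending vs trainee
# split) -> learning curves -> skill segmentation -> post-segmentation
# competitions. Artifacts are deterministic given the root seed; the run
# log (which carries timestamps) is excluded from the MANIFEST checksums.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] to simulate from, or `NULL` when
#'   loading an existing cohort.
#' @param cohort_csv Path to an existing cohort CSV (used when `cohort` is
#'   `NULL`; must exist).
#' @param grid A [model_grid()].
#' @param curve Curve parameters: `perplexity`, `seed`, `n_iter`, `window`,
#'   `polyorder`, `aggregate`.
#' @param segmentation Segmentation options: `representation`.
#' @param shap SHAP options: `top_k`, `nsim`, `explain_n`.
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cohort_csv = NULL,
                            grid = model_grid(),
                            curve = list(),
                            segmentation = list(),
                            shap = list(),
                            out_dir = tempfile("opilearn_run_")) {
  curve <- modifyList(list(perplexity = 30, seed = 0L, n_iter = 500,
                           window = 5, polyorder = 2, aggregate = "mean"),
                      curve)
  segmentation <- modifyList(list(representation = "count"), segmentation)
  shap <- modifyList(list(top_k = 20, nsim = 10, explain_n = 60), shap)
  if (is.null(cohort)) {
    if (is.null(cohort_csv) || !file.exists(cohort_csv))
      stop("pipeline configuration: cohort_csv does not exist: ",
           cohort_csv %||% "<missing>", call. = FALSE)
  }
  structure(list(cohort = cohort, cohort_csv = cohort_csv, grid = grid,
                 curve = curve, segmentation = segmentation, shap = shap,
                 out_dir = out_dir),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_to_list <- function(report) {
  list(feature_set = report$feature_set,
       subset_label = report$subset_label,
       per_family = report$per_family,
       winner = list(family = report$winner$family,
                     params = as.list(report$winner$params),
                     cv_f1 = report$winner$cv_f1,
                     macro_recall = report$winner$macro_recall,
                     per_class = report$winner$per_class))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes the artifact bundle
#' (`cohort.csv`, `ground_truth.json`, `reports.json`, `curves.csv`,
#' `segmentation.json`, SHAP rankings, `summary.md`, `MANIFEST.json`) to
#' `config$out_dir`. Any stage failure aborts with the stage name; partial
#' artifacts are retained and the MANIFEST notes incompleteness.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle (named list of stage outputs), invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat(sprintf("opilearn %s | R %s\n",
              as.character(utils::packageVersion("opilearn")),
              getRversion()), file = log_path)
  bundle <- list()
  artifacts <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      write_manifest(config$out_dir, artifacts, complete = FALSE,
                     failed_stage = name)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    cat(sprintf("stage %-16s %8.2fs\n", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        file = log_path, append = TRUE)
    out
  }
  emit <- function(fname) artifacts <<- union(artifacts, fname)

  bundle$cohort <- stage("simulate", {
    if (!is.null(config$cohort)) {
      sim <- generate_cohort(config$cohort)
      write_cohort(sim$cases, file.path(config$out_dir, "cohort.csv"))
      write_ground_truth(sim$truth,
                         file.path(config$out_dir, "ground_truth.json"))
      emit("cohort.csv"); emit("ground_truth.json")
      sim$cases
    } else {
      cs <- read_cohort(config$cohort_csv)
      write_cohort(cs, file.path(config$out_dir, "cohort.csv"))
      emit("cohort.csv")
      cs
    }
  })
  bundle$filtered <- stage("filter", filter_cohort(bundle$cohort))

  bundle$reports <- stage("competitions", {
    sets <- c("opi_only", "clinical_only", "combined")
    fs <- lapply(sets, function(s)
      run_competition(encode_features(bundle$filtered, s), config$grid))
    names(fs) <- sets
    roles <- run_subset_comparison(bundle$filtered, subset_by_role,
                                   config$grid, feature_set = "opi_only")
    list(feature_sets = fs, role_subsets = roles)
  })

  stage("shap", {
    for (s in c("clinical_only", "opi_only")) {
      rk <- suppressMessages(rank_shap(
        bundle$reports$feature_sets[[s]],
        top_k = config$shap$top_k, nsim = config$shap$nsim,
        explain_n = config$shap$explain_n, seed = config$grid$seed))
      df <- do.call(rbind, lapply(names(rk), function(cl)
        cbind(data.frame(class = cl, stringsAsFactors = FALSE), rk[[cl]])))
      fn <- sprintf("shap_%s.csv", s)
      readr::write_csv(df, file.path(config$out_dir, fn))
      emit(fn)
    }
    NULL
  })

  bundle$curves <- stage("curves", {
    cv <- build_curves(bundle$filtered,
                       perplexity = config$curve$perplexity,
                       seed = config$curve$seed,
                       n_iter = config$curve$n_iter,
                       window = config$curve$window,
                       polyorder = config$curve$polyorder,
                       aggregate = config$curve$aggregate)
    readr::write_csv(curves_to_df(cv), file.path(config$out_dir,
                                                 "curves.csv"))
    emit("curves.csv")
    cv
  })

  bundle$segmentation <- stage("segmentation", {
    att <- bundle$filtered[bundle$filtered$primary_surgeon_role ==
                             "attending", , drop = FALSE]
    seg <- segment_cases(att,
                         representation = config$segmentation$representation,
                         perplexity = config$curve$perplexity,
                         seed = config$curve$seed,
                         n_iter = config$curve$n_iter)
    jsonlite::write_json(
      list(transition_eigen = seg$transition_eigen,
           transition_hull = seg$transition_hull,
           transition_t = seg$transition_t,
           transition_date = as.character(seg$transition_date),
           disagreement = seg$disagreement,
           eigen = list(t = seg$eigen$t, value = seg$eigen$value,
                        fitted = seg$eigen$fitted,
                        labels = seg$eigen$labels,
                        params = seg$eigen$params),
           hull = list(t = seg$hull$t, value = seg$hull$value,
                       fitted = seg$hull$fitted, labels = seg$hull$labels,
                       params = seg$hull$params)),
      file.path(config$out_dir, "segmentation.json"),
      auto_unbox = TRUE, digits = NA)
    emit("segmentation.json")
    seg
  })

  bundle$post_segmentation <- stage("post_segmentation",
    rerun_after_segmentation(bundle$filtered, bundle$segmentation,
                             config$grid))

  stage("report", {
    rep_list <- list(
      feature_sets = lapply(bundle$reports$feature_sets, report_to_list),
      role_subsets = lapply(bundle$reports$role_subsets, report_to_list),
      post_segmentation = lapply(bundle$post_segmentation, report_to_list))
    jsonlite::write_json(rep_list,
                         file.path(config$out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    emit("reports.json")
    writeLines(summary_text(config$out_dir),
               file.path(config$out_dir, "summary.md"))
    emit("summary.md")
    NULL
  })

  write_manifest(config$out_dir, artifacts, complete = TRUE)
  invisible(bundle)
}

write_manifest <- function(out_dir, artifacts, complete,
                           failed_stage = NULL) {
  files <- artifacts[file.exists(file.path(out_dir, artifacts))]
  md5 <- as.character(tools::md5sum(file.path(out_dir, files)))
  jsonlite::write_json(
    list(complete = complete, failed_stage = failed_stage,
         artifacts = data.frame(file = files, md5 = md5,
                                stringsAsFactors = FALSE)),
    file.path(out_dir, "MANIFEST.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(NULL)
}

early_late_ratio <- function(curve_df, k = 10) {
  n <- nrow(curve_df)
  k <- min(k, floor(n / 2))
  mean(curve_df$smoothed_d[seq_len(k)]) /
    mean(curve_df$smoothed_d[seq(n - k + 1, n)])
}

summary_text <- function(out_dir) {
  lines <- c("# Run summary", "")
  gap <- function(what) sprintf("- MISSING artifact: %s", what)
  rp <- file.path(out_dir, "reports.json")
  lines <- c(lines, "## Model competitions", "")
  if (file.exists(rp)) {
    rep <- jsonlite::read_json(rp, simplifyVector = TRUE)
    for (s in names(rep$feature_sets))
      lines <- c(lines, sprintf("- %s winner: %s (CV F1 = %.4f)", s,
                                rep$feature_sets[[s]]$winner$family,
                                rep$feature_sets[[s]]$winner$cv_f1))
    for (s in names(rep$role_subsets))
      lines <- c(lines, sprintf("- subset %s winner: %s (CV F1 = %.4f)", s,
                                rep$role_subsets[[s]]$winner$family,
                                rep$role_subsets[[s]]$winner$cv_f1))
    for (s in names(rep$post_segmentation))
      lines <- c(lines,
                 sprintf("- post-segmentation %s winner: %s (CV F1 = %.4f)",
                         s, rep$post_segmentation[[s]]$winner$family,
                         rep$post_segmentation[[s]]$winner$cv_f1))
  } else lines <- c(lines, gap("reports.json"))
  lines <- c(lines, "", "## Learning curve", "")
  cp <- file.path(out_dir, "curves.csv")
  if (file.exists(cp)) {
    cdf <- as.data.frame(readr::read_csv(cp, show_col_types = FALSE,
                                         progress = FALSE))
    for (g in unique(cdf$group))
      lines <- c(lines, sprintf(
        "- %s: early/late smoothed-distance ratio = %.4f", g,
        early_late_ratio(cdf[cdf$group == g, ])))
  } else lines <- c(lines, gap("curves.csv"))
  lines <- c(lines, "", "## Skill segmentation", "")
  sp <- file.path(out_dir, "segmentation.json")
  if (file.exists(sp)) {
    seg <- jsonlite::read_json(sp, simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("- transition bin %d (%s), eigen %d / hull %d%s",
                       seg$transition_t, seg$transition_date,
                       seg$transition_eigen, seg$transition_hull,
                       if (isTRUE(seg$disagreement))
                         " [traces disagree]" else ""))
  } else lines <- c(lines, gap("segmentation.json"))
  lines
}

#' Human-readable summary of a run's artifact bundle
#'
#' Reads the artifacts in an output directory and produces a markdown
#' summary (winner F1 per feature set and subset, early/late curve ratio,
#' transition date). Missing artifacts are listed as absent; a summary is
#' still produced.
#'
#' @param out_dir A [run_all()] output directory.
#' @return Character vector of markdown lines.
#' @export
summarize_run <- function(out_dir) summary_text(out_dir)

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [cohort_config()],
#' [model_grid()] and [pipeline_config()]. Recognised top-level keys:
#' `cohort` (list of cohort_config arguments or `csv: path`), `grid`
#' (families, cv_folds, scoring, seed), `curve`, `segmentation`, `shap`,
#' `out_dir`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- NULL; cohort_csv <- NULL
  if (!is.null(raw$cohort$csv)) cohort_csv <- raw$cohort$csv
  else cohort <- do.call(cohort_config, raw$cohort %||% list())
  grid <- do.call(model_grid, raw$grid %||% list())
  pipeline_config(cohort = cohort, cohort_csv = cohort_csv, grid = grid,
                  curve = raw$curve %||% list(),
                  segmentation = raw$segmentation %||% list(),
                  shap = raw$shap %||% list(),
                  out_dir = raw$out_dir %||% tempfile("opilearn_run_"))
}
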