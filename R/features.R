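# Design matrices for the complexity models: clinical-only, OPI-only, and
# combined covariate sets. Categorical covariates are one-hot encoded over
# all observed levels (no reference-level drop, mirroring the treatment of
# surgeon identity); the primary surgeon's prior case count is the
# experience feature and belongs to every set.

clinical_numeric_cols <- c("age", "bmi", "asa", "hpw_stage", "vhwg_grade",
                           "defect_area")
clinical_flag_cols <- c("hypertension", "myocardial_infarction",
                        "coronary_artery_disease", "copd", "smoking_history",
                        "diabetes", "immunosuppression",
                        "wound_infection_history", "steroid_use",
                        "hypoalbuminemia", "multiple_defects", "emergent")
clinical_onehot_cols <- c("sex", "hernia_etiology", "hernia_location",
                          "repair_approach", "platform",
                          "primary_surgeon_id")

onehot <- function(x, col, levels = NULL) {
  x <- as.character(x)
  obs <- if (is.null(levels)) sort(unique(x)) else levels
  unseen <- setdiff(unique(x), obs)
  if (length(unseen))
    stop(sprintf("unseen categor%s in '%s' at transform time: %s",
                 if (length(unseen) > 1) "ies" else "y", col,
                 paste(unseen, collapse = ", ")), call. = FALSE)
  if (length(obs) < 2) {
    warning(sprintf("dropping single-level categorical '%s'", col),
            call. = FALSE)
    return(NULL)
  }
  m <- vapply(obs, function(l) as.numeric(x == l), numeric(length(x)))
  colnames(m) <- paste0(col, "_", obs)
  m
}

#' Encode a case list into a design matrix
#'
#' Builds the numeric feature matrix for one of the three covariate sets:
#' `opi_only` (all four representations of every OPI, plus the experience
#' feature), `clinical_only` (patient, hernia and operative covariates with
#' categorical fields one-hot encoded over all levels, surgeon identity
#' one-hot, plus experience), or `combined` (the union, without
#' duplicates). The complexity label itself never enters the matrix.
#'
#' @param cases Cohort data frame (already filtered).
#' @param feature_set `"opi_only"`, `"clinical_only"` or `"combined"`.
#' @param encoding Optional encoding map (from a previous call's
#'   `$encoding`) to re-apply; unseen categories raise an error naming
#'   them.
#' @return An object of class `feature_matrix`: list with `X` (numeric
#'   matrix), `feature_names`, `y` (3-level factor), `feature_set`,
#'   `case_ids`, `encoding`.
#' @export
encode_features <- function(cases,
                            feature_set = c("opi_only", "clinical_only",
                                            "combined"),
                            encoding = NULL) {
  if (inherits(cases, "feature_matrix"))
    stop("input is already an encoded feature_matrix; re-encoding is not ",
         "supported", call. = FALSE)
  feature_set <- match.arg(feature_set)
  stopifnot(is.data.frame(cases), nrow(cases) > 0)

  blocks <- list()
  enc <- list()
  add_clinical <- feature_set %in% c("clinical_only", "combined")
  add_opi <- feature_set %in% c("opi_only", "combined")

  if (add_clinical) {
    for (cc in clinical_numeric_cols)
      blocks[[cc]] <- matrix(as.numeric(cases[[cc]]), ncol = 1,
                             dimnames = list(NULL, cc))
    for (cc in clinical_flag_cols)
      blocks[[cc]] <- matrix(as.numeric(cases[[cc]]), ncol = 1,
                             dimnames = list(NULL, cc))
    for (cc in clinical_onehot_cols) {
      lev <- if (!is.null(encoding)) encoding[[cc]] else NULL
      m <- onehot(cases[[cc]], cc, lev)
      if (!is.null(m)) {
        blocks[[cc]] <- m
        enc[[cc]] <- sub(paste0("^", cc, "_"), "", colnames(m))
      }
    }
  }
  if (add_opi) {
    opi_cols <- grep("^opi_", names(cases), value = TRUE)
    if (!length(opi_cols)) stop("no OPI columns present", call. = FALSE)
    for (cc in opi_cols)
      blocks[[cc]] <- matrix(as.numeric(cases[[cc]]), ncol = 1,
                             dimnames = list(NULL, cc))
  }
  blocks[["prior_case_count"]] <-
    matrix(as.numeric(cases$prior_case_count), ncol = 1,
           dimnames = list(NULL, "prior_case_count"))

  X <- do.call(cbind, blocks)
  if (anyNA(X)) stop("missing values after encoding", call. = FALSE)
  fm <- list(X = X, feature_names = colnames(X),
             y = factor(as.character(cases$complexity),
                        levels = complexity_levels),
             feature_set = feature_set, case_ids = cases$case_id,
             encoding = enc)
  class(fm) <- "feature_matrix"
  fm
}

#' Pearson correlation screen against the complexity ordinal
#'
#' The quality check used to rule out trivially collinear covariates: every
#' feature is correlated (Pearson) with the complexity ordinal (minor = 0,
#' moderate = 1, major = 2). Zero-variance features are reported as `NA`
#' rather than 0.
#'
#' @param fm A `feature_matrix`.
#' @return Data frame `(feature, r)` sorted by `|r|` descending, `NA` last.
#' @export
corr_screen <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$X) < 3) stop("need at least 3 cases", call. = FALSE)
  ordinal <- as.numeric(fm$y) - 1
  r <- vapply(seq_len(ncol(fm$X)), function(j) {
    x <- fm$X[, j]
    if (sd(x) == 0 || sd(ordinal) == 0) return(NA_real_)
    cor(x, ordinal)
  }, numeric(1))
  out <- data.frame(feature = fm$feature_names, r = r,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r), out$feature, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
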