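# Synthetic registry of robotic ventral hernia repairs (RVHR) described by
# clinical covariates and objective performance indicators (OPIs), with a
# planted skill dynamic: per-case OPI noise decays with the primary surgeon's
# cumulative experience.

# Catalogue of event-based OPIs captured by the robotic platform's data
# stream. `baseline` is the typical event count per case, `event_sec` a
# typical single-event duration.
opi_catalogue <- data.frame(
  name = c(
    "head_in_console", "head_out_console", "nondominant_clutch",
    "dominant_clutch", "camera_control", "camera_movement",
    "third_arm_swap", "instrument_exchange", "energy_activation",
    "monopolar_energy", "bipolar_energy", "master_clutch",
    "arm_collision", "wrist_rotation_left", "wrist_rotation_right",
    "retraction_event", "needle_grasp", "suture_throw",
    "field_of_view_change", "table_motion"
  ),
  baseline = c(18, 16, 42, 35, 28, 55, 9, 12, 60, 38, 24, 30,
               6, 48, 52, 20, 34, 26, 22, 4),
  event_sec = c(25, 6, 1.5, 1.5, 4, 3, 8, 20, 2.5, 2, 2.5, 2,
                3, 1.5, 1.5, 6, 4, 9, 3, 12),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic RVHR cohort generator
#'
#' Defines the statistical structure of a simulated single-institution
#' registry: an eight-year monthly case stream with ramping volume, Slater
#' complexity marginals, a complexity drift over calendar time (early months
#' oversample minor cases), and OPI noise that decays with the primary
#' surgeon's cumulative case count,
#' \eqn{\sigma(t) = \sigma_\infty + (\sigma_0-\sigma_\infty)
#' e^{-n_{prior}/\tau}}.
#'
#' @param n_months Number of calendar months simulated.
#' @param cases_per_month Mean monthly case volume (Poisson, linear ramp).
#' @param volume_ramp Relative linear ramp of monthly volume in `[0, 1)`;
#'   0 gives constant volume.
#' @param complexity_marginals Target minor/moderate/major proportions
#'   (must sum to 1).
#' @param complexity_drift Strength of the calendar-time term in the latent
#'   complexity score; positive values concentrate minor cases early.
#' @param n_opi Number of OPI event types.
#' @param sigma0,sigma_inf Initial and asymptotic relative OPI noise scales
#'   (`sigma0 > sigma_inf > 0`).
#' @param tau Experience decay constant, in cumulative cases.
#' @param trainee_fraction Share of cases with a non-attending (fellow)
#'   primary console surgeon.
#' @param concurrent_procedure_rate Share of cases flagged for exclusion
#'   because of concurrent non-hernia procedures.
#' @param p_empty_month Probability that a month is forced empty (exercises
#'   the calendar-gap weighting downstream).
#' @param start_date First day of the first simulated month.
#' @param seed Root RNG seed; all generation stages derive child seeds from
#'   it deterministically.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_months = 96,
                          cases_per_month = 5.85,
                          volume_ramp = 0.4,
                          complexity_marginals = c(minor = 0.387,
                                                   moderate = 0.455,
                                                   major = 0.158),
                          complexity_drift = 1.5,
                          n_opi = 20,
                          sigma0 = 3.0,
                          sigma_inf = 0.5,
                          tau = 30,
                          trainee_fraction = 0.25,
                          concurrent_procedure_rate = 93 / 561,
                          p_empty_month = 0.02,
                          start_date = "2013-02-01",
                          seed = 1L) {
  cfg <- list(
    n_months = as.integer(n_months), cases_per_month = cases_per_month,
    volume_ramp = volume_ramp, complexity_marginals = complexity_marginals,
    complexity_drift = complexity_drift, n_opi = as.integer(n_opi),
    sigma0 = sigma0, sigma_inf = sigma_inf, tau = tau,
    trainee_fraction = trainee_fraction,
    concurrent_procedure_rate = concurrent_procedure_rate,
    p_empty_month = p_empty_month,
    start_date = as.Date(start_date), seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
         call. = FALSE)
  if (cfg$n_months < 1) fail("n_months", "must be >= 1")
  if (cfg$cases_per_month <= 0) fail("cases_per_month", "must be > 0")
  if (length(cfg$complexity_marginals) != 3 ||
      abs(sum(cfg$complexity_marginals) - 1) > 1e-12 ||
      any(cfg$complexity_marginals < 0))
    fail("complexity_marginals", "must be a 3-simplex summing to 1")
  if (!(cfg$sigma0 >= cfg$sigma_inf) || cfg$sigma_inf <= 0)
    fail("sigma0/sigma_inf", "must satisfy sigma0 >= sigma_inf > 0")
  if (cfg$sigma0 < cfg$sigma_inf) fail("sigma0", "must be >= sigma_inf")
  if (cfg$tau <= 0) fail("tau", "must be > 0")
  for (f in c("trainee_fraction", "concurrent_procedure_rate",
              "p_empty_month", "volume_ramp")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "must lie in [0, 1]")
  }
  if (cfg$n_opi < 1) fail("n_opi", "must be >= 1")
  invisible(cfg)
}

complexity_levels <- c("minor", "moderate", "major")

opi_names_for <- function(n_opi) {
  base <- opi_catalogue$name
  if (n_opi <= length(base)) return(base[seq_len(n_opi)])
  c(base, sprintf("opi_extra_%02d", seq_len(n_opi - length(base))))
}

opi_params_for <- function(n_opi) {
  k <- nrow(opi_catalogue)
  idx <- ((seq_len(n_opi) - 1) %% k) + 1
  data.frame(name = opi_names_for(n_opi),
             baseline = opi_catalogue$baseline[idx],
             event_sec = opi_catalogue$event_sec[idx],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic RVHR cohort with ground truth
#'
#' Draws a full case registry from a [cohort_config()]: monthly Poisson case
#' counts with a linear volume ramp, console assignments for an attending
#' surgeon and rotating fellows, clinical covariates matched to published
#' registry marginals, a three-level complexity label generated by a noisy
#' multinomial-logit on clinical covariates (dominant coefficient on hernia
#' defect area) with a calendar-time drift, and per-OPI metrics whose noise
#' scale decays exponentially with the primary surgeon's prior case count.
#'
#' The returned ground truth records the planted skill transition (first
#' month in which the attending's noise scale is within 10% of its
#' asymptote), the dominant clinical covariate, and the realised per-case
#' noise schedule. Ground truth is simulator metadata for recovery tests;
#' no analysis stage reads it.
#'
#' @param config A [cohort_config()].
#' @return A list with `cases` (data frame, one row per case, chronological)
#'   and `truth` (list: `transition_month`, `planted_top_clinical_feature`,
#'   `sigma_schedule`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 6L)

  n_m <- config$n_months
  month_start <- seq(config$start_date, by = "month", length.out = n_m)
  month_end <- seq(config$start_date, by = "month", length.out = n_m + 1)[-1] - 1

  # --- monthly volumes -------------------------------------------------
  set.seed(stage_seed[1])
  ramp <- if (n_m > 1) (seq_len(n_m) - 1) / (n_m - 1) else 0.5
  lambda <- config$cases_per_month * (1 - config$volume_ramp +
                                        2 * config$volume_ramp * ramp)
  n_t <- rpois(n_m, lambda)
  n_t[runif(n_m) < config$p_empty_month] <- 0L
  if (sum(n_t) < 8) n_t[1] <- n_t[1] + (8L - sum(n_t))  # degenerate guard
  n_cases <- sum(n_t)
  month_index <- rep.int(seq_len(n_m), n_t)
  days_in_month <- as.integer(month_end - month_start) + 1L
  date <- month_start[month_index] +
    floor(runif(n_cases) * days_in_month[month_index])
  ord <- order(date, runif(n_cases))
  date <- date[ord]; month_index <- month_index[ord]

  # --- consoles and surgeons -------------------------------------------
  set.seed(stage_seed[2])
  n_fellows <- max(1L, ceiling(n_m / 16))
  fellow_of_month <- sprintf("fellow_%02d",
                             pmin(n_fellows, ceiling(month_index /
                                                       (n_m / n_fellows))))
  trainee_primary <- runif(n_cases) < config$trainee_fraction
  dual_console <- trainee_primary | (runif(n_cases) < 0.4)
  console2_surgeon <- ifelse(dual_console, fellow_of_month, NA_character_)
  cases <- data.frame(
    case_id = sprintf("case_%04d", seq_len(n_cases)),
    date = date,
    month_index = month_index,
    console1_surgeon = "attending_01",
    console1_active = !trainee_primary,
    console2_surgeon = console2_surgeon,
    console2_active = trainee_primary,
    stringsAsFactors = FALSE
  )
  cases <- assign_primary_surgeon(cases)
  prior <- integer(n_cases)
  tallies <- new.env(parent = emptyenv())
  for (i in seq_len(n_cases)) {
    s <- cases$primary_surgeon_id[i]
    prev <- if (is.null(tallies[[s]])) 0L else tallies[[s]]
    prior[i] <- prev
    tallies[[s]] <- prev + 1L
  }
  cases$prior_case_count <- prior

  # --- clinical covariates (registry marginals) ------------------------
  set.seed(stage_seed[3])
  n <- n_cases
  cases$age <- as.integer(pmin(90, pmax(18, round(rnorm(n, 55, 13)))))
  cases$sex <- ifelse(runif(n) < 0.491, "female", "male")
  cases$bmi <- round(exp(rnorm(n, log(31.9), 0.21)), 1)
  cases$asa <- sample(1:4, n, TRUE, prob = c(0.053, 0.455, 0.481, 0.011))
  flags <- c(hypertension = 0.545, myocardial_infarction = 9 / 468,
             coronary_artery_disease = 37 / 468, copd = 0.113,
             smoking_history = 0.235, diabetes = 0.197,
             immunosuppression = 6 / 468,
             wound_infection_history = 40 / 468, steroid_use = 32 / 468,
             hypoalbuminemia = 6 / 468)
  for (f in names(flags)) cases[[f]] <- runif(n) < flags[[f]]
  cases$hernia_etiology <- sample(c("primary", "incisional", "both"), n,
                                  TRUE, prob = c(0.53, 0.455, 0.015))
  cases$hernia_location <- sample(c("midline", "non_midline", "both"), n,
                                  TRUE, prob = c(0.923, 0.045, 0.032))
  cases$multiple_defects <- runif(n) < 0.152
  cases$hpw_stage <- sample(1:4, n, TRUE,
                            prob = c(0.192, 0.739, 0.066, 0.003))
  cases$vhwg_grade <- sample(1:3, n, TRUE, prob = c(0.197, 0.786, 0.017))
  cases$repair_approach <- sample(c("rIPOM", "rTAPP", "rRS", "rTAR"), n,
                                  TRUE, prob = c(0.293, 0.235, 0.274, 0.199))
  cases$emergent <- runif(n) < 0.056
  cases$defect_area <- round(exp(rnorm(n, log(12.6), 1.0)), 2)
  # platform migrates Si -> Xi over the series, as in real deployments
  cases$platform <- ifelse(
    runif(n) < stats::plogis(8 * (month_index / n_m - 0.53)),
    "daVinci_Xi", "daVinci_Si")
  cases$concurrent_procedure <- runif(n) < config$concurrent_procedure_rate

  # --- complexity: noisy multinomial-logit with drift ------------------
  set.seed(stage_seed[4])
  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  tnorm <- if (n_m > 1) 2 * (month_index - 1) / (n_m - 1) - 1 else 0
  eta <- 2.5 * z(log(cases$defect_area)) +
    0.7 * z(cases$bmi) +
    0.6 * (cases$asa - 2) +
    0.6 * (cases$hernia_etiology == "incisional") +
    1.2 * cases$emergent +
    config$complexity_drift * tnorm +
    rlogis(n, 0, 0.55)
  cuts <- quantile(eta, cumsum(config$complexity_marginals)[1:2],
                   names = FALSE)
  ordinal <- findInterval(eta, cuts, left.open = TRUE)
  cases$complexity <- factor(complexity_levels[ordinal + 1],
                             levels = complexity_levels)
  cases$console_time_min <-
    round(exp(rnorm(n, log(60), 0.45)) * 1.15 ^ ordinal, 1)

  # --- OPI metrics with experience-decaying noise ----------------------
  set.seed(stage_seed[5])
  sigma_case <- config$sigma_inf + (config$sigma0 - config$sigma_inf) *
    exp(-cases$prior_case_count / config$tau)
  pars <- opi_params_for(config$n_opi)
  case_dur_sec <- cases$console_time_min * 60
  for (k in seq_len(config$n_opi)) {
    b <- pars$baseline[k]
    count <- pmax(0, round(b + 0.03 * b * ordinal +
                             rnorm(n, 0, (b / 8) * sigma_case)))
    durn <- pmin(count * pars$event_sec[k] * exp(rnorm(n, 0, 0.1)),
                 case_dur_sec)
    nm <- pars$name[k]
    cases[[paste0("opi_", nm, "_count")]] <- count
    cases[[paste0("opi_", nm, "_duration")]] <- round(durn, 3)
    cases[[paste0("opi_", nm, "_rate")]] <- count / cases$console_time_min
    cases[[paste0("opi_", nm, "_normalized_duration")]] <-
      round(durn, 3) / case_dur_sec
  }
  rownames(cases) <- NULL

  # --- ground truth ----------------------------------------------------
  att_prior_at_month <- vapply(seq_len(n_m), function(m) {
    sum(cases$primary_surgeon_id == "attending_01" & cases$month_index < m)
  }, integer(1))
  sigma_month <- config$sigma_inf + (config$sigma0 - config$sigma_inf) *
    exp(-att_prior_at_month / config$tau)
  hit <- which(sigma_month <= 1.1 * config$sigma_inf)
  transition_month <- if (length(hit)) hit[1] else n_m
  truth <- list(
    transition_month = as.integer(transition_month),
    planted_top_clinical_feature = "defect_area",
    sigma_schedule = sigma_case
  )
  list(cases = cases, truth = truth)
}

#' Exclude cases with concurrent non-hernia procedures
#'
#' Mirrors the registry's patient-selection stage: cases flagged with a
#' concurrent procedure outside of ventral hernia repair are removed;
#' order is preserved.
#'
#' @param cases Cohort data frame with a logical `concurrent_procedure`
#'   column.
#' @return The retained cases.
#' @export
filter_cohort <- function(cases) {
  stopifnot(is.data.frame(cases), "concurrent_procedure" %in% names(cases))
  out <- cases[!as.logical(cases$concurrent_procedure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map console activity to a primary surgeon
#'
#' Applies the surgeon-to-console mapping rule: the primary surgeon is the
#' one at the single active console; dual-console cases with only one
#' active console are treated as single-console cases. Zero active
#' consoles, or two simultaneously active consoles, are data errors.
#'
#' @param cases Data frame with `console1_surgeon`, `console1_active`,
#'   `console2_surgeon`, `console2_active` columns.
#' @return `cases` with `primary_surgeon_id` and `primary_surgeon_role`
#'   (`attending` / `non_attending`) columns set.
#' @export
assign_primary_surgeon <- function(cases) {
  a1 <- as.logical(cases$console1_active)
  a2 <- as.logical(cases$console2_active)
  a2[is.na(a2)] <- FALSE
  n_active <- a1 + a2
  if (any(n_active == 0))
    stop("console mapping error: case(s) with zero active consoles: ",
         paste(head(which(n_active == 0)), collapse = ", "), call. = FALSE)
  if (any(n_active == 2))
    stop("console mapping error: case(s) with two simultaneously active ",
         "consoles and no tie-break metadata: ",
         paste(head(which(n_active == 2)), collapse = ", "), call. = FALSE)
  cases$primary_surgeon_id <- ifelse(a1, cases$console1_surgeon,
                                     cases$console2_surgeon)
  cases$primary_surgeon_role <- ifelse(
    grepl("^attending", cases$primary_surgeon_id), "attending",
    "non_attending")
  cases
}

cohort_numeric_cols <- function(nms) {
  num <- c("month_index", "age", "bmi", "asa", "hpw_stage", "vhwg_grade",
           "defect_area", "console_time_min", "prior_case_count")
  c(num[num %in% nms], grep("^opi_", nms, value = TRUE))
}

cohort_logical_cols <- function(nms) {
  lg <- c("console1_active", "console2_active", "hypertension",
          "myocardial_infarction", "coronary_artery_disease", "copd",
          "smoking_history", "diabetes", "immunosuppression",
          "wound_infection_history", "steroid_use", "hypoalbuminemia",
          "multiple_defects", "emergent", "concurrent_procedure")
  lg[lg %in% nms]
}

#' Write / read a cohort as CSV
#'
#' Round-trip-lossless persistence: dates ISO-8601, booleans 0/1, OPI
#' columns named `opi_<name>_<metric>`, doubles at full precision.
#'
#' @param cases Cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   cohort data frame.
#' @export
write_cohort <- function(cases, path) {
  out <- cases
  for (cc in cohort_logical_cols(names(out)))
    out[[cc]] <- as.integer(out[[cc]])
  if (is.factor(out$complexity)) out$complexity <- as.character(out$complexity)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c(""), guess_max = 100000)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0)
    stop(sprintf("malformed cohort file '%s': parse failure at line %d (%s)",
                 path, probs$row[1] + 1L, probs$expected[1]), call. = FALSE)
  cases <- as.data.frame(raw, stringsAsFactors = FALSE)
  for (cc in cohort_numeric_cols(names(cases)))
    if (!is.numeric(cases[[cc]]))
      stop(sprintf("malformed cohort file '%s': non-numeric value in '%s' at line %d",
                   path, cc, which(is.na(suppressWarnings(
                     as.numeric(cases[[cc]]))) & !is.na(cases[[cc]]))[1] + 1L),
           call. = FALSE)
  for (cc in cohort_logical_cols(names(cases)))
    cases[[cc]] <- as.logical(cases[[cc]])
  if ("date" %in% names(cases)) cases$date <- as.Date(cases$date)
  if ("complexity" %in% names(cases))
    cases$complexity <- factor(cases$complexity, levels = complexity_levels)
  intish <- c("month_index", "age", "asa", "hpw_stage", "vhwg_grade",
              "prior_case_count")
  for (cc in intersect(intish, names(cases)))
    cases[[cc]] <- as.integer(cases[[cc]])
  cases
}

#' Write the generator's ground truth as a JSON sidecar
#'
#' Stored apart from the cohort CSV so that no analysis stage can read it
#' accidentally; only recovery tests consume it.
#'
#' @param truth Ground-truth list from [generate_cohort()].
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
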