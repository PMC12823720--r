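# Shared simulation profiles. The analysis profile keeps the full 96-month
# timeline but scales monthly volume, OPI count and the experience decay
# constant together (tau proportional to volume) so the planted transition
# stays at the same calendar position at a fraction of the compute.
analysis_profile <- function(seed = 1, ...) {
  cohort_config(seed = seed, cases_per_month = 3.2, n_opi = 6, tau = 16,
                ...)
}

# Small, fast cohort for unit tests.
tiny_config <- function(seed = 3, n_months = 18, ...) {
  cohort_config(seed = seed, n_months = n_months, cases_per_month = 6,
                n_opi = 3, tau = 8, ...)
}

tiny_cases <- function(seed = 3, ...) {
  filter_cohort(generate_cohort(tiny_config(seed, ...))$cases)
}

# Hand-built console assignment table for mapping tests.
console_df <- function(a1, a2, s2 = "fellow_01") {
  data.frame(console1_surgeon = "attending_01", console1_active = a1,
             console2_surgeon = s2, console2_active = a2,
             stringsAsFactors = FALSE)
}
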