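#' Synthetic cohort configuration
#'
#' Marginal structure defaults follow the combined two-cohort descriptive
#' table of the study population this package targets: deletion-allele
#' frequency 0.111 (HWE genotypes), stage mix ~29/37/33% with ~1% unknown,
#' 56% female, 34% diabetes (14% unknown), age ~N(66, 10) clipped to 20-92,
#' and stage-specific exponential overall-survival hazards with medians of
#' 24 (localized), 16.8 (locally advanced) and 10.8 (metastatic) months.
#' The carrier log hazard ratio defaults to 0 (null effect). Diagnosis
#' dates are anchored on a fixed synthetic accrual epoch (2009-2020) with
#' an administrative cutoff analog of 2023-12-31.
#'
#' @param n_subjects Number of subjects.
#' @param q Deletion-allele frequency.
#' @param stage_probs Probabilities for localized / locally advanced /
#'   metastatic / unknown (sums to 1).
#' @param sex_f_prob,diabetes_prob,diabetes_unknown_prob Marginal rates.
#' @param age_mean,age_sd Age-at-diagnosis distribution (years).
#' @param os_median_by_stage Baseline exponential median OS per stage (months).
#' @param log_hr True carrier log hazard ratio applied to OS and progression.
#' @param ltf_median Loss-to-follow-up exponential median (months).
#' @param ttp_median Baseline exponential median time to progression (months).
#' @param competing_median Exponential median for non-progression competing
#'   events (surgery / chemo switch) after treatment start (months).
#' @param chemo_prob Fraction of subjects treated with chemotherapy (TTP
#'   fields are generated only for them).
#' @param missing_geno_rate Fraction of subjects with a missing genotype.
#' @param accrual_start,accrual_end,admin_cutoff Date anchors.
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_subjects = 1000, q = 0.111,
                              stage_probs = c(localized = 0.29,
                                              locally_advanced = 0.37,
                                              metastatic = 0.33,
                                              unknown = 0.01),
                              sex_f_prob = 0.556, diabetes_prob = 0.34,
                              diabetes_unknown_prob = 0.14,
                              age_mean = 66, age_sd = 10,
                              os_median_by_stage = c(localized = 24,
                                                     locally_advanced = 16.8,
                                                     metastatic = 10.8),
                              log_hr = 0, ltf_median = 120,
                              ttp_median = 12, competing_median = 40,
                              chemo_prob = 0.42, missing_geno_rate = 0.005,
                              accrual_start = "2009-01-01",
                              accrual_end = "2020-12-31",
                              admin_cutoff = "2023-12-31", seed = 1) {
  stopifnot(n_subjects >= 1, q >= 0, q <= 1,
            abs(sum(stage_probs) - 1) < 1e-8, all(stage_probs >= 0),
            all(os_median_by_stage > 0), ttp_median > 0, competing_median > 0)
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a synthetic subject cohort
#'
#' Generates a subject table with HWE genotypes, covariates, and event
#' dates back-computed from exponential survival/progression times so that
#' [compute_os()] and [compute_ttp()] recover the generated (time, event)
#' pairs exactly (times are materialized as whole days before any date is
#' written). Carrier status multiplies the OS and progression hazards by
#' `exp(log_hr)`.
#'
#' @param config A `cohort_sim_config`.
#' @return Data frame of subject records (schema consumed by the survival
#'   layer) with attribute `"truth"`: list with per-subject true OS/TTP
#'   (time, event) pairs and the generating parameters.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  cutoff <- as.Date(config$admin_cutoff)

  p_g <- c((1 - config$q)^2, 2 * config$q * (1 - config$q), config$q^2)
  genotype <- sample(c("0/0", "0/1", "1/1"), n, TRUE, p_g)
  carrier <- as.numeric(genotype != "0/0")
  genotype[stats::runif(n) < config$missing_geno_rate] <- "./."

  stage <- sample(names(config$stage_probs), n, TRUE, config$stage_probs)
  sex <- sample(c("F", "M"), n, TRUE, c(config$sex_f_prob, 1 - config$sex_f_prob))
  diabetes <- sample(c("yes", "no"), n, TRUE,
                     c(config$diabetes_prob, 1 - config$diabetes_prob))
  diabetes[stats::runif(n) < config$diabetes_unknown_prob] <- "unknown"
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 20), 92)
  bmi <- round(pmin(pmax(stats::rnorm(n, 27, 5), 13), 65), 1)
  chemo <- stats::runif(n) < config$chemo_prob
  chemo_class <- ifelse(chemo,
                        sample(c("gemcitabine_based", "fu_based", "other"),
                               n, TRUE, c(0.45, 0.45, 0.10)), "none")

  dx <- as.Date(config$accrual_start) +
    floor(stats::runif(n, 0, as.numeric(as.Date(config$accrual_end) -
                                          as.Date(config$accrual_start)) + 1))
  admin_days <- as.numeric(cutoff - dx)

  # OS: exponential baseline per stage (unknown stage gets the middle rate),
  # hazard scaled by exp(log_hr * carrier); all times materialized in days
  med <- config$os_median_by_stage
  base_med <- ifelse(stage == "unknown", med[["locally_advanced"]], med[stage])
  rate_os <- log(2) / base_med * exp(config$log_hr * carrier)
  t_os_days <- pmax(1, round(stats::rexp(n, rate_os) * DAYS_PER_MONTH))
  ltf_days <- pmax(1, round(stats::rexp(n, log(2) / config$ltf_median) *
                              DAYS_PER_MONTH))
  death_observed <- t_os_days <= pmin(ltf_days, admin_days)
  death_date <- as.Date(ifelse(t_os_days <= ltf_days, dx + t_os_days, NA),
                        origin = "1970-01-01")  # death after cutoff kept: admin censoring is the analysis's job
  last_followup <- as.Date(ifelse(is.na(death_date), dx + pmin(ltf_days, admin_days),
                                  pmin(as.numeric(death_date), as.numeric(dx + admin_days))),
                           origin = "1970-01-01")
  os_truth_time <- ifelse(death_observed, t_os_days,
                          pmin(ltf_days, admin_days)) / DAYS_PER_MONTH
  os_truth_event <- death_observed

  # TTP (chemotherapy-treated subjects only)
  t0_days <- pmax(14, round(stats::runif(n, 14, 60)))
  rate_pr <- log(2) / config$ttp_median * exp(config$log_hr * carrier)
  p_days <- pmax(1, round(stats::rexp(n, rate_pr) * DAYS_PER_MONTH))
  k_days <- pmax(1, round(stats::rexp(n, log(2) / config$competing_median) *
                            DAYS_PER_MONTH))
  treat <- dx + t0_days
  has_ttp <- chemo & (t_os_days > t0_days)
  d_rel <- t_os_days - t0_days                      # death, days after treatment
  admin_rel <- admin_days - t0_days
  ltf_rel <- ltf_days - t0_days
  # progression is documented only if it precedes every competing/censoring bound
  prog_seen <- has_ttp & p_days < pmin(k_days, d_rel) &
    p_days <= pmin(ltf_rel, admin_rel)
  comp_seen <- has_ttp & k_days < d_rel & k_days <= pmin(ltf_rel, admin_rel) &
    (!prog_seen | k_days > p_days)
  progression_date <- as.Date(ifelse(prog_seen, treat + p_days, NA),
                              origin = "1970-01-01")
  competing_date <- as.Date(ifelse(comp_seen, treat + k_days, NA),
                            origin = "1970-01-01")
  ttp_cens_days <- pmin(ifelse(comp_seen, k_days, Inf),
                        ifelse(t_os_days <= ltf_days, d_rel, Inf),
                        ltf_rel, admin_rel)
  ttp_truth_time <- ifelse(prog_seen, p_days, ttp_cens_days) / DAYS_PER_MONTH
  ttp_truth_event <- prog_seen

  records <- data.frame(
    subject_id = sprintf("P%05d", seq_len(n)),
    cohort = sample(1:2, n, TRUE, c(0.14, 0.86)),
    genotype = genotype, age_at_dx = age, sex = sex, stage = stage,
    diabetes = diabetes, bmi = bmi, chemo_class = chemo_class,
    dx_date = dx,
    treatment_start = as.Date(ifelse(has_ttp, treat, NA), origin = "1970-01-01"),
    progression_date = progression_date,
    death_date = death_date,
    competing_event_date = competing_date,
    last_followup_date = last_followup,
    stringsAsFactors = FALSE)
  attr(records, "truth") <- list(
    os = data.frame(time = os_truth_time, event = os_truth_event),
    ttp = data.frame(time = ifelse(has_ttp, ttp_truth_time, NA),
                     event = ifelse(has_ttp, ttp_truth_event, NA)),
    carrier = carrier, log_hr = config$log_hr, config = config)
  records
}

#' Write / read subject tables as TSV with ISO-8601 dates
#'
#' @param records Subject table.
#' @param path TSV path.
#' @return `write_subject_table()`: `path` invisibly;
#'   `read_subject_table()`: the subject data frame with Date columns.
#' @export
write_subject_table <- function(records, path) {
  out <- records
  for (v in grep("date|treatment_start", names(out), value = TRUE))
    out[[v]] <- as.character(out[[v]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (v in grep("date|treatment_start", names(r), value = TRUE))
    r[[v]] <- as.Date(r[[v]])
  r
}
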