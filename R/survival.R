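DAYS_PER_MONTH <- 30.4375  # 365.25 / 12

as_date <- function(x) if (inherits(x, "Date")) x else as.Date(as.character(x))

months_between <- function(from, to) as.numeric(to - from) / DAYS_PER_MONTH

#' Construct the overall-survival endpoint from subject dates
#'
#' OS runs from the date of diagnosis to the date of death (event);
#' subjects without an observed death on or before the administrative
#' cutoff are censored at the earlier of their last follow-up and the
#' cutoff. Times are in months (days / 30.4375).
#'
#' @param records Data frame with columns `dx_date`, `death_date`,
#'   `last_followup_date` (ISO-8601 strings or Dates; `death_date` may be NA).
#' @param admin_cutoff Administrative cutoff date.
#' @return Data frame with `time` (months) and `event` (logical), one row
#'   per input record.
#' @export
compute_os <- function(records, admin_cutoff) {
  cutoff <- as_date(admin_cutoff)
  dx <- as_date(records$dx_date)
  death <- as_date(records$death_date)
  lfu <- as_date(records$last_followup_date)
  if (any(is.na(dx))) stop("dx_date is required for every record")
  if (any(!is.na(death) & death < dx)) stop("data error: death before diagnosis")
  event <- !is.na(death) & death <= cutoff
  censor_date <- pmin(lfu, cutoff, na.rm = TRUE)
  time <- ifelse(event, months_between(dx, death), months_between(dx, censor_date))
  data.frame(time = time, event = event)
}

#' Construct the time-to-progression endpoint from subject dates
#'
#' TTP runs from first treatment to documented progression (event).
#' Competing-risk conditions censor: death, or receipt of surgery /
#' another chemotherapy for non-progression reasons (the
#' `competing_event_date` field), whichever comes first; subjects without
#' progression are additionally censored at last follow-up or the
#' administrative cutoff. A progression occurring after a competing event
#' does not count as an event (the subject is censored at the competing
#' event).
#'
#' @param records Data frame with `treatment_start`, `progression_date`,
#'   `death_date`, `competing_event_date`, `last_followup_date`.
#' @param admin_cutoff Administrative cutoff date.
#' @return Data frame with `time` (months) and `event` (logical).
#' @export
compute_ttp <- function(records, admin_cutoff) {
  cutoff <- as_date(admin_cutoff)
  trt <- as_date(records$treatment_start)
  prog <- as_date(records$progression_date)
  death <- as_date(records$death_date)
  comp <- as_date(records$competing_event_date)
  lfu <- as_date(records$last_followup_date)
  if (any(is.na(trt))) stop("treatment_start is required for every record")
  if (any(!is.na(prog) & prog < trt)) stop("data error: progression before treatment start")
  competing <- pmin(death, comp, na.rm = TRUE)            # first competing risk
  censor_date <- pmin(competing, lfu, cutoff, na.rm = TRUE)
  event <- !is.na(prog) & prog <= censor_date &
    (is.na(competing) | prog < competing)
  time <- ifelse(event, months_between(trt, prog), months_between(trt, censor_date))
  data.frame(time = time, event = event)
}

#' Encode genotype as model covariates
#'
#' @param genotype Character vector in `{0/0, 0/1, 1/1}` (NA propagated).
#' @param model `"dominant"` (carrier indicator: at least one deletion
#'   allele) or `"three_level"` (two indicators, het and hom, vs 0/0).
#' @return For `"dominant"` a numeric vector; for `"three_level"` a
#'   two-column matrix `het` / `hom`.
#' @export
code_genotype <- function(genotype, model = c("dominant", "three_level")) {
  model <- match.arg(model)
  g <- as.character(genotype)
  g[g %in% c("./.", "")] <- NA_character_
  bad <- setdiff(unique(g[!is.na(g)]), c("0/0", "0/1", "1/1"))
  if (length(bad)) stop("uncallable genotype code(s): ", paste(bad, collapse = ", "))
  if (model == "dominant")
    return(ifelse(is.na(g), NA_real_, as.numeric(g %in% c("0/1", "1/1"))))
  cbind(het = ifelse(is.na(g), NA_real_, as.numeric(g == "0/1")),
        hom = ifelse(is.na(g), NA_real_, as.numeric(g == "1/1")))
}

#' Kaplan-Meier curve with median and confidence interval
#'
#' Product-limit estimator via [survival::survfit()]; the median is the
#' earliest time at which the curve drops to 0.5 or below, with its 95% CI
#' from the log-log (complementary log) transformed Greenwood variance
#' (Brookmeyer-Crowley style). The median is `NA` when the curve never
#' reaches 0.5.
#'
#' @param time Event/censoring times (months, > 0).
#' @param event Logical/0-1 event indicators.
#' @return A `km_curve`: list with `time`, `surv`, `n_risk`, `n_event`,
#'   `median`, `median_ci`, and the underlying `survfit` object.
#' @export
km_fit <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median = unname(tab["median"]),
                 median_ci = c(lower = unname(tab["0.95LCL"]),
                               upper = unname(tab["0.95UCL"])),
                 survfit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points; median %.1f (95%% CI %.1f-%.1f) months\n",
              length(x$time), x$median, x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood via [survival::coxph()] with Efron tie
#' handling by default (Breslow available for parity with SAS's TIES
#' default). Hazard ratios with Wald 95% confidence intervals and p-values.
#' Monotone likelihood (complete separation) is flagged as non-convergence
#' and no estimates are reported for the affected fit.
#'
#' @param data Data frame containing `time`, `event`, and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @return A `cox_fit`: list with `table` (term, coef, HR, se, lower, upper,
#'   p), `loglik`, `n`, `n_event`, `converged`, and the `coxph` object.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  d <- data[stats::complete.cases(data[, c("time", "event", covariates)]), ,
            drop = FALSE]
  if (sum(d$event) < 1) stop("no events in the analysis data")
  for (v in covariates)
    if (is.numeric(d[[v]]) && stats::var(d[[v]]) == 0)
      stop("constant covariate: ", v)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, as.integer(event)) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  warn <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  se <- sqrt(diag(fit$var))
  monotone <- any(grepl("infinite", warn)) || any(se > 1e3) ||
    any(abs(stats::coef(fit)) > 15)
  converged <- !monotone && fit$iter < 50
  tab <- if (converged) {
    cf <- stats::coef(fit)
    data.frame(term = names(cf), coef = unname(cf), HR = exp(unname(cf)),
               se = se, lower = exp(unname(cf) - 1.96 * se),
               upper = exp(unname(cf) + 1.96 * se),
               p = 2 * stats::pnorm(-abs(unname(cf) / se)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else NULL
  structure(list(table = tab, loglik = fit$loglik[2], n = fit$n,
                 n_event = fit$nevent, converged = converged, ties = ties,
                 coxph = fit, warnings = warn),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Cox fit: NOT converged (monotone likelihood or iteration limit)\n")
    return(invisible(x))
  }
  cat(sprintf("Cox fit (%s ties): n=%d, events=%d\n", x$ties, x$n, x$n_event))
  print(transform(x$table, HR = round(HR, 3), lower = round(lower, 3),
                  upper = round(upper, 3), p = signif(p, 3)))
  invisible(x)
}

# Build the analysis frame for one endpoint, excluding subjects with
# missing/unknown covariates; returns the frame plus an exclusion log.
build_analysis_frame <- function(records, endpoint = c("os", "ttp"),
                                 admin_cutoff, model = "dominant",
                                 add_cohort = FALSE) {
  endpoint <- match.arg(endpoint)
  excl <- list()
  keep <- rep(TRUE, nrow(records))
  note <- function(mask, why) {
    excl[[why]] <<- sum(mask & keep); keep <<- keep & !mask
  }
  if (endpoint == "ttp")
    note(is.na(records$treatment_start), "no_treatment_start")
  note(is.na(records$genotype) | !(records$genotype %in% c("0/0", "0/1", "1/1")),
       "missing_genotype")
  note(is.na(records$stage) | records$stage == "unknown", "unknown_stage")
  note(is.na(records$diabetes) | records$diabetes == "unknown", "unknown_diabetes")
  note(is.na(records$age_at_dx), "missing_age")
  note(is.na(records$sex), "missing_sex")
  r <- records[keep, , drop = FALSE]
  obs <- if (endpoint == "os") compute_os(r, admin_cutoff) else compute_ttp(r, admin_cutoff)
  ok_t <- obs$time > 0
  excl[["nonpositive_time"]] <- sum(!ok_t)
  r <- r[ok_t, , drop = FALSE]; obs <- obs[ok_t, , drop = FALSE]
  d <- data.frame(time = obs$time, event = obs$event,
                  age = r$age_at_dx, sex_male = as.numeric(r$sex == "M"),
                  diabetes = as.numeric(r$diabetes == "yes"),
                  stage_la = as.numeric(r$stage == "locally_advanced"),
                  stage_met = as.numeric(r$stage == "metastatic"),
                  stage = r$stage, stringsAsFactors = FALSE)
  if (model == "dominant") {
    d$carrier <- code_genotype(r$genotype, "dominant")
  } else {
    gm <- code_genotype(r$genotype, "three_level")
    d$het <- gm[, "het"]; d$hom <- gm[, "hom"]
  }
  if (add_cohort) d$cohort2 <- as.numeric(r$cohort == 2)
  attr(d, "exclusions") <- excl
  d
}

#' Endpoint association analysis stratified by tumor stage
#'
#' For each tumor-stage stratum (localized, locally advanced, metastatic),
#' fits a Cox model for deletion-carrier status adjusted for age, sex and
#' diabetes (plus a cohort indicator when more than one cohort is present),
#' and summarizes per-group N and Kaplan-Meier median (95% CI) -- the shape
#' of a stage-stratified association table. Subjects with unknown stage or
#' missing covariates are excluded and counted in the exclusion log
#' (attribute `"exclusions"`). Strata with no events or a non-converged fit
#' are reported as not estimable.
#'
#' @param records Subject table (see [simulate_cohort()] for the schema).
#' @param endpoint `"os"` or `"ttp"`.
#' @param admin_cutoff Administrative cutoff date.
#' @param ties Tie handling passed to [cox_fit()].
#' @return Data frame with one row per stage x carrier group: N, events,
#'   median and CI, HR (95% CI) vs non-carriers, and Wald p.
#' @export
stage_stratified_analysis <- function(records, endpoint = c("os", "ttp"),
                                      admin_cutoff = "2023-12-31",
                                      ties = "efron") {
  endpoint <- match.arg(endpoint)
  add_cohort <- "cohort" %in% names(records) &&
    length(unique(records$cohort[!is.na(records$cohort)])) > 1
  d <- build_analysis_frame(records, endpoint, admin_cutoff,
                            model = "dominant", add_cohort = add_cohort)
  covars <- c("carrier", "age", "sex_male", "diabetes",
              if (add_cohort) "cohort2")
  out <- list()
  for (st in c("localized", "locally_advanced", "metastatic")) {
    ds <- d[d$stage == st, , drop = FALSE]
    if (!nrow(ds)) next
    for (grp in c(0, 1)) {
      dg <- ds[ds$carrier == grp, , drop = FALSE]
      med <- c(NA_real_, NA_real_, NA_real_)
      if (nrow(dg)) {
        km <- km_fit(dg$time, dg$event)
        med <- c(km$median, km$median_ci)
      }
      out[[length(out) + 1L]] <- data.frame(
        stage = st, carrier = c("absent", "present")[grp + 1L],
        n = nrow(dg), events = sum(dg$event),
        median = med[1], median_lcl = med[2], median_ucl = med[3],
        HR = NA_real_, HR_lcl = NA_real_, HR_ucl = NA_real_, p = NA_real_,
        estimable = TRUE, stringsAsFactors = FALSE)
    }
    i_pres <- length(out)  # 'present' row gets the HR; absent is reference
    fit <- tryCatch({
      if (sum(ds$event) < 1 || length(unique(ds$carrier)) < 2)
        stop("not estimable")
      cox_fit(ds, covars, ties = ties)
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      row <- fit$table[fit$table$term == "carrier", ]
      out[[i_pres]]$HR <- row$HR
      out[[i_pres]]$HR_lcl <- row$lower
      out[[i_pres]]$HR_ucl <- row$upper
      out[[i_pres]]$p <- row$p
    } else {
      out[[i_pres]]$estimable <- FALSE
    }
  }
  res <- do.call(rbind, out)
  attr(res, "exclusions") <- attr(d, "exclusions")
  res
}

#' Descriptive cohort summary (characteristics table)
#'
#' Medians (range) for continuous variables and frequencies with
#' proportions for categorical variables, per cohort; percentages use
#' non-missing denominators. Carrier percentage pools heterozygous and
#' homozygous deletion genotypes.
#'
#' @param records Subject table with at least a `genotype` column; optional
#'   `cohort`, `sex`, `age_at_dx`, `stage`, `diabetes`, `bmi`.
#' @return A `cohort_summary`: named list (one element per cohort) of
#'   statistic lists; percentages are rounded to one decimal.
#' @export
cohort_summary <- function(records) {
  cohorts <- if ("cohort" %in% names(records)) sort(unique(records$cohort))
  else "all"
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  med_range <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(median = NA_real_, range = c(NA_real_, NA_real_)))
    list(median = stats::median(x), range = range(x))
  }
  out <- lapply(cohorts, function(co) {
    r <- if (identical(co, "all")) records else records[records$cohort == co, , drop = FALSE]
    g <- as.character(r$genotype)
    g[g %in% c("./.", "")] <- NA_character_
    called <- g[!is.na(g)]
    gcnt <- c(n_00 = sum(called == "0/0"), n_01 = sum(called == "0/1"),
              n_11 = sum(called == "1/1"))
    ncall <- length(called)
    carrier_n <- gcnt[["n_01"]] + gcnt[["n_11"]]
    sex <- if ("sex" %in% names(r)) r$sex else rep(NA_character_, nrow(r))
    stage <- if ("stage" %in% names(r)) r$stage else rep(NA_character_, nrow(r))
    diab <- if ("diabetes" %in% names(r)) r$diabetes else rep(NA_character_, nrow(r))
    stage_known <- stage[!is.na(stage) & stage != "unknown"]
    diab_known <- diab[!is.na(diab) & diab != "unknown"]
    list(
      cohort = co, n = nrow(r),
      sex_f_n = sum(sex == "F", na.rm = TRUE),
      sex_f_pct = pct(sum(sex == "F", na.rm = TRUE), sum(!is.na(sex))),
      age = med_range(if ("age_at_dx" %in% names(r)) r$age_at_dx else NA),
      bmi = med_range(if ("bmi" %in% names(r)) r$bmi else NA),
      stage_n = table(factor(stage_known,
                             c("localized", "locally_advanced", "metastatic"))),
      stage_pct = vapply(c("localized", "locally_advanced", "metastatic"),
                         function(s) pct(sum(stage_known == s), length(stage_known)),
                         numeric(1)),
      stage_unknown = sum(is.na(stage) | stage == "unknown"),
      diabetes_yes_n = sum(diab_known == "yes"),
      diabetes_yes_pct = pct(sum(diab_known == "yes"), length(diab_known)),
      diabetes_unknown = sum(is.na(diab) | diab == "unknown"),
      genotype_counts = gcnt,
      genotype_pct = c(pct(gcnt[["n_00"]], ncall), pct(gcnt[["n_01"]], ncall),
                       pct(gcnt[["n_11"]], ncall)),
      carrier_n = carrier_n,
      carrier_pct = pct(carrier_n, ncall),
      noncarrier_pct = pct(gcnt[["n_00"]], ncall),
      genotype_missing = sum(is.na(g)))
  })
  names(out) <- as.character(cohorts)
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (s in x) {
    cat(sprintf("Cohort %s (n = %d)\n", s$cohort, s$n))
    cat(sprintf("  Female: %d (%.1f%%)\n", s$sex_f_n, s$sex_f_pct))
    cat(sprintf("  Age: %.0f [%.0f-%.0f]\n", s$age$median, s$age$range[1],
                s$age$range[2]))
    cat(sprintf("  Stage L/LA/M: %s (%s%%), unknown %d\n",
                paste(s$stage_n, collapse = "/"),
                paste(s$stage_pct, collapse = "/"), s$stage_unknown))
    cat(sprintf("  Diabetes: %d (%.1f%%), unknown %d\n", s$diabetes_yes_n,
                s$diabetes_yes_pct, s$diabetes_unknown))
    cat(sprintf("  Genotype 0/0, 0/1, 1/1: %s (%s%%)\n",
                paste(s$genotype_counts, collapse = ", "),
                paste(s$genotype_pct, collapse = ", ")))
    cat(sprintf("  Deletion carriers: %d (%.1f%%)\n", s$carrier_n, s$carrier_pct))
  }
  invisible(x)
}
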