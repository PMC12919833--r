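test_that("overall survival follows diagnosis-to-death with cutoff censoring", {
  cutoff <- "2023-12-31"
  r <- subject_row(dx_date = "2010-01-01", death_date = "2011-01-01",
                   last_followup_date = "2011-01-01")
  os <- compute_os(r, cutoff)
  expect_true(os$event)
  expect_equal(os$time, 365 / 30.4375, tolerance = 1e-10)

  r <- subject_row(dx_date = "2010-01-01", last_followup_date = "2012-01-01")
  os <- compute_os(r, cutoff)
  expect_false(os$event)
  expect_equal(os$time, 730 / 30.4375, tolerance = 1e-10)  # ~24.0 months

  # death after the administrative cutoff: censored at the cutoff
  r <- subject_row(dx_date = "2010-01-01", death_date = "2024-06-01",
                   last_followup_date = "2024-06-01")
  os <- compute_os(r, cutoff)
  expect_false(os$event)
  expect_equal(os$time,
               as.numeric(as.Date(cutoff) - as.Date("2010-01-01")) / 30.4375)

  expect_error(compute_os(subject_row(dx_date = "2010-01-01",
                                      death_date = "2009-12-31",
                                      last_followup_date = "2010-01-02"),
                          cutoff), "death before diagnosis")
})

test_that("time-to-progression treats death, surgery and chemo switch as censoring", {
  cutoff <- "2023-12-31"
  # documented progression, no competing event
  r <- subject_row(treatment_start = "2010-02-01",
                   progression_date = "2010-08-01",
                   last_followup_date = "2011-01-01")
  tt <- compute_ttp(r, cutoff)
  expect_true(tt$event)
  expect_equal(tt$time, 181 / 30.4375, tolerance = 1e-10)  # ~5.9 months

  # death without progression censors at the death date
  r <- subject_row(treatment_start = "2010-02-01", death_date = "2010-06-01",
                   last_followup_date = "2010-06-01")
  tt <- compute_ttp(r, cutoff)
  expect_false(tt$event)
  expect_equal(tt$time, as.numeric(as.Date("2010-06-01") - as.Date("2010-02-01")) / 30.4375)

  # competing surgery before a later progression censors at the surgery
  r <- subject_row(treatment_start = "2010-02-01",
                   progression_date = "2010-09-01",
                   competing_event_date = "2010-05-01",
                   last_followup_date = "2011-01-01")
  tt <- compute_ttp(r, cutoff)
  expect_false(tt$event)
  expect_equal(tt$time, as.numeric(as.Date("2010-05-01") - as.Date("2010-02-01")) / 30.4375)

  expect_error(compute_ttp(subject_row(treatment_start = "2010-02-01",
                                       progression_date = "2010-01-15",
                                       last_followup_date = "2010-03-01"),
                           cutoff), "progression before treatment")
})

test_that("endpoint times never exceed the administrative horizon (property fuzz)", {
  set.seed(23)
  cutoff <- as.Date("2023-12-31")
  for (i in 1:100) {
    dx <- as.Date("2008-01-01") + sample.int(4000, 1)
    death <- if (runif(1) < 0.5) dx + sample.int(3000, 1)
    lfu <- dx + sample.int(4000, 1)
    if (!is.null(death)) lfu <- min(lfu, death)
    r <- subject_row(dx_date = as.character(dx),
                     death_date = if (is.null(death)) NA else as.character(death),
                     last_followup_date = as.character(lfu))
    os <- compute_os(r, cutoff)
    expect_lte(os$time, as.numeric(cutoff - dx) / 30.4375 + 1e-9)
    if (os$event) expect_true(!is.na(r$death_date) && as.Date(r$death_date) <= cutoff)
  }
})

test_that("genotype covariate codings implement dominant and three-level models", {
  g <- c("0/0", "0/1", "1/1", "./.")
  expect_equal(code_genotype(g, "dominant"), c(0, 1, 1, NA))
  m <- code_genotype(g, "three_level")
  expect_equal(m[, "het"], c(0, 1, 0, NA))
  expect_equal(m[, "hom"], c(0, 0, 1, NA))
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  km <- km_fit(1:5, rep(TRUE, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)

  # all censored: flat curve, undefined median
  km <- km_fit(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))

  # without censoring KM equals the empirical survival function (n <= 8)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    tm <- sample(1:20, n, replace = TRUE)
    km <- km_fit(tm, rep(TRUE, n))
    oracle <- km_oracle(tm, rep(1, n))
    expect_equal(km$time[km$n_event > 0], oracle$time)
    expect_equal(km$surv[km$n_event > 0], oracle$surv)
    ecdf_surv <- vapply(oracle$time, function(t) mean(tm > t), numeric(1))
    expect_equal(oracle$surv, ecdf_surv)
    if (n %% 2 == 1)  # odd n, no censoring: median is the middle order stat
      expect_equal(km$median, sort(tm)[(n + 1) / 2])
  }
})

test_that("Cox coefficient maximizes the Efron partial likelihood (grid oracle)", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = rep(TRUE, 6),
                  x = c(1, 1, 0, 1, 0, 0))
  fit <- cox_fit(d, "x")
  expect_true(fit$converged)
  beta_grid <- efron_grid_argmax(d$time, d$event, d$x)
  expect_lt(abs(fit$table$coef - beta_grid), 1e-3)

  # with ties
  d2 <- data.frame(time = c(1, 1, 2, 2, 3, 4, 5, 6),
                   event = c(1, 1, 1, 0, 1, 1, 1, 1) == 1,
                   x = c(1, 0, 1, 1, 0, 1, 0, 0))
  fit2 <- cox_fit(d2, "x")
  expect_lt(abs(fit2$table$coef - efron_grid_argmax(d2$time, d2$event, d2$x)),
            1e-3)
  # score at the maximum vanishes (numerical derivative of the oracle)
  eps <- 1e-5
  sc <- (efron_loglik(fit2$table$coef + eps, d2$time, d2$event, d2$x) -
           efron_loglik(fit2$table$coef - eps, d2$time, d2$event, d2$x)) / (2 * eps)
  expect_lt(abs(sc), 1e-4)
})

test_that("Cox fit is invariant to affine covariate rescaling", {
  set.seed(41)
  n <- 120
  x <- rnorm(n)
  tm <- rexp(n, exp(0.5 * x))
  d <- data.frame(time = tm, event = TRUE, x = x, x10 = 10 * x + 3)
  f1 <- cox_fit(d, "x")
  f2 <- cox_fit(d, "x10")
  expect_equal(f2$table$coef, f1$table$coef / 10, tolerance = 1e-6)
  expect_equal(f2$table$p, f1$table$p, tolerance = 1e-6)
  expect_equal(log(f2$table$lower), log(f1$table$lower) / 10, tolerance = 1e-5)
})

test_that("complete separation is flagged as non-convergence without estimates", {
  d <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = rep(TRUE, 6),
                  x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(d, "x")
  expect_false(fit$converged)
  expect_null(fit$table)
})

test_that("stage-stratified analysis excludes unknown strata and reports per-group medians", {
  cfg <- cohort_sim_config(n_subjects = 800, log_hr = 0, seed = 47)
  rec <- simulate_cohort(cfg)
  res <- stage_stratified_analysis(rec, endpoint = "os",
                                   admin_cutoff = cfg$admin_cutoff)
  expect_setequal(unique(res$stage),
                  c("localized", "locally_advanced", "metastatic"))
  expect_true(all(c("absent", "present") %in% res$carrier))
  excl <- attr(res, "exclusions")
  expect_gt(excl$unknown_stage + excl$unknown_diabetes, 0)
  pres <- res[res$carrier == "present" & res$estimable, ]
  expect_true(all(is.finite(pres$HR)))
  expect_true(all(pres$HR_lcl < pres$HR & pres$HR < pres$HR_ucl))

  # single-stage input gives a single-stratum table
  rec1 <- rec[rec$stage == "metastatic", ]
  res1 <- stage_stratified_analysis(rec1, endpoint = "os",
                                    admin_cutoff = cfg$admin_cutoff)
  expect_setequal(unique(res1$stage), "metastatic")
})

test_that("cohort summary reproduces carrier percentages from genotype counts", {
  mk <- function(n00, n01, n11, cohort)
    data.frame(cohort = cohort,
               genotype = rep(c("0/0", "0/1", "1/1"), c(n00, n01, n11)))
  rec <- rbind(mk(514, 110, 9, 1), mk(3091, 733, 72, 2))
  s <- cohort_summary(rec)
  expect_equal(s[["1"]]$carrier_pct, 18.8)
  expect_equal(s[["1"]]$noncarrier_pct, 81.2)
  expect_equal(s[["2"]]$carrier_pct, 20.7)
  expect_equal(s[["2"]]$noncarrier_pct, 79.3)
  expect_equal(unname(s[["1"]]$genotype_pct), c(81.2, 17.4, 1.4))
  expect_equal(cohort_summary(mk(50, 0, 0, 1))[["1"]]$carrier_pct, 0)
})
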