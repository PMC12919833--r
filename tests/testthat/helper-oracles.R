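# Independent oracles used to cross-check the package implementation.
# These deliberately use different formulations/algorithms than the
# package code paths they validate.

# Hardy-Weinberg exact test by direct enumeration: conditional probability
# of each heterozygote configuration from binomial coefficients.
hwe_oracle <- function(n_00, n_01, n_11) {
  N <- n_00 + n_01 + n_11
  rare <- 2 * min(n_00, n_11) + n_01
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- N - h - hom_r
    if (hom_c < 0) return(0)
    choose(N, hom_r) * choose(N - hom_r, h) * 2^h
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_01, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Efron-tie Cox log partial likelihood for a single covariate.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (tj in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == tj)
    R <- which(time >= tj)
    m <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(log(sR - (seq_len(m) - 1) / m * sD))
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood (step 1e-4).
efron_grid_argmax <- function(time, event, x, lo = -3, hi = 3, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, efron_loglik, numeric(1), time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Hand product-limit estimator (no ties in censoring handling beyond the
# standard convention: events before censorings at equal times).
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv,
       median = if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_)
}

# Brute-force recount of evidence classes from a simulator truth table,
# replaying the classification definitions on fragment provenance rather
# than on emitted alignment records.
recount_from_truth <- function(sim, insert_median, insert_sd,
                               params = classify_params()) {
  locus <- sim$config$locus
  D <- locus$deleted$start; E <- locus$deleted$end
  del_len <- E - D
  rl <- sim$config$read_length
  tr <- sim$truth[is.na(sim$truth$haplotype) | !sim$truth$dropped, ]
  n_del <- 0L; n_ref_read <- 0L
  for (i in seq_len(nrow(tr))) {
    f <- tr[i, ]
    if (is.na(f$haplotype)) next  # confounder pairs counted separately
    fs <- f$frag_start; fl <- f$frag_len
    r1 <- c(fs, fs + rl); r2 <- c(fs + fl - rl, fs + fl)  # haplotype coords
    if (f$is_del_hap) {
      # deletion support: both mates clear of the junction and template
      # length (physical + deletion) in the acceptance band
      if (r1[2] <= D && r2[1] >= D) {
        tlen <- fl + del_len
        shift <- tlen - insert_median
        if (shift >= del_len - params$k_sd * insert_sd &&
            shift <= del_len + params$k_sd * insert_sd)
          n_del <- n_del + 1L
      }
    } else {
      # reference support per read: >= min_overlap aligned bases in deleted
      for (r in list(r1, r2)) {
        ov <- min(r[2], E) - max(r[1], D)
        if (ov >= params$min_overlap) n_ref_read <- n_ref_read + 1L
      }
    }
  }
  list(n_del_support = n_del, n_ref_read = n_ref_read)
}

# Verbatim strict genotype rule on raw counts: 1/1 iff only deletion
# support (and none for the exon sequence), 0/0 iff no deletion support,
# otherwise 0/1.
strict_rule_oracle <- function(n_del, n_ref) {
  if (n_del > 0 && n_ref == 0) "1/1"
  else if (n_del == 0) "0/0"
  else "0/1"
}

# Minimal subject-record builder for endpoint tests.
subject_row <- function(dx_date = NA, treatment_start = NA,
                        progression_date = NA, death_date = NA,
                        competing_event_date = NA, last_followup_date = NA) {
  data.frame(dx_date = dx_date, treatment_start = treatment_start,
             progression_date = progression_date, death_date = death_date,
             competing_event_date = competing_event_date,
             last_followup_date = last_followup_date,
             stringsAsFactors = FALSE)
}
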