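#' Hardy-Weinberg exact test
#'
#' Exact conditional test: holding the allele counts fixed, the p-value is
#' the sum of the conditional probabilities of every heterozygote count
#' (same parity as the minor-allele count) whose probability does not exceed
#' that of the observed count. Valid at rare genotype counts where the
#' chi-square approximation breaks down; `hwe_chisq_test()` offers the
#' asymptotic alternative for large counts.
#'
#' @param n_00,n_01,n_11 Genotype counts (hom-ref, het, hom-alt).
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(5, 0, 5)   # strong HWE violation
#' hwe_exact_test(90, 8, 2)
#' @export
hwe_exact_test <- function(n_00, n_01, n_11) {
  counts <- c(n_00, n_01, n_11)
  stopifnot(length(counts) == 3L, all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) < 1) stop("at least one genotyped sample required")
  N <- sum(counts)
  rare <- 2L * min(n_00, n_11) + n_01        # minor-allele copies
  if (rare == 0L) return(1.0)                # monomorphic: single configuration

  hets <- seq(rare %% 2L, rare, by = 2L)
  hom_r <- (rare - hets) / 2L
  hom_c <- N - hets - hom_r
  ok <- hom_c >= 0
  hets <- hets[ok]; hom_r <- hom_r[ok]; hom_c <- hom_c[ok]
  # conditional probability up to a constant: 2^h * N! / (hom_r! h! hom_c!)
  lp <- hets * log(2) - lfactorial(hom_r) - lfactorial(hets) - lfactorial(hom_c)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_01, hets)]
  min(1.0, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' @rdname hwe_exact_test
#' @export
hwe_chisq_test <- function(n_00, n_01, n_11) {
  N <- n_00 + n_01 + n_11
  stopifnot(N >= 1)
  p <- (2 * n_00 + n_01) / (2 * N)
  if (p == 0 || p == 1) return(1.0)
  expct <- N * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_00, n_01, n_11) - expct)^2 / expct)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-variant genotype quality control
#'
#' Computes call rate, minor allele frequency (over called genotypes only)
#' and the Hardy-Weinberg exact-test p-value, and applies the standard
#' per-variant filters with the inequalities exactly as conventionally
#' printed: fail iff call rate < 0.95, MAF < 0.05, or HWE p < 1e-6 (all
#' thresholds configurable). Every violated rule is reported.
#'
#' @param genotypes Character vector of genotypes in `{0/0, 0/1, 1/1, ./.}`
#'   (`NA` treated as missing).
#' @param min_call_rate,min_maf,min_hwe_p Filter thresholds.
#' @return A `variant_qc` list: `call_rate`, `maf`, `hwe_p`,
#'   `genotype_counts`, `pass`, `reasons`.
#' @export
variant_qc <- function(genotypes, min_call_rate = 0.95, min_maf = 0.05,
                       min_hwe_p = 1e-6) {
  stopifnot(length(genotypes) >= 1)
  g <- as.character(genotypes)
  g[is.na(g)] <- "./."
  bad <- setdiff(unique(g), c("0/0", "0/1", "1/1", "./."))
  if (length(bad)) stop("unrecognized genotype code(s): ", paste(bad, collapse = ", "))
  called <- g[g != "./."]
  call_rate <- length(called) / length(g)
  cnt <- c(n_00 = sum(called == "0/0"), n_01 = sum(called == "0/1"),
           n_11 = sum(called == "1/1"))
  if (length(called)) {
    p_alt <- (cnt[["n_01"]] + 2 * cnt[["n_11"]]) / (2 * length(called))
    maf <- min(p_alt, 1 - p_alt)
    hwe_p <- hwe_exact_test(cnt[["n_00"]], cnt[["n_01"]], cnt[["n_11"]])
  } else {
    maf <- NA_real_; hwe_p <- NA_real_
  }
  reasons <- character()
  if (call_rate < min_call_rate) reasons <- c(reasons, "call_rate")
  if (!is.na(maf) && maf < min_maf) reasons <- c(reasons, "maf")
  if (!is.na(hwe_p) && hwe_p < min_hwe_p) reasons <- c(reasons, "hwe")
  structure(list(call_rate = call_rate, maf = maf, hwe_p = hwe_p,
                 genotype_counts = cnt, pass = length(reasons) == 0L,
                 reasons = reasons),
            class = "variant_qc")
}

#' @export
print.variant_qc <- function(x, ...) {
  cat(sprintf("Variant QC: call_rate=%.3f maf=%.3f hwe_p=%.3g -> %s%s\n",
              x$call_rate, x$maf, x$hwe_p,
              if (x$pass) "PASS" else "FAIL",
              if (x$pass) "" else paste0(" (", paste(x$reasons, collapse = ", "), ")")))
  invisible(x)
}

#' Per-sample genotype quality control
#'
#' A sample fails when its proportion of missing genotypes exceeds
#' `max_missing` (strictly greater, as conventionally printed: "> 5%").
#'
#' @param genotype_matrix Matrix or data frame of genotype codes with
#'   samples in rows and variants in columns; `./.` or `NA` is missing.
#' @param max_missing Maximum tolerated missing fraction.
#' @return Data frame with sample, missing_rate, pass.
#' @export
sample_qc <- function(genotype_matrix, max_missing = 0.05) {
  m <- as.matrix(genotype_matrix)
  stopifnot(ncol(m) >= 1)
  miss <- rowMeans(is.na(m) | m == "./.")
  data.frame(sample = if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m),
             missing_rate = miss, pass = !(miss > max_missing),
             row.names = NULL, stringsAsFactors = FALSE)
}
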