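#' Genotype-calling thresholds
#'
#' Noise-tolerant fraction cutoffs on the deletion-supporting fraction of
#' informative evidence units. `del_fraction = n_del_support / (n_del_support
#' + ref_units)` with `ref_units = n_ref_read + n_ref_pair`; confounder units
#' count toward total coverage but toward neither allele. A sample is called
#' 1/1 when `del_fraction >= t_hom`, 0/0 when `del_fraction < t_het`, 0/1
#' otherwise, and ./. when fewer than `min_depth` informative units are
#' present. In the limit `t_het -> 0+`, `t_hom = 1`, `min_depth = 1` the rule
#' reduces exactly to the strict published statement: 1/1 iff only
#' deletion-supporting units (and none supporting the exon 6 sequence),
#' 0/0 iff no deletion-supporting units, 0/1 otherwise.
#'
#' @param t_hom Lower `del_fraction` bound for a 1/1 call.
#' @param t_het Lower `del_fraction` bound for a 0/1 call.
#' @param min_depth Minimum informative units for any call.
#' @return A `call_thresholds` object.
#' @export
call_thresholds <- function(t_hom = 0.9, t_het = 0.1, min_depth = 8) {
  stopifnot(t_het > 0, t_het < t_hom, t_hom <= 1, min_depth >= 1)
  structure(list(t_hom = t_hom, t_het = t_het, min_depth = as.integer(min_depth)),
            class = "call_thresholds")
}

#' @rdname call_thresholds
#' @details `strict_thresholds()` returns the limit configuration
#'   reproducing the verbatim count rule (any deletion support excludes 0/0;
#'   any reference support excludes 1/1; one informative unit suffices).
#' @export
strict_thresholds <- function() call_thresholds(t_hom = 1, t_het = 1e-9,
                                                min_depth = 1)

#' Call a diploid genotype from evidence counts
#'
#' @param counts An `evidence_counts` object, or a list/one-row data frame
#'   with `n_del_support`, `n_ref_read`, `n_ref_pair`.
#' @param thresholds A `call_thresholds` object.
#' @return A `genotype_call`: list with `genotype` (0/0, 0/1, 1/1 or ./.),
#'   `del_fraction`, `informative_depth`, `thresholds_used`, `sample_id`.
#' @examples
#' call_genotype(evidence_counts(n_del_support = 0, n_ref_read = 30))$genotype  # "0/0"
#' call_genotype(evidence_counts(n_del_support = 25))$genotype                  # "1/1"
#' call_genotype(evidence_counts(n_del_support = 13, n_ref_read = 14))$genotype # "0/1"
#' @export
call_genotype <- function(counts, thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  n_del <- counts$n_del_support
  ref_units <- counts$n_ref_read + (counts$n_ref_pair %||% 0)
  depth <- n_del + ref_units
  if (depth < thresholds$min_depth) {
    gt <- "./."
    frac <- if (depth > 0) n_del / depth else NA_real_
  } else {
    frac <- n_del / depth
    gt <- if (frac >= thresholds$t_hom) "1/1"
    else if (frac < thresholds$t_het) "0/0"
    else "0/1"
  }
  structure(list(genotype = gt, del_fraction = frac,
                 informative_depth = as.integer(depth),
                 thresholds_used = thresholds,
                 sample_id = counts$sample_id %||% NA_character_),
            class = "genotype_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("Genotype %s (del fraction %.3f over %d informative units)\n",
              x$genotype, x$del_fraction, x$informative_depth))
  invisible(x)
}

#' Calibrate calling thresholds against truth labels
#'
#' Exhaustive grid search maximizing overall concordance between
#' [call_genotype()] output and truth genotypes (a no-call counts as
#' discordant). Ties are broken deterministically: larger margin
#' `t_hom - t_het`, then smaller `min_depth`, then smaller `t_het`, then
#' smaller `t_hom`.
#'
#' @param calset Data frame with columns `n_del_support`, `n_ref_read`,
#'   optionally `n_ref_pair`, and `truth` (values 0/0, 0/1, 1/1) -- e.g. an
#'   evidence table joined to PCR-determined genotypes.
#' @param grid List with numeric vectors `t_het`, `t_hom`, `min_depth`
#'   defining the candidate grid; defaults cover fractions 0.005-0.2 /
#'   0.7-0.98 and depths 4 and 8.
#' @return A `call_thresholds` object with attributes `concordance` (achieved
#'   fraction concordant) and `confusion` (truth x call table).
#' @export
calibrate_thresholds <- function(calset,
                                 grid = list(t_het = c(0.005, 0.01, 0.02, 0.05,
                                                       0.1, 0.15, 0.2),
                                             t_hom = c(0.7, 0.75, 0.8, 0.85,
                                                       0.9, 0.95, 0.98),
                                             min_depth = c(4, 8))) {
  stopifnot(is.data.frame(calset), "truth" %in% names(calset),
            all(c("n_del_support", "n_ref_read") %in% names(calset)))
  for (cls in c("0/0", "0/1", "1/1"))
    if (!any(calset$truth == cls))
      stop("calibration set lacks truth class ", cls)
  if (is.null(calset$n_ref_pair)) calset$n_ref_pair <- 0L

  n_del <- calset$n_del_support
  depth <- n_del + calset$n_ref_read + calset$n_ref_pair
  frac <- ifelse(depth > 0, n_del / depth, NA_real_)
  truth <- calset$truth

  combos <- expand.grid(t_het = grid$t_het, t_hom = grid$t_hom,
                        min_depth = grid$min_depth, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[combos$t_het < combos$t_hom & combos$t_hom <= 1, , drop = FALSE]
  if (!nrow(combos)) stop("empty threshold grid")

  conc <- vapply(seq_len(nrow(combos)), function(i) {
    th <- combos[i, ]
    gt <- ifelse(depth < th$min_depth, "./.",
                 ifelse(frac >= th$t_hom, "1/1",
                        ifelse(frac < th$t_het, "0/0", "0/1")))
    mean(gt == truth)
  }, numeric(1))

  ord <- order(-conc, -(combos$t_hom - combos$t_het), combos$min_depth,
               combos$t_het, combos$t_hom)
  best <- combos[ord[1L], ]
  th <- call_thresholds(t_hom = best$t_hom, t_het = best$t_het,
                        min_depth = best$min_depth)
  gt <- vapply(seq_along(depth), function(i)
    call_genotype(list(n_del_support = n_del[i],
                       n_ref_read = calset$n_ref_read[i],
                       n_ref_pair = calset$n_ref_pair[i]), th)$genotype,
    character(1))
  attr(th, "concordance") <- conc[ord[1L]]
  attr(th, "confusion") <- table(truth = truth,
                                 call = factor(gt, c("0/0", "0/1", "1/1", "./.")))
  th
}

#' Genotype a cohort evidence table and write calls (TSV/VCF)
#'
#' @param evidence_table Data frame with one row per sample (schema of
#'   [extract_evidence_cohort()]); `sample_id` must be unique.
#' @param thresholds `call_thresholds`.
#' @param locus `deletion_locus` (used for the VCF record).
#' @param vcf_path Optional path: when given, a VCF 4.2 file with one
#'   symbolic `<DEL>` record and per-sample `GT:DP` fields is written.
#' @return Data frame with sample_id, genotype, del_fraction,
#'   informative_depth.
#' @export
genotype_cohort <- function(evidence_table, thresholds = call_thresholds(),
                            locus = default_locus(), vcf_path = NULL) {
  stopifnot(is.data.frame(evidence_table))
  if (anyDuplicated(evidence_table$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(evidence_table$sample_id[duplicated(evidence_table$sample_id)]),
               collapse = ", "))
  calls <- do.call(rbind, lapply(seq_len(nrow(evidence_table)), function(i) {
    gc <- call_genotype(evidence_table[i, ], thresholds)
    data.frame(sample_id = evidence_table$sample_id[i], genotype = gc$genotype,
               del_fraction = gc$del_fraction,
               informative_depth = gc$informative_depth,
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls))
    calls <- data.frame(sample_id = character(), genotype = character(),
                        del_fraction = numeric(), informative_depth = integer(),
                        stringsAsFactors = FALSE)
  if (!is.null(vcf_path)) write_genotype_vcf(calls, locus, vcf_path)
  calls
}

#' Write genotype calls as a VCF 4.2 symbolic-deletion record
#'
#' One record: symbolic `<DEL>` ALT at the deleted interval with INFO
#' `END`/`SVLEN`/`SVTYPE` and per-sample `GT:DP` (DP = informative depth);
#' no-calls are written as `./.`.
#'
#' @param calls Data frame from [genotype_cohort()].
#' @param locus `deletion_locus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(calls, locus, path) {
  d <- locus$deleted
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", locus$reference_build),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    sprintf("##contig=<ID=%s>", d$chrom),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Informative evidence units\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$sample_id), collapse = "\t"))
  if (nrow(calls) == 0L) {       # no samples: header-only VCF
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt_field <- sprintf("%s:%d", calls$genotype, calls$informative_depth)
  rec <- paste(c(d$chrom, format(d$start, scientific = FALSE), locus$name, "N",
                 "<DEL>", ".", ".",
                 sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d",
                         as.integer(d$end), as.integer(interval_length(d))),
                 "GT:DP", gt_field), collapse = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Simulate an evidence-count calibration set directly from the count model
#'
#' Draws per-sample informative depths and allocates deletion-supporting vs
#' reference units binomially at the expected per-genotype deletion-support
#' fraction, reproducing the shape of a labelled calibration panel (e.g. the
#' 605-sample PCR-typed panel with 9 homozygous and 106 heterozygous
#' carriers) without full read simulation. The expected heterozygote
#' deletion-support fraction is far below one half because one deletion
#' haplotype yields few countable bridging pairs while one reference
#' haplotype yields many reference-supporting reads; the default 0.10
#' matches the read simulator's geometry at the bundled locus.
#'
#' @param truth Character vector of truth genotypes.
#' @param mean_depth Mean informative depth per sample.
#' @param het_fraction Expected deletion-support fraction for heterozygotes.
#' @param noise_rate Rate at which a unit is miscounted into the opposite
#'   class (sequencing/mapping noise).
#' @return Data frame with n_del_support, n_ref_read, n_ref_pair, truth.
#' @export
simulate_calibration_set <- function(truth, mean_depth = 110,
                                     het_fraction = 0.10,
                                     noise_rate = 0.002) {
  stopifnot(all(truth %in% c("0/0", "0/1", "1/1")))
  n <- length(truth)
  depth <- pmax(1L, stats::rpois(n, mean_depth))
  p_del <- ifelse(truth == "1/1", 1 - noise_rate,
                  ifelse(truth == "0/1", het_fraction, noise_rate))
  # homozygous deleted samples carry no reference haplotype, so their
  # informative depth is only the bridging-pair yield (about twice the
  # heterozygote yield)
  depth <- ifelse(truth == "1/1",
                  pmax(1L, stats::rpois(n, 2 * het_fraction * mean_depth)),
                  depth)
  n_del <- stats::rbinom(n, depth, p_del)
  data.frame(n_del_support = n_del, n_ref_read = depth - n_del,
             n_ref_pair = 0L, truth = truth, stringsAsFactors = FALSE)
}
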