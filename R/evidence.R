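#' Read-pair classification parameters
#'
#' @param min_mapq Minimum mapping quality for a read to be eligible.
#' @param k_sd Half-width, in robust fragment-length SDs, of the template-
#'   length acceptance windows: a pair supports the deletion when
#'   `|tlen| - insert_median` lies within `deletion length +/- k_sd * insert_sd`
#'   and its mates flank the deleted interval; a normal-insert pair has
#'   `|tlen|` within `insert_median +/- k_sd * insert_sd`.
#' @param min_overlap Minimum aligned bases inside the deleted interval for a
#'   read to count as reference support.
#' @param min_insert_pairs Minimum proper pairs required to estimate the
#'   fragment-length distribution.
#' @return A `classify_params` list.
#' @export
classify_params <- function(min_mapq = 20, k_sd = 3, min_overlap = 20,
                            min_insert_pairs = 50) {
  stopifnot(min_mapq >= 0, k_sd > 0, min_overlap >= 1, min_insert_pairs >= 1)
  structure(list(min_mapq = min_mapq, k_sd = k_sd, min_overlap = min_overlap,
                 min_insert_pairs = min_insert_pairs),
            class = "classify_params")
}

#' Read-pair observation
#'
#' One classification unit: a read pair (or a lone read whose mate was not
#' observed in the fetched region). Spans are aligned reference spans,
#' 0-based half-open.
#'
#' @param qname Read-pair identifier.
#' @param mapq Mapping quality (for a pair, the minimum across mates).
#' @param tlen Signed template length as recorded in the alignment.
#' @param span1 `genomic_interval`: this read's aligned span.
#' @param span2 Mate's aligned span, or `NULL` if not observed.
#' @param mate_orientation One of `"proper_FR"`, `"inverted"`, `"unmapped"`,
#'   `"distant"`.
#' @param duplicate,secondary,supplementary,qc_fail Flag booleans.
#' @return A `read_pair_obs` list.
#' @export
read_pair_observation <- function(qname, mapq, tlen, span1, span2 = NULL,
                                  mate_orientation = "proper_FR",
                                  duplicate = FALSE, secondary = FALSE,
                                  supplementary = FALSE, qc_fail = FALSE) {
  stopifnot(inherits(span1, "genomic_interval"),
            is.null(span2) || inherits(span2, "genomic_interval"),
            mapq >= 0,
            mate_orientation %in% c("proper_FR", "inverted", "unmapped", "distant"))
  structure(list(qname = qname, mapq = mapq, tlen = tlen, span1 = span1,
                 span2 = span2, mate_orientation = mate_orientation,
                 flags = list(duplicate = duplicate, secondary = secondary,
                              supplementary = supplementary, qc_fail = qc_fail)),
            class = "read_pair_obs")
}

#' Eligibility filter for alignment records
#'
#' A read is ineligible iff it is flagged duplicate, secondary,
#' supplementary, or QC-fail, or its mapping quality is below
#' `params$min_mapq`.
#'
#' @param obs A `read_pair_obs`.
#' @param params `classify_params`.
#' @return TRUE when the read is eligible for evidence counting.
#' @export
filter_read <- function(obs, params = classify_params()) {
  f <- obs$flags
  !(isTRUE(f$duplicate) || isTRUE(f$secondary) || isTRUE(f$supplementary) ||
      isTRUE(f$qc_fail) || obs$mapq < params$min_mapq)
}

#' Estimate the sample fragment-length distribution
#'
#' Robust location/scale of the absolute template length over proper
#' (FR-oriented, same-chromosome) pairs found in the sampling regions:
#' location is the median, scale is 1.4826 x MAD, floored at 1 bp. Sampling
#' regions should sit away from the structural variant (by default the
#' window flanks), since bridging pairs at the variant inflate both.
#'
#' @param records Alignment record data frame (see [extract_evidence()]) or
#'   a numeric vector of template lengths.
#' @param sampling_regions List of `genomic_interval`s to draw pairs from;
#'   ignored when `records` is already a numeric vector.
#' @param min_pairs Minimum number of proper pairs required.
#' @return List with `insert_median` and `insert_sd` (bp).
#' @export
estimate_insert_distribution <- function(records, sampling_regions = NULL,
                                         min_pairs = 50) {
  if (is.numeric(records)) {
    tl <- abs(records[records != 0])
  } else {
    r <- decorate_records(records)
    ok <- r$proper_fr & r$tlen > 0 & r$eligible_flags
    if (!is.null(sampling_regions) && length(sampling_regions)) {
      in_region <- rep(FALSE, nrow(r))
      for (sr in sampling_regions)
        in_region <- in_region |
          (r$rname == sr$chrom & r$start0 >= sr$start & (r$start0 + r$tlen) <= sr$end)
      ok <- ok & in_region
    }
    tl <- abs(r$tlen[ok])
  }
  if (length(tl) < min_pairs)
    stop("too few proper pairs (", length(tl), " < ", min_pairs,
         ") to estimate the fragment-length distribution; ",
         "use larger sampling regions")
  list(insert_median = stats::median(tl),
       insert_sd = max(stats::mad(tl), 1.0))
}

#' Classify one read-pair observation at a deletion locus
#'
#' Assigns exactly one evidence class, in precedence order:
#' \describe{
#'   \item{CONFOUNDER}{inverted mate orientation with either mate overlapping
#'     a confounder region -- paralog-inversion mapping artifacts count only
#'     toward total coverage, never toward either allele, and take precedence
#'     over the deletion-support test.}
#'   \item{DEL}{template length elevated by approximately the deletion length
#'     (`|tlen| - insert_median` within `del_len +/- k_sd * insert_sd`) AND
#'     the two mates flank the deleted interval (one aligned wholly before
#'     its start, the other wholly after its end).}
#'   \item{REF_READ}{at least `min_overlap` aligned bases inside the deleted
#'     interval (direct evidence the deleted sequence is present).}
#'   \item{REF_PAIR}{proper FR orientation, normal template length
#'     (`|tlen|` within `insert_median +/- k_sd * insert_sd`), and the pair's
#'     outer span containing the deleted interval.}
#'   \item{UNINFORMATIVE}{anything else.}
#' }
#'
#' @param obs A `read_pair_obs` that passed [filter_read()].
#' @param locus A `deletion_locus`.
#' @param insert_median,insert_sd Fragment-length location/scale (bp).
#' @param params `classify_params`.
#' @return One of `"DEL"`, `"REF_READ"`, `"REF_PAIR"`, `"CONFOUNDER"`,
#'   `"UNINFORMATIVE"`.
#' @export
classify_pair <- function(obs, locus, insert_median, insert_sd,
                          params = classify_params()) {
  del <- locus$deleted
  del_len <- interval_length(del)
  spans <- Filter(Negate(is.null), list(obs$span1, obs$span2))
  atl <- abs(obs$tlen)

  if (identical(obs$mate_orientation, "inverted") && length(locus$confounders)) {
    for (cf in locus$confounders)
      for (sp in spans)
        if (interval_overlap_width(sp, cf) > 0) return("CONFOUNDER")
  }

  if (!is.null(obs$span2)) {
    shift <- atl - insert_median
    in_del_band <- shift >= del_len - params$k_sd * insert_sd &&
      shift <= del_len + params$k_sd * insert_sd
    s1 <- obs$span1; s2 <- obs$span2
    flanking <- identical(s1$chrom, del$chrom) && identical(s2$chrom, del$chrom) &&
      ((s1$end <= del$start && s2$start >= del$end) ||
         (s2$end <= del$start && s1$start >= del$end))
    if (in_del_band && flanking) return("DEL")
  }

  for (sp in spans)
    if (interval_overlap_width(sp, del) >= params$min_overlap) return("REF_READ")

  if (identical(obs$mate_orientation, "proper_FR") && !is.null(obs$span2) &&
      abs(atl - insert_median) <= params$k_sd * insert_sd) {
    outer <- genomic_interval(obs$span1$chrom,
                              min(obs$span1$start, obs$span2$start),
                              max(obs$span1$end, obs$span2$end))
    if (interval_contains(outer, del)) return("REF_PAIR")
  }

  "UNINFORMATIVE"
}

#' Per-sample evidence counts
#'
#' @param n_del_support Pairs with anomalously large template length bridging
#'   the deleted interval (counted once per pair).
#' @param n_ref_read Reads with aligned bases inside the deleted interval
#'   (counted per read).
#' @param n_ref_pair Normal-insert pairs whose outer span contains the
#'   deleted interval (once per pair).
#' @param n_confounder Inverted-orientation pairs over confounder regions
#'   (once per pair).
#' @param insert_median,insert_sd Fragment-length location/scale used (bp).
#' @param n_softclip Diagnostic: eligible reads soft-clipped at a breakpoint
#'   (not counted as deletion support).
#' @param window_reads Diagnostic: eligible reads overlapping the window.
#' @param sample_id Sample label.
#' @return An `evidence_counts` object; `n_total` is the sum of the four
#'   evidence classes.
#' @export
evidence_counts <- function(n_del_support = 0, n_ref_read = 0, n_ref_pair = 0,
                            n_confounder = 0, insert_median = NA_real_,
                            insert_sd = NA_real_, n_softclip = 0,
                            window_reads = 0, sample_id = NA_character_) {
  cnts <- c(n_del_support, n_ref_read, n_ref_pair, n_confounder)
  stopifnot(all(cnts >= 0), all(cnts == round(cnts)))
  structure(list(sample_id = sample_id,
                 n_del_support = as.integer(n_del_support),
                 n_ref_read = as.integer(n_ref_read),
                 n_ref_pair = as.integer(n_ref_pair),
                 n_confounder = as.integer(n_confounder),
                 n_total = as.integer(sum(cnts)),
                 insert_median = insert_median, insert_sd = insert_sd,
                 n_softclip = as.integer(n_softclip),
                 window_reads = as.integer(window_reads)),
            class = "evidence_counts")
}

#' @export
print.evidence_counts <- function(x, ...) {
  cat(sprintf(paste0("Evidence counts [%s]: DEL=%d REF_READ=%d REF_PAIR=%d ",
                     "CONFOUNDER=%d total=%d (insert %.0f +/- %.0f bp)\n"),
              x$sample_id, x$n_del_support, x$n_ref_read, x$n_ref_pair,
              x$n_confounder, x$n_total, x$insert_median, x$insert_sd))
  invisible(x)
}

#' @method as.data.frame evidence_counts
#' @export
as.data.frame.evidence_counts <- function(x, ...) {
  data.frame(sample_id = x$sample_id, n_del_support = x$n_del_support,
             n_ref_read = x$n_ref_read, n_ref_pair = x$n_ref_pair,
             n_confounder = x$n_confounder, n_total = x$n_total,
             insert_median = x$insert_median, insert_sd = x$insert_sd,
             n_softclip = x$n_softclip, window_reads = x$window_reads,
             stringsAsFactors = FALSE)
}

# --- record plumbing ---------------------------------------------------------

# Normalize an alignment record data frame: add 0-based spans, strand and
# flag decodes. Required columns: qname, flag, rname, pos, mapq, cigar,
# rnext/mrnm, tlen/isize.
decorate_records <- function(records) {
  r <- records
  if (is.null(r$tlen)) r$tlen <- r$isize
  if (is.null(r$rnext)) r$rnext <- as.character(r$mrnm)
  r$tlen[is.na(r$tlen)] <- 0L
  fl <- r$flag
  r$start0 <- r$pos - 1L
  r$end0 <- r$start0 + GenomicAlignments::cigarWidthAlongReferenceSpace(r$cigar)
  r$rev <- bitwAnd(fl, 16L) > 0L
  r$mate_rev <- bitwAnd(fl, 32L) > 0L
  r$mate_unmapped <- bitwAnd(fl, 8L) > 0L
  r$dup <- bitwAnd(fl, 1024L) > 0L
  r$secondary <- bitwAnd(fl, 256L) > 0L
  r$supplementary <- bitwAnd(fl, 2048L) > 0L
  r$qcfail <- bitwAnd(fl, 512L) > 0L
  r$mate_same_chrom <- r$rnext %in% c("=", as.character(r$rname))
  r$proper_fr <- !r$mate_unmapped & r$mate_same_chrom & (r$rev != r$mate_rev)
  r$eligible_flags <- !(r$dup | r$secondary | r$supplementary | r$qcfail)
  r
}

mate_orientation_of <- function(rec_row) {
  if (rec_row$mate_unmapped) return("unmapped")
  if (!rec_row$mate_same_chrom) return("distant")
  if (rec_row$rev == rec_row$mate_rev) return("inverted")
  "proper_FR"
}

# Fetch alignment records over regions from a BAM/SAM file path, a
# sim_sample, or a raw data frame.
fetch_records <- function(input, regions) {
  if (inherits(input, "sim_sample")) input <- input$records
  if (is.data.frame(input)) {
    r <- decorate_records(input)
    keep <- rep(FALSE, nrow(r))
    for (g in regions)
      keep <- keep | (r$rname == g$chrom & r$end0 > g$start & r$start0 < g$end)
    return(r[keep, , drop = FALSE])
  }
  stopifnot(is.character(input), length(input) == 1L)
  path <- input
  if (grepl("\\.sam$", path, ignore.case = TRUE)) path <- sam_to_bam(path)
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    stop("BAM index (.bai) required for region access on ", path,
         "; run Rsamtools::indexBam() first")
  gr <- GenomicRanges::GRanges(
    vapply(regions, function(g) g$chrom, character(1)),
    IRanges::IRanges(vapply(regions, function(g) g$start + 1, numeric(1)),
                     vapply(regions, function(g) g$end, numeric(1))))
  gr <- GenomicRanges::reduce(gr)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "isize"),
    which = gr)
  res <- Rsamtools::scanBam(path, param = param)
  df <- do.call(rbind, lapply(res, function(x)
    data.frame(qname = x$qname, flag = x$flag, rname = as.character(x$rname),
               pos = x$pos, mapq = x$mapq, cigar = x$cigar,
               rnext = as.character(x$mrnm), tlen = x$isize,
               stringsAsFactors = FALSE)))
  df <- df[!is.na(df$pos), , drop = FALSE]
  df <- df[!duplicated(paste(df$qname, df$flag, df$pos)), , drop = FALSE]
  decorate_records(df)
}

#' Extract deletion-genotyping evidence from aligned reads
#'
#' Streams alignment records over the locus window, filters them
#' ([filter_read()] semantics), assembles read pairs by name (first-seen
#' primary mates), classifies each pair with [classify_pair()], and tallies
#' per-sample [evidence_counts()]. Each eligible pair lands in exactly one
#' class; DEL / REF_PAIR / CONFOUNDER are counted once per pair, REF_READ
#' once per qualifying read. The fragment-length distribution is estimated
#' from proper pairs in `sampling_regions` (default: 2-kb flanks on each
#' side of the window, clear of the variant) unless `insert_stats` is given.
#'
#' @param input BAM path (indexed; SAM accepted and converted), a
#'   `sim_sample`, or an alignment record data frame.
#' @param locus A `deletion_locus`.
#' @param params `classify_params`.
#' @param insert_stats Optional precomputed list(insert_median, insert_sd).
#' @param sampling_regions Regions for fragment-length estimation.
#' @param sample_id Sample label carried into the result.
#' @return An `evidence_counts` object.
#' @export
extract_evidence <- function(input, locus, params = classify_params(),
                             insert_stats = NULL,
                             sampling_regions = default_sampling_regions(locus),
                             sample_id = NA_character_) {
  stopifnot(inherits(locus, "deletion_locus"))
  if (inherits(input, "sim_sample") && is.na(sample_id))
    sample_id <- input$sample_id
  regions <- c(list(locus$window), sampling_regions)
  r <- fetch_records(input, regions)

  elig <- r$eligible_flags & r$mapq >= params$min_mapq
  r <- r[elig, , drop = FALSE]
  win <- locus$window
  in_win <- r$rname == win$chrom & r$end0 > win$start & r$start0 < win$end
  if (!any(in_win))
    return(evidence_counts(insert_median = NA_real_, insert_sd = NA_real_,
                           sample_id = sample_id))

  if (is.null(insert_stats))
    insert_stats <- estimate_insert_distribution(
      r, sampling_regions, min_pairs = params$min_insert_pairs)
  imed <- insert_stats$insert_median
  isd <- insert_stats$insert_sd

  # pair assembly over window-overlapping read names; first-seen mates
  wr <- r[in_win, , drop = FALSE]
  qn_win <- unique(wr$qname)
  rp <- r[r$qname %in% qn_win, , drop = FALSE]
  rp <- rp[!duplicated(paste(rp$qname, bitwAnd(rp$flag, 192L))), , drop = FALSE]
  by_q <- split(seq_len(nrow(rp)), rp$qname)

  del <- locus$deleted
  n_del <- n_ref_read <- n_ref_pair <- n_conf <- 0L
  for (ii in by_q) {
    ii <- ii[order(rp$start0[ii])]
    a <- rp[ii[1L], ]
    span1 <- genomic_interval(a$rname, a$start0, a$end0)
    span2 <- NULL
    if (length(ii) >= 2L) {
      b <- rp[ii[2L], ]
      span2 <- genomic_interval(b$rname, b$start0, b$end0)
    }
    obs <- read_pair_observation(
      qname = a$qname,
      mapq = min(rp$mapq[ii]),
      tlen = a$tlen,
      span1 = span1, span2 = span2,
      mate_orientation = mate_orientation_of(a))
    cls <- classify_pair(obs, locus, imed, isd, params)
    if (cls == "DEL") n_del <- n_del + 1L
    else if (cls == "CONFOUNDER") n_conf <- n_conf + 1L
    else if (cls == "REF_PAIR") n_ref_pair <- n_ref_pair + 1L
    else if (cls == "REF_READ") {
      for (sp in list(span1, span2))
        if (!is.null(sp) &&
            interval_overlap_width(sp, del) >= params$min_overlap)
          n_ref_read <- n_ref_read + 1L
    }
  }

  # soft-clip breakpoint diagnostic (never counted as deletion support)
  has_clip <- grepl("S", wr$cigar, fixed = TRUE)
  near_bp <- (abs(wr$end0 - del$start) <= 5) | (abs(wr$start0 - del$end) <= 5)
  n_softclip <- sum(has_clip & near_bp)

  evidence_counts(n_del_support = n_del, n_ref_read = n_ref_read,
                  n_ref_pair = n_ref_pair, n_confounder = n_conf,
                  insert_median = imed, insert_sd = isd,
                  n_softclip = n_softclip, window_reads = sum(in_win),
                  sample_id = sample_id)
}

#' Default fragment-length sampling regions for a locus
#'
#' Two flanks adjacent to the evidence window (clear of the deletion), where
#' template lengths reflect the undisturbed library fragment distribution.
#'
#' @param locus A `deletion_locus`.
#' @param flank Flank width (bp).
#' @return List of two `genomic_interval`s (one if the window starts at 0).
#' @export
default_sampling_regions <- function(locus, flank = 2000) {
  w <- locus$window
  out <- list()
  if (w$start > 0)
    out <- c(out, list(genomic_interval(w$chrom, max(0, w$start - flank), w$start)))
  c(out, list(genomic_interval(w$chrom, w$end, w$end + flank)))
}

#' Extract evidence for many samples into one table
#'
#' @param inputs Named list of inputs accepted by [extract_evidence()] (names
#'   become sample ids), or a list of `sim_sample`s.
#' @inheritParams extract_evidence
#' @return Data frame with one row per sample (TSV-ready schema: sample_id,
#'   n_del_support, n_ref_read, n_ref_pair, n_confounder, n_total,
#'   insert_median, insert_sd, n_softclip, window_reads).
#' @export
extract_evidence_cohort <- function(inputs, locus, params = classify_params(),
                                    sampling_regions = default_sampling_regions(locus)) {
  ids <- names(inputs)
  rows <- lapply(seq_along(inputs), function(i) {
    sid <- if (!is.null(ids) && nzchar(ids[i])) ids[i] else NA_character_
    as.data.frame(extract_evidence(inputs[[i]], locus, params,
                                   sampling_regions = sampling_regions,
                                   sample_id = sid))
  })
  do.call(rbind, rows)
}
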