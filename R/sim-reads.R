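#' Synthetic deletion locus for simulation
#'
#' A scaled-down analog of the bundled CTRB2 exon 6 locus placed on a
#' 5200-bp synthetic contig: a 1300-bp evidence window with the 584-bp
#' deleted interval centered in it, a 200-bp confounder interval at the
#' window's left edge (standing in for inverted-paralog mappings), and
#' ~1950 bp of flanking sequence on each side from which the fragment-length
#' distribution can be estimated away from the structural variant.
#'
#' @param contig Contig name.
#' @return A `deletion_locus` on the synthetic contig.
#' @export
sim_locus <- function(contig = "sim16") {
  win <- genomic_interval(contig, 1950, 3250)
  del <- genomic_interval(contig, 1950 + 358, 1950 + 358 + 584)
  deletion_locus("CTRB2ex6_sim", deleted = del, window = win,
                 confounders = list(genomic_interval(contig, 1950, 2150)),
                 reference_build = "synthetic")
}

#' Paired-end read simulation configuration
#'
#' Fragments are drawn uniformly over the diploid haplotypes of a synthetic
#' contig at `coverage/2` mean depth each; fragment lengths are normal,
#' truncated below at `2 * read_length`. Fragments on a deletion haplotype
#' that bridge the deleted interval are emitted with reference-coordinate
#' mates flanking the gap, so their recorded template length equals the
#' physical fragment length plus the deletion length. Reads crossing a
#' breakpoint are soft-clipped at it (`junction_mode = "clip"`) or the whole
#' pair is omitted (`"drop"`; a pair with a junction-crossing read can never
#' satisfy the mates-flanking deletion-evidence condition, so dropping the
#' pair keeps the emitted records a valid paired set without touching the
#' deletion-supporting count). A `confounder_rate` fraction of extra pairs is
#' emitted in inverted (same-strand) orientation over the confounder region,
#' mimicking paralog-inversion mapping artifacts.
#'
#' @param locus A `deletion_locus`; default [sim_locus()].
#' @param contig_len Synthetic contig length (bp).
#' @param coverage Mean sequencing depth (x).
#' @param fragment_mean,fragment_sd Fragment-length distribution (bp).
#' @param read_length Read length (bp).
#' @param n_samples Number of samples for cohort simulation.
#' @param genotypes Optional explicit genotype vector (length `n_samples`,
#'   values in 0/0, 0/1, 1/1); if NULL genotypes are drawn under
#'   Hardy-Weinberg equilibrium at allele frequency `q`.
#' @param q Deletion-allele frequency for the HWE draw. The default 0.111 is
#'   the combined two-cohort allele frequency implied by the published
#'   genotype counts ((110 + 2*9 + 733 + 2*72) / (2*(633 + 3896))).
#' @param junction_mode `"clip"` or `"drop"` (see above).
#' @param confounder_rate Fraction of fragments emitted as inverted-
#'   orientation artifacts over the confounder region.
#' @param seed Integer seed driving all sampling.
#' @param ref_seed Seed for the synthetic reference sequence itself (kept
#'   separate from `seed` so the "genome" is stable across runs).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(locus = sim_locus(), contig_len = 5200,
                              coverage = 30, fragment_mean = 350,
                              fragment_sd = 50, read_length = 100,
                              n_samples = 1, genotypes = NULL, q = 0.111,
                              junction_mode = c("clip", "drop"),
                              confounder_rate = 0.02, seed = 1,
                              ref_seed = 160001) {
  junction_mode <- match.arg(junction_mode)
  stopifnot(inherits(locus, "deletion_locus"), coverage > 0,
            fragment_sd >= 0, read_length > 0, n_samples >= 1,
            q >= 0, q <= 1, confounder_rate >= 0, confounder_rate < 1)
  if (fragment_mean <= 2 * read_length)
    warning("fragment_mean <= 2 * read_length: most fragments will be truncated")
  if (locus$window$end > contig_len)
    stop("contig_len must contain the locus window")
  if (!is.null(genotypes)) {
    if (length(genotypes) != n_samples)
      stop("genotypes must have length n_samples")
    bad <- setdiff(unique(genotypes), c("0/0", "0/1", "1/1"))
    if (length(bad)) stop("invalid genotype label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(locus = locus, contig_len = contig_len, coverage = coverage,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 read_length = read_length, n_samples = n_samples,
                 genotypes = genotypes, q = q, junction_mode = junction_mode,
                 confounder_rate = confounder_rate, seed = as.integer(seed),
                 ref_seed = as.integer(ref_seed)),
            class = "sim_config")
}

# Run code with an isolated RNG state (used for the fixed-seed reference
# sequence so it never perturbs the simulation stream).
with_isolated_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic reference sequence for the simulation contig
#'
#' @param config A `sim_config`.
#' @return A named `Biostrings::DNAStringSet` of length 1.
#' @export
sim_reference <- function(config) {
  seqchr <- with_isolated_rng(config$ref_seed,
    paste(sample(c("A", "C", "G", "T"), config$contig_len, replace = TRUE),
          collapse = ""))
  ref <- Biostrings::DNAStringSet(seqchr)
  names(ref) <- config$locus$window$chrom
  ref
}

# Haplotype sequence: reference with the deleted interval excised.
haplotype_seq <- function(ref_chr, locus, is_del) {
  if (!is_del) return(ref_chr)
  d <- locus$deleted
  paste0(substr(ref_chr, 1, d$start), substr(ref_chr, d$end + 1, nchar(ref_chr)))
}

#' Simulate aligned paired-end reads for one diploid sample
#'
#' Emits coordinate-correct alignment records (a data frame in SAM column
#' order) for a diploid with the given genotype at the configured locus,
#' together with a per-fragment truth table recording each fragment's
#' haplotype of origin, start, and length, whether its reads cross a
#' breakpoint, and whether it is expected to be countable deletion support
#' (both mates clear of the breakpoints on a deletion haplotype).
#'
#' @param config A `sim_config`.
#' @param genotype One of "0/0", "0/1", "1/1".
#' @param sample_id Sample identifier (used in read names).
#' @param seed Seed set before sampling; `NULL` to continue the current RNG
#'   stream (used by [simulate_cohort_reads()]).
#' @return A `sim_sample`: list with `records` (alignment data frame),
#'   `truth` (fragment truth table), `genotype`, `sample_id`, `config`.
#' @export
simulate_sample <- function(config, genotype, sample_id = "S1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!genotype %in% c("0/0", "0/1", "1/1"))
    stop("invalid genotype label: ", genotype)
  if (!is.null(seed)) set.seed(seed)

  locus <- config$locus
  chrom <- locus$window$chrom
  D <- locus$deleted$start; E <- locus$deleted$end
  del_len <- interval_length(locus$deleted)
  rl <- config$read_length
  ref_chr <- as.character(sim_reference(config)[[1]])

  hap_is_del <- switch(genotype, "0/0" = c(FALSE, FALSE),
                       "0/1" = c(FALSE, TRUE), "1/1" = c(TRUE, TRUE))

  rec_list <- list(); truth_list <- list(); frag_id <- 0L
  for (h in 1:2) {
    is_del <- hap_is_del[h]
    hap_len <- config$contig_len - if (is_del) del_len else 0L
    n_frag <- round((config$coverage / 2) * hap_len / (2 * rl))
    if (n_frag < 1L) next
    flen <- round(stats::rnorm(n_frag, config$fragment_mean, config$fragment_sd))
    flen <- pmin(pmax(flen, 2 * rl), hap_len)
    fs <- floor(stats::runif(n_frag, 0, hap_len - flen + 1))  # 0-based hap coord
    hap_chr <- haplotype_seq(ref_chr, locus, is_del)

    # read intervals in haplotype coordinates
    r1s <- fs; r1e <- fs + rl
    r2s <- fs + flen - rl; r2e <- fs + flen
    cross1 <- is_del & r1s < D & r1e > D
    cross2 <- is_del & r2s < D & r2e > D
    keep <- rep(TRUE, n_frag)
    if (config$junction_mode == "drop") keep <- !(cross1 | cross2)

    # haplotype -> reference coordinate map (deletion haplotype skips the gap)
    map_pos <- function(p) if (is_del) ifelse(p < D, p, p + del_len) else p
    mk_read <- function(s, e, cross) {
      # returns list(ref_start0, cigar, ref_end0) vectors
      a <- D - s              # aligned length left of junction (if crossing)
      b <- e - D              # right of junction
      left_anchor <- a >= b
      ref_start <- ifelse(cross, ifelse(left_anchor, s, E), map_pos(s))
      width <- ifelse(cross, ifelse(left_anchor, a, b), rl)
      cigar <- ifelse(cross,
                      ifelse(left_anchor, paste0(a, "M", b, "S"),
                             paste0(a, "S", b, "M")),
                      paste0(rl, "M"))
      list(start = ref_start, end = ref_start + width, cigar = cigar)
    }
    R1 <- mk_read(r1s, r1e, cross1); R2 <- mk_read(r2s, r2e, cross2)
    tlen <- pmax(R1$end, R2$end) - pmin(R1$start, R2$start)
    qn <- sprintf("%s:h%d:f%05d", sample_id, h, seq_len(n_frag))
    seq1 <- substring(hap_chr, r1s + 1, r1e)
    seq2 <- substring(hap_chr, r2s + 1, r2e)

    idx <- which(keep)
    if (length(idx)) {
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        qname = rep(qn[idx], 2L),
        flag = rep(c(99L, 147L), each = length(idx)),
        rname = chrom,
        pos = c(R1$start[idx], R2$start[idx]) + 1L,  # SAM 1-based
        mapq = 60L,
        cigar = c(R1$cigar[idx], R2$cigar[idx]),
        rnext = "=",
        pnext = c(R2$start[idx], R1$start[idx]) + 1L,
        tlen = c(tlen[idx], -tlen[idx]),
        seq = c(seq1[idx], seq2[idx]),
        stringsAsFactors = FALSE)
    }
    truth_list[[length(truth_list) + 1L]] <- data.frame(
      sample_id = sample_id, qname = qn, haplotype = h, is_del_hap = is_del,
      frag_start = fs, frag_len = flen,
      r1_cross = cross1, r2_cross = cross2, dropped = !keep,
      del_informative = is_del & keep & (r1e <= D) & (r2s >= D),
      stringsAsFactors = FALSE)
    frag_id <- frag_id + n_frag
  }

  # inverted-orientation confounder pairs over the confounder region
  n_emitted_pairs <- sum(vapply(rec_list, nrow, integer(1))) / 2
  n_conf <- round(config$confounder_rate * n_emitted_pairs)
  if (n_conf > 0 && length(locus$confounders)) {
    cf <- locus$confounders[[1]]
    c1 <- floor(stats::runif(n_conf, cf$start, cf$end - rl + 1))
    gap <- round(stats::runif(n_conf, 1200, 2200))
    c2 <- pmin(c1 + gap, config$contig_len - rl)
    qn <- sprintf("%s:conf:%04d", sample_id, seq_len(n_conf))
    rec_list[[length(rec_list) + 1L]] <- data.frame(
      qname = rep(qn, 2L),
      flag = rep(c(65L, 129L), each = n_conf),  # paired, both forward, not proper
      rname = chrom,
      pos = c(c1, c2) + 1L,
      mapq = 60L,
      cigar = paste0(rl, "M"),
      rnext = "=",
      pnext = c(c2, c1) + 1L,
      tlen = c(c2 + rl - c1, -(c2 + rl - c1)),
      seq = c(substring(ref_chr, c1 + 1, c1 + rl),
              substring(ref_chr, c2 + 1, c2 + rl)),
      stringsAsFactors = FALSE)
    truth_list[[length(truth_list) + 1L]] <- data.frame(
      sample_id = sample_id, qname = qn, haplotype = NA_integer_,
      is_del_hap = FALSE, frag_start = c1, frag_len = c2 + rl - c1,
      r1_cross = FALSE, r2_cross = FALSE, dropped = FALSE,
      del_informative = FALSE, stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, rec_list)
  records <- records[order(records$pos, records$qname, records$flag), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, truth = do.call(rbind, truth_list),
                 genotype = genotype, sample_id = sample_id, config = config),
            class = "sim_sample")
}

#' Write simulated alignments as SAM (and optionally convert to indexed BAM)
#'
#' @param sim A `sim_sample`.
#' @param path Output SAM path.
#' @return `write_sam()`: the SAM path, invisibly. `sam_to_bam()`: the BAM
#'   path (sorted, indexed).
#' @export
write_sam <- function(sim, path) {
  stopifnot(inherits(sim, "sim_sample"))
  cfg <- sim$config
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", cfg$locus$window$chrom, cfg$contig_len),
           sprintf("@RG\tID:%s\tSM:%s", sim$sample_id, sim$sample_id))
  r <- sim$records
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                  r$rnext, r$pnext, r$tlen, r$seq, strrep("I", nchar(r$seq)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @param sam_path Path to a SAM file with `@SQ` header lines.
#' @export
sam_to_bam <- function(sam_path) {
  dest <- sub("\\.sam$", "", sam_path)
  bam <- Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Simulate a cohort of samples with genotypes under Hardy-Weinberg
#'
#' Genotypes are taken verbatim from `config$genotypes` when given, otherwise
#' drawn per sample from the HWE proportions ((1-q)^2, 2q(1-q), q^2) at the
#' configured deletion-allele frequency. All randomness flows from
#' `config$seed` through one RNG stream, so a fixed seed gives byte-identical
#' truth tables.
#'
#' @param config A `sim_config` with `n_samples` set.
#' @param dir Optional directory: when given, per-sample SAM files, the
#'   reference FASTA, a truth TSV and a config echo JSON are written there.
#' @return List with `samples` (list of `sim_sample`), `truth` (data frame
#'   sample_id/genotype), and `dir` (or NULL).
#' @export
simulate_cohort_reads <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"), config$n_samples >= 1)
  set.seed(config$seed)
  n <- config$n_samples
  if (is.null(config$genotypes)) {
    p <- c((1 - config$q)^2, 2 * config$q * (1 - config$q), config$q^2)
    gts <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE, prob = p)
  } else gts <- config$genotypes
  ids <- sprintf("S%04d", seq_len(n))
  samples <- vector("list", n)
  for (i in seq_len(n))
    samples[[i]] <- simulate_sample(config, gts[i], ids[i], seed = NULL)
  names(samples) <- ids
  truth <- data.frame(sample_id = ids, genotype = gts, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(sim_reference(config),
                                file.path(dir, "reference.fa"))
    for (s in samples) write_sam(s, file.path(dir, paste0(s$sample_id, ".sam")))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg_echo <- config; cfg_echo$locus <- jsonlite::fromJSON(serialize_locus(config$locus))
    jsonlite::write_json(unclass(cfg_echo), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(samples = samples, truth = truth, dir = dir)
}
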