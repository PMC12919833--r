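test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 5)
  a <- simulate_sample(cfg, "0/1")
  b <- simulate_sample(cfg, "0/1")
  expect_identical(a$truth, b$truth)
  expect_identical(a$records, b$records)
})

test_that("a reference-only diploid emits no deletion-bridging large-insert pairs", {
  cfg <- simulation_config(seed = 3)
  s <- simulate_sample(cfg, "0/0")
  D <- cfg$locus$deleted$start; E <- cfg$locus$deleted$end
  r <- s$records
  end0 <- r$pos - 1 + as.integer(sub("M.*", "", sub("^[0-9]+S", "", r$cigar)))
  # pairs with both mates flanking the gap and tlen elevated by ~ the deletion
  first <- r[r$tlen > 0, ]
  elevated <- abs(first$tlen - (cfg$fragment_mean + 584)) < 3 * cfg$fragment_sd
  flank_left <- (first$pos - 1 + 100) <= D
  mate_right <- first$pnext - 1 >= E
  expect_identical(sum(elevated & flank_left & mate_right), 0L)
})

test_that("junction_mode drop removes every read with aligned bases in the deleted interval", {
  cfg <- simulation_config(seed = 3, junction_mode = "drop", confounder_rate = 0)
  s <- simulate_sample(cfg, "1/1")
  r <- s$records
  expect_true(all(r$cigar == paste0(cfg$read_length, "M")))
  start0 <- r$pos - 1
  end0 <- start0 + cfg$read_length
  D <- cfg$locus$deleted$start; E <- cfg$locus$deleted$end
  overlap <- pmin(end0, E) - pmax(start0, D)
  expect_true(all(overlap <= 0))
})

test_that("clip mode soft-clips junction reads at the breakpoints", {
  cfg <- simulation_config(seed = 31, confounder_rate = 0)
  s <- simulate_sample(cfg, "1/1")
  clipped <- s$records[grepl("S", s$records$cigar), ]
  expect_gt(nrow(clipped), 0)
  D <- cfg$locus$deleted$start; E <- cfg$locus$deleted$end
  for (i in seq_len(nrow(clipped))) {
    cg <- clipped$cigar[i]
    if (grepl("M[0-9]+S$", cg)) {  # left-anchored: aligned part ends at D
      m <- as.numeric(sub("M.*", "", cg))
      expect_equal(clipped$pos[i] - 1 + m, D)
    } else {                       # right-anchored: aligned part starts at E
      expect_equal(clipped$pos[i] - 1, E)
    }
  }
})

test_that("heterozygote evidence matches the truth-table expectation", {
  cfg <- simulation_config(seed = 3)
  s <- simulate_sample(cfg, "0/1")
  ev <- extract_evidence(s, cfg$locus)
  expect_gt(ev$n_del_support, 0)
  expect_gt(ev$n_ref_read, 0)
  oracle <- recount_from_truth(s, ev$insert_median, ev$insert_sd)
  p <- oracle$n_del_support / (oracle$n_del_support + oracle$n_ref_read)
  n <- ev$n_del_support + ev$n_ref_read + ev$n_ref_pair
  band <- 4 * sqrt(p * (1 - p) / n)
  frac <- ev$n_del_support / n
  expect_lt(abs(frac - p), band + 0.02)
})

test_that("mean depth over non-deleted window positions honours the coverage setting", {
  cfg <- simulation_config(seed = 17, coverage = 40, confounder_rate = 0)
  s <- simulate_sample(cfg, "0/0")
  r <- s$records
  w <- cfg$locus$window
  cov <- integer(cfg$contig_len)
  for (i in seq_len(nrow(r))) {
    a <- r$pos[i]; b <- a + cfg$read_length - 1
    cov[a:b] <- cov[a:b] + 1L
  }
  mean_depth <- mean(cov[(w$start + 1):w$end])
  expect_lt(abs(mean_depth - 40) / 40, 0.10)
})

test_that("explicit genotype assignments pass through verbatim; q = 0 gives all 0/0", {
  gts <- c("0/0", "1/1", "0/1", "0/0", "1/1")
  cfg <- simulation_config(n_samples = 5, genotypes = gts, seed = 2, coverage = 4)
  out <- simulate_cohort_reads(cfg)
  expect_identical(out$truth$genotype, gts)
  cfg0 <- simulation_config(n_samples = 12, q = 0, seed = 2, coverage = 4)
  expect_true(all(simulate_cohort_reads(cfg0)$truth$genotype == "0/0"))
})

test_that("every alignment record's coordinates are consistent with its truth fragment", {
  cfg <- simulation_config(seed = 29, coverage = 8, confounder_rate = 0,
                           junction_mode = "drop")
  for (gt in c("0/0", "0/1", "1/1")) {
    s <- simulate_sample(cfg, gt)
    tr <- s$truth
    D <- cfg$locus$deleted$start
    del_len <- interval_length(cfg$locus$deleted)
    by_q <- split(seq_len(nrow(s$records)), s$records$qname)
    for (qn in names(by_q)) {
      f <- tr[tr$qname == qn, ]
      expect_equal(nrow(f), 1)
      recs <- s$records[by_q[[qn]], ]
      expect_equal(nrow(recs), 2)
      # leftmost reported position maps from the fragment start
      exp_start <- if (f$is_del_hap && f$frag_start >= D)
        f$frag_start + del_len else f$frag_start
      expect_equal(min(recs$pos) - 1, exp_start)
      # recorded template length = physical length (+ deletion if bridging)
      bridges <- f$is_del_hap && f$frag_start < D &&
        f$frag_start + f$frag_len > D
      expect_equal(max(abs(recs$tlen)),
                   f$frag_len + if (bridges) del_len else 0)
    }
  }
})

test_that("simulated cohorts write SAM, FASTA, truth and config artifacts", {
  dir <- file.path(tempdir(), "simcohort")
  cfg <- simulation_config(n_samples = 3, seed = 4, coverage = 6)
  out <- simulate_cohort_reads(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "reference.fa")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  sams <- list.files(dir, pattern = "\\.sam$")
  expect_length(sams, 3)
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_equal(Biostrings::width(ref)[1], cfg$contig_len)
})
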