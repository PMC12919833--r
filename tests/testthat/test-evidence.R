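toy_locus <- function() {
  deletion_locus("toy", genomic_interval("c1", 1000, 1584),
                 genomic_interval("c1", 700, 1900),
                 confounders = list(genomic_interval("c1", 700, 900)),
                 reference_build = "toy")
}

obs_at <- function(span1, span2 = NULL, tlen = 350,
                   orientation = "proper_FR", mapq = 60, ...) {
  read_pair_observation("q1", mapq, tlen,
                        genomic_interval("c1", span1[1], span1[2]),
                        if (!is.null(span2)) genomic_interval("c1", span2[1], span2[2]),
                        mate_orientation = orientation, ...)
}

test_that("insert distribution estimation is robust and errors when starved", {
  set.seed(1)
  tl <- round(rnorm(5000, 350, 50))
  est <- estimate_insert_distribution(tl)
  expect_lt(abs(est$insert_median - 350), 5)
  expect_lt(abs(est$insert_sd - 50), 10)
  degenerate <- estimate_insert_distribution(rep(300, 60))
  expect_equal(degenerate$insert_median, 300)
  expect_equal(degenerate$insert_sd, 1.0)  # scale floored at 1 bp
  expect_error(estimate_insert_distribution(numeric(0)), "too few proper pairs")
})

test_that("read eligibility follows flag and mapping-quality rules", {
  base <- obs_at(c(100, 200))
  expect_true(filter_read(base))
  expect_false(filter_read(obs_at(c(100, 200), duplicate = TRUE)))
  expect_false(filter_read(obs_at(c(100, 200), secondary = TRUE)))
  expect_false(filter_read(obs_at(c(100, 200), supplementary = TRUE)))
  expect_false(filter_read(obs_at(c(100, 200), qc_fail = TRUE)))
  expect_false(filter_read(obs_at(c(100, 200), mapq = 19)))
  expect_true(filter_read(obs_at(c(100, 200), mapq = 20)))
})

test_that("pair classification implements the evidence-class definitions", {
  loc <- toy_locus()
  # large-insert pair with mates flanking the 584-bp deleted interval
  expect_equal(classify_pair(obs_at(c(850, 950), c(1780, 1880), tlen = 930),
                             loc, 350, 50), "DEL")
  # read wholly inside the deleted interval supports the reference allele
  expect_equal(classify_pair(obs_at(c(1100, 1200)), loc, 350, 50), "REF_READ")
  # normal-insert proper pair whose outer span contains the deleted interval
  expect_equal(classify_pair(obs_at(c(900, 990), c(1600, 1700), tlen = 350),
                             loc, 350, 50), "REF_PAIR")
  # inversion artifact over the confounder region beats the DEL test
  expect_equal(classify_pair(obs_at(c(750, 850), c(1780, 1880), tlen = 930,
                                    orientation = "inverted"),
                             loc, 350, 50), "CONFOUNDER")
  # generic discordance is uninformative
  expect_equal(classify_pair(obs_at(c(800, 900), c(1700, 1800), tlen = 2000),
                             loc, 350, 50), "UNINFORMATIVE")
})

test_that("classification is a total deterministic function over random observations", {
  loc <- toy_locus()
  classes <- c("DEL", "REF_READ", "REF_PAIR", "CONFOUNDER", "UNINFORMATIVE")
  set.seed(7)
  for (i in 1:200) {
    s1 <- sort(sample(600:1900, 2)); if (diff(s1) == 0) s1[2] <- s1[1] + 50
    s2 <- sort(sample(600:1900, 2)); if (diff(s2) == 0) s2[2] <- s2[1] + 50
    obs <- obs_at(s1, if (runif(1) < 0.8) s2, tlen = sample(100:1500, 1),
                  orientation = sample(c("proper_FR", "inverted",
                                         "unmapped", "distant"), 1))
    c1 <- classify_pair(obs, loc, 350, 50)
    expect_true(c1 %in% classes)
    expect_identical(classify_pair(obs, loc, 350, 50), c1)
  }
})

test_that("extraction separates homozygous genotypes as the evidence model predicts", {
  cfg <- simulation_config(seed = 7)
  ev00 <- extract_evidence(simulate_sample(cfg, "0/0"), cfg$locus)
  expect_identical(ev00$n_del_support, 0L)
  expect_gt(ev00$n_ref_read, 0L)
  ev11 <- extract_evidence(simulate_sample(cfg, "1/1"), cfg$locus)
  expect_identical(ev11$n_ref_read, 0L)
  expect_gt(ev11$n_del_support, 0L)
  expect_gt(ev11$n_confounder, 0L)
  expect_identical(ev11$n_total, ev11$n_del_support + ev11$n_ref_read +
                     ev11$n_ref_pair + ev11$n_confounder)
})

test_that("extraction is deterministic and an empty window yields zero counts", {
  cfg <- simulation_config(seed = 9)
  s <- simulate_sample(cfg, "0/1")
  e1 <- extract_evidence(s, cfg$locus)
  e2 <- extract_evidence(s, cfg$locus)
  expect_identical(as.data.frame(e1), as.data.frame(e2))

  empty <- s$records[0, ]
  ev <- extract_evidence(empty, cfg$locus)
  expect_identical(ev$n_total, 0L)
  expect_identical(ev$n_del_support, 0L)
})

test_that("deletion-support count matches a truth-table recount (junction reads dropped)", {
  cfg <- simulation_config(seed = 21, junction_mode = "drop")
  for (gt in c("0/1", "1/1")) {
    s <- simulate_sample(cfg, gt, seed = cfg$seed + match(gt, c("0/1", "1/1")))
    est <- estimate_insert_distribution(s$records,
                                        default_sampling_regions(cfg$locus))
    ev <- extract_evidence(s, cfg$locus, insert_stats = est)
    oracle <- recount_from_truth(s, est$insert_median, est$insert_sd)
    expect_identical(ev$n_del_support, oracle$n_del_support)
    expect_identical(ev$n_ref_read, oracle$n_ref_read)
  }
})

test_that("doubling coverage does not decrease any evidence class on average", {
  tot <- function(cov) {
    cnt <- c(0, 0, 0, 0)
    for (sd in 1:3) {
      cfg <- simulation_config(coverage = cov, seed = 100 + sd)
      ev <- extract_evidence(simulate_sample(cfg, "0/1"), cfg$locus)
      cnt <- cnt + c(ev$n_del_support, ev$n_ref_read, ev$n_ref_pair,
                     ev$n_confounder)
    }
    cnt
  }
  lo <- tot(30); hi <- tot(60)
  expect_true(all(hi[c(1, 2, 4)] >= lo[c(1, 2, 4)]))
})

test_that("BAM region access without an index raises an explicit error", {
  cfg <- simulation_config(seed = 3)
  s <- simulate_sample(cfg, "0/0")
  sam <- file.path(tempdir(), "noindex.sam")
  write_sam(s, sam)
  bam <- sam_to_bam(sam)
  file.remove(paste0(bam, ".bai"))
  expect_error(extract_evidence(bam, cfg$locus), "index")
})
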