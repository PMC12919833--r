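---
title: "Genotyping the CTRB2 exon 6 deletion: evidence model, calibration and cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping the CTRB2 exon 6 deletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrb2del)
```

## The problem

A 584-bp germline deletion overlapping exon 6 of *CTRB2* (chymotrypsinogen
B2, chr16q23.1) truncates the protein, triggers endoplasmic-reticulum
stress in pancreatic acinar cells, and is a risk allele for pancreatic
ductal adenocarcinoma. Standard small-variant callers do not genotype it:
the informative signal is structural — read *pairs* whose template length
is stretched by the missing 584 bp — and the adjacent *CTRB1* paralog
carries a germline inversion that makes some pairs masquerade as a large
insertion. This package implements a targeted genotyper for exactly this
situation (one known deletion, paired-end alignments over a small window)
plus the downstream layers a cohort study needs: genotype QC, endpoint
construction, Kaplan-Meier and Cox analyses, and simulators for both reads
and cohorts so the whole chain is verifiable without patient data.

## Evidence model

All coordinates are 0-based half-open internally (BED/BAM native);
human-readable output echoes 1-based inclusive positions. The locus object
carries three intervals: the deleted sequence, an evidence window
containing it (default chr16:75,204,400–75,205,700, 1300 bp), and
confounder regions for the paralog inversion. The published description
fixes the window and the deletion length but not the breakpoints, so the
bundled deleted interval is centered in the window and documented as
approximate — breakpoints are configuration, not algorithm.

For a fragment of physical length $F$ bridging the deleted interval on a
deletion haplotype, the mapped template length is $F + L$ with $L = 584$.
We therefore estimate the insert distribution robustly (median and
$1.4826 \times$ MAD, floored at 1 bp) from *flanking* regions (default
2 kb each side of the window) — never from the window itself, where
bridging pairs contaminate the estimate — and accept a pair as
deletion-supporting (DEL) when

$$|\mathrm{TLEN}| - \tilde{m} \in [\,L - k\sigma,\; L + k\sigma\,],\qquad k = 3,$$

*and* its mates align wholly on opposite sides of the deleted interval.
Tying the anomaly to the specific event rejects generic discordance.
Reference support comes from reads with at least 20 aligned bases inside
the deleted interval (REF_READ, counted per read) and from normal-insert
proper pairs whose outer span contains it (REF_PAIR). Inverted-orientation
pairs over a confounder region are tallied as CONFOUNDER — coverage, not
allele evidence — and this test precedes the DEL test, because inversion
artifacts can satisfy the template-length band. Reads that cross a
breakpoint appear soft-clipped in real alignments; soft-clip support is
*not* counted as deletion evidence (the method is insert-size based) but
is reported in a diagnostic field. Eligibility follows standard practice:
no duplicates, secondary, supplementary or QC-fail records, MAPQ ≥ 20;
all configurable via `classify_params()`.

## Genotype rule and calibration

With $d$ DEL pairs and $r$ reference units, the deletion fraction
$f = d/(d+r)$ (confounders excluded from both numerator and denominator)
is compared to two cutoffs: call `1/1` when $f \ge t_{\mathrm{hom}}$,
`0/0` when $f < t_{\mathrm{het}}$, otherwise `0/1`; below `min_depth`
informative units the sample is a no-call (`./.`) — absence of evidence at
low depth is not evidence of absence. The strict count rule ("only
deletion-supporting reads → 1/1; no deletion-supporting reads → 0/0;
otherwise 0/1") is the exact limit $t_{\mathrm{het}} \to 0^+$,
$t_{\mathrm{hom}} = 1$, `min_depth = 1`, available as
`strict_thresholds()`.

An important geometric fact: a heterozygote's expected $f$ is far below
one half. At 30× with 100-bp reads and 350 ± 50 bp fragments, one deletion
haplotype yields roughly a dozen countable bridging pairs (both mates must
clear the breakpoints and the template length must fall in the band),
while one reference haplotype yields ~100 reads overlapping a 584-bp
interval by ≥ 20 bp. So $f \approx 0.1$ for heterozygotes, $0$ for
non-carriers, and $1$ for homozygotes (whose junction reads are
soft-clipped, not counted as reference). The packaged defaults
(`t_het = 0.1`, `t_hom = 0.9`, `min_depth = 8`) are deliberately generic;
the supported workflow calibrates cutoffs against a labelled panel with
`calibrate_thresholds()`, mirroring how the cutoffs were chosen in the
original application (a PCR-typed panel of 605 samples with 9 homozygous
and 106 heterozygous carriers; the published text never prints the
calibrated values). Calibration is an exhaustive grid search maximizing
concordance, with deterministic tie-breaking (largest
$t_{\mathrm{hom}} - t_{\mathrm{het}}$ margin, then smallest `min_depth`,
then smallest $t_{\mathrm{het}}$, then smallest $t_{\mathrm{hom}}$); on
the simulated panel it lands near $t_{\mathrm{het}} = 0.02$,
$t_{\mathrm{hom}} = 0.98$. Calls export as TSV and as a VCF 4.2 symbolic
`<DEL>` record (INFO `END`/`SVLEN`/`SVTYPE`, per-sample `GT:DP`).

## The read simulator

`simulate_sample()` emits aligned records directly (no FASTQ/aligner round
trip — the genotyper consumes alignments, and this removes any external
download or tool): uniform fragment starts per haplotype at coverage/2
each over a 5200-bp synthetic contig, normal fragment lengths truncated at
twice the read length, FR pairs, MAPQ 60, sequences copied from a
fixed-seed synthetic reference so SAM output is valid and convertible to
indexed BAM. On deletion haplotypes the deleted interval is excised from
the coordinate map, so bridging fragments acquire TLEN = $F + L$ by
construction; junction-crossing reads are soft-clipped at the breakpoint
(`junction_mode = "clip"`, default) or the whole pair is omitted
(`"drop"` — a pair with a junction-crossing read can never satisfy the
mates-flanking DEL condition, so dropping the pair leaves the
deletion-support count untouched while keeping the record set a valid
paired SAM). A configurable fraction of pairs (default 2%) is emitted in
same-strand orientation over the confounder region to mimic the inversion
artifact. Every fragment is logged in a truth table (haplotype, start,
length, junction crossings), which the tests replay with an independent
brute-force recount to verify the extractor.

What the simulator does *not* model — base-call errors, GC and capture
bias, multi-mapping, indels near the breakpoints, real *CTRB1* homology —
bounds what passing tests can claim: they validate the counting and
decision logic under the stated evidence geometry, not robustness to
every artifact of real exome data. Genotype draws for simulated cohorts
use Hardy-Weinberg proportions at deletion-allele frequency
`q = 0.111`, the combined-cohort frequency implied by the published
genotype counts $(110 + 2\cdot 9 + 733 + 2\cdot 72)/(2 \cdot (633+3896))$.

## Genotype QC

`variant_qc()` applies the conventional thresholds with the inequalities
exactly as printed: fail when call rate < 0.95, MAF < 0.05 (computed over
called genotypes only), or Hardy-Weinberg exact p < 1e-6; `sample_qc()`
fails samples with > 5% missing genotypes (strict inequality). The HWE
test is the exact conditional test — the sum of probabilities of all
heterozygote counts (same allele totals and parity) no more likely than
the observed one — implemented from log-factorials, which stays valid at
the rare-homozygote counts seen at this locus where the chi-square
approximation does not; `hwe_chisq_test()` is provided for large counts.
These filters are generic over variants: in the original setting they are
applied to the SNP backbone, and here they are equally applicable to the
deletion calls themselves.

## Endpoints and survival analysis

OS runs from diagnosis to death, censoring at the last date known alive
or an administrative cutoff (a December 2023 analog), whichever is first.
TTP runs from first treatment to documented progression, with competing
risks handled by censoring, as in the source design: death, surgery for
non-progressive disease, or a chemotherapy change for non-progression
reasons censor at their date, and a progression recorded after a
competing event does not count as an event. Censoring at competing
events — rather than a cumulative-incidence estimator — is a faithful
reproduction of the analysed design and a known methodological caveat,
not something this package "fixes". Months are days/30.4375; published
medians in multiples of 1.2 months suggest 0.1-year rounding upstream, so
exact numeric parity with such tables is not expected.

Kaplan-Meier curves come from `survival::survfit` with log-log
(Brookmeyer-Crowley style) median CIs (no method is named in the source;
this is the common default). Cox models use `survival::coxph` with Efron
tie handling by default — less biased under ties — and a Breslow switch
for comparability with SAS's TIES default. Monotone likelihood (complete
separation) is flagged and no estimates are reported. The covariate set
follows the source analyses: carrier status (dominant coding; a
three-level het/hom coding is also provided), age (continuous), sex,
tumor stage (two indicators vs localized) and type II diabetes, with a
cohort indicator added when two cohorts are combined; subjects with
unknown stage or diabetes, or missing genotype, are excluded per model and
logged. Whether the original models entered age continuously and stage as
two indicators is unstated; these defaults are this package's choice.

## The cohort simulator

`simulate_cohort()` draws HWE genotypes, covariates matching the combined
descriptive table (56% female, age ~N(66, 10) clipped to 20–92, stage mix
29/37/33% with 1% unknown, 34% diabetes with 14% unknown), and
exponential event times with stage-specific baseline medians (24, 16.8,
10.8 months — the combined-cohort medians by stage) scaled by
$\exp(\beta \cdot \mathrm{carrier})$; loss to follow-up is exponential
(median 120 months) and diagnosis dates are anchored on a fixed synthetic
2009–2020 accrual epoch with a 2023-12-31 cutoff. All times are
materialized as whole days *before* any date is written, so
`compute_os()`/`compute_ttp()` recover the generated (time, event) pairs
bit-exactly — the round trip is a test invariant, not an approximation.
The default carrier effect is null ($\beta = 0$); effect sizes are
injected explicitly in tests (e.g. true HR 2.0 recovery).

## Numerical choices and problem sizes

Degenerate inputs: the insert-scale estimate is floored at 1 bp so a
degenerate library does not zero the acceptance band; estimation requires
≥ 50 proper pairs (configurable) and fails with advice otherwise; an empty
window returns all-zero counts rather than an error; a monomorphic
variant has HWE p = 1 by construction. Pair deduplication is by read name
with first-seen primary mates, preventing double counting in a single
streaming pass. All simulation randomness flows from one seeded RNG;
the synthetic reference sequence uses its own fixed seed so the "genome"
is stable across runs.

The shipped test suite exercises: exhaustive genotype-rule equivalence to
depth 50; HWE enumeration equivalence for all count triples with N ≤ 30;
a 200-sample 30× simulate→SAM→BAM→extract→call round trip (≥ 99%
concordance against truth); calibration vs brute-force grid equality on a
605-sample panel shaped like the PCR calibration panel; Cox grid-search
oracles on ≤ 8-subject data, a 200-replicate null-calibration check and
HR-recovery at n = 2000–5000. These sizes were chosen to make Monte Carlo
error small relative to the tolerances while keeping a full run in the
low minutes on a single core.

## Known limitations

Real-cohort hazard ratios and medians cannot be reproduced here — the
patient-level data are not redistributable — so the survival layer is
validated by oracle equivalence and parameter recovery instead. The
genotyper assumes a single biallelic deletion per locus (no multi-allelic
or multi-locus definitions, no liftover), consumes alignments only (no
split-read assembly or genome-wide discordant-pair scanning), and the
calibrated cutoffs of the original program are not recoverable from the
published text; recalibration on any labelled panel is the supported
substitute. Relatedness, heterozygosity and contamination QC require
genome-wide data this artifact does not model and are out of scope.
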