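---
title: "Gene essentiality from mariner Tn-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene essentiality from mariner Tn-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnseqr)
```

## The experiment the package models

In a Tn-seq screen, a pooled library of transposon insertion mutants is
grown under a selective condition; mutants carrying an insertion in a gene
required for growth drop out of the pool. Sequencing the transposon–genome
junctions before and after selection therefore reads out per-gene fitness.
`tnseqr` implements this analysis for mariner (Himar1) transposons, which
insert exclusively at TA dinucleotides, with junction fragments liberated by
MmeI — a type IIS enzyme that cuts about 20 bp away from its recognition
site inside the transposon's terminal inverted repeat (IR), releasing a
short fixed-length genomic tag next to each insertion.

The pipeline stages are:

1. **Candidate sites** — every forward-strand TA position is a potential
   insertion site; TA is its own reverse complement, so one position covers
   both strands (`enumerate_ta_sites()`).
2. **Junction-read extraction** — raw forward reads have the layout
   `[revcomp(IR/MmeI junction)][4 bp IR remnant][genomic insert starting
   TA][sequencing adapter][...]`; `process_fastq()` recovers the 14–18 bp
   insert (`extract_insert()` is the single-read reference implementation).
3. **Exact unique mapping** — inserts are placed only where they match the
   genome with 100% identity at a single location (`map_inserts()`).
4. **Per-gene tabulation** — reads at unique TA sites within the first 95%
   of each gene are summed, and normalized to reads per kilobase per 10^7
   uniquely mapped reads (`tabulate_genes()`).
5. **Classification** — per replicate, an outlier-trimmed normal fit of
   log2(normalized RpK) across genes defines z-score categories; replicate
   unanimity gives the consensus (`classify_replicates()`).
6. **Cross-condition sets** — core essential genome, condition-specific
   essential genes, and UpSet-style membership patterns
   (`core_essential()`, `condition_specific()`, `membership_matrix()`).

## The classification model

For one replicate, let $r_g$ be the reads summed over unique TA sites in
the first 95% of gene $g$, $L_g$ the annotated gene length in bp, and $T$
the library total of uniquely mapped reads. Then

$$\mathrm{RpK}_g = \frac{r_g}{L_g/1000}, \qquad
  \mathrm{nRpK}_g = \mathrm{RpK}_g \cdot \frac{10^7}{T}, \qquad
  y_g = \log_2 \mathrm{nRpK}_g .$$

The $y_g$ of all scoreable genes with $r_g > 0$ form an approximately
normal distribution whose left tail is the signal: genes depleted of
insertions. After one-pass Tukey trimming (fences at $Q_1 - 3\,\mathrm{IQR}$
and $Q_3 + 3\,\mathrm{IQR}$, quartiles by linear interpolation), the sample
mean $\hat\mu$ and sample SD $\hat\sigma$ (with $n-1$ denominator)
parameterize the fit, and $z_g = (y_g - \hat\mu)/\hat\sigma$ is thresholded:

| category        | rule                          |
|-----------------|-------------------------------|
| Essential       | $z < -3$, or $r_g = 0$        |
| GrowthDefect    | $-3 \le z < -2$               |
| NonEssential    | $-2 \le z \le 2$              |
| GrowthAdvantage | $z > 2$                       |

The Essential region sits strictly below the interval covering 99.7% of a
normal distribution; "less than 3 SD below the mean" is read strictly, so
$z = -3$ exactly is GrowthDefect. Genes with no recovered insertions are
Essential categorically — insertion may simply be lethal — and are excluded
from the fit because $\log_2 0$ is undefined. A gene's consensus over
replicates is the unanimous category, or `Uncertain` on any disagreement;
genes the TA-site filters exclude are `Excluded`. No multiple-testing
correction is applied: the categories are descriptive bands of a fitted
distribution, not hypothesis tests.

### Parameters that matter

* `classifier_config()`: thresholds $-3/-2/+2$ SD (the field's convention
  for this design); `tukey_k = 3` — the conventional "far out" fence.
  Trimming exists to keep gross outliers from inflating $\hat\sigma$; at
  $k = 3$ it removes clearly separated mass (e.g. strongly depleted genes)
  while barely touching the central distribution. With $k = 1.5$ the fit
  would shave genuine tails and shrink $\hat\sigma$, silently widening all
  categories' reach; we therefore default to 3 and record the value in the
  run provenance.
* `processing_config()`: `max_mismatches = 2` for both anchor matches
  (Hamming, no indels — matching is over the full anchor length);
  `ir_remnant_len = 4` (the IR bases left between the MmeI site and genomic
  DNA after end repair removes the 2-base 5' overhang); insert length gate
  14–18 bp; sliding-window quality truncation with window 1 and threshold
  Q20, with the 14 bp minimum re-applied after truncation. The default
  `junction_seq` is a 23 bp Himar1-style IR segment ending in the MmeI
  recognition site (TCCGAC). The anchor must be long: with 2 mismatches
  allowed, a 6 bp anchor matches random sequence at ~4% per offset and
  destroys roughly half of all reads by truncating inside the insert,
  whereas a 23 bp anchor has a negligible false-match rate. Real libraries
  should set `adapter_seq`/`junction_seq` from their primer design.

### Filtering rules and coordinate conventions

Coordinates are 0-based half-open internally (GFF3's 1-based inclusive is
converted at the boundary), and a TA site is the 0-based index of its T.
This makes the "first 95%" rule exact: a site at strand-aware offset $o$
($o = p - \mathrm{start}$ on `+`, $o = (\mathrm{end} - 2) - p$ on `-`)
is counted when $o < \lfloor 0.95 L_g \rfloor$ — floor plus a strict
comparison is the conservative reading of "insertions in the last 5% are
omitted" (such insertions often fail to disrupt function). Genes are
excluded, with precedence, when they have no TA sites at all
(`no_ta`), none outside the last 5% (`no_ta_first95`), or strictly fewer
than half of their TA sites unique (`under_half_unique`; exactly half
passes). A site inside overlapping genes credits every gene containing it,
as no disambiguation rule is defensible without strand-resolved evidence.

Because 14 bp is short, some TA sites sit in repeated sequence context. A
site is `duplicated` when its forward k-mer (14-mer starting at the T) or
reverse k-mer (reverse complement of the 14 bases ending at the A) recurs
as the forward or reverse k-mer of any other site. Both orientations are
compared by default since junction fragments are recovered from either
transposon side; `both_orientations = FALSE` restricts the comparison to
forward k-mers for single-side designs. K-mers wrap around the origin of
circular replicons; on linear replicons a k-mer that does not fit is
undefined and the site is conservatively treated as duplicated for that
orientation. Reads at duplicated sites map as multi-hits and are discarded
(never rescued by random assignment), and duplicated sites never contribute
to gene counts.

### Mapping by exact lookup

Accepted inserts begin with TA, so every exact genomic occurrence of an
insert is anchored at a TA site: forward occurrences start at a site's T,
and reverse occurrences end at a site's A. Mapping therefore reduces to a
keyed lookup over per-site context k-mers for each supported insert length
(14–18), rather than seed-and-extend alignment — appropriate because the
analysis discards anything but perfect unique hits anyway. An insert with
exactly one occurrence across both strands maps to its site (reverse-strand
hits report the same TA position, collapsing both recovery orientations of
one insertion event); several occurrences are `multi`; none, `unmapped`.
A query hitting both strands of one palindromic locus counts as two
occurrences and is `multi`.

## What the synthetic data emulate

`sim_config()` defaults describe a realistic study system: a ~4.2 Mb
circular chromosome plus a 130 kb plasmid at 64% GC, 4,000 non-overlapping
genes of 300–1,500 bp (every gene guaranteed at least 5 TA dinucleotides),
a mutant library covering 50% of TA sites, and three replicates of 2
million reads. Fitness classes are drawn per gene at 13% essential / 3%
growth defect / 82% neutral / 2% growth advantage. Selection acts on mutant
abundances before sequencing: each mutagenized site gets an Exponential(1)
pre-selection abundance; sites in the first 95% of essential genes drop to
zero, growth-defect sites are multiplied by 0.05, growth-advantage sites by
4; intergenic and last-5% sites are untouched. Replicates are independent
multinomial draws over the post-selection abundances — the simplest noise
model consistent with a well-mixed outgrowth — and reads wrap each insert
in the documented junction/IR/adapter layout at uniform Q30. Insert lengths
are drawn from a distribution over 14–18 bp with mean 14.5 bp, matching the
MmeI geometry. Everything is a pure function of `(config, seed)`:
regenerated files are byte-identical.

What the generator does **not** emulate: realistic base-call error
profiles, PCR duplicates, positional insertion bias, bottleneck
genealogies across outgrowths, or rRNA/tRNA features. Passing recovery
tests on these data therefore demonstrates the correctness of the
bookkeeping and the statistical machinery under the stated model, not
robustness to every artifact of real libraries.

### What recovery on simulated data can and cannot reach

On an i.i.d. GC-64% genome, about 8% of TA sites have non-unique 14-mer
context — repeated context is an intrinsic property of short MmeI tags,
not only of biological repeats. Truth-essential genes are recovered
essentially perfectly (zero surviving insertions force the Essential
call). For truth-neutral genes there is a structural ceiling: the
NonEssential band $|z| \le 2$ holds only $2\Phi(2) - 1 \approx 95.45\%$ of
a normal population *by construction*, and requiring unanimity across
three independently fitted replicates converts a further ~2–3% of
borderline genes into `Uncertain`, so neutral consensus recovery settles
around 94–95% at the default read depth. This is a property of the
banded-z-plus-unanimity design itself; deeper sequencing narrows the
replicate noise but cannot move the 95.45% band mass.

## Numerical and degenerate-input choices

* Quartiles use `stats::quantile` type 7 (linear interpolation). A zero
  IQR collapses the fences to the quartiles, so an all-identical sample
  loses nothing; a zero-variance fit is an error, as no z-score exists.
* Outlier trimming needs at least 4 finite values, a normal fit at least 2.
* `find_approx` ties are impossible by construction: the leftmost
  qualifying offset wins.
* Reads with no adapter match keep their full length (Trimmomatic
  semantics); the junction match is the mandatory anchor — a read without
  it cannot contain a junction fragment and is rejected.
* The TA/length gate is applied before quality truncation, and the
  minimum-length check re-applied after it; an insert shortened below
  14 bp by quality truncation is a `quality_fail`, not a length failure.
* Empty FASTQ input yields empty output with zeroed counters; every input
  read is accounted for by exactly one acceptance or rejection counter.

## Problem sizes used by the test-suite

The brute-force oracle comparisons (TA enumeration, duplicate flags,
mapping occurrence counts, per-gene tabulation, set algebra) run on ≤50 kb
genomes where quadratic scans are exact and fast. Full end-to-end FASTQ
round trips run at 4–30 thousand reads; the classifier recovery experiment
runs at the full default scale (4.33 Mb, 4,000 genes, 3 × 2,000,000 reads)
through the ledger-level bridge `library_insertion_tables()`, which is
exactly equivalent to read encoding plus decoding for error-free reads and
keeps the experiment inside a few seconds.

## Known limitations

* The insert extractor is Hamming-only; indel sequencing errors in the
  anchors lose the read (rejected, never silently misplaced).
* Gene length in the RpK denominator is the full annotated length, not 95%
  of it; the toggle is deliberate and testable but not exposed as a
  config knob.
* The classifier assumes enough scoreable genes for a stable fit
  (thousands); it is not meant for small plasmids analyzed in isolation.
* `Uncertain` absorbs genuine replicate disagreement and borderline noise
  alike; downstream set algebra treats it as "not essential" in that
  condition, which is conservative for core-genome claims.
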