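---
title: "Models and methods in bsmethy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bsmethy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model and the algorithmic choices
behind each stage of the pipeline: what is computed, under which
assumptions, which parameters matter, and where the design was genuinely
open and a decision had to be made.

## Bisulfite alignment

### Model

A directional MethylC-seq library sequences the two bisulfite-converted
strands of the genome. Unmethylated cytosines read as T, so a read differs
from the reference at every converted position. The standard
methylation-unbiased solution is adopted: both the reads and the reference
are collapsed to a three-letter alphabet before matching.

* Two converted references are built: the Watson strand with every C
  replaced by T, and the Crick strand (reverse complement of Watson)
  likewise converted. Neither contains a C.
* Read 1 is C→T converted directly. Read 2 is the base complement of the
  bisulfite strand: its methylation signal lives in G/A, not C/T, so it is
  reverse-complemented **first** and then C→T converted. After this
  transformation both mates of a fragment match the *same* converted
  reference forward, which is what the implementation searches.
* Matching is substitutions-only (no indels), at most `max_mismatches`
  (default 2) counted on the converted read against the converted
  reference. This mirrors the 2-mismatch short-read alignment mode the
  design descends from; reads needing gapped alignment are simply lost to
  the unmapped fraction.

### Candidate generation

The alignment contract is exhaustive: *every* placement within the
mismatch budget on either converted strand is found. Candidates come from
a k-mer seed table (seed length 20 by default) with pigeonhole seeding:
`max_mismatches + 1` disjoint seeds are taken from the read, so at least
one seed is untouched by any admissible set of substitutions, and each
seed hit is verified by capped Hamming comparison. Reads too short to host
the full seed set (under 60 bases at the defaults) are scanned
exhaustively against every offset instead, so the contract holds for them
too; reads shorter than one seed (20 bases) after trimming are discarded
and counted. The test suite checks the whole pipeline — hit sets,
uniqueness decisions, coordinates, duplicates — against a naive
all-offsets Hamming-scan oracle on random genomes, for both single- and
paired-end input. `N` never matches anything, including another `N`.

### Filters

* **Trimming** (before alignment): the 3' adapter is removed where the
  longest read suffix matches an adapter prefix (minimum overlap 3, at
  most one mismatch per 10 overlap bases), then 3' bases below Phred 5 are
  stripped. 5' trimming exists behind a flag but is off by default —
  adapters and quality decay are 3' phenomena on this platform.
* **Uniqueness** is best-stratum: a read is kept iff exactly one placement
  exists at its minimum attained mismatch count. For pairs the unit is the
  candidate pair (same chromosome, same strand of origin, inward facing,
  outer insert within 50–600 by default), unique at minimum total
  mismatches. Per-pair rather than per-mate uniqueness was an open point;
  per-pair is chosen because the insert constraint is part of what makes a
  placement unique.
* **Both-strand ambiguity**: any read/pair whose best stratum spans both
  converted strands is discarded — its strand of origin, and therefore its
  methylation reading, is undecidable.
* **Duplicates** are removed last (filter first, deduplicate last, the
  other open ordering point): fragments sharing (chromosome, leftmost
  start, strand of origin, insert size — read length for single-end
  reads) collapse to the fragment with the greatest base-quality sum,
  ties broken by smallest read id, making the output deterministic.

A methylation-neutrality property follows from the construction: with
fragments held fixed, the set of mapped positions is identical whatever
the methylation level, because conversion differences vanish under the
three-letter collapse. The suite asserts exact set equality across 5%,
50% and 100% CpG methylation.

## Methylation calling and methylation density

Every retained record contributes, at each reference cytosine it covers
*on its own strand of origin*, a C (methylated) or T (unmethylated)
observation; any other read base there — sequencing error or variant — is
ignored rather than forced into either state, because the density is
defined on C and T counts only. When the two mates of a short fragment
overlap a cytosine, the observation counts once, taking the mate with the
higher base quality (ties go to mate 1).

The methylation density of a set of cytosines is the pooled fraction

$$\mathrm{MD} = 100 \cdot \frac{\sum_i C_i}{\sum_i (C_i + T_i)}$$

reported as a percentage; with one site this is single-base resolution.
Zero total depth yields a missing value, never zero — an uncovered region
is unknown, not unmethylated. Sites appear in output from depth ≥ 1; a
`min_depth` argument gates reporting, with 5 and 10 used downstream (DMR
validity, array comparison).

Contexts are the cytosine plus the next two bases 5'→3' on its own strand
(`CG.` → CpG, `C.G` → CHG, else CHH); positions within two bases of a
chromosome end pad with N and fall to CHH unless the CG dinucleotide is
complete. Crick-strand cytosines are reported at the Watson coordinate of
their G so both strands share one axis; calls are emitted per strand
(separate Watson and Crick call files), and strand-merging per CpG
dinucleotide is an explicit option of downstream consumers, not a default.

The bisulfite conversion rate is estimated from an unmethylated spike-in
chromosome (classically lambda phage) as 100·ΣT/(ΣC+ΣT) over all its
cytosines; absent a spike the statistic is missing and nothing else
changes.

## DMR detection

Two samples, no replicates. Per chromosome:

1. **Seeds.** A 500-bp window slides in 100-bp steps from position 1. A
   window is a seed when it holds ≥ `m` = 5 valid CpGs — positions (same
   position, same strand) covered by ≥ `n` = 5 reads in *both* samples.
   The same-positions reading of the validity rule was an open point and
   is the stricter choice; it guarantees the rank test below always
   compares paired site sets of equal length.
2. **Seed test.** The two per-CpG MD vectors are compared with a
   Mann-Whitney U test; p < 0.01 (two-sided) marks a differentially
   methylated seed, with direction the sign of the pooled MD difference.
3. **Extension.** While the current region is ≤ `k` = 1000 bases long, the
   adjacent downstream 500-bp window is tested the same way (window-alone,
   not cumulative — the other open reading); qualifying windows of the
   same direction are merged, so a pre-merge region reaches at most
   `k + w` = 1500 bases. The worst constituent window p is retained.
   After a region is finalized scanning resumes one slide increment after
   its end.
4. **Merging and region test.** Adjacent regions ≤ 1000 bases apart with
   the same direction and pooled MDs within 10 percentage points per
   sample are united (left to right, transitively; valid CpGs in the
   bridged gap join the pooled counts). Each final region's pooled counts
   form a 2×2 table tested by χ² (1 df, no continuity correction — guard:
   a zero marginal gives p = 1); regions with p ≤ 0.01 are emitted as
   DMRs, labelled hyper when sample 2 exceeds sample 1.

Regions whose Mann-Whitney p exceeds 0.25 can instead be classified as
methylation-unchanged, the basis of the unchanged-region arm of
array-based evaluation.

Region boundaries are window boundaries: a DMR's end can overshoot the
last covered base (or even the chromosome end, which the caller does not
know from call tables) by up to one window. Reported counts and MDs always
come from the valid CpGs inside the interval.

### The Mann-Whitney p-value

U is computed from midranks. For combined sample sizes up to 20 the
p-value is exact: from the Wilcoxon distribution when no value is tied,
and by full enumeration of the `choose(n1+n2, n1)` assignments of the
midranks to groups when ties exist (the two agree in the tie-free case;
the enumeration yields e.g. p = 2/252 for five 0s against five 100s).
Beyond 20 observations a normal approximation with tie correction and
continuity correction is used. Exact inference under ties matters here
because window MDs at depth ~5–10 are heavily tied by construction; a
tie-corrected normal approximation at n = 5 + 5 cannot even reach
p < 0.01 and would silently disable the seed test at the default `m`.

### Known limitations

At the fixed default thresholds the caller has a small but real
false-positive rate on null data: a chance rank separation (MW p ≈ 0.002–
0.008) of binomial noise at depth 10 frequently also passes the pooled χ²
test, giving on the order of one spurious 500-bp call per thousand
background windows. This is intrinsic to fixed per-region p thresholds
(no multiple-testing control across windows, a deliberate non-goal) and
should be kept in mind when scanning large genomes at low depth. The
simulation studies in the test suite quantify it: planted-block
sensitivity is 1.00 over 100 replicates, while the matched-depth
background of the same replicates (≈ 3,100 null windows) yields a handful
of false calls rather than zero.

## Profiling, array concordance and gold-standard evaluation

* Fixed windows (default 100 kb) tile each chromosome from position 1;
  pooled MD is reported per window and strand. Pooling all windows equals
  the genome-wide MD (a conservation property in the tests).
* The 16-trinucleotide spectrum reports pooled MD per context plus, per
  context class, the fractional methylated C: the share of all sequenced
  methylated cytosines carried by that class.
* Array concordance pools Watson and Crick CpG counts per dinucleotide
  (keyed by the Watson C), keeps loci with ≥ 10 pooled reads, rescales MD
  to a fraction, and reports the Pearson correlation with array beta
  values. Beta values are consumed as given — the array's internal beta
  computation is out of scope.
* Gold-standard regions are 500-bp windows of mean beta per sample:
  between-sample differences > 0.25 define hyper/hypomethylated windows,
  ≤ 0.03 unchanged windows, anything between is unassigned (the 25%/3%
  thresholds are applied on the beta fraction scale). Detection
  proportions use ≥ 1 bp overlap with a concordant-direction call;
  tissue-scale accuracy figures require real paired array/WGBS data, so
  the package ships the procedure plus a synthetic concordance property
  (r ≥ 0.95 at depth ≥ 10 with moderate beta noise).
* DMR-to-gene annotation assigns the closest transcription start site
  (gene start for `+`, end for `-`), ties broken by name, and flags DMRs
  overlapping the 2-kb window upstream of that TSS as promoter hits.

## The simulator and what passing tests do (and do not) show

The simulator generates: an i.i.d. random genome at a configurable GC
fraction; a truth methylome assigning each cytosine of both strands the
level of its context class; and paired reads with uniform fragment start,
uniform outer insert, fair-coin strand of origin, per-molecule bisulfite
conversion (a cytosine is methylated with its site level; unmethylated
cytosines convert with probability `conversion_rate`, shared by
overlapping mates of one fragment), and i.i.d. substitution errors applied
per sequenced base after conversion. Qualities are constant Q40 with an
optional linear decay for QC-plot realism.

Defaults are the validation conditions of the alignment study: a 48,500-bp
genome (a *synthetic* stand-in for the lambda genome, so no download is
needed; lambda's length and approximate GC are matched, its sequence is
not), 50,000 pairs of 75-bp reads, inserts 75–600 bp, CpG methylation
100%, CHG/CHH 0%, conversion 100%, error 0.001. Where the study left a
value unstated (GC fraction, CHG/CHH levels, error model) the choice is a
plain one — 50% GC, unmethylated non-CpG cytosines as in the lambda
spike-in convention, uniform substitution errors — made once and not
revisited.

What the simulator deliberately does not model: positional coverage bias,
quality-dependent and indel errors, PCR duplication (duplicates arise only
by positional coincidence), M-bias along the read, CpG islands or any
spatial methylation autocorrelation, and SNVs. Passing the recovery tests
therefore demonstrates correctness of the pipeline's logic under its own
model assumptions — not robustness to the full error structure of real
libraries, where trimming choices, conversion efficiency and mapping bias
all matter more.

### Planted-DMR study design

The DMR recovery study uses 100 replicates of a two-sample call-table
methylome: one 4-kb chromosome, a CpG site every 80 bp (six to seven per
500-bp window), binomial counts at depth exactly 10, sample A at 80%
methylation everywhere, sample B at 80% outside and 20% inside a planted
1-kb block — a 60-point difference of the kind placenta-versus-blood
comparisons produce. 4 kb gives each replicate a 3-kb matched-depth null
background (roughly 31 windows) around the block, large enough to expose
false positives without swamping the runtime; the block sits away from
both chromosome ends so edge windows are mixtures, as in real data.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive in every file and table; BED input
  (0-based half-open) is converted on read. Quality encoding is fixed to
  Phred+33, no autodetection.
* MD, conversion rate, per-window MD, class fractions: zero denominators
  give missing values, never zero.
* χ² with any zero marginal returns statistic 0, p = 1 (the proportions
  are not comparable); all χ² arithmetic is done in doubles because pooled
  genome-scale counts overflow 32-bit integers.
* The Mann-Whitney variance under the normal branch uses the tie-corrected
  form; a zero variance (all values identical) returns p = 1.
* Deterministic output everywhere: files sort by (chromosome, start,
  read id); duplicate retention ties break on read id; equidistant-gene
  ties break on gene name.
* Problem sizes in the shipped tests (50,000-pair alignment runs, 100
  2-kb oracle genomes, 100 DMR replicates, 20,000-pair low-level recovery)
  were chosen so the whole suite completes in a few minutes on one core
  while keeping every binomial tolerance comfortably non-vacuous.
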