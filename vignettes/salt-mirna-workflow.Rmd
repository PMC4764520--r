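---
title: "Identifying salt-responsive miRNAs from sRNA and degradome libraries"
author: "salmir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying salt-responsive miRNAs from sRNA and degradome libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmir)
```

## The problem

Plants reprogram gene expression under salt stress partly through
microRNAs: 18–25-nt regulatory RNAs excised from one arm of a hairpin
precursor that guide cleavage of complementary mRNAs. In diploid and
tetraploid *Paulownia fortunei*, four small RNA libraries (diploid and
tetraploid leaves, each with and without NaCl treatment: PF2U, PF2S, PF4U,
PF4S) plus matched degradome libraries allow three questions to be asked:

1. which miRNAs exist in the transcriptome (conserved ones matching a
   mature reference, novel ones supported by a fold-back precursor),
2. which of them respond to salt in both ploidies — and, after removing
   ploidy-intrinsic differences, which plausibly underlie the tetraploid's
   higher salt tolerance, and
3. which transcripts they actually cleave, as witnessed by degradome
   (PARE) 5'-end signatures.

`salmir` implements this workflow end to end, together with a
synthetic-data generator that plants known miRNAs, fold changes and
cleavage sites so that every stage can be validated against ground truth.

## Read processing and annotation

Raw reads are cleaned by locating the 3' adapter (best prefix-anchored
match, up to `max_adapter_mismatch` mismatches over at least
`min_overlap = 5` nt), then discarding inserts shorter than 18 nt, longer
than 30 nt, with mean Phred below 20, containing `N`, or with an A
fraction of 0.8 or more. The numeric values of the quality, ambiguity and
poly-A filters are this package's defaults — sRNA studies rarely print
them — and all are overridable through `cleaning_params()`. Cleaned reads
are collapsed to unique sequences with per-library counts; all later
statistics operate on collapsed reads.

Reads are classified by perfect matching into rRNA/tRNA/snRNA/snoRNA
reference sets and a mismatch-tolerant match against the mature miRNA
reference, with the fixed precedence miRNA > rRNA > tRNA > snRNA >
snoRNA > unannotated. A precedence is needed because reference sets
overlap and an annotation summary must assign each read exactly one
label; the order puts the classes that dominate real libraries first.
Percentages in the summary are rounded half away from zero to two
decimals, the convention used in published annotation tables
(`annotation_percentage()`).

Conserved matching allows two mismatches, with length differences counted
against the same budget (the community convention is silent here; counting
overhangs keeps the distance symmetric). Ties report every tied best
reference rather than picking one arbitrarily. At scale the matcher uses
an exact 5-mer pigeonhole prefilter — with at most two substitutions, at
least one of three disjoint 5-mers in the first 15 nt is intact — which is
lossless for the default budget and is property-tested against brute
force.

## Hairpin folding and novel miRNA criteria

Candidate precursors are excised around unannotated reads that map
perfectly to the transcript set: two windows per locus (mature near the
5' end, mature near the 3' end; 250-nt flank, capped at 350 nt — the cap
reflects the longest plant pre-miRNAs seen in practice). Each window is
folded by a dynamic program that maximises stacking-weighted base pairs
(GC = 3, AU = 2, GU = 1, +1 per stacked pair, hairpin loops of at least
3 nt). This folder is deterministic and exactly checkable against a
brute-force enumeration of all nested structures, which is what the test
suite does; its "minimum free energy" is a pseudo-energy
(`-0.4` kcal/mol per score unit by default) and is *not* comparable to
thermodynamic folding engines, so every energy threshold downstream is a
configurable estimate.

A candidate passes the annotation criteria (`check_meyers()`) iff:

* mature and star sit on opposite arms of a single stem-loop,
* at most 4 mature positions are unpaired in the mature/star duplex,
* asymmetric bulges in the duplex total at most 2 nt,
* the star is definable by the 2-nt 3'-overhang rule,
* the energy estimate is at or below −18 kcal/mol (configurable), and
* the precursor is 60–350 nt.

The numeric operationalisation (4 duplex mismatches, 2-nt bulge, 2-nt
overhang) follows the community annotation criteria for plant miRNAs;
failed criteria are returned as reason codes. Accepted loci consume their
precursor window so star and isomiR reads of the same hairpin do not
spawn duplicate loci, and windows around reads already matched to the
conserved reference are excluded up front.

## Differential expression

Counts are normalised to reads per million (no pseudo-count) and a
comparison written "A/B" uses B as baseline:
\(\mathrm{FC} = \log_2(\mathrm{RPM}_A/\mathrm{RPM}_B)\).
The P-value is the count-ratio exact test. With library totals
\(N_1, N_2\) and counts \(x, y\),

\[
p(y\,|\,x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\left(1+\frac{N_2}{N_1}\right)^{x+y+1}},
\qquad
C = \sum_{y' \le y} p(y'|x), \quad D = \sum_{y' \ge y} p(y'|x),
\]

with the two-sided P-value \(\min(1, 2\min(C, D))\). Terms are evaluated
in log space via `lgamma`; \(D\) is \(1 - C(y-1)\) except when that
difference would cancel catastrophically, in which case the (rapidly
decaying) upper tail is summed directly in finite blocks. The two-sided
rule is a design choice — the direction of change is not privileged — and
no multiple-testing adjustment is applied by default (`p_adjust` exposes
one), matching the raw-threshold convention of sRNA surveys. This
conditional formulation is exactly a negative binomial in \(y\) with size
\(x+1\), which the tests exploit as an independent cross-check, alongside
an exact-rational oracle.

Low-expression handling: a miRNA below 1 RPM in *both* libraries is
removed; a single low side is floored at 1 RPM so fold changes stay
finite. The alternative reading (remove if below 1 anywhere) is available
via `floor_single = FALSE`. Significance needs \(|\mathrm{FC}| \ge 1\)
and \(P \le 0.05\).

Salt-associated sets are pure set logic over the four comparisons:
significant in PF2S/PF2U **and** PF4S/PF4U (salt-responsive in both
ploidies); additionally significant in PF4S/PF2S (cross-ploidy); and
finally minus the miRNAs whose up/down status is identical in PF4S/PF2S
and PF4U/PF2U, which removes ploidy-intrinsic differences and leaves the
tolerance candidates. `ddct()` provides the companion
\(2^{-\Delta\Delta C_T}\) arithmetic for qPCR validation (triplicates
averaged first).

Note one asymmetry of the exact test: it conditions on the baseline
count, so relabeling the two libraries does not exactly swap the discrete
tails; the two-sided P-value is symmetric only up to discreteness (exact
at large counts). The log2 fold change negates exactly.

## Degradome target calling

Signatures are mapped by exact forward-strand matching; each mapped 5'
end is tested as a cleavage site opposite miRNA positions 10 and 11. The
candidate site is reverse complemented and scored without gaps against
the miRNA: Watson–Crick 0, G:U wobble 0.5, mismatch or overhang 1, with
penalties at positions 10/11 doubled; calls require score ≤ 4. The
weights are the standard plant target-scoring convention of
CleaveLand-class tools — the study convention fixes only the threshold —
and all are configurable. Per-transcript t-plots accumulate signature
abundances by position, and each call is categorised:

* **I** — the cleavage-site count is the unique transcript-wide maximum;
* **II** — above the median of non-zero positions, but not the unique
  maximum;
* **III** — the rest.

Published degradome studies describe categories only as
"based on expression abundances"; the unique-maximum / above-median
operationalisation used here is a reconstruction and is flagged as such.
Signature length defaults to 31 nt and is configurable down to the
~20 nt produced by MmeI-based protocols.

## The synthetic-data generator

`simulation_config()` fixes the study conditions the tests run under:
four libraries of 2×10^5 reads, 300 conserved and 10 novel hairpin loci
embedded in transcripts, 30 miRNAs spiked at \(|\log_2\mathrm{FC}| = 2\)
in both salt comparisons (half up, half down), log-normal background
abundances (meanlog log 100, sdlog 1.2 — reproducing the heavy-tailed
count range of real libraries), spiked miRNAs at a controlled spike-in
abundance (meanlog log 200, sdlog 0.8, as one would choose detectable
spike-ins), 2% star reads, 5% 1-nt 3' isomiRs, 20% ncRNA fragments,
0.5% poly-A and 0.3% low-quality reads, the remainder random degradation;
reads are 36 nt with a TruSeq small-RNA 3' adapter. The degradome
generator plants complementary sites (0–2 designed mismatches, never
opposite positions 10/11) and puts 80% of a target transcript's 5'-end
mass on the planted cleavage position, the rest uniform. Each artifact
draws from an RNG stream keyed by (seed, artifact name), so adding an
output never perturbs the others and a seed fixes everything
bit-for-bit.

What the generator does *not* emulate: sequencing error beyond planted
low-quality reads, genome duplication structure of the tetraploid,
5' isomiRs, multi-locus miRNA families, and transcriptome-wide
degradation gradients. Passing the closed-loop tests therefore shows the
algorithms are internally correct at realistic scales, not that the
thresholds are optimal for any particular real library.

## Benchmarks the package runs on itself

The problem sizes are chosen to exercise the statistics at realistic
collapsed-library scale while staying desk-sized: `benchmark_de_recovery`
(4 × 2×10^5 reads, 300 miRNAs, 30 spikes; recall and empirical FDR
against truth, 5 seeds), `benchmark_null_type1` (300 null count pairs;
the test is conservative at low counts, so the acceptance band is
0.01–0.08), `benchmark_hairpin_criteria` (50 planted hairpins must pass,
50 dinucleotide-shuffled controls must fail), and
`benchmark_degradome_recovery` (50 planted targets recovered
site-exactly as category I; 20 shuffled decoy miRNAs produce no call at
score ≤ 2). `scripts/acceptance.R` re-runs all of these from scratch and
writes the numbers as JSON.

## Numerical and degenerate-input choices

* Folding ties are broken deterministically (right end unpaired first,
  then smallest pairing partner; stacking preferred), so reruns are
  byte-identical.
* `fold_rna()` accepts any length ≥ 1; sequences too short to pair fold
  to the open structure with energy 0.
* Degradome windows truncated at transcript ends are flagged; sites that
  would run off the transcript are skipped rather than padded.
* An empty read set is a valid input everywhere (empty outputs, zeroed
  statistics), not an error.
* In `find_star()`, unpaired anchor positions fall back to the nearest
  paired mature base; a mature spanning the hairpin loop is an error
  (`mature_in_loop`), which `check_meyers()` converts into a reason code.

## Known limitations

* The pseudo-energy scale is linear in the pairing score; it ranks
  hairpins sensibly but the −18 kcal/mol default is calibrated to this
  package's scale only.
* Target categories depend on the t-plot of mapped signatures only;
  no background noise model is fitted.
* The exact test has no replicate-aware dispersion; with biological
  replicates a count-model package would be the right tool.
* GO/KEGG annotation of targets is out of scope; only a pass-through
  join against a user-supplied annotation table is provided.
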