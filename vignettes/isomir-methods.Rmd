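---
title: "Methods: isomiR calling, quantification and differential testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR calling, quantification and differential testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRpipe)
```

## Scope and model

isomiRpipe analyzes single-end small-RNA sequencing libraries at isomiR
resolution. The biological object is the mature miRNA and its end-variant
isoforms: Dicer and Drosha cleave the precursor hairpin at slightly
variable positions, so a mature miRNA is observed as a family of reads
differing by a few nucleotides of 5′/3′ trimming or extension, plus
post-transcriptional non-templated 3′ additions (e.g. uridylation). A
regulatory change in the processing machinery — for instance loss of a
Dicer cofactor that favors longer cleavage products — shows up as a shift
in the *relative proportions* of these isoforms even when total abundance
barely moves. The package therefore separates two questions per miRNA:
did its abundance change, and did its isomiR composition change?

The reference model is a set of hairpin precursors with located mature
annotations. Internally all sequences are DNA-alphabet uppercase (`U → T`)
and coordinates are 0-based half-open; miRBase-dialect GFF3 (1-based
inclusive, landmark = hairpin id) is converted at the boundary, and a
5-column TSV is accepted for toy references. Each hairpin carries at most
one 5p and one 3p mature; the arm is read from the `-5p`/`-3p` id suffix,
with a fallback to which hairpin half the mature's midpoint occupies, so
toy references that do not follow miRBase naming still load. Hairpins with
a single annotated mature are allowed; the arm-ratio analysis simply skips
them.

## Preprocessing

Reads are filtered and trimmed in a fixed order, and each read is counted
in exactly one bucket so the report is auditable:

1. **Quality** (on the untrimmed read): pass iff at least
   `quality_percent` % of bases have Phred ≥ `quality_cutoff`
   (defaults 90 and 30, both inclusive — the FASTX
   `fastq_quality_filter` semantics).
2. **Adapter**: the leftmost exact occurrence of the 3′ adapter
   (default `AGATCGGAAGAGCACACGTCT`), or an exact adapter *prefix* of ≥ 5
   nt reaching the read's 3′ end (read-through rescue). No occurrence →
   dropped (`no_adapter`); occurrence at position 0 → dropped
   (`adapter_only`).
3. **Length**: trimmed inserts shorter than 15 nt are dropped.

The quality-before-trim order is a deliberate fix: prose descriptions of
such protocols rarely state the order, and a single deterministic pipeline
is worth more than guessing a tool's internal sequencing. Adapter matching
is exact; an error-tolerant matcher is out of scope because the rescue
rule already covers the dominant failure mode (the read ending inside the
adapter), and exactness keeps the fate partition reproducible. Only the
Sanger +33 quality encoding is accepted; scores outside [0, 93] are an
error, never silently re-interpreted.

## IsomiR calling

A candidate assignment of read *r* to mature *m* is a pair of signed end
offsets `(offset5, offset3)` (negative = trimming, positive = extension)
such that the implied hairpin span has exactly the read's length. The
rules:

* 5′ extensions are accepted only when drawn from the hairpin (templated);
  biologically, 5′ non-templated additions are rare, and the upstream
  mapping conventions this reproduces treat additions as 3′-specific.
* A positive `offset3` whose read bases equal the hairpin flank exactly is
  a **templated extension**. Otherwise the entire extension is recorded as
  a **non-templated tail**; tail bases are never counted as mismatches.
  A mixed extension (first base templated, second not) is deliberately
  represented as a full tail — the call record holds one offset and one
  tail, and the resolution order below makes the tail reading win anyway.
* Substitutions are counted over the templated portion only and must not
  exceed `max_mismatch` (default 1).
* Window defaults: ≤ 3 nt trimming each side, ≤ 3 nt addition (both
  5′-templated and 3′).

Among all candidates the caller picks the lexicographically best by
(fewest mismatches, smallest `|offset5| + |offset3|`, templated before
non-templated, shortest tail), with mature id as the final deterministic
tie-break. If two candidates from *different* matures tie on the full
score, the read is ambiguous and dropped by default — the conservative,
reproducible policy; fractional assignment is not implemented.

Labels project calls onto the familiar one-axis isomiR nomenclature:
canonical = `"0"`, pure 3′ variants = signed offsets, any 5′ variant =
`5p:±k` (a read varying at both ends is reported under its 5′ compound
label, because a single-axis label cannot encode both ends; both offsets
remain in the call table), non-templated tails = `nt:<tail>`. Calls that
carry internal substitutions get a `|m<k>` suffix so that `"0"` always
means an exactly-canonical read. Mismatch-carrying calls are included in
miRNA totals by default (they pass the mismatch-tolerant window, as in
standard small-RNA mapping); a flag excludes them.

The engine hashes unique read sequences and compares byte matrices per
read length, which makes the call table byte-identical across runs and
fast at library scale; its contract is checked against a literal
brute-force enumerator (every variant string in the window, naive
character comparison) in the test suite.

## Quantification

Counts are aggregated per (mature, label) and per mature. RPM uses the
total miRNA-mapped reads per sample as the denominator by default (columns
then sum to exactly 10⁶); total clean reads is available as an
alternative, which matters when non-miRNA contamination differs between
libraries. Abundance filters keep a mature at mean ≥ 10 RPM in at least
one condition, and an isomiR at mean ≥ 1 RPM in at least one condition
(condition mean over replicates; thresholds inclusive). The mean is the
natural aggregation when a filter is phrased per condition over
replicates.

IsomiR proportions are computed per (miRNA, sample) over **templated
labels only** — non-templated tails are excluded from numerator and
denominator, since the analysis targets shifted cleavage rather than
post-processing tailing; a flag restores the denominator-inclusive mode.
Cells whose miRNA has zero included reads are *missing* (`NA`), never
zero: a zero would fabricate evidence of absence downstream, whereas a
missing replicate is simply dropped from its test.

Arm ratios are `log2((RPM_5p + ε)/(RPM_3p + ε))` with ε = 0.5 RPM — a
half-read pseudocount on the RPM scale, small enough not to bias expressed
hairpins and large enough to keep the log finite; it is a configurable
argument, not a constant.

## Differential testing

Both t-test variants follow the spreadsheet nomenclature used in wet-lab
reporting: type 2 = two-sample pooled-variance, type 3 = Welch with
Satterthwaite degrees of freedom; two-tailed p-values. Degenerate inputs
have fixed conventions: zero standard error with equal means gives
`t = 0, p = 1`; with unequal means, the smallest representable positive p.
The default contrast test is **unpaired**, because "type 2" denotes the
unpaired homoscedastic test (the paired test is type 1 in that
nomenclature); a paired-by-replicate mode is provided for designs where
stimulations are paired within cultures. Fold changes, by contrast, are
always averaged over replicate-paired ratios:
`mean_k log2((RPM_treated,k + ε)/(RPM_control,k + ε))` — pairing the ratio
is harmless under an unpaired design and correct under a paired one.

Per-feature significance is unadjusted p < α (default 0.05), matching the
per-feature usage this pipeline reproduces; a Benjamini–Hochberg column is
emitted alongside, clearly an extension, so users scanning hundreds of
miRNAs can control FDR instead. Proportion tests run per (miRNA, label) on
replicate proportions; replicates with missing proportions are excluded,
and a feature with fewer than two usable replicates in either group is
flagged as skipped rather than silently tested. Negative-binomial GLMs and
dispersion shrinkage are deliberate non-goals: at n = 3 with proportions
in [0, 1], the t-test on replicate summaries is the transparent choice,
and external count-model packages can always be applied to the exported
count tables.

## The synthetic-data generator

The generator emulates the study shape this pipeline targets: six
libraries (two conditions × three replicates), 50-cycle single-end reads
with 3′ adapter read-through, inserts drawn from designed per-miRNA isomiR
mixtures. Defaults, chosen once as realistic study conditions:

* 200,000 reads per library; read length 50; the NEBNext adapter.
* Default mixture per miRNA: canonical 0.60, `-1` 0.15, `-2` 0.07, `-3`
  0.05, templated `+1` 0.08, and a 1-nt non-templated tail 0.05 (its base
  chosen per-miRNA to differ from the hairpin flank, so the class is
  genuinely non-templated).
* Abundance weights: a deterministic 50-fold geometric spread across
  matures — a compressed but realistic dynamic range that keeps every
  mature above the 10 RPM filter at test depths.
* Per-base substitution error 0.001; 2 % of reads uniformly low-quality
  (Phred 2, guaranteed to fail the 90/30 rule); all other bases Phred 40.
* Replicate-level log-normal noise (sd 0.05 on the log scale) on both
  abundance weights and mixture probabilities, giving the between-replicate
  variance that the t-tests need to be honestly calibrated.

The truth table records realized per-class counts (and how many reads of
each class received an error), so recovery can be measured against an
honest denominator. Scenario derivation is explicit: a null scenario
(identical settings), a proportion shift (canonical 0.60 → 0.45 with the
mass moved to the −3 class — the "canonical down, shorter isomiR up"
pattern), and a half-abundance scenario (designed log2FC = −1).

What the generator does **not** emulate: ligation bias, PCR duplicates,
platform-specific quality profiles, indels, or genomic background reads.
Passing round-trip tests therefore demonstrates the pipeline's internal
correctness — preprocessing, calling, counting and testing recover a known
generative truth — not robustness to every artifact of real libraries.

## Numerical and validation choices

* Validation problem sizes, chosen as a compromise between statistical
  resolution and desk-scale runtimes: exact round-trip identity at
  6 × 200k reads with error rate 0; type-I calibration from 10 null
  repeats of a 20-mature reference at 50k reads (200 tests per family,
  rejection compared to the exact binomial 95 % interval around 0.05);
  effect recovery over 20 seeded repeats at 200k reads. The effect-target
  miRNA is a mid-abundance mature (~5 % of the library): abundant enough
  for tight proportions, small enough that halving it barely perturbs the
  RPM denominator (the compositional bias on its log2FC is ~0.04, well
  inside the ±0.1 recovery band).
* The caller's correctness oracle is a brute-force enumerator kept free of
  any shared code with the engine; candidate tables are compared
  call-for-call on 1,000 constructed and random reads.
* Proportion conservation is asserted at 10⁻⁹; everything upstream is
  exact integer counting, so the only tolerance needed is floating-point
  division.
* All simulations are seeded; identical seeds give byte-identical FASTQ
  and truth tables. When a seed is supplied to `scripts/acceptance.R`, all
  derived seeds stay below 2³¹.

## Known limitations

* Single-end data only; no UMIs; no adapter mismatch tolerance.
* The caller is designed for mature-miRNA-sized references, not
  genome-scale alignment; candidate enumeration is exhaustive within the
  window rather than seed-and-extend.
* Reads varying at both ends are collapsed to the 5′ compound label in
  single-axis summaries (the full call table retains both offsets).
* The differential layer is a replicate-level t-test by design; it does
  not model count overdispersion and should not be pushed to n ≫ 3
  designs where count-model packages are more appropriate.
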