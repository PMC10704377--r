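---
title: "Single-molecule bisulfite footprinting of single-stranded DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule bisulfite footprinting of single-stranded DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisfoot)
```

## The measurement

Sodium bisulfite deaminates cytosine to uracil, but only when the
cytosine sits in single-stranded DNA. When genomic DNA is treated
under non-denaturing conditions, amplified, cloned and Sanger
sequenced, each clone is a snapshot of one DNA molecule, and the
positions where C reads as T map the single-stranded regions of that
molecule at nucleotide resolution. Structures that expose one strand
— R-loops, where nascent RNA hybridises to the template strand and
displaces its partner, and G-quadruplexes, whose complementary C-rich
strand is left unpaired — therefore leave a *footprint* of clustered
conversions. `bisfoot` implements the full analysis from clone
sequences to footprint intervals, together with the companion
computations used around such an experiment: AID hotspot and
G-quadruplex motif scanning, AID deamination mutation frequencies, a
breakpoint-cluster utility and signal-track summaries.

Everything is expressed in top-strand coordinates, 0-based and
half-open (BED-native); 1-based positions appear only in the VCF-like
mutation export.

## Strand logic

A bisulfite-converted top-strand molecule shows C→T against the
reference. A bottom-strand molecule converts its own cytosines, which
in top-strand coordinates are the reference G's, read as G→A. Strand
of origin is therefore called from the dominant class of
bisulfite-consistent mismatches (`assign_strand`): at least 3
informative mismatches and 80% dominance are required, otherwise the
clone is `undetermined`. These two thresholds are analysis choices —
the experiment itself fixes no rule — and both are exposed as
arguments. On simulated clones carrying at least five conversions the
call is essentially always correct (the acceptance suite measures
this at 1000 clones).

This strand separation carries the central control of the assay: a
genuine R-loop exposes one strand only, so conversion stretches must
appear in clones of one strand while the other strand stays at
background. The simulator plants footprints strand-specifically for
exactly this reason, and `positionwise_frequency` refuses to mix
strands.

## Alignment

Clones are aligned globally with affine gaps
(match +1, mismatch −1, gap open 4, gap extend 1). To stop heavy
conversion from attracting spurious gaps, both sequences are first
*bisulfite-folded* (C→T and G→A), which makes every C/T and G/A pair
an exact match — the two-sided analogue of the reduced-alphabet trick
used by bisulfite read mappers. Clone quality is then gated on the
columns where folding does not apply: identity across exact matches
and non-neutral mismatches must reach 0.9, or the clone is rejected.
A run aborts when more than half the clones are rejected. One
consequence of symmetric folding is that a clone resembling the
*complement* of the reference can align with few informative columns;
such clones pass the identity gate but resolve as `undetermined`
strand and drop out of the summaries.

## Conversion calls and the CpG rule

For each informative position (reference C for top-strand clones,
reference G for bottom-strand), the call is `converted`
(bisulfite-expected base), `unconverted` (reference base), `excluded`
(gap or N), or `mismatch_other` (any other substitution —
bisulfite-inconsistent, tallied for QC; clones above 5%
mismatch_other are flagged).

CpG cytosines need special care: an unconverted CpG may be protected
by methylation rather than by double-strandedness, and a converted
CpG in otherwise unconverted surroundings is uninterpretable. A
converted CpG keeps its status only when the `cpg_run_k` immediately
preceding non-CpG calls — preceding in the molecule's own 5'→3'
direction, i.e. decreasing coordinates for bottom-strand clones — are
all converted; otherwise it is reclassified `excluded`. The default
is `cpg_run_k = 4` (the stricter of the two values in circulation for
this assay; 2 is the other) and the parameter is exposed rather than
hidden because the two conventions genuinely disagree. `k = 0`
disables the rule.

## Stretches, clone classes and footprints

Single-strandedness in one molecule is operationalised as a *stretch*
of conversions, in two modes:

* **continuous** — a maximal run of at least `min_run` consecutive
  converted calls. Excluded calls break runs: an indel column is not
  evidence of conversion. Run length counts cytosines, not
  nucleotides; the nt span is reported separately, since at ~25% base
  composition a 13-cytosine run typically spans 50-65 nt.
* **windowed** — some window of `window` consecutive informative
  calls contains at least `min_in_window` conversions (default 12 of
  15). Excluded calls are skipped, not failed. A sliding window is
  used (the fixed-partition alternative misses stretches straddling
  partition edges); overlapping qualifying windows merge, and the
  merged stretch is trimmed to its first and last converted call.

Clones are classified by their strongest evidence
(`run_gt15` > `run_gt10` > `windowed_only` > `none`), and
`compare_conditions` tabulates these counts per condition — with and
without RNase H being the canonical comparison, since RNase H
degrades the RNA of an RNA:DNA hybrid and must erase R-loop
footprints but not G-quadruplex ones. Counts in the comparison table
are cumulative (a 17-run clone counts in both `n_run_gt10` and
`n_run_gt15`), matching how such counts are conventionally plotted;
zeroes are reported as 0, never substituted.

Population-level footprints come from `positionwise_frequency`
(conversions over covered clones per position; excluded calls reduce
coverage) followed by `call_footprints`: positions at fraction ≥
`min_fraction` (0.5) merge into intervals, and intervals spanning ≥
`min_span` (30 nt, the shortest biologically reported footprint
class) are kept. Two rules govern merging, both worth stating
precisely because they decide borderline loci:

* A span with *no* informative cytosine carries no evidence either
  way and never splits a footprint — absence of cytosines is not
  absence of single-strandedness. Only *contrary* evidence splits:
  covered sub-threshold positions spanning more than `max_gap`
  (10 nt).
* Positions whose coverage has collapsed below half the table's
  median coverage are treated as no-data. This matters in practice:
  CpG sites demoted by the conversion-run rule retain only the
  biased residue of clones in which they were unconverted, and their
  apparent 0% frequency would otherwise cut real footprints in two.

Supporting clones for a footprint are those whose covered calls
inside the interval are at least half converted.

## Motif scanning

The AID hotspot WRC (W = A/T, R = A/G, then C) is scanned on both
strands by default — minus-strand hits are GYW on the given strand —
because published per-region counts for this assay plausibly sum both
strands; single-strand counts are reported alongside.

The conventional G-quadruplex motif is four tracts of ≥3 G separated
by loops of 1-7 nt. The extended definition reflects structures
validated biochemically at this locus that the conventional formula
misses: at most **one** loop may stretch to `max_long_loop` (21 nt,
the range over which a loop can fold back as a duplex hairpin), and
at most **one** tract may be bulged `G+NG+` (a single non-G
interruption) provided its G count still reaches `min_tract`. Greedy
reporting is leftmost-maximal and non-overlapping, as in common G4
scanners; an exhaustive overlapping mode enumerates every
decomposable span and exists to be checked against a brute-force
decomposition oracle (the test suite does this on strings up to
40 nt, where exhaustive enumeration is tractable). Every conventional
span is an extended span by construction, and the suite verifies the
inclusion on 1000 random G-rich strings.

GC content and windowed GC skew `(G−C)/(G+C)` complete the sequence
summaries; skew matters because a G-rich displaced strand
thermodynamically favours R-loop formation.

## The simulator

`simulate_bisulfite_clones` emulates exactly the decisions the assay
makes: a strand of origin per clone (`strand_mix`), conversion of
each informative cytosine with probability `p_ss = 0.95` inside a
planted footprint on the clone's strand and `p_bg = 0.02` elsewhere,
then uniform sequencing error at `p_seq_err = 0.001` per base. The
defaults describe the reference condition used throughout the
package's validation: a 600 nt locus at 50% GC with one 60 nt
bottom-strand footprint and 50 clones — sizes chosen to match the
footprint lengths (30-100 nt) and clone counts (tens per strand) the
assay realistically produces. `simulate_aid_clones` deaminates
exposed cytosines on both strands at a given rate, with an optional
misrepair fraction producing non-transition substitutions, emulating
aberrant base-excision repair of uracil. Ground truth records every
decision, and `evaluate_recovery` scores called intervals against
truth at reciprocal overlap ≥ 0.5.

What the simulator does *not* model, and what passing tests therefore
do not establish about real data: PCR duplicates and chimeras, clone
lineage (each clone is independent), primer bias, quality-score
structure, true CpG methylation (methylation is only handled as a
confounder on the calling side), and partial or breathing structures
whose conversion probability varies within the footprint. Detection
performance on real clones will be bounded by these effects, not by
the algorithmics validated here.

## Numerical and degenerate-input choices

* Seeds fully determine simulator output; the reference, bisulfite
  and AID generators draw from distinct seed offsets so that fixing
  one stage does not perturb another.
* Empty inputs are values, not errors, wherever a downstream sum is
  meaningful: zero breakpoints give zero clusters, an empty frequency
  table gives zero footprints, zero mutations give frequency 0. A
  fully uncovered region reports `covered_fraction = 0` with `NA`
  mean; a window without G or C reports `NA` skew.
* Overlapping signal-track intervals are an error, not a silent
  overwrite; the same base covered twice indicates a malformed file.
* `undetermined` strand is a value from `assign_strand` but an error
  in `call_conversions`, which cannot proceed without a strand.
* Region offsets are interpreted downstream of a configurable anchor
  on the sense strand; because promoter anchors are annotation
  choices, the scan workflow is designed to be swept over nearby
  anchors, and the acceptance suite demonstrates count stability
  under ±20 nt perturbation on a synthetic locus.

## Validation sizes

The test and acceptance suites run entirely on data generated in
code: 1000 random call strings (≤ 60 calls) against brute-force
stretch oracles; ~100-150 G-rich strings (≤ 40 nt) against the
exhaustive G4 oracle plus 1000 strings (≤ 120 nt) for the
conventional-within-extended inclusion; 20 seeded simulations of the
reference condition for footprint recovery; 1000 clones for strand
assignment; 50 clones for the RNase-H emulation; and 10,000 simulated
nucleotides for mutation-frequency recovery, with 40 clones per arm
for the two-condition reduction. These sizes give the binomial checks
standard errors comfortably below the asserted tolerances.

## Limitations

The aligner is a global pairwise aligner: clones must be full-length
amplicon sequences, not fragmented reads. Mutation calling excludes
columns within 2 nt of a gap and counts each occurrence across clones
(no UMI or duplicate logic), so PCR errors inflate frequencies
identically in compared conditions but not against an external
standard. The G4 scanner is combinatorial, not thermodynamic: it
reports motif compatibility, not folding propensity.
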