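---
title: "Methods: iterative profile-HMM discovery of SPRE-like elements"
author: "spretrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative profile-HMM discovery of SPRE-like elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spretrace)
```

## The problem

The syncytin post-transcriptional regulatory element (SPRE) is a short
tripartite RNA element found near the 3' ends of endogenous retrovirus (ERV)
families: a 17-nt core motif (`TCAGCAGGAAGCAGTTA`) flanked on both sides by
C-rich motifs. Searching a repeat-family consensus library for such an
element is awkward: the core alone is too short to be specific, and the
full element is too diverged across families for exact matching. spretrace
implements the standard remedy, a two-step search:

1. **Seed (step 1).** Scan every consensus for an exact occurrence of the
   core motif, on both strands, and cut out each occurrence with 40 nt of
   flanking context — a fixed-width, core-anchored 97-column window.
2. **Refine (step 2).** Fit a nucleotide profile hidden Markov model (HMM)
   to the stacked windows, search the whole library with it under an
   E-value threshold, realign the significant hits in model coordinates,
   rebuild the model from the realigned hits, and repeat. The cycle with
   the most hits is selected.

The selected model is then applied to long targets (genomes, viral
sequence sets), and the hits are analysed downstream: their position along
the family consensus (3'-bias), and their strand-aware overlap with
RepeatMasker-style repeat annotations after directional extension.

Because the package's validation is entirely synthetic (see below), a
generator module produces every input with machine-readable ground truth.

## Seeding and the anchored alignment

Step-1 matching is exact string matching; `N` never matches, so windows
with an ambiguous core are excluded by construction. Both strands are
searched by default (minus-strand occurrences are reported on the forward
coordinate frame and their windows are reverse-complemented so the core
always reads 5'→3'); a flag restricts the search to the plus strand.

The first-cycle alignment is *anchor-based*: windows are fixed-width with
the core pinned at columns 41–57, so stacking them is already an
alignment. A general multiple-alignment step would add nothing here — the
only anchored signal is the core, which is identical across windows by
construction — and removing it makes the first profile deterministic.
Windows that run off a short consensus are padded with `-`; the padding is
treated as *missing data* (a local fragment), not as deletions, when the
model is fitted.

## The profile HMM

The model is a Plan-7-style nucleotide profile HMM in local mode:

* match states `M_1 … M_M` with per-state emission distributions over
  A,C,G,T; insert states `I_k` between matches; delete states `D_k`;
* transitions `M→M, M→I, M→D, I→M, I→I, D→M, D→D` per node (no `I↔D`
  edges);
* **local entry**: begin → `M_k` uniformly with probability `1/M` for any
  `k`; **local exit**: free from any match state. There is no flanking
  self-loop segment; multiple hits on one target are found by accepting
  the best local alignment, masking its span, and rescanning.

A path's **bit score** is its log₂ odds against an i.i.d. background
`q`: `log2(1/M) + Σ log2 t + Σ log2 e(x)/q(x)`. Viterbi gives the best
local path (with traceback, so each hit carries its model-column
alignment); the forward score sums over all legal local paths and always
dominates Viterbi. Both recursions are exact dynamic programming,
implemented in C++ for Mb-scale targets, and are tested against exhaustive
path enumeration on small instances (`M ≤ 3`, targets ≤ 6 nt).

**Fitting.** Columns with gap fraction strictly below 0.5 (a parameter)
become match states. Emissions are `(counts + c·q)/(total + c)` with
pseudocount weight `c = 1` — background-proportional additive smoothing,
stable for the small seed alignments this pipeline starts from (tens of
rows). Transitions are counted from each row's match/insert/delete path
with the same pseudocount spread uniformly over each state's outgoing
options. `N` counts as state occupancy but contributes no emission count.
Rare insert runs adjacent to a deletion have no legal edge in this
architecture; the node-to-node transition is kept and the insert residues
contribute emissions only.

**Background.** `q` defaults to uniform and is estimated from the searched
database in the pipeline (floored at 0.05 per base, so skewed synthetic
compositions cannot push log-odds to infinity).

## E-values

The search tool this pipeline's design follows reports E-values from its
own internal statistics; a reimplementation cannot and should not promise
numeric compatibility. What the pipeline needs from E-values is (i) honest
thresholding at `E < 1e-5`, (ii) monotonicity in score, and (iii)
calibration: predicted tail probabilities should match observed background
score frequencies. spretrace therefore calibrates empirically:

* draw `n` i.i.d. background sequences (default 1000 × 200 nt, seeded),
* record the best local Viterbi bit score per sequence,
* fit a Gumbel by maximum likelihood (the scale parameter solves a 1-D
  profile-likelihood equation by root bracketing; the location then has a
  closed form),
* `P(s) = 1 − exp(−exp(−λ(s − μ)))` and `E = N_eff · P(s)`.

`N_eff` is the number of database sequences × 2 strands in library mode,
and total residues / model length in genome mode. Calibration sanity is a
tested property: on fresh background sequence the empirical frequency of
scores with predicted `P ≤ 0.01` must lie within a factor of 3 of 0.01.
The fitted `λ` recovers a known synthetic Gumbel within 5% at n = 5000.
A degenerate (zero-variance) score distribution is an error, not a fit.

## The refinement loop

Each cycle: build the model from the previous alignment, recalibrate it
(model length and entropy change between cycles; the calibration seed is
the same each cycle so a true fixed point is exactly reproducible), scan
every library sequence on both strands, keep hits with `E <` threshold,
merge overlapping same-strand hits on a target (keeping the lower
E-value), and realign the survivors: each hit's residues are placed into
the M model columns via its Viterbi path, deletions becoming gaps and
insert residues being dropped.

The loop runs a fixed number of cycles (default 10) and **selects the
cycle with the most hits, ties broken earliest**. Early stopping — on a
cycle with zero hits or a hit set identical to the previous cycle's —
cannot change the selection under that tie rule and is enabled by default;
`early_stop = FALSE` reproduces the fixed-cycle run.

On synthetic data the hit-count trajectory rises and then drifts: as
cycles pass, weakly conserved flank columns fall below the gap threshold
and the model shortens (visible as `model_M` in the cycle table). The
package records every cycle's model and hit table so this drift can be
studied; no mechanism is asserted beyond the observation.

## Genome scanning

Long targets are scanned in overlapping chunks (default 100 kb, overlap
500 nt ≥ model length, a precondition). Chunk-local coordinates are lifted
to the global frame, and each hit is kept only by the chunk that *owns*
its start (the chunk minus its trailing overlap; the last chunk owns its
tail). Because the overlap exceeds any hit length, the owning chunk always
sees the hit in full — a match straddling a chunk edge is reported exactly
once and never truncated. Identical span+strand duplicates are removed as
a second guard. The hit set is invariant to the chunk size, and that
invariance is a test.

The background is estimated globally, not per chunk, so E-values do not
depend on local composition. Hits with `E` between the threshold and 0.01
can be logged separately (`record_near`): near-threshold matches are worth
inspecting by hand but never enter the main tables.

## Overlap analytics

* **Relative position score** `[(S+E)/2]/L` with `S`, `E` 1-based
  inclusive hit coordinates and `L` the consensus length; values near 1
  are 3'-terminal. Strandness is honoured by reflecting minus-strand
  scores to `1 − score`, i.e. position is measured along the element's own
  5'→3' reading — the reading under which a 3'-terminal bias is the
  biologically meaningful statement. `strand_reflect = FALSE` gives the
  unreflected value, since the convention is genuinely ambiguous.
* **Directional extension** grows an interval by a fixed amount (default
  50 nt) in its own 5' or 3' direction (strand-aware), clamped to the
  sequence; extension by `a` then `b` equals extension by `a+b` absent
  clamping.
* **Stranded intersection** pairs intervals overlapping by ≥ 1 nt on the
  same sequence and strand, reporting both records of every pair —
  `bedtools intersect -s -wa -wb` semantics, implemented on
  GenomicRanges and tested against an all-pairs brute-force oracle.
* **Tallies** count annotation *records* per repeat name among the pairs
  (an element spanning two tracks contributes two), matching the "number
  of tracks" reading of the summary this mirrors.
* **LTR fraction** uses prefix matching on the repeat class, so internal
  regions (`LTR-int` and the like) count as LTR-type, over a complete
  denominator (unknown classes map to `"other"`, never dropped).
* **Relative synonymous codon frequencies** normalise codon counts within
  each amino acid's synonymous family; unused families are all-zero, and
  internal stop codons are rejected.

## The synthetic-data generator

`make_library()` emulates the statistical structure the analysis assumes:

* a consensus library (default 50 families, 1.5–3 kb) in which a fraction
  (default 20%) carry one element copy;
* carriers are predominantly LTR-class; non-carriers mix LTR and other
  classes;
* the element is tripartite — 5' C-rich motif, spacer, 17-nt core, spacer,
  3' C-rich motif. The core default is the real motif; **the C-rich motif
  defaults (`CCTCCCC`/`CCCACCC`) and spacer ranges are declared synthetic
  stand-ins**, configuration rather than claims about the true consensus,
  which is not a tabulated quantity;
* the element midpoint's relative position is drawn from Beta(5, 1.5)
  (mean ≈ 0.77), a stand-in for the observed 3'-terminal bias; draws are
  minimally shifted when the element would not fit (a negligible
  correction at the default sizes, and a tested one);
* per-copy divergence: substitutions in the flanking motifs/spacers
  (default 10%), a separate core substitution rate (default 0, so exact
  seeding finds every carrier under the default conditions), and optional
  geometric-length indels to exercise the model's D/I states;
* elements are planted on the minus strand with probability 0.3, measured
  along their own orientation, so strand reflection is exercised
  everywhere.

`make_genome()` has two layouts. `"copies"` inserts diverged family copies
at random non-overlapping loci on both strands and writes one
RepeatMasker-style annotation record per copy; element truth coordinates
and strands are composed through the insertion. `"element_upstream_ltr"`
is the overlap-geometry construction: element instances are planted with
their family context *on the 5' side only*, so the element's informative
3' terminus is flush with the insert edge, and an LTR annotation record is
placed exactly `gap` nt (default 30) away in the element's own 3'
direction, with blocks isolated by ≥ 150 nt. Raw hits then overlap no
annotation, 5'-extended hits still overlap none, and 50-nt 3'-extended
hits overlap all of them — the qualitative signature of elements sitting
just upstream of LTRs. Context is included because profile hits are
windows, not bare motifs: a bare ~40-nt element against a 97-column model
sits near the detection threshold, which would make the construction probe
sensitivity rather than geometry.

`make_decoys()` provides negatives: plain background, core-only (exact
core, no C-rich flanks — found by step 1, but scoring below any full
element under the refined model), and shuffled-core sequences.

Every generator is a pure function of its parameters and a seed, and every
dataset ships a truth table; recall/FDR computations consume only truth
plus pipeline output.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: phylogenetic correlation between families (each
synthetic family is independent), realistic ERV decay (uniform
substitution, no CpG or indel hotspots), genome composition heterogeneity
(i.i.d. background), nested or fragmented repeat structure, and the true
C-rich motif consensus. The recovery numbers below are statements about
this generative model at desk scale, not about any particular genome.

## Problem sizes and numerical choices

The shipped validation runs at desk scale, chosen so the full suite and
the acceptance script each complete in minutes on one CPU: 50-family
libraries (20% carriers) for recovery, 1 Mb genomes with 20 planted copies
for scanning, 1,100 carriers for the position-bias statistic, 1,000 × 200
nt calibration samples per cycle and 10,000 for the tail check. The
statistics scale with these sizes (3-standard-error bands, factor-of-3
tail agreement), so they are not tuned to particular draws; the seeds are
explicit arguments throughout.

Other numerical choices: `N` in a target is scored neutrally (log-odds 0)
while masked spans are forbidden (−∞), so masking cannot leak hits but
genuine ambiguity does not veto them; emission/transition rows are checked
to sum to 1 within 1e−9; Viterbi ties break deterministically
(entry, then match, insert, delete predecessors); E-value thresholds are
converted to bit-score cutoffs through the exact inverse of the Gumbel
tail, clamped below saturation; the Gumbel fit centers scores before
exponentiating. Degenerate inputs — all-gap alignments, empty hit sets,
zero-variance calibration scores, overlaps smaller than the model —
are errors with messages naming the offending stage, because each one
invalidates a downstream assumption silently if allowed through.

## Limitations

* E-values are calibrated per model and are not comparable across tools
  or across differently calibrated models.
* Mask-and-rescan multi-hit search is greedy; two strongly overlapping
  true matches on the same strand resolve to the better-scoring one.
* The EMBL and RepeatMasker parsers cover the minimal field subsets the
  pipeline consumes, not the full formats.
* Step-1 seeding requires at least one exact core occurrence in the
  library; a library of uniformly diverged cores cannot be seeded without
  supplying an external seed alignment (any equal-width alignment is
  accepted).
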