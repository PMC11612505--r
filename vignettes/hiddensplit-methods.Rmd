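---
title: "Calling copy-number variants with hidden split reads: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy-number variants with hidden split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hiddensplit)
```

## The problem

Deletions and tandem duplications alter copy number locally; in human-like
genomes the majority of them fall inside tandem repeats and add or remove an
integer number of repeat units. Such events often leave none of the evidence
classical short-read callers rely on. If the deleted unit *D* is identical
to its neighbour, the junction sequence created by the deletion is not novel
— every read sequenced across it aligns end-to-end somewhere on the
reference — so there are no clipped ("split") reads. Events shorter than a
few hundred base pairs barely perturb the insert-size distribution, and
read-depth methods only resolve large events. What usually *does* survive is
a faint signal: repeat copies are rarely identical, so a junction read
aligns fully but carries the mismatches of the neighbouring copy. The
aligner prefers that full, slightly mismatched placement over clipping, and
in doing so hides the variant.

## Hidden split reads

Let `score(s)` be the optimal local-alignment score of a fragment *s*
against the reference, under a single affine-gap scheme used everywhere in
this package: match +1, mismatch −4, gap opening −6, gap extension −1 (the
first base of a gap costs −7). A read *r*[1..*n*] is a *hidden split read*
(HSR) when some split index *i* satisfies
`score(r[1..i]) + score(r[i+1..n]) > score(r)`; the maximal gain over all
*i* is the HSR-score. It is never negative — a free split can only add
options — and each mismatch that the linear alignment was forced to absorb
but the split resolves contributes +5 under the default scheme.

Two implementation points matter:

* **All splits in two passes.** `score(r[1..i])` for every *i* is the
  running maximum of row maxima of one Smith–Waterman pass (a prefix
  alignment is any local alignment ending at a row ≤ *i*); a second pass on
  the reversed sequences gives every suffix. `compute_hsr_split()` therefore
  evaluates all *n* − 1 splits at the cost of two alignments. The engine is
  compiled (Rcpp); ties are broken deterministically toward the smallest
  reference start, then query start.
* **Candidacy is gated before scoring.** Only unclipped reads with at least
  3 differences from the reference (mismatches plus indel *events*; an
  indel of any length counts once) enter the split search. Raw single-read
  HSR realignment is overwhelmingly noisy — most splits of most imperfect
  reads suggest a spurious event — so individual HSRs are never trusted:
  they only ever contribute, as *virtual clips*, to the same consensus
  machinery as real clipped reads.

A reported split is converted to a virtual clip by asking which half stayed
anchored at the read's recorded position: an anchored left half is a virtual
right-clip at that half's alignment end, and symmetrically. An HSR is
emitted only when its score reaches `hsr_min_score = 8`: the split
explanation must beat the linear one by two mismatches' worth. The printed
definition puts no floor on the score, but without one every sequencing
error in a repeat would spawn a virtual clip; 8 is the smallest margin that
cannot be produced by a single mismatch.

## The calling pipeline

**Evidence scan.** Reads with a soft/hard clip ≥ 5 bp on a side are split
reads (smaller clips are treated as trimming noise); unclipped reads with
≥ 3 differences are HSR candidates. A pair is deletion-type discordant when
its insert size exceeds `max_is = μ + 3σ` (estimated from the first 100,000
proper forward–reverse pairs; σ is the population standard deviation of the
sampled insert sizes) and duplication-type when the forward read maps
downstream of the reverse read (outward orientation).

**Consensus piling.** Real and virtual clips on the same side whose clip
positions lie within `cluster_tol = 5` bp chain into a cluster; clusters
with ≥ 3 members — and at least one member with mapping quality above 0, so
multi-mapping reads never seed — emit a consensus: per-column plurality base
(ties resolved A &lt; C &lt; G &lt; T), breakpoint at the median clip
position, and an *opposite breakpoint range* derived from the members'
mates (for a right clip, `[min mate start, max mate end + max_is)`;
mirrored on the left; a mate-less cluster falls back to
`[breakpoint, breakpoint + max_is)` and is flagged).

**Junctions.** Right- and left-clipped consensuses that lie within each
other's opposite range pair up greedily by combined support; each pair is
merged through its best suffix–prefix overlap (≥ 20 bp, ≥ 90% identity —
long enough that a chance 20-mer agreement is negligible). Unpaired
consensuses are extended by greedy overlap–layout–consensus over the local
reads, capped at twice the read length of novel sequence (which also stops
runaway extension around perfect repeats) and discarded if the clipped tail
cannot reach 1.5 read lengths. Each junction is realigned by the same
all-splits machinery: the best split whose halves both anchor with ≥ 90% of
their length aligned gives `e_l` (left half end) and `s_r` (right half
start); `s_r > e_l` calls a deletion `[e_l, s_r)`, `s_r < e_l` a duplication
`[s_r, e_l)`, and events below `min_size` (default 50 bp; set 30 for the
small-indel mode that complements small-variant callers) are dropped. Calls
are precise and left-aligned: while the base preceding the start equals the
base preceding the end, the interval shifts left, so repeat-internal events
get a canonical representation. Duplication copy number is deliberately not
estimated; a DUP record denotes the duplicated reference span.

**Discordant module and merge.** Same-kind discordant pairs are compatible
when both their left ends and their right starts agree within `max_is`;
single-linkage groups of ≥ 3 pairs emit imprecise candidates. A deletion
takes the inner gap `[max left-read end, min right-read start)`. For a
duplication the analogous inner formula is empty in the typical geometry —
each outward pair's forward read starts *downstream* of its reverse read's
end, and both reads lie inside the duplicated span — so the call takes the
outer hull of its supporting reads instead. When an imprecise call matches
a precise one under the imprecise comparison parameters, only the precise
call survives.

**Features and filtering.** For each candidate the pipeline collects the
insert sizes of bracketing pairs (deletion: forward read ends at/before the
start, reverse read starts at/after the end; duplication: outward pairs
around the interval, re-expressed as `μ + (forward start − reverse end)` so
that the same machinery applies — the outward span is zero-expected under
the null). Under the null these are modelled i.i.d. Normal(μ, σ), giving a
shift estimate, a 95% CI (`± 1.96 σ/√n`) and an upper-tail p-value. This
normal-tail formulation is this package's concrete instantiation of
insert-size testing; heterozygous events mix shifted and unshifted pairs,
which halves the effective shift and costs power — accepted and documented
rather than modelled. Per-candidate p-values are features; no genome-wide
multiplicity correction is applied. Depth features average coverage (mapq
≥ 20) over the event and over flanks of `max(2·read_len, 300)` bp.

Filtering uses a class-balanced 200-tree probability forest over the
feature set when a trained model is supplied (`rf_train()` /
`rf_apply()`, PASS at probability ≥ 0.5), and otherwise hard filters: (i)
≥ 3 split-plus-hidden or ≥ 3 discordant supports; (ii) p ≤ 0.05 *or* a
precise call whose junction realigns at a score ratio ≥ 0.9; (iii) for
events ≥ 300 bp, depth consistency (deletion ≤ 0.75×, duplication ≥ 1.25×
the mean flank depth). Clause (ii) matters for small duplications: a
duplication shorter than the insert size produces no outward pairs at all,
so its p-value carries no information and the junction quality must carry
the call.

## Comparison, clustering and the ES score

Two same-type events match when start and end distances are within
*max distance*, the shorter event is overlapped over at least *min
overlap*, and the lengths differ by at most *max length difference* —
(100 bp, 0.8, 100 bp) when both records are precise, (500 bp, 0.5, 500 bp)
when either is imprecise. Inside a shared tandem repeat (each event ≥ 90%
covered by the same annotated interval) any copy of the unit may be
reported, so only the length criterion applies. Duplications are matched
against insertion-style records by requiring the insertion site within
*max distance* of either duplication boundary and a local alignment of the
inserted sequence against ⌈i/d⌉ concatenated copies of the duplicated
sequence covering ≥ 80% of it. Both inputs are left-aligned before
comparison. Multi-sample catalogues are clustered by a deterministic
clique-cover heuristic: events sorted by start grow the current clique
while compatible with *all* its members, else open a new one — every
cluster is a clique by construction; the representative takes member-wise
median coordinates. Repeat-aware comparison is switched off during
clustering, mirroring how large catalogues are merged in practice.

The *expected support* (ES) score asks how discoverable an event is in
principle: build the reference window `r_ref` (event ± 2000 bp) and the CNV
allele `r_cnv` (event applied), enumerate every positioned read of length
*l* strictly straddling a breakpoint of `r_cnv`, and report the fraction
aligning strictly better to `r_cnv` than to `r_ref`. Reads are positioned —
equal sequences at different offsets count separately, matching how
sequencing samples positions — the enumeration is error-free (ES is a
property of the alleles, not of a sequencer), and ties count against
support. Full-unit events in perfect repeats give ES = 0 exactly, provided
the read length does not exceed the remaining repeat span. For unique
random junctions ES approaches 1 but can dip slightly below it: a read
grazing the junction by one or two bases ties on the reference whenever the
neighbouring base coincides by chance (probability ~1/4 per base of
overhang). The same strict-inequality definition makes
`classify_read_support()` (SPLIT if clipped on `r_ref` only; HSR if
unclipped but strictly better on `r_cnv`) consistent with ES:
supporting = SPLIT ∪ HSR.

## The simulator: what it emulates and what it does not

`simulate_dataset()` produces a random contig with tandem-repeat arrays
(each copy independently mutated from the unit at the `divergence` rate, so
two copies differ at ≈ 2·divergence of positions — the knob is a per-copy
substitution rate, the standard simulator parameterisation), plants
non-overlapping deletions/duplications (heterozygous on one haplotype,
homozygous on both, with donor-to-reference block maps retained), and draws
fragments with Normal(μ, σ) lengths to the target coverage, injecting
substitution errors at a constant rate. Reads inside one collinear block
map directly. Reads spanning a block boundary — a CNV junction — go through
an aligner emulation that mirrors the behaviour that creates hidden split
reads: the best *full-length ungapped* placement at any donor-implied
anchor competes with the best per-segment clipped placement, and clipping
wins only when it beats the full placement by more than `clip_margin = 8`.
The margin equals the caller's `hsr_min_score`, so the simulated aligner
and the caller draw the clip/no-clip line identically. Real short-read
aligners do not open SV-sized gaps inside a read, so gapped full placements
are not modelled.

Not emulated: base-quality profiles (the method never uses qualities),
indel sequencing errors, GC or coverage bias, chimeric fragments,
multi-mapping reads (all records carry mapq 60; the mapq-0 consensus rule
is exercised by constructed unit tests instead), and real repeat family
structure. Consequently, passing the planted-truth experiments demonstrates
the correctness of the evidence definitions, the consensus/junction
machinery and the statistics under the stated generative model — not
performance on real data, where noisy or unsequenceable breakpoint regions
are a major additional loss mode.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run the same experiment designs,
chosen once as the package's study conditions: 1 Mb contigs, 30× total
coverage, 150 bp reads, μ = 400, σ = 50; events planted homozygous so that
expected evidence counts are deterministic functions of coverage. The
unique-junction regime plants 30 deletions and 30 duplications of 60–2000
bp (log-uniform) in non-repetitive sequence; recovery is scored with the
precise parameter set and split-supported calls are required to reproduce
planted breakpoints exactly after left-alignment. The hidden-split regime
plants full-unit events on *interior* copies of 60–120 bp arrays with 5–7
copies and per-copy divergence uniform in 0.02–0.05: interior placement
keeps the junction's homologous continuation longer than a read, the regime
in which split reads cannot exist and hidden split reads are the only
breakpoint evidence; the same dataset re-called with the HSR module
disabled provides the ablation. A 0%-divergence array provides the negative
control (ES exactly 0; no clipped or HSR-candidate reads near the event).
Calibration uses 1000 null replicates (type-I error at α = 0.05) and 500
shifted replicates with 20–40 spanning pairs (CI coverage). Smaller
per-operation fixtures (reads ≤ 150 bp, windows ≤ a few kb) back the
brute-force oracle comparisons, with Smith–Waterman scores independently
cross-checked against Biostrings' implementation.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open internally and converted at the VCF
boundary (POS is the 1-based base preceding the event, REF that base, ALT a
symbolic allele; END is the 1-based inclusive end, which numerically equals
the 0-based exclusive end; SVLEN is negative for deletions; imprecise calls
carry IMPRECISE with CIPOS/CIEND = ±(max_is − read_len)). `N` never
matches. Empty local alignments score 0 with empty spans. Alignment ties
prefer the smallest reference start, then query start; plurality ties in
consensus columns follow base order; greedy pairing breaks support ties
toward smaller breakpoints. Empty callsets write header-only VCFs; an
unmapped or cross-contig mate makes a pair neutral; a contig present in the
alignments but absent from the reference is a hard error naming the contig.
Candidate events at contig edges get truncated, flagged flanks (depth) and
flanks (ES) rather than errors.

## Known limitations

Single-sample, single-threaded calling (per-contig processing is
independent, so parallelism can be added without changing results);
breakpoints in duplications longer than the read but shorter than the
fragment rely entirely on junction quality; heterozygous events lose
insert-size power (mixture not modelled); no genotype likelihoods — the
VCF reports `./.`; tumour/normal joint calling is out of scope; and the
random-forest filter ships untrained — `run_train()` builds a model from
any callset with long-read-style truth labels, and without one the hard
filters apply.
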