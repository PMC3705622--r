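---
title: "hervkit: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hervkit: models, generator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each
stage computes, under what assumptions, which tunables matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates

Internally everything is 0-based half-open. 1-based inclusive coordinates
exist at exactly two boundaries: UCSC-style display spans
(`parse_ucsc_span()` / `format_ucsc_span()`) and native RepeatMasker
`.out` rows. Having one conversion site makes the display→internal→display
round-trip testable and keeps `length = end − start` true everywhere else.

## Repeat catalog

RepeatMasker reports one row per contiguous masked segment, so a single
element disrupted by deletions, insertions, or heavily mutated stretches
appears as several fragments. The catalog stage deliberately works at the
*fragment* level by default — fragment counts and 20-bp (LTR) / 200-bp
(internal) size histograms are the primary view — because that is the
level at which the repeat-table input is defined. Element-level calls are
a separate, explicitly derived product:

* fragments sharing a RepeatMasker joining ID group together; without
  IDs, same-chromosome same-strand fragments with gaps ≤ `gap_tol_bp`
  (default 2,000 bp) cluster positionally. The default sits above typical
  masker split gaps and well below the generator's inter-element spacing;
  it is a clustering knob, not a biological constant.
* an element with internal and LTR fragments is a `provirus`; LTR-only
  elements are `solo_ltr` when they cover ≥ 50% of a full LTR
  (`ltr_full_bp = 968`) and `ltr_fragment` otherwise; internal-only
  elements are reported as such.
* overlapping same-strand fragments are merged with a warning rather than
  rejected — real tables contain them.

Catalog statistics report the real-valued mean alongside an integer
rendering. The integer rendering **truncates** rather than rounds: the
published accounting style prints 487,441/255 = 1911.53 as 1,911.
Percentages round to the nearest percent. The full-length internal
segment size is a caller-supplied parameter (≈ 7,500 bp); the
fragments-per-element ratio is `full_length / mean`, ≈ 3.9 for the
numbers above.

## Gene-context intersection

Overlap requires ≥ 1 nt (`min_overlap`, half-open arithmetic, so
adjacency is not overlap). Orientation is `same` iff locus and feature
strands are equal. Three conventions the upstream description leaves
open, fixed here:

* strandless loci (`.`) count as `same` and carry a `strandless` flag —
  they are reported, not silently dropped or guessed;
* a locus under two genes transcribed in opposite directions contributes
  one orientation count per gene (the double-counting rule);
* a locus overlapping several feature kinds of one gene yields one record
  per kind; counts are per (locus, gene) pair with no further
  deduplication.

Introns are derived as gene-minus-exons when the GTF has no intron rows.
The production implementation uses `GenomicRanges::findOverlaps`; the
test suite keeps an independent quadratic all-pairs scan and requires
exact record-set equality on random instances.

## Clone-to-locus assignment

Paralogous HERV-K loci are ~99% identical, so the assignment rule's tie
semantics matter more than its score. The score is a best local
alignment under unit match/mismatch with affine gaps (open 2, extend 1);
`N` never counts as a match. The original analysis used BLAT's "highest
identity score" without defining it; this package fixes a two-key rule:
primary key integer match count, secondary key percent identity, and a
tie requires equality of **both**. Integer comparison avoids
floating-point tie fragility; a genuine tie yields `ambiguous` with the
tied set, never an arbitrary winner. Identity below `min_identity_pct`
(default 99, after the observation that genuine clones match their locus
by > 99%) yields `below_threshold`. Both query orientations are scored
and the better kept, which makes the call orientation-invariant by
construction.

For long targets a 16-mer seeded window restricts the alignment region
(margin 150 nt); if no seed fires in either orientation the full
alignment is computed, so small or divergent inputs never lose the
exhaustive path. Queries within threshold but below 100% carry their
mismatch list (position, query base, locus base) — these are the
polymorphism-or-misincorporation calls a reviewer will want to inspect.

`diagnostic_sites()` exposes the discriminating columns by aligning every
candidate globally to the first; insertions relative to that reference
are ignored, which is acceptable at the ≥ 90% identity this operation
requires.

## Splice-junction inference

A junction is a split placement of the cDNA: a prefix ending at a donor
(first intron base) and a suffix starting at an acceptor (first exon base
after the intron), both within `search_window` (default ± 1,000 nt) of
the model's canonical sites. The implementation anchors candidate prefix
and suffix offsets with staggered 18-mers (≤ 1 mismatch) and then finds
the exact best split point from cumulative match vectors. This is
equivalent to the exhaustive search over all placements whenever the cDNA
differs from the locus by substitutions only — which is the generator's
world, and a good approximation for RT-PCR products; cDNAs with true
indels near the junction are outside the method's guarantees and would
need a gapped spliced aligner.

Numerical choices:

* **Margin.** The spliced optimum must beat the best contiguous placement
  by ≥ 8 matches (`min_margin`), preventing spurious micro-introns on
  unspliced cDNAs. The value is configurable and was chosen as clearly
  above the 1–2 match fluctuations that chance end-alignments produce.
* **Tie-breaks.** Equal-match placements are ordered by intron
  dinucleotides `GT..AG` > `AT..AC` > other, then smallest
  `|donor_offset| + |acceptor_offset|`, then leftmost donor. Junction
  shifts with identical sequence support are a real ambiguity (they occur
  whenever the base before the donor equals the base before the
  acceptor); the motif rank resolves them the way splice-site biology
  does.
* **Classification precedence.** Offsets (0, 0) → `canonical`; otherwise
  intron-starts-`GT` → `alt_major`, else the U12-type donor pattern
  `[GA]TATCC` → `alt_minor`, else `non_canonical`. The published analysis
  names a minor-spliceosome consensus without printing it; the pattern
  here is an explicit, configurable choice (`minor_donor_pattern`), and
  the acceptor dinucleotide is reported alongside but never decides the
  class.

Provirus typing aligns a locus globally to a type II reference and calls
type I only when a deletion of 292 ± 10 bp overlaps the reference's
pol–env segment; the deletion length is reported exactly, and alignments
may legitimately place the gap a few bases left or right when flanking
bases repeat.

## qPCR quantification

ΔCt = mean(reference replicates) − mean(target replicates); replicates
aggregate by arithmetic mean with no outlier rejection (none is
described for the assay this models). Fold = `efficiency^ΔCt` with
efficiency fixed at 2.0 by default (the doubling heuristic; configurable
in (1, 2]). Proviral transcripts run R-to-R and therefore carry two LTR
R-region copies per env copy, so `fold / r_copies` (default 2) is the
solo-LTR excess; values below 1 are flagged as deficits. Housekeeping
normalization reports one ΔCt per control gene, never an average. The
per-sample ΔCt is the primary quantity; the across-sample mean is
appended as a separately labelled row because the upstream description
does not say at which level its single summary figure was computed.

## The synthetic world

The generator states one world and the tests live in it:

* a type II ancestor of 9,450 bp — byte-identical 968-bp LTRs
  (U3 700 / R 110 / U5 158) around a 7,514-bp internal segment — with
  GT/AG planted at the canonical env splice sites, a 292-bp pol–env
  segment, and a U12-type donor motif (`ATATCC`, with an `AT..AC` intron
  context) planted 435 nt downstream of the canonical donor;
* each locus mutates independently from the ancestor at
  `pairwise_divergence / 2` (default 0.005) so paralog *pairs* differ by
  ≈ 1%, matching the ~99% pairwise identity of the real family;
* insertions carry 6-bp target-site duplications (`tsd_len`; a typical
  value for this family — the source material draws the duplication
  without a length);
* type I loci have the 292-bp segment excised and their internal region
  is emitted as two joined masker fragments, exactly as a masker scoring
  against a type II consensus reports them;
* fragmentation is modelled as foreign insertions into the internal
  segment of untranscribed proviruses (probability `p_insert`, default
  0.25, 100–500 bp), which split masker rows. Substitution-driven
  "recognition loss" — a plausible cause of real fragment counts — is
  **not** simulated;
* the transcript program gives every provirus a sense unspliced mRNA,
  the first type II a canonically spliced env mRNA, the first type I the
  +435/+6 alternative splice (the K60-like program), one provirus an
  antisense transcript, and every solo LTR an R-initiated transcript;
  abundances are arbitrary units with defaults 10/5/20/3;
* Ct values are `baseline − log_E(abundance) + N(0, noise_sd)`; the
  q-LTR amplicon sees `2 × (sense proviral) + 1 × solo` template copies
  and q-env sees sense proviral only. Antisense transcripts are excluded
  from qPCR abundance — the modelled assay primes with oligo-dT on
  polyadenylated sense transcripts.

Everything is deterministic given the seed; per-stage seeds derive from
it and stay below 2^31.

What a green test does establish: the pipeline recovers the generator's
truth — element kinds, clone origins (with ties only where paralogs are
genuinely identical), planted junction offsets, and programmed abundance
ratios — under substitution-only divergence and noise-free to moderate Ct
noise. What it does not establish: performance on real RepeatMasker
tables (whose fragment boundaries reflect alignment scoring, not clean
breakpoints), on cDNAs with indels or template switching, on unfixed
insertions absent from the candidate set (K113-like), or the real-genome
summary percentages, which depend on the annotation version and are
deliberately not test targets.

## Known limitations

* The junction search is single-intron; multi-intron transcripts (2×-
  spliced rec/np9-like isoforms) are out of scope.
* `diagnostic_sites()` ignores insertions relative to its reference
  candidate.
* The published fragment accounting contains an internal inconsistency
  (an LTR mean printed as 864 bp where the printed totals give 854.4);
  the package reports computed values and does not reconcile printed
  ones.
* In-silico PCR is exact-ish matching (≤ `max_mismatch` per primer) with
  no thermodynamics; it is a structural tool (band-size logic), not a
  primer-design tool.
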