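# hervkit

Locus-resolved analysis of human endogenous retrovirus K (HERV-K, HML2
subtype) repeats and transcripts.

## The problem

HERV-K(HML2) is the youngest endogenous retrovirus family in the human
genome: over a thousand loci ranging from solo LTRs to near-intact
proviruses, with paralogous loci roughly 99% identical to one another in
pairwise comparisons. That near-identity makes the two questions this
package addresses genuinely hard:

1. **Which locus did a transcript come from?** A cDNA read matches many
   loci; only the handful of single-nucleotide differences between
   paralogs (diagnostic sites) identify the locus of origin.
2. **What does the repeat landscape actually look like?** RepeatMasker
   reports one row per contiguous masked segment, so a provirus disrupted
   by deletions or insertions appears as several fragments that must be
   accounted for — and solo LTRs, which outnumber proviruses by more than
   10:1, turn out to dominate LTR-region transcription.

`hervkit` implements the full computational chain for these questions as
a tested R package: repeat-table parsing and fragment accounting,
orientation-aware intersection with gene models, best-identity clone
assignment with an explicit tie rule, splice-junction inference with
canonical/alternative site classification, type I/II provirus typing via
the 292-bp pol–env segment, and ΔCt-based quantification of solo-LTR
transcript excess — plus a fully seeded synthetic-genome generator that
emulates this world with complete ground truth.

## The statistics at the core

* **Highest-identity assignment.** A clone is scored against every
  candidate locus by best local alignment (unit match/mismatch, affine
  gaps open 2 / extend 1, both orientations). The call is the argmax of
  integer match count, then percent identity; an exact tie on both keys
  is reported `ambiguous`, never forced; identity below 99% is
  `below_threshold`.
* **Splice junctions.** For a spliced cDNA, the donor (first intron base)
  and acceptor (first exon base after the intron) maximize total prefix +
  suffix matches within ±1 kb of the canonical sites; ties break by
  intron dinucleotides (`GT..AG` > `AT..AC` > other), then proximity to
  the canonical sites. Offsets are signed, downstream-positive — the
  K60-style alternative junction reads (+435, +6). Donors are classed
  against the major (`GT`) and minor/U12 (`[GA]TATCC`) spliceosome
  consensus.
* **Provirus typing.** Type I proviruses lack a 292-bp segment spanning
  the pol–env boundary; `detect_type()` finds it as a 292 ± 10 bp
  alignment deletion overlapping the segment.
* **Solo-LTR excess.** With ΔCt = mean Ct(env) − mean Ct(LTR) and
  amplification base E, fold = E^ΔCt. Proviral mRNAs carry two LTR
  R-region copies per env copy, so `fold / 2` is the LTR signal beyond
  what proviral transcription explains.

## Worked example

```r
library(hervkit)

## Fragment accounting: 255 internal fragments totalling 487,441 bp
stats_from_totals(255, 487441, 7500)
#> 255 fragments, 487,441 bp total
#> mean length 1911.5 bp (~1911), 25.5% (~25%) of full length, ~3.9 fragments/element

## UCSC display coordinates are 1-based inclusive; internally 0-based half-open
interval_length(parse_ucsc_span("1q22:155,596,457-155,605,636"))
#> [1] 9180

## A synthetic world with ground truth, and junction recovery on its
## alternatively spliced (K60-like) transcript
world <- plant_loci(sim_config(seed = 1))
cdnas <- transcribe(world)
tr <- world$truth$transcripts
alt <- tr[which(tr$spliced & tr$donor_offset != 0), ][1, ]
jx <- find_junction(cdnas[[alt$transcript_id]],
                    world$truth$models[[alt$locus_id]])
jx[c("donor_offset", "acceptor_offset", "ss_class")]
#> $donor_offset    [1] 435
#> $acceptor_offset [1] 6
#> $ss_class        [1] "alt_minor"

## A 7.2-cycle LTR-vs-env delta-Ct
f <- fold_change(7.2)              # 147.0, i.e. >= 100-fold
solo_ltr_excess(f)$excess          # 73.5-fold beyond the 2 R copies/mRNA
```

Interpretation: the mean internal fragment is ~25% of a full-length
internal segment (fragmentation), the junction inference recovers the
planted +435/+6 minor-spliceosome junction exactly, and a 7.2-cycle ΔCt
implies ~147-fold more LTR than env template — a ~74-fold excess over
what proviral transcripts alone would give, i.e. abundant solo-LTR
transcription.

## Command line

```sh
inst/cli/hervkit catalog   --rmsk rmsk.tsv --out out/
inst/cli/hervkit assign    --clones clones.fa --candidates loci.fa --out out/
inst/cli/hervkit end-to-end --seed 42 --out out/
```

## Vignette

`vignettes/hervkit-methods.Rmd` documents the models, the synthetic
world's assumptions, numerical choices, and known limitations.
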