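---
title: "Comparative mitogenomics of conspecific honeybee trios: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics of conspecific honeybee trios: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotrio)
```

## The problem

Honeybee (*Apis mellifera*) subspecies differ by only a handful of sites
across their ~16.4 kb circular mitochondrial genomes. Characterising a new
assembly therefore means: transferring a trusted reference annotation onto
it, finding the few dozen variable sites relative to close relatives,
classifying each site by where it falls (protein-coding gene, tRNA, rRNA,
control region, intergenic spacer) and by its sharing pattern (unique to
the new genome, or shared by the conspecific pair against the other
subspecies), predicting which coding changes alter a protein, and placing
the genome among relatives with distance-based methods. `mitotrio`
implements that workflow end to end and, because the interesting claims
are about *recovering sparse planted signal*, ships a synthetic-trio
generator whose ground-truth ledger makes every stage falsifiable without
any downloads.

## The data model

A `MitoGenome` is a circular uppercase `{A,C,G,T,N}` sequence plus an
ordered feature table (1-based inclusive spans; a span with `end < start`
wraps the origin; classes `PCG`, `tRNA`, `rRNA`, `control`, `intergenic`;
strands `light`/`heavy`). Coordinates are 1-based inclusive throughout —
both at the GenBank interface and internally — because R's string and
vector semantics are 1-based; all wrap-aware span arithmetic is tested in
both directions. GenBank flat files are parsed and written directly
(LOCUS/FEATURES/ORIGIN; `join(x..N,1..y)` becomes a wrapped span;
ambiguity codes other than `N` are rejected, since the genomes this
package targets are unambiguous). If a record leaves the control region
unannotated, the longest unannotated gap (if ≥ 200 bp) is synthesised as
`control_region`, making region tallies reproducible; the inferred span
absorbs any unannotated spacer adjacent to the true control region, which
is the correct behaviour for a parser that cannot know the missing
boundary.

## Alignment

Conspecific mitogenomes are globally alignable at ≥ 99.5 % identity, so
the package uses a banded global aligner with affine gaps (Gotoh's three
states, C++ core). Defaults: match +2, mismatch −3, gap open −6, gap
extend −1, a gap of length *L* scoring `open + L·extend`. These values
keep one indel (−7) cheaper than two substitutions (−10 vs two matches),
which is the right prior for organelle DNA; any sensible scheme produces
the same alignment at this identity away from the AT-rich control region.
The band half-width defaults to 300 columns around the anchor diagonal —
an order of magnitude above the largest observed length difference
between these genomes (control-region polymorphism, ~120 bp) — and
doubles automatically (to a cap of 2400) whenever the optimal path
touches the band edge; hitting the cap raises a classed error rather
than returning a possibly suboptimal path.

After alignment every gap run is shifted maximally leftward while the
aligned residue pairs it touches are preserved (the VCF left-alignment
convention). Site counts in this problem are sensitive to where an
aligner puts an indel inside an AT microsatellite; fixing one normal form
makes event coordinates reproducible across runs and aligners.

**Circularity.** All alignment happens on rotated linearisations. The
annotated reference is rotated so that the first gene downstream of the
control region starts at position 1, keeping the hypervariable control
region intact at the sequence end; other genomes are rotated to the
reference by exact k-mer anchoring (k = 31, successive reference seeds
tried when a seed is mutated).

**Anchored merge.** Pairwise alignments sharing the reference are merged
into one column space. At a junction where several pairs insert columns
(the reference lacks material), the insertions *share* columns
left-aligned, padded right, rather than being interleaved pair-by-pair:
when the reference carries a deletion relative to both other genomes the
retained residues are homologous, and sharing columns is what lets the
event be called once, with the correct sharing pattern, instead of
fragmenting into per-pair artefacts. This is the one place the package
deliberately chooses the standard reference-anchored-merge behaviour over
a plausible alternative (strict interleaving), and it is load-bearing for
event recovery.

## Annotation transfer

Feature endpoints are mapped through the alignment column maps; endpoints
landing in target gaps snap inward to the nearest aligned column. A
projected span shorter than half its reference length is declared failed
— mirroring how liftover tools drop short tRNAs with weak alignment
support — and failed features are re-sought by a small glocal alignment
(global in the feature, free ends in a ±600 bp target window), placed if
identity ≥ 0.85. That threshold is a package default, configurable,
chosen as a round value safely below the ≥ 99 % identity of true
homologs and above what random AT-rich sequence achieves; the tool whose
behaviour this mirrors does not publish its internal threshold.

Overlap curation implements the manual rules used for honeybee
mitogenomes: a light-strand PCG running into a downstream tRNA is trimmed
back to a truncated stop (T/TA, completed to TAA by polyadenylation) when
one is available in frame at the tRNA boundary — the cox1 case — and the
known atp8/atp6 overlap (19 bases) is whitelisted. Trims that would break
the ORF are aborted and logged. The operation is idempotent.

## Translation

NCBI table 5 (invertebrate mitochondrial: AGA/AGG → Ser, ATA → Met,
TGA → Trp) is taken from `Biostrings::getGeneticCode("5")`; the
start/stop conventions are implemented here: initiators rendered as `M`
with the raw codon (ATN) preserved for the start-codon survey, full stops
TAA/TAG, and coding lengths ≡ 1 (mod 3) ending `T` or ≡ 2 ending `TA`
accepted as polyadenylation-completed stops. Internal stops raise an
integrity error naming the codon, because in this pipeline they always
mean misannotation or frameshift, not biology.

## Event calling and classification

In the three-row anchored MSA every non-unanimous column belongs to
exactly one event: residue-only columns are single-site substitutions;
maximal runs of columns sharing one gap pattern coalesce into one indel
event. The sharing pattern is a pure function of the allele triple
(target first): `unique_target`, `unique_other*`, `diagnostic_pair`
(target + conspecific vs the third genome), `all_distinct`. Coding
effects translate the containing codon *from each genome's own sequence*
(strand-aware, positions mapped through the MSA), so indel-shifted
coordinates cannot corrupt the codon; events at start/stop codons or with
codon extraction crossing a feature edge are reported as `boundary`
rather than guessed. Amino-acid changes are reported as
(comparator → target): for unique-target events the comparator is the
agreeing pair, for diagnostic events the differing third genome —
matching the convention of reading changes as
"other-subspecies-like → new-genome-like".

Tallies count one multi-base indel as one site by default (`count_mode =
"event"`); published tallies of this kind sometimes count columns
instead, so `"column"` is available and reports weigh each event by its
column span. Both modes are exact recounts of the same event list.

## Distances and group delimitation

Distances operate on MSA rows under pairwise deletion (columns gapped or
`N` in either row of a pair are dropped). With gamma-distributed rate
variation (shape α):

* Jukes–Cantor: `d = (3α/4)·[(1 − 4p/3)^(−1/α) − 1]`, which at α = 1
  simplifies to `p/(1 − 4p/3)` and at α → ∞ to `−(3/4)·ln(1 − 4p/3)`;
* K80: `d = (α/2)·[(1−2P−Q)^(−1/α) −1] + (α/4)·[(1−2Q)^(−1/α) −1]` with
  transition/transversion proportions P, Q, reducing to the familiar
  logarithmic forms at α → ∞.

The gamma transforms are computed with `expm1`, which matters at large α
where the exponent is tiny: convergence to the plain model is O(1/α)
(about 3.6×10⁻⁸ at α = 10⁶ and p = 0.2 — an exact series gap, not
rounding — and below 10⁻⁹ from α ≈ 10⁸). `p ≥ 3/4` (or the analogous K80
saturation) raises an error rather than returning NaN. The
implementations are cross-checked in the tests against `ape::dist.dna`,
which is never used as the computation path.

Automatic Barcode Gap Discovery is implemented as a documented
formulation of the published method's recursion: sort the pairwise
distances, find the first jump exceeding `X · max(d_below, P)` where P is
the prior maximal intraspecific distance and X the relative gap width
(default 1.5, the method's canonical default), split the samples into
connected components of the sub-gap graph, and recurse inside components
of at least 3 samples. The original software's exact sliding-slope
heuristic is not published as a closed formula; this formulation keeps
its defining properties, which the tests assert: determinism, label-order
invariance, one group on gap-free matrices, and partitions that only
coarsen as the prior grows.

## The mitotype marker

The classic lineage marker is the intergenic stretch between the
tRNA-Leu gene adjacent to cox1 and the start of cox2. The marker is
defined here as purely intergenic — `[tRNA-Leu end + 1, cox2 start − 1]`
— with an option to include the tRNA, since amplicon conventions in the
literature vary. Which tRNA-Leu copy flanks cox2 is resolved from an
`anticodon=UUR` note when the annotation carries one; otherwise the copy
nearest downstream of cox1 is used and the result is flagged. The DraI
digest cuts every `TTTAAA` between the third T and first A; fragment
lengths always sum to the marker length. Naming mitotypes (e.g. "C2e")
requires comparison against named reference haplotypes in an external
database and is out of scope; the package outputs sequence and profile.

## The synthetic generator

`makeBase()` builds a 16,447 bp circular genome in the *A. mellifera*
arrangement: 13 PCGs with valid table-5 ORFs (start codons assigned to
reproduce the canonical tally of one ATC, three ATG, three ATA, six ATT;
TAA stops except cox1, which ends on a truncated T), 22 tRNAs of 63–78
bp, two rRNAs (1371 and 786 bp), an AT-rich 945 bp control region, and
realistic intergenic spacers including a 96 bp mitotype marker carrying
two DraI sites. The atp8/atp6 19-base overlap is generated jointly so
both reading frames are clean, and tRNA-Leu1 begins `TTTAA` so that the
cox1 curation scenario (an apparent in-tRNA TAA behind a truncated T) is
constructible from every base genome. Base composition targets 85 % AT
(draws at A .43 / T .42 / C .095 / G .055; control region A .50 / T .46),
matching the strong AT bias of these genomes; at 16.4 kb the realised AT
fraction lands within ±1 % of target.

`makeTrio()` plants events into three copies of the base: unique-target
events mutate the target only, diagnostic events mutate the third genome
only (so the conspecific pair keeps the ancestral allele), each verified
against table 5 at generation time (missense plants must change the
amino acid without creating a stop; synonymous plants are third-position
exchanges within a synonymous family). The default plant spectrum
mirrors the observed comparison of a Slovenian/Austrian carnica pair
against ligustica: 44 unique events (16 PCG, of which 8 missense; 3
tRNA; 8 rRNA including one 4 bp rRNA deletion; 10 control region
including length-polymorphism indels; 7 intergenic) and 23 diagnostic
events (8 PCG, of which 3 missense; 2 tRNA; 5 rRNA; 4 control region; 4
intergenic including one 2 bp deletion). Indels are re-drawn until their
placement is unambiguous under left-normalisation (flanking base differs
from the run's last base), events keep ≥ 15 bp spacing and stay ≥ 6 bp
inside feature boundaries, and every genome receives a recorded random
rotation. The ledger stores each event's coordinates in all three
genomes, its expected pattern and effect, the rotations, and the truth
feature tables — the oracle for the recovery tests.

What the generator does *not* emulate: recombination (absent in
mitochondria), rate heterogeneity along the molecule beyond the planted
spectrum, sequencing error, heteroplasmy, and the deep AT-microsatellite
ambiguity of real control regions (planted indels deliberately avoid
ambiguous context, because a site count is only well-defined relative to
a normal form; real control-region alignments are noisier than anything
the recovery tests certify). Passing the recovery suite therefore shows
the pipeline is exact on clean sparse signal, not that real control
regions align unambiguously.

## Problem sizes and budgets

The test suite runs 20 full trios (16.4 kb genomes, two banded
alignments each) for the recovery property, 50 random 300 bp pairs
against an unbanded dynamic-programming oracle for the aligner, a 0–0.49
grid for the distance closed forms, and constructed 9–14 sample matrices
for the delimitation properties; the whole suite completes in well under
five minutes on one CPU. `scripts/acceptance.R` recomputes the headline
quantities on 5 fresh trios per run. These sizes are the package's
choice of a thorough-but-quick default; all generators scale by
argument.

## Known limitations

* Real-data tallies (totals like 64/59 sites) depend on the aligner
  dialect in the AT-rich control region; this package fixes one dialect
  (banded + left-normalisation) and exposes both site-counting modes,
  but column-exact concordance with any particular published alignment
  is not promised — event-level concordance is the designed contract.
* Heavy-strand PCG/tRNA overlap curation mirrors the light-strand rule
  set only; no such case occurs in these genomes.
* The ABGD implementation is a documented reformulation, not a port; on
  pathological distance distributions (continuous gradients) it returns
  one group rather than attempting slope estimation.
* Mitotype naming against haplotype databases, tRNA secondary structure,
  and tree inference are out of scope.
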