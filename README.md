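# mitotrio

Comparative analysis of closely related circular mitochondrial genomes,
built for the honeybee (*Apis mellifera*) case: a newly assembled
~16.4 kb mitogenome compared against two close relatives (its
conspecific and the reference subspecies genome), with the handful of
variable sites found, classified and interpreted.

Subspecies-level honeybee mitogenomics turns on a few dozen sites in a
genome of ~16,400 bp. The questions a practitioner asks are always the
same: where does each variable site fall (protein-coding gene, tRNA,
rRNA, AT-rich control region, intergenic spacer)? Is it unique to the new
genome or shared by the conspecific pair against the other subspecies
(a diagnostic site)? Which coding changes are missense under the
invertebrate mitochondrial code (NCBI table 5: AGA/AGG → Ser, ATA → Met,
TGA → Trp)? How far apart are the genomes under standard distance models,
and do distance-based methods delimit the expected groups?

`mitotrio` implements that workflow end to end:

* **I/O** — GenBank flat files (wrapped origin-spanning features,
  heavy-strand `complement()` locations) and FASTA; base composition and
  per-position region classification.
* **Alignment** — a banded global aligner with affine gaps (C++ core,
  automatic band doubling), VCF-style left-normalisation of gap runs,
  exact k-mer rotation anchoring of circular sequences, and a
  reference-anchored multiple-alignment merge.
* **Annotation transfer** — projection of a reference feature table
  through the alignment, rescue of dropped short features by local
  re-alignment, curation of PCG/tRNA overlaps to truncated stop codons
  (T/TA completed by polyadenylation; the cox1 case), with the known
  atp8/atp6 19-base overlap whitelisted.
* **Variant discovery** — every non-unanimous alignment column assigned
  to exactly one event (substitution or coalesced indel), classified by
  region and sharing pattern, with strand-aware codon translation from
  each genome's own sequence for missense/synonymous calls.
* **Distances & delimitation** — p, Jukes–Cantor and K80 distances with
  gamma rate variation (`d_JC = (3α/4)[(1−4p/3)^(−1/α)−1]`, which at
  α = 1 is `p/(1−4p/3)`) under pairwise deletion, and Automatic Barcode
  Gap Discovery partitioning given a prior maximal intraspecific
  distance.
* **Mitotype marker** — extraction of the tRNA-Leu/cox2 intergenic
  marker and its in-silico DraI (`TTTAAA`) restriction profile.
* **Synthetic trios** — a seeded generator building honeybee-like
  genomes (valid table-5 ORFs, canonical start-codon tally, truncated-T
  cox1, atp8/atp6 overlap, 85 % AT) and planting a realistic spectrum of
  unique/diagnostic events with a ground-truth ledger, so the whole
  pipeline is testable offline.

## Worked example

```r
library(mitotrio)

base <- makeBase(seed = 1)                      # honeybee-like 16,447 bp genome
trio <- makeTrio(base, seed = 1)                # plant 44 unique + 23 diagnostic events
res  <- runTrioPipeline(trio$genomes$SIC,       # target (new assembly)
                        trio$genomes$ATC,       # conspecific
                        trio$genomes$REF)       # annotated reference

res$target_annotated
#> MitoGenome 'SIC': 16444 bp, circular, 38 features
#>   PCG: 13, tRNA: 22, rRNA: 2, control: 1, intergenic: 0

res$tallies$pair_totals
#> SIC|ATC SIC|REF ATC|REF
#>      44      67      23

table(res$events$pattern, res$events$region_class)
#>                   control intergenic PCG rRNA tRNA
#>   diagnostic_pair       4          4   8    5    2
#>   unique_target        10          7  16    8    3

round(res$distances, 5)
#>         SIC     ATC     REF
#> SIC 0.00000 0.00250 0.00385
#> ATC 0.00250 0.00000 0.00134
#> REF 0.00385 0.00134 0.00000
```

The target genome differs from its conspecific at the 44 planted
unique-target sites and from the reference subspecies at all 67 planted
events; the conspecific pair differs from the reference at the 23
diagnostic sites. Eight of the unique PCG substitutions are missense
(e.g. `nd2` position 1397, L → W) and three of the diagnostic ones, all
verified against the generator's ledger. Jukes–Cantor distances with
gamma shape 1 under pairwise deletion sit at the few-per-thousand scale
typical of conspecific honeybee mitogenomes. The mitotype marker and its
restriction profile come from the transferred annotation:

```r
mk <- extractMarker(res$target_annotated)
draiProfile(mk$seq)$fragments
#> [1] 53 43

codonUsageSurvey(res$target_annotated)$starts
#> ATA ATC ATG ATT
#>   3   1   3   6
```

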