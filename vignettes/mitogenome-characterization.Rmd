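---
title: "Methods: characterizing a circular mitochondrial genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a circular mitochondrial genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

This vignette records the models, conventions and numerical choices
behind each stage of the pipeline, in the spirit of a methods section:
what is computed, under which assumptions, and where the design was
genuinely open, why it was resolved the way it was.

## Coordinates and annotation model

All coordinates are 1-based and inclusive, the convention of GenBank
flat files and published mitogenome tables. A feature on the minor
strand ("R" in printed tables) is stored with its major-strand
coordinates and reverse-complemented on extraction, so `start <= end`
always holds except for origin-spanning features, which are expressed
with `end > genome_length` on a circular molecule. This keeps published
tables representable verbatim — including their occasional anomalies.
`validate_annotation()` deliberately *reports* rather than repairs:
declared-size/coordinate mismatches, origin spanning, census deviations
from the canonical 13 PCG / 22 tRNA / 2 rRNA / 1 control region, and
out-of-vocabulary names are all returned as records. Published tables
do contain such anomalies (the shipped example annotation has two
declared sizes that disagree with their own coordinates, and an
intergenic cell that disagrees with the adjacent coordinates by 1 bp),
and downstream judgement, not silent correction, is the right response.

Gene names are normalized on read (ND1 → nad1, COI → cox1, 16S → rrnL,
D-loop → control_region, isoacceptor decorations stripped), since
GenBank dialects vary widely.

## Composition and skews

Skew is the classical strand-asymmetry statistic, AT skew =
(A − T)/(A + T) and GC skew = (G − C)/(G + C). Because it is a ratio of
linear combinations, counts and percentages from the same sequence give
identical values; a zero denominator yields `NA`. Partition statistics
are computed on the concatenation of each class's *gene-strand* (sense)
sequences in table order — the convention under which published
per-class rows are computed — with `partition_strand = "major"`
available as the alternative, since sources rarely state the choice.
Overlapping genes contribute their full spans to their class, matching
the sizes such tables print; N bases count toward length but are
excluded from composition denominators.

Rounding is presentation-only and half-away-from-zero (2 dp for
percentages, 3 dp for skews), via `round_half_up()`; internal values
stay at full precision. One consequence worth recording: recomputing a
published skew column from *printed* percentages (2 dp) can differ from
the published skew (computed from raw counts) by one unit in the third
decimal — the propagated rounding error of the inputs is up to about
0.0015 for a GC skew at ~20% G+C. The test suite therefore checks the
shipped 17-species table to one printed ulp, and the focal-species
values (which reproduce exactly) at full 3 dp equality.

## Codon usage

The invertebrate mitochondrial code (NCBI table 5, via Biostrings) has
62 sense codons and stops TAA/TAG only; AGA/AGG encode Ser, ATA Met,
TGA Trp. Families carry the conventional mitochondrial split labels
Leu1 = CTN, Leu2 = TTR, Ser1 = AGN, Ser2 = TCN. RSCU follows the
standard observed/family-mean definition; empty families give `NA`
rather than 0, and the mean-RSCU-equals-1 identity per nonempty family
is enforced in tests with an independent per-family loop.

Start codons are *included* in codon counts (they are sense codons, and
standard tools count them); incomplete stop remnants (a trailing T or
TA, completed to TAA by post-transcriptional polyadenylation) are
excluded, as are complete terminal stops, which are tallied separately.
A CDS whose frame remainder and terminal bases disagree (e.g. length
divisible by 3 but no terminal TAA/TAG) classifies as "unresolved"
rather than erroring — annotation tables do produce such cases, and two
of them exist in the shipped example annotation, where printed spans of
two genes are ≡ 1 (mod 3) although a complete TAA stop is printed. An
internal in-frame stop, by contrast, is an error naming gene and codon,
because every downstream count would be wrong.

## Junction ledger and gene order

The ledger assigns each adjacent pair the gap `next.start − prev.end −
1`; negatives are overlaps, zero abutting, positives spacers. On a
circular genome the wrap junction is computed modulo the genome length
but excluded from summaries by default, as are junctions involving the
control region — matching how published overlap/spacer censuses are
tallied (their control-region cells are printed as "—"). Both
exclusions are arguments. A `use_declared` mode reproduces a table's
printed intergenic column verbatim where it disagrees with its own
coordinates, so both the printed census (e.g. a 205 bp spacer total)
and the coordinate-derived one (206 bp) are available and clearly
distinguished.

Gene-order comparison uses rotation-invariant adjacency sets on the
circle; the breakpoint count is the number of observed adjacencies
absent from the reference. Unsigned adjacencies are the default because
the rearrangement of interest here (trnM-trnI-trnQ vs the ancestral
trnI-trnQ-trnM) is an order change, not an inversion; a strand-aware
variant is behind `signed = TRUE`. No rearrangement-distance
optimization (DCJ, inversion distance) is attempted.

## tRNA cloverleaf folding

The folder is an exhaustive, deterministic search over arm-boundary
placements, not a free-energy minimization: acceptor stem 6–7 pairs
(target 7), D stem 0 or 2–4 (a 1-bp helix is not a stem; 0 models the
D-armless state of mitochondrial trnS1(AGN)), anticodon stem fixed at 5
pairs around a 7-nt loop with the anticodon at loop positions 3–5,
T stem 2–5, spacers of 1–2 and 0–1 nt, variable region up to 9 nt,
0–2 unpaired 3′ nt. T is treated as U for pairing. Scores are WC +2,
G·U wobble +1, tolerated in-stem mismatch −1 (all configurable with the
invariant wc > wobble > 0 > mismatch); the admissible boundary space
for a 60–80 nt gene is a few thousand vectors after the length
constraint, so enumeration is exact and fast. Ties are broken by the
lexicographically smallest boundary vector, making refolds
bit-identical. One representational subtlety: when the D stem is empty,
the spacer/loop split is unidentifiable, so D-armless structures are
canonicalized to the minimal spacer. A structure whose acceptor stem
has fewer than six paired positions is flagged `non_cloverleaf` rather
than rejected.

Mismatches are tolerated *inside* stems at a penalty rather than forced
into bulges, which is how mitochondrial tRNA structure reports count
them (e.g. a U-U opposition in an acceptor stem is reported as an
in-stem mismatch, not a bulge). The anticodon decodes as the
translation of its reverse complement under table 5, labelled with the
family splits (so GCT → AGC → Ser1).

## Control-region scanners

All scanners are exact and definitional, so every hit re-validates by a
direct substring or identity check. Motif search reports all (possibly
overlapping) exact occurrences, optionally on both strands. Poly-tracts
are maximal runs with a default minimum of 10 nt — long enough to be a
feature, short enough to keep an unannotated poly-A "element"
detectable. Microsatellites are maximal *perfect* repeats of a
primitive 1–6 nt unit with ≥ 5 copies, reported once per tract at the
leftmost phase with the unit in canonical (lexicographically smallest)
rotation, so an alternating stretch is "(AT)n", never "(TA)n".

The tandem-repeat finder is deliberately simpler than alignment-based
tools: for each period p it chains maximal runs of offset-p matches
across short gaps while the ungapped identity stays ≥ 0.9, emits every
chain prefix as a candidate, and merges overlapping reports keeping the
highest identity (then longest span, then smallest period). There are
no indels in the model; a repeat with an insertion will score as two
shorter repeats. This suffices for the presence/period/copies questions
these regions are scanned for, and it admits a crisp brute-force
cross-check: for exact (identity-1) repeats the chained definition
coincides with "maximal interval where s[k] = s[k+p] with span ≥ 2p",
which the tests verify with an independent quadratic scanner, alongside
no-hit agreement on random regions and recovery of planted exact and
single-mismatch duplications.

## Distance phylogeny

The supermatrix concatenates the 13 PCGs in a fixed canonical order,
trimming incomplete-stop remnants so each block is a whole number of
codons; per-gene sequences must be equal-length across taxa (true by
construction for synthetic families; real data must be aligned
externally first — no aligner is bundled). Distances (p, JC69, K2P) and
neighbor joining are delegated to ape, the field-standard
implementation; the package adds the mitogenome plumbing, flags pairs
with undefined log corrections (setting them to the maximum observed
distance plus one rather than propagating NaN), clamps the small
negative branch lengths NJ can produce on non-additive matrices to
zero, and computes bootstrap support by seeded column resampling.
Tests hold this stage to independent oracles: closed-form p/JC69/K2P
values on constructed pairs, exact recovery of random additive 6–10
taxon matrices (path-length matrices of the NJ tree must equal the
input exactly), and JC branch-length recovery within three standard
errors on seeded simulations. Maximum-likelihood tree search is out of
scope by design: a distance method with a bootstrap is reproducible at
desk scale and honest about what it is.

## The synthetic-data generator

The generator exists because the pipeline needs a genome whose every
feature is known. It emulates the study conditions of a typical
lepidopteran mitogenome: a ~15.4 kb A+T-rich (~80%) circle with the
full 37-gene complement, the derived trnM-trnI-trnQ order, the real
overlap geometry (including the 7 bp atp8/atp6 and 8 bp trnW/trnC
overlaps), a CGA-started cox1, incomplete stops where the coordinate
frames require them, ten planted G·U wobble pairs across ten tRNAs
plus a U-U acceptor-stem mismatch in trnA, a conserved ATACTAA spacer
motif, and a control region carrying ATAGA + 18 bp poly-T + (AT)8 +
poly-A (optionally with planted exact duplications for the
tandem-repeat tests).

Assembly is constraint-driven: PCG start/stop codons are imposed on the
genome first (strand-aware), then features are generated left to right,
each honouring already-written bases. This is what makes the real
overlap geometry work — atp6's ATG lives inside atp8, whose stop lies
inside atp6's first codons, exactly as in real genomes — and it means
the recorded codon tally is exact: the census recount equals the
generator's tally identically, which the tests assert.

Codon draws use a stationary AT-biased distribution with weight
∝ (codon A+T fraction)^γ. γ = 2.5 by default: the weight calculus gives
an expected PCG A+T of ≈ 0.75 at γ = 2 and ≈ 0.785 at γ = 2.5, and only
the latter, combined with partition-typical A+T levels for the
non-coding classes (tRNA 0.82, rRNA 0.84, spacers and control region
0.94), lands the whole genome at the ~80% condition being emulated.
This also makes the AT-rich amino acids (Asn, Ile, Leu2, Lys, Tyr, Phe)
the most frequent and leaves a handful of GC-rich codons rare or
absent, as in real AT-rich mitogenomes.

Planted tRNAs are built arm-by-arm at deterministic boundaries with
Watson–Crick stems, and the generator actively protects the planted
fold's optimality: stem 5′ sides never repeat a base within distance
two (so ±1/±2 shifted pairings cannot score as WC), D-loop boundary
bases and the inter-arm spacer bases are chosen to mismatch the
positions a one-step stem extension would recruit, and D-armless tRNAs
get an unpairable poly-A D region. Without these guards an AT-rich stem
is shift-tolerant and the enumeration finds spurious equal-or-better
structures; with them, planted-boundary recovery is 199/200 on random
fixtures (the residual case is an exact score tie in the variable
region/T-loop trade, resolved by the deterministic tie-break against
the planted vector). Two genome tRNAs whose acceptor ends are
overwritten by neighbouring gene overlaps may fold with shifted
boundaries; the end-to-end test therefore requires ≥ 20 of 22 exact
recoveries, and the census tests read the recorded ground-truth
structures.

Tree mode evolves the root genome along a rooted tree under
Jukes–Cantor on all sites (per branch of length b, each site mutates
with probability 3/4(1 − e^{−4b/3}), uniformly to the other bases).
Annotation coordinates are preserved, so per-gene homology is
positional. There is no selection, no strand-asymmetric mutation
spectrum, no indels, and no rate variation — deliberate, because the
distance-recovery tests need a known model. Consequently, passing
tests demonstrate correctness of the *computations*, not robustness to
alignment error, annotation error or model misspecification in real
data.

What the generator does not emulate: real lepidopteran sequence
content (it is a stand-in for genomes with no available reference
sequence), realistic mutation spectra, heteroplasmy, or control-region
length variation. The synthetic template keeps the layout of the
shipped reference annotation but is internally consistent where that
printed table is not:
coordinate spans are used as sizes (so the printed nad4 1339 becomes
1343), the two frame-inconsistent TAA stops become incomplete stops,
and the circle is closed at 15,370 bp so the control region ends
exactly at the origin.

## Problem sizes and runtime choices

The shipped tests run the folder's planted-recovery contract at 200
fixtures, microsatellite brute-force equivalence at 200 random regions
up to 500 nt, tandem-repeat brute-force agreement at 40 random regions
up to 300 nt, NJ additivity at 8–18 random matrices of 6–10 taxa, and
JC recovery on full-genome two-taxon simulations — sizes chosen so the
complete suite runs in well under a minute per heavy file while keeping
every statistical band (95% recovery, 3 standard errors) meaningful.
Bootstrap examples use 30–50 replicates in tests; analyses of real data
should use the conventional 1000.

## Known limitations

* Annotation is an input; there is no similarity-based gene finding.
* The folder models cloverleaf geometry only — no free energies, no
  covariance models; unusual tRNAs beyond a missing D arm (e.g. missing
  T arms) will fold as flagged best-effort structures.
* The tandem-repeat model is ungapped; indel-containing repeats are
  under-reported relative to alignment-based tools.
* The phylogeny stage is distance-based by design and assumes
  pre-aligned, equal-length per-gene blocks.
* Composition partitions double-count overlapping spans, matching the
  printed convention rather than a strict partition of the circle.
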