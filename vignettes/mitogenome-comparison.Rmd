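---
title: "Comparative analysis of fragmented mitochondrial genomes with mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of fragmented mitochondrial genomes with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The problem

Animal mitochondrial genomes are usually compact, AT-rich circles with a
conserved 37-gene complement. Calanoid copepod mitogenomes break most of these
expectations: assemblies of 27-29 kb split over two to six contigs, non-coding
regions (NCRs) so long that they dominate the sequence, overall AT content
close to that of the nuclear background, negligible strand asymmetry, repeated
and missing tRNA genes, and gene orders so reshuffled that congeneric species
differ by several rearrangement events. `mitocomp` packages the analyses this
situation requires: strand-aware coordinate handling on circular and
fragmented contigs, compositional skew statistics, codon-level accounting
under the invertebrate mitochondrial code, distance estimation with bootstrap
errors, rearrangement inference on signed gene orders, repeat profiling of the
NCRs, and read-level k-mer characterization of the nuclear background.

## Coordinate and strand conventions

Internally every feature is a 0-based half-open interval on the forward strand
of its contig; on disk the GFF3 subset uses the standard 1-based inclusive
convention. Features that span the origin of a circular contig are encoded
with `start > end` plus a `circular_wrap=true` attribute — a documented
dialect, since plain GFF3 has no native way to express a wrap (and interval
containers that enforce `start <= end` cannot represent one). The strand given
in the FASTA record is "forward"; the *heavy* strand is defined operationally
as the strand with the greater G+T content, matching how strand asymmetry is
discussed for these genomes. `N` bases are allowed but excluded from every
compositional count.

## Compositional statistics

AT skew is `(A − T)/(A + T)` and GC skew `(G − C)/(G + C)`. A zero denominator
yields `NA`, never 0: a skew of 0 is a meaningful observation (perfect
balance), absence of the two bases is not. Both skews flip sign under reverse
complementation, a property the test suite asserts on random sequences.
Sliding windows default to 300 bp, anchored with the first window starting at
position 0 (the anchoring is configurable; window centers are reported).
On circular contigs windows may cross the origin, giving `ceiling(L/step)`
windows; linear profiles have `floor((L − width)/step) + 1`.

The strand molecular-weight difference uses average residue masses of the
deoxyribonucleoside monophosphates (dAMP 313.21, dCMP 289.18, dGMP 329.21,
dTMP 304.20 g/mol). The constants are arguments, because published values of
this statistic rarely state whether average or monoisotopic masses were used;
the defaults reproduce hand-calculated examples to 3 decimals.

## Codon accounting and neutral sites

Under NCBI translation table 5, `AGA`/`AGG` encode serine and `TGA`
tryptophan; only `TAA`/`TAG` are stops. Mitochondrial CDS often end in `T` or
`TA`, completed to `TAA` by polyadenylation of the transcript; `classify_stop()`
detects this from length mod 3 together with the trailing bases, and
`aa_chain_length()` implements the bookkeeping rule: a complete stop costs one
codon (`bp/3 − 1` residues), an incomplete stop costs nothing
(`floor(bp/3)`). When only printed lengths are available,
`stop_status_from_length()` infers status from the length remainder alone.
When both a sequence and an annotation are present and disagree, the sequence
wins and the conflict is logged.

A third codon position is four-fold degenerate when its codon family (first
two bases) encodes one amino acid for all four completions; under table 5 this
includes `AGN` (all serine), which standard-code intuitions miss. We
deliberately implement the strict family-based definition, not a per-site
usage-weighted one, and never pool two-fold degenerate families. The GC skew
at these neutral sites is computed on each gene's own sense strand ("native
direction"); for a minus-strand gene this equals minus the skew of the
complementary forward-strand bases, which is the property the tests assert.

Relative standard deviations use the sample (n−1) standard deviation over the
mean, as a percentage, rounded half away from zero to 2 decimals. The
population SD was considered and rejected: it fails to reproduce the published
per-gene values the package ships (`calanus_cds_table()`), e.g. giving 0.35
instead of 0.41 for *atp6*.

## Distances

p-distances are uncorrected mismatch proportions after *complete deletion*
(every alignment column containing `-` or `?` in any row is removed; `?` is
treated exactly like a gap). Standard errors come from a site bootstrap:
columns resampled with replacement, 1000 replicates by default, with the SE
taken as the standard deviation of the replicate distances. The bootstrap is
reproducible bit-for-bit given a seed, and the RNG state is isolated so the
caller's random state is untouched.

The built-in aligner is plumbing, not a contribution: linear-gap
Needleman-Wunsch with deterministic tie-breaking (diagonal, then gap-in-B,
then gap-in-A). Affine gaps are out of scope; real studies align with
dedicated tools and the package consumes any gap-aware alignment through
`alignment_block()`. Sliding-window distance profiles report coordinates in
alignment space, not sequence space, since windows are placed on the aligned
columns.

## Gene orders and rearrangements

Gene orders are signed circular permutations normalized to an anchor gene
(*cox1*, forward) — published genome maps draw circles without a stated
origin, so an explicit anchor makes orders comparable. The breakpoint distance
counts signed circular adjacencies of one order absent from the other; each
transposition, reversal or reverse transposition changes at most three
adjacencies, giving the lower bound `ceiling(bp/3)` used to prune the event
search. The event vocabulary is limited to those three classes; tandem
duplication random loss is excluded as it is not needed for the genomes this
package models.

`infer_events()` is an iterative-deepening search with breakpoint pruning and
children ordered by resulting breakpoint distance; it is a heuristic with an
exactness certificate only where the exact oracle (`bfs_min_events()`, a
bidirectional breadth-first search, feasible to about 10-12 genes and depth 4)
confirms it — the acceptance suite checks agreement on hundreds of planted
instances. Every returned solution is replayed onto the source order and
asserted to reproduce the target exactly; events act on the anchored
linearization, so a block spanning the origin is represented by its
complement.

The 4-taxon `parsimony_scenario()` proposes internal-node orders from the
intersection of radius-`k` event balls around each cherry's leaves and
minimizes the total event count over the five tree edges. The ball radius
defaults to `k = 1`: materializing radius-2 balls costs on the order of 10^5
states even for 8 genes, while radius 1 already recovers star-like scenarios
(one event per leaf) exactly and keeps the candidate enumeration small. `k`
is a parameter for users who need deeper proposals on tiny gene sets.

## Repeats and dotplots

Tandem arrays are maximal runs of period `u <= max_unit`, found by comparing
the sequence against itself shifted by `u`; units are reported in canonical
(lexicographically smallest) rotation so `TA` and `AT` describe the same
locus once, and arrays whose unit is a multiple of a shorter reported unit at
the same locus are merged. A fractional trailing copy counts when it covers at
least half a unit. Dotplot matching is exact and word-based (default word 11),
in both orientations, with word hits merged into maximal diagonals — mismatch
tolerance is deliberately out of scope, matching the word-dotplot methodology
standard in sequence-manipulation suites. Terminal palindromes (inverted
repeats within each terminal window of a contig, the signature of fragmented
mitochondrial chromosome ends) reuse the reverse-orientation word machinery.

## k-mer profiles and genome size

K-mers are counted canonically (minimum of forward and reverse complement), so
histograms are invariant to read orientation; k defaults to 21, the
conventional choice for short-read genome profiling, and k-mers containing `N`
are skipped. The genome-size estimator finds the largest local maximum of the
3-bin-smoothed histogram at multiplicity at least 4 (excluding the low-copy
slope); the size is `total_kmers / peak_multiplicity`. The smoothing exists
because desk-scale histograms are noisy bin by bin; requiring the peak to beat
both neighbours after smoothing avoids spurious one-bin maxima. A monotone
decreasing histogram returns an explicit `no_nontrivial_maximum` status — the
expected outcome when coverage is far below what the (possibly very large,
repeat-rich) genome requires — rather than a fabricated size. The pg→bp
conversion uses 1 pg = 0.978×10⁹ bp.

## The synthetic-data generator

`simulate_genome()` emits an annotated genome that emulates the structure
described above: the 13 CDS at their published lengths (so the three genes
whose lengths are not divisible by 3 — *cytb*, *nd1*, *nd5* — get incomplete
stops), rRNA genes of 1125 and 656 bp, 22 tRNA genes of 65 bp, genome-wide AT
content 58.3%, three long internal NCRs each carrying a planted TATA tandem
array, and terminal NCRs carrying planted inverted repeats. CDS are valid
table-5 reading frames; their base-sampling probabilities are adjusted
(by solving for the pre-rejection AT level) so that rejecting stop codons
does not pull the realized genome AT below target. All randomness flows from
one seed through a single RNG stream in a documented order, so outputs are
byte-identical across runs. `diverge_pair()` applies uniform (Jukes-Cantor
style) substitutions — the p-distances being estimated are model-free, so the
simplest substitution process suffices — and records realized per-gene
divergence as truth. `simulate_reads()` draws error-free, uniformly placed,
randomly oriented reads.

What the generator does *not* emulate — indels, sequencing error,
selection-shaped codon usage, heterogeneous substitution rates, assembly
artefacts — bounds what green tests mean: they validate the statistics and
search algorithms against exactly known truth, not the upstream steps
(assembly, annotation, multiple alignment) that real data would add.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to exercise the mathematics
rather than throughput: search-oracle agreement on 500+ planted instances
over 8 genes, divergence recovery (within 3 bootstrap SEs in at least 95 of
100 seeded pairs at p = 0.05-0.2 over 2 kb), genome-size recovery within 10%
from 50-fold error-free 150 bp reads of a 20 kb circular genome, and 2000-odd
assertions of the unit-level invariants. Ties in the event search are broken
deterministically (fewest events, then ordered move encoding); degenerate
inputs (empty alignments after complete deletion, zero-denominator skews,
histograms with no interior maximum) return explicit errors, `NA` markers or
statuses rather than silent zeros.

## Known limitations

The event search is exponential in the bound and practical only for small
event counts; multi-contig gene orders are concatenated in declared contig
order with fragment boundaries recorded, so adjacencies across joins are
provisional; the aligner is linear-gap only; k-mer counting is in-memory and
meant for mitogenome-scale read sets, not full nuclear runs; and model-based
distance corrections, tree inference and repeat classification are
intentionally outside the package's scope.
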