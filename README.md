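# mitocomp

Comparative analysis of fragmented, repeat-rich mitochondrial genomes in R.

Calanoid copepods (genus *Calanus*) carry the longest mitogenomes known among
copepods: 27-29 kb assemblies split over several contigs, with unusually long
non-coding regions (NCRs) that are not AT-rich, TATA microsatellite arrays,
inverted repeats at contig ends, incomplete stop codons completed by transcript
polyadenylation, and heavily reshuffled gene orders. `mitocomp` implements the
full comparative toolbox this kind of genome calls for, end to end, with a
deterministic synthetic-genome generator so every stage can be validated
against planted truth.

## What it computes

* **Composition** — AT skew `(A−T)/(A+T)` and GC skew `(G−C)/(G+C)` whole-genome
  and in sliding windows (default 300 bp), heavy-strand G+T content, and the
  relative molecular-weight difference between strands.
* **Codon accounting** under the invertebrate mitochondrial code (NCBI table 5,
  `AGA`/`AGG` = Ser, `TGA` = Trp): incomplete stop detection from length mod 3
  (`T`/`TA` tails), amino-acid chain lengths (`bp/3 − 1` for a complete stop,
  `floor(bp/3)` otherwise), four-fold degenerate sites and the neutral-site GC
  skew per gene, and relative standard deviations (sample SD / mean, %).
* **Distances** — uncorrected p-distances with complete deletion of gapped
  columns, site-bootstrap standard errors (1000 replicates), per-gene and
  concatenated alignments, and sliding-window distance profiles (300 bp / 10 bp).
* **Gene order** — signed circular orders anchored at *cox1*, breakpoint
  distances, a shortest-event search over transpositions, reversals and reverse
  transpositions (with an exact BFS oracle for small instances), and a 4-taxon
  parsimony scenario.
* **Repeats** — tandem arrays (canonical units), terminal inverted repeats,
  exact word-based dotplot matches in both orientations.
* **Reads** — canonical k-mer histograms (default k=21), genome-size estimation
  from the coverage peak, per-read GC distributions, pg→bp conversion
  (1 pg = 0.978×10⁹ bp) and coverage ratios.
* **Simulation** — annotated mitogenomes with planted gene orders, divergence,
  repeats and read sets, deterministic per seed.

## Worked example

```r
library(mitocomp)

cfg <- sim_config(seed = 42,
                  planted_events = list(list(kind = "reversal", block = c(4, 8))))
sim <- simulate_genome(cfg)
build_genome_report(sim$genome)
#> <genome_report> sim
#>   contigs: 22533 (total 22,533 bp)
#>   AT 58.6%, GC 41.4%, heavy-strand (forward) G+T 50.1%
#>   strand weight difference 0.030%
#>   13 CDS (3698 aa total), 3 with incomplete stops
#>   22 tRNA genes; 5 NCR(s) >= threshold

gB <- diverge_pair(sim$genome, 0.05, seed = 43)      # 5% per-site divergence
g0 <- simulate_genome(sim_config(seed = 42))$genome  # same genome, no reversal
build_comparison_report(g0, gB, seed = 44)
#> <comparison_report> sim vs sim_div
#>   concatenated aa p-distance 0.1109 +/- 0.0053 (3698 sites)
#>   rrnL nt p-distance 0.0418 +/- 0.0061
#>   rrnS nt p-distance 0.0595 +/- 0.0095
#>   breakpoint distance 2 (with tRNA) / 2 (without)
#>   gene-order scenario: 1 event(s)
#>   dotplot: 1056 match(es), longest 149 bp
```

Reading the output: the simulated genome reproduces the published CDS length
roster, so its 13 protein genes sum to 3698 amino acids, three of them ending
in incomplete stops. After planting one block reversal and 5% nucleotide
divergence, the amino-acid p-distance over the concatenated, gap-free
alignment is ~0.11 (nucleotide changes hit ~2/3 of codons non-synonymously),
the reversal shows up as a breakpoint distance of 2, and the event search
recovers it as a single reversal.

Published accounting from printed tables ships with the package:

```r
tab <- calanus_cds_table()
cg  <- tab[tab$species == "glacialis", ]
sum(aa_chain_length(cg$bp, stop_status_from_length(cg$bp)))
#> [1] 3698
```

A thin command-line wrapper with `simulate`, `report`, `compare`,
`kmer-hist`, `genome-size` and `gene-order` subcommands is installed under
`exec/mitocomp`.

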