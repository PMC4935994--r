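---
title: "Satellitome discovery by iterative clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellitome discovery by iterative clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satkit)
library(tibble)
library(dplyr)
```

## The problem

Satellite DNA (satDNA) consists of a single unit — the monomer — tandemly
repeated many times. A genome typically carries not one but dozens of
distinct satDNA families, collectively its *satellitome*. Finding them from
low-coverage short-read data is hard for two reasons. First, graph-based
read clustering can only hold a few hundred thousand reads at a time, so a
single clustering run only surfaces the most abundant repeats. Second, once
an abundant family dominates the read pool, rarer families hide below the
minimum cluster size at any affordable sampling depth.

satkit implements the iterative answer to both problems: cluster a read
sample, call consensus monomers for the satellite-like clusters, then
*subtract* every read matching anything found so far and cluster a fresh,
larger sample. Each round strips the read pool of known repeats, so the
same clustering capacity is spent on progressively rarer families, until a
round discovers nothing new. Families are then classified into
variants/families/superfamilies, named by decreasing abundance, and
quantified by aligning reads back against the catalog.

## The pipeline, stage by stage

### Quality filtering

`trim_and_filter_pairs()` mirrors the Trimmomatic options
`LEADING:3 TRAILING:3 SLIDINGWINDOW:4:20 MINLEN:<read length>` but keeps a
pair only when *neither* mate would be trimmed at all: every retained read
keeps all of its nucleotides. This full-length-only rule is what makes
abundance denominators exact — every retained read contributes exactly
`read_len` nucleotides. A window mean of exactly 20 passes (Trimmomatic
cuts strictly below the threshold). Only Phred+33 input is accepted;
files that look Phred+64 are rejected with an error rather than silently
mis-scored. N bases carry whatever quality the FASTQ assigns them.

### Read graph and cluster selection

`build_read_graph()` places an edge between two reads when their best local
alignment — on either strand — reaches 90% identity over at least 0.55 of
the shorter read. These defaults follow the published defaults of the
clustering stage this emulates. An exact canonical 13-mer prefilter decides
which pairs are worth aligning; at these thresholds a true edge shares a
13-mer with near certainty (a 55-bp overlap at 90% identity leaves mismatch
gaps averaging ten times the word size), so the prefilter is an
optimisation, not a change of definition.

Connected components become clusters. Density is the mean number of links
per read, `2E/V`; we read the published gloss of "density" literally as
mean degree and expose the `0.1` selection threshold as configuration.
Shape matters because tandem repeats produce characteristic cluster
geometries: monomers much shorter than the read give near-complete
"globular" balls; monomers between one and two read lengths give ring-like
graphs (reads connect only to phase-neighbours around the monomer circle);
single-copy sequence covered by chance gives elongated, path-like
components. `classify_shape()` checks ring first — the 2-core must be a
single cycle covering at least 80% of nodes — because a cycle's
diameter-to-size ratio is exactly the 0.5 linear cutoff and would otherwise
be caught by the linear rule; everything neither ring nor linear
(normalised diameter `D/V >= 0.5`) is globular. For clusters too large for
an exact diameter (over 2000 reads) a double-BFS eccentricity estimate is
used; it is tight on the path-like graphs where the linear call matters.
Candidate clusters are the globular or ring ones with density strictly
above 0.1.

### Contigs, periods and consensus monomers

`assemble_cluster_contig()` grows a contig greedily from the highest-scoring
dovetail overlaps. The subtle point is alignment mode: a tandem read aligns
*anywhere* along a tandem contig, so an ordinary local alignment happily
places it fully inside the tail and never extends. We therefore use a
tail-anchored alignment (best alignment forced to end at the contig's end)
so reads take the dovetail placement. Array-edge reads carry flanking
sequence that would poison the tail and stall extension; when extension
stalls the assembler rolls the last junction back and tries the next
candidate, so contigs run along the array and stop cleanly at its edge.
Contigs are capped at 1.5 kb — enough for several copies of any monomer
up to 400 bp — and ordered by the number of reads they absorbed.

`detect_tandem_period()` is a numeric stand-in for the dotplots used when
this protocol is run by hand: the smallest shift at which the contig
matches itself ungapped at 70% identity, provided it spans two periods.
The smallest-period rule resolves nested periodicities (a dimer repeat
reports the monomer, not the dimer). The ungapped comparison assumes
copies have not drifted by indels; the simulator's indel-free default
matches that assumption, and real arrays with frequent indels would need
the threshold lowered.

`consensus_monomer()` takes the per-column majority over the stacked
monomers, dropping columns that are gaps in more than half the rows and
breaking ties by the fixed base order A < C < G < T. Monomers cut from one
contig are equal-length, so the stack needs no alignment; unequal-length
copies are first projected onto the modal-length copy by global alignment.
Every consensus is reported in canonical rotation — the lexicographically
smallest string over all rotations of both strands — so the same satellite
discovered at a different phase or on the other strand compares equal.

### The mining loop

`satminer_loop()` samples each iteration's pairs from the *unused* pool
(reads already seen are not resampled), subtracts everything known, and
clusters the rest. Subtraction references are concatenated monomers:
dimers by default, more copies for short monomers until the reference
strictly exceeds 200 bp — "exceeds" read strictly, so a 100-bp monomer gets
three copies. A pair is dropped when either mate matches any reference at
90% identity over 90% of its length. Non-tandem contigs from candidate
clusters enter a custom repeat database that is subtracted alongside the
satellites; this keeps recurring non-satellite repeats (and, at higher
coverage, stochastic background clusters) from being re-examined every
round.

A candidate consensus is *new* only if its rotation/strand-normalised
identity to every known satellite is at most 95%; matches above 95% but
below 100% merge into the known family as a variant. A cluster needs at
least 10 reads before a consensus is attempted — below that, period calls
are unreliable. The loop stops at the first iteration that adds nothing,
or reports non-convergence if the schedule runs out first.

### Classification and nomenclature

`group_catalog()` applies the published identity tiers — same variant above
95%, same family above 80%, same superfamily when a significant but weaker
alignment exists — with single-linkage closure, the only choice that makes
grouping independent of input order. Both thresholds are strict
inequalities. "Significant" similarity for superfamilies is operationalised
as at least 50 aligned bp at 60% identity between doubled monomers (the
doubling makes the local alignment rotation-safe); the source protocol
records "all matches" from its masking tool without stating a floor, so
the floor is configurable. Families are named
`<Abbrev>Sat<NN>-<length>` in decreasing abundance order, ties broken by
longer monomer then lexicographic sequence, so naming is a deterministic
bijection.

`build_mst()` links variants by substitutions plus indel *events* — a
3-bp indel is one change, with its nucleotide count reported separately on
the edge. The alternative reading (every gap column a change) is available
via `indel_unit = "nt"`.

### Quantification

Reads are aligned locally against the concatenated-monomer library on both
strands; within a read, hits are accepted greedily by score, discarding
hits overlapping an accepted one by more than half their length. Each
hit's transition proportion `P` and transversion proportion `Q` are
counted over non-gap columns, and divergence is the Kimura 2-parameter
distance `K = -1/2 ln((1-2P-Q) sqrt(1-2Q))`. Hits outside the model's
domain would be flagged saturated and excluded from means; in practice the
65% identity floor keeps `2P+Q` far from saturation. Family abundance is
the summed aligned nucleotides of all the family's variants over the total
sampled nucleotides, as a percentage — genome proportion — and the repeat
landscape bins that abundance by 1% of divergence, so young, homogeneous
amplifications pile up near zero. Landscape bin sums reproduce the family
abundances exactly.

`scan_assembly()` applies the same alignment to assembly contigs through
3-kb windows (800 bp overlap, hits deduplicated by interval union), scoring
per family the number of contigs with at least 200 aligned bp and the
maximum number of repeats per contig (aligned nucleotides over monomer
length, rounded down).

### Random-occurrence control

`dinucleotide_shuffle()` is an Euler-path shuffle: the sequence is a walk
on the 4-vertex graph whose edges are its dinucleotides; a random
arborescence of last-exit edges towards the terminal base (sampled by
loop-erased random walks) plus a random permutation of the remaining edges
yields a new Eulerian walk. Length, first and last base, and all 16
dinucleotide counts are conserved *exactly* — the invariant the
random-occurrence control depends on. Runs of N split the sequence into
independently shuffled segments. `random_occurrence()` shuffles each
contig, rescans against the library, and reports how often each family's
signal arises from composition alone; short monomers (8-15 bp) appear by
chance in genome-scale sequence, long monomers essentially never do.

### Satellitome statistics

`satellitome_summary()` reproduces the table-level statistics from an
annotation table: cluster-location totals, clusters per family and per
chromosome, the monomer-length dichotomy, the abundance-contig rank
correlation, the clustered-vs-non-clustered contig comparison, and the
chromosome-specific family count. Two operationalisations deserve note.

*The length gap.* The distribution of monomer lengths in the shipped
locust table is bimodal, and the published reading is the gap *dividing
the families into two groups*. The literal largest gap between consecutive
distinct lengths is not that: a single 400-bp family sits 101 bp from its
nearest neighbour. `length_distribution()` therefore takes the largest gap
whose two sides each hold at least `max(2, ceiling(0.05 n))` families; on
the locust working set this is the 37-bp gap between 90 and 127 bp,
splitting 26 short from 32 long families.

*Which abundance pairs with contig counts.* The draft-genome contig counts
in the table come from the Northern-lineage individual, so the
abundance-contig correlation uses the Northern abundance column by default
(`abundance_col = "ab_nl"`); the Southern column gives a visibly different
coefficient because the two genomes differ in which rare families they
carry. Missing abundances (families absent from one lineage) are treated
as zero and flagged in the documentation. The Mann-Whitney statistic is
reported as `min(U1, U2)` with half-credit ties, the classical two-sided
convention.

## What the simulator does and does not emulate

`simulate_genome()` plants tandem arrays into an i.i.d. random background
at exact target proportions: clustered families as one large array,
scattered families as many arrays below the 1.5-kb cytological visibility
threshold, every copy independently substituted at the family's per-copy
divergence. `simulate_reads()` draws uniform fragments with
truncated-normal insert sizes (defaults 226 ± 81 bp, floored at the read
length), both strands, independent substitution errors, and flat qualities
consistent with the error rate.

The truth table is exact by construction, which is what makes recovery
tests sharp. The price is realism: the background has no gene structure,
GC isochores, transposable elements or segmental duplications; copy
mutation is substitution-only by default (an optional flag adds indels at
a tenth of the substitution rate would break the exact-accounting
invariant and is off); there are no higher-order repeat structures; and
quality strings carry no instrument error profile. Passing recovery tests
therefore demonstrates the *algorithmic* chain — clustering, subtraction,
consensus, quantification — not robustness to every artefact of real
libraries. Conversely, nothing in the pipeline exploits simulator
regularities: all thresholds are the protocol's published or documented
defaults.

## Study sizes and numerical choices

Desk-scale runs use a 1-Mb genome with an abundant (1%) and a rare
(0.02% — a single 200-bp locus) family, sampled at 3,000 pairs for the
first round and 25,000 for later rounds of 2 × 100 nt reads. The later
depth is a power choice: a read joins the rare family's cluster when at
least 55 bp of it lie in the 200-bp array, so 50,000 reads put the
expected informative count near 10 (the cluster floor) from array
homology alone, and the locus's genomic neighbourhood — which merges into
the same component at this coverage — roughly doubles it, keeping the
miss probability at the percent level rather than a coin flip. The first
round stays shallow so the rare family genuinely sits below the floor
there — the situation the iterative protocol exists for. Because a
rare-family cluster absorbs neighbouring single-copy reads, its contig
can carry flanking sequence that dilutes whole-contig periodicity; the
mining loop therefore also scans contig windows and crops to the periodic
segment, which mirrors what a human does with a dotplot. Quantification
checks use planted proportions of 0.1/1/5% at 40,000 pairs, where
counting noise on the rarest family is a few percent. The landscape check
plants 5% per-copy divergence in a family sized to yield a few thousand
hits (4% of 300 kb at 30,000 pairs): per-hit divergence over ~100
aligned bp has a standard deviation above 2 percentage points, so the
binned mode is only stable once thousands of hits are pooled. Reads are
simulated error-free there so the mode isolates copy divergence; with
1%-error reads the mode shifts up by about one bin, which is expected
behaviour, not a defect.

Alignment scoring is match +2, mismatch −3, gap open −5, gap extend −2
throughout; identities are matches over alignment columns. Rotation
handling picks the best-scoring rotation by a score-only pass, then
computes statistics from a single full alignment of that rotation.
Sampling and simulation take explicit integer seeds and restore the
caller's RNG state; reruns with equal seeds are identical to the byte.

## Known limitations

- Period detection is ungapped; arrays whose copies drift by indels need a
  lower shift-identity threshold or will be missed.
- The greedy assembler targets tandem arrays; it is not a general-purpose
  assembler and caps contigs at 1.5 kb.
- At read-pool coverages above ~1× of a small genome, chance overlap
  clusters of unique sequence pass the density/shape gate; they cost time,
  are caught by the tandem-structure test, and end up in the subtraction
  database, but they are the reason mining runs are sampled shallow
  relative to the genome.
- Superfamily linking uses the single best local alignment between two
  monomers; diverged members linked only through a chain of intermediates
  are found (single linkage), but a superfamily whose members share no
  50-bp alignable core at all will not be.
- `scan_assembly()` reports aligned nucleotides by query-interval union;
  overlapping variant hits are not double-counted, but columns deleted
  from the query are invisible to the per-contig totals.
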