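---
title: "Detecting chromosomal fusion-with-mixing from macrosynteny"
author: "karyofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal fusion-with-mixing from macrosynteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyofuse)
```

## The problem

Chromosome fusions followed by intra-chromosomal rearrangement — *fusion
with mixing* (FWM) — interleave the genes of the two partner chromosomes
beyond any realistic chance of reversal. A shared FWM character is
therefore a strong synapomorphy: if two lineages show the same pair of
ancestral chromosomes fused *and mixed*, the event predates their split.
This logic is central to karyotype evolution in coleoid cephalopods,
where octopodiform genomes (~30 chromosomes) and decapodiform genomes
(~46 chromosomes) must be connected by some history of fusions or
fissions, and where draft (sub-chromosomal) assemblies of key taxa force
the inference to be robust to fragmentation.

karyofuse implements the full inference chain:

1. mutual-best ortholog placements from protein-to-genome mapping output,
   collected into pairwise synteny tables (`.psynt`);
2. chromosome-homology tests (one-sided Fisher exact, Bonferroni);
3. a contig-level co-occurrence test for FWM on draft assemblies;
4. a sequence-turbulence statistic quantifying the *degree* of mixing;
5. a karyotype-evolution simulator providing ground truth for all of the
   above;
6. Oxford-grid dotplots and machine-readable reports.

## Mutual-best orthologs and .psynt tables

A single reference peptide set is mapped (externally, e.g. with a spliced
protein aligner) to each genome. `bestPlacement()` keeps, per peptide,
the highest-scoring placement iff it passes an identity floor (default
0, i.e. off) and a uniqueness guard: the second-best score must be at
most `scoreRatio` (default 0.9) of the best, and exact ties always drop
the peptide. An ortholog pair is then the (best-in-A, best-in-B)
placement pair of one peptide (`buildPsynt()`). This construction is
deterministic and auditable; both guards are arguments.

Positions are interval midpoints, but the positional currency downstream
is the *ordinal gene rank* within each scaffold (ties broken by ortholog
id): the statistics of interest are order statistics, and ranks compare
genomes whose physical sizes differ twenty-fold. Scaffolds with fewer
than 15 orthologs are dropped (`filterScaffolds()`); sparser contigs
carry too little syntenic signal to classify. With `side = "both"` the
filter iterates to a fixed point, so it is idempotent.

Internal coordinates are 0-based half-open everywhere; GFF3 input is
converted once at the boundary, BED is taken as-is.

## Homology tests and fusion counting

`sharedOrthologMatrix()` cross-tabulates orthologs per scaffold pair.
Each cell is collapsed to a 2×2 table (on both scaffolds / on one / on
the other / elsewhere) and tested with the one-sided exact
hypergeometric tail P(X ≥ a) — every hypothesis here is an enrichment
hypothesis, so the "greater" side is used throughout. Bonferroni
correction runs over the number of cells of the filtered matrix, and
edges with adjusted p < 0.05 form the homology graph.

Reference-chromosome fates follow from graph topology
(`chromosomeFate()`): `one_to_one` (single exclusive partner), `fused`
(a partner shared with another reference chromosome), `split` (several
exclusive partners), `unplaced` (no partner). `countFused()` counts
reference chromosomes participating in at least one fusion.

For draft query assemblies, chromosome-level fates are unavailable; the
contig-level route (`cooccurrenceFwmTest()`) instead asks whether the
orthologs of two reference chromosomes land on the *same set* of query
contigs: contigs are classified by presence (≥ 1 ortholog) of each
reference, and the 2×2 presence table is Fisher-tested one-sided at an
uncorrected 0.05 (a `correct` flag enables Bonferroni over pairs). Note
the asymmetry, which is intrinsic and intended: the co-occurrence test
detects *mixed* fusions — a sharp fusion contributes only the single
boundary-spanning contig and stays invisible — whereas chromosome-level
counting detects both. The exact 2×2 construction for draft assemblies
is this package's normative choice; it is one of several constructions
compatible with published descriptions of the approach.

## The turbulence statistic of mixing

A derived scaffold is read as the sequence of ancestral-chromosome
labels of its genes, in gene order (`labelSequence()`). Run-length
encoding gives the spell states and durations (`dssEncode()`); the
composite is

$$T(x) = \log_2\!\Big(\varphi(x)\,\frac{s^2_{max} + 1}{s^2 + 1}\Big)$$

with $\varphi(x)$ the number of distinct subsequences of the spell-state
sequence (empty subsequence included), $s^2$ the *population* variance
of spell durations, and $s^2_{max} = (d - 1)(1 - \bar t)^2$ its maximum
over duration configurations with the same spell count $d$ and mean
$\bar t = n/d$ (attained by concentrating all excess in a single spell).
$\varphi$ is computed by the standard recurrence
$\varphi_i = 2\varphi_{i-1} - \varphi_{j-1}$ (previous occurrence $j$)
in exact arbitrary-precision integer arithmetic — the count overflows
doubles beyond ~1500 spells — and only the final $\log_2$ leaves integer
space.

Normalization is min–max with explicit, attainable endpoints:
$T_{min}$ is the single-spell sequence of the same length (always 1) and
$T_{max}$ the strictly alternating sequence of the same length over the
observed alphabet. Constant sequences map to 0, alternating ones to 1.
Published analyses of this statistic use a sequence-analysis package
whose normalization mode is not printed; reproduction of specific
published values therefore hinges on that equivalence, and the
normalization here is pluggable (pass a function as `normalization`).
Orientation only: a sharp 100+100 fusion scores ≈ 0.10, the regime of
published sharp-translocation values (≈ 0.08), and mixed fusions of the
same size score ≈ 0.5.

`pairwiseMixing()` restricts a query scaffold to two reference labels
and returns the normalized turbulence; `fusedPairQuartiles()` summarizes
all fused pairs by (Q1, Q3) using linear order-statistic interpolation
(R's default quantile type 7 — the convention is fixed here because
"quartile range" alone does not pin one down), and
`classifyFusedPair()` calls a pair `sharp` below Q1 and `mixed` at or
above it (inclusive boundary).

## The simulator: what it emulates and what it does not

`makeAncestor(k, g)` builds a `k`-chromosome ancestor (default 46,
mirroring the decapodiform-like karyotype) with `g` genes per chromosome
and ancestry labels equal to the home chromosome. Events
(`applyEvent()`, `evolveKaryotype()`): sharp fusion, fusion-with-mixing,
fission, inter-chromosomal translocation of a contiguous segment,
intra-chromosomal shuffling, and independent gene loss. Gene counts are
conserved by everything except loss; ancestry labels are immutable.

The mixing operator is a design point. At `m = 1` the merged gene order
is an exact uniform permutation. At `0 < m < 1`, `ceiling(m*n)` randomly
chosen genes are relocated to uniform random positions — a non-local
move emulating intrachromosomal translocation. A local
adjacent-transposition walk was evaluated and rejected: its boundary
diffusion inflates spell-duration variance faster than it grows the
spell count, so the turbulence composite transiently *drops below* the
sharp-fusion value at intermediate intensity (measured means 0.103 /
0.076 / 0.096 / 0.538 across m = 0, 0.25, 0.5, 1 on 100+100 fusions).
Relocation restores the intended monotone dial (0.103 / 0.265 / 0.410 /
0.541).

`emitObserved()` bridges simulator and pipeline: shared genes become
mutual-best orthologs, each retained with probability `retention`
(default use here: 0.9, a realistic recovery rate for cross-species
protein mapping), positions synthesized from rank at 10 kb spacing —
only order matters downstream. `fragmentGenome()` cuts each scaffold
into consecutive blocks with sizes drawn with replacement from an
empirical genes-per-contig profile (last block truncated); matching is
distributional, not per-contig, since only the size distribution of a
real draft assembly is available in general. `unfragmentGenome()` is an
exact inverse.

The simulator deliberately omits: nucleotide sequence, repeat content,
paralogy and whole-genome duplication, gene gain, and mapping noise
other than uniform loss. Tests passing on simulated data therefore
demonstrate the *inference machinery* — that the statistics recover
known fusions, survive fragmentation, and separate mixing regimes — not
that any particular biological dataset will behave as cleanly.

Randomness: every stochastic operation takes a `seed` and runs under a
local RNG stream (the caller's RNG state is untouched); a scenario is
seeded once by `evolveKaryotype()`, so fixed seeds reproduce descendants
and logs bit-for-bit.

## Numerical and degenerate-input choices

- Fisher tails via the exact hypergeometric distribution; a zero grand
  total is an error, `a = 0` with positive margins gives p = 1.
- Bonferroni is `min(1, m·p)`; p-values outside [0,1] are rejected.
- Quantiles: type 7 (position `1 + (k-1)q`), at least 4 values required.
- Turbulence of a single-label sequence: d = 1, T = 1, normalized 0.
- Rank ties (identical midpoints) break lexicographically by ortholog
  id, making every table deterministic.
- Ward clustering (`clusterOrder()`): `ward.D2` on Euclidean distances
  between shared-ortholog count vectors; rows are pre-sorted by id so
  zero-distance merges resolve lexicographically and leaf order is
  shuffle-invariant. A single-scaffold axis returns as-is with a
  warning.
- Empty annotation files parse to empty collections with a warning;
  malformed lines error with their line number; duplicate gene or
  ortholog ids error with the offending ids.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at the
scale the statistics are designed for while staying quick: a
46-chromosome, 4600-gene ancestor; 20 fusion events per scenario;
retention 0.9; genes-per-contig profile uniform on 10..30 (mean 20);
1000 replicates for the null calibration of the family-wise error rate;
10 seeds for recovery, discrimination and fragmentation checks. The
exact-oracle tests run the distinct-subsequence count against full
enumeration (4096 sequences up to length 12) and the Fisher tail against
full-margin enumeration for all tables with N ≤ 40.

## Known limitations

- The mutual-best construction assumes one reference peptide set mapped
  to both genomes; reciprocal-best-hit graphs from all-vs-all searches
  are out of scope.
- Pairwise inference only: multi-genome synthesis is done by reading
  per-pair results side by side, not by a joint model.
- The co-occurrence FWM test is presence/absence at contig level; very
  long contigs dilute it, very short ones are removed by the 15-ortholog
  filter.
- Normalization equivalence with other turbulence implementations is
  not guaranteed (see above); compare regimes, not third decimals.
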