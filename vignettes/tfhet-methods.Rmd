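---
title: "Methods: TF occupancy, CCAAT motifs and small-RNA tracks at heterochromatic repeats"
author: "tfhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF occupancy, CCAAT motifs and small-RNA tracks at heterochromatic repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfhet)
```

# The biological problem

Constitutive heterochromatin in fission yeast is nucleated at repeat
elements — the pericentromeric *dg*/*dh* repeats and the single
*dh*-homologous *cenH* element in the silent mating-type region — and the
RNAi pathway that nucleates it depends, paradoxically, on those repeats
being transcribed. `tfhet` implements the computational side of the
analysis showing that sequence-specific transcription factors (the NF-Y-like
PhpC trimer together with the Zn-finger protein Moc3) bind CCAAT-box loci
inside heterochromatin, drive strand-specific transcripts that carry
inefficiently spliced ("cryptic") introns, and that these transcripts feed
siRNA production. Everything runs on synthetic data with planted ground
truth, so each analytical claim can be tested quantitatively without any
sequencing download.

# Track arithmetic

ChIP enrichment is represented as a `SignalTrack`: per chromosome, sorted
non-overlapping 0-based half-open intervals with non-negative values.
The enrichment statistic is a ratio of ratios,

$$
\mathrm{FE}(x) \;=\;
\frac{(\mathrm{IP}_\text{tagged}(x)+\varepsilon)\,/\,(\mathrm{input}_\text{tagged}(x)+\varepsilon)}
     {(\mathrm{IP}_\text{untagged}(x)+\varepsilon)\,/\,(\mathrm{input}_\text{untagged}(x)+\varepsilon)},
$$

evaluated per base on the union of breakpoints, with a symmetric
pseudocount $\varepsilon$ (default 0.1, configurable) guarding zero
coverage. Dividing by the untagged-strain enrichment cancels
sequence-composition and accessibility biases shared by every strain. The
ratio track is then mean-binned into non-overlapping 10 bp windows
(length-weighted mean, uncovered bases contributing 0; the
chromosome-terminal partial bin is averaged over its actual width rather
than dropped, so no contig-end signal is lost), and regions excluded from
alignment are modelled by zeroing the signal inside mask intervals instead
of removing them — downstream binning then still sees total coverage. The
default configuration carries the two standard masks (the mating-type
region on chromosome 2 and the *mat1M* locus on the 40 kb MAT contig).

Coordinates are 0-based half-open throughout (BED/bedGraph convention);
conversion to 1-based happens only when SGR records are emitted.

# The binding-site library and occupancy matrix

Each TF's peak summits (1 bp positions) are expanded symmetrically by
25 bp into uniform 50 bp sites; sites sharing at least one base are merged
transitively. Two conventions had to be fixed that the merging rule itself
does not determine:

* *Abutting* intervals (`end == start`) are **not** merged — under the
  half-open convention they share no base. Tests verify the merge against
  an independent transitive-closure oracle under the same rule.
* The center of a merged (wider than 50 bp) site is the floor midpoint of
  the merged interval, and a site's identity is its coordinate string
  `chrom:start-end`, which is stable across runs.

Per-site TF signal is the *maximum* of the enrichment track over a 1 kb
window straddling the site center (clamped at chromosome ends), a choice
robust to the varying peak widths and centering of different TFs.
Collecting these maxima over all sites and TFs gives the occupancy matrix
(rows: sites in coordinate order; columns: TFs lexicographically).

# CCAAT-box counting

The NF-Y-family recognition motif is the pentanucleotide CCAAT. Both
strands are scanned (CCAAT and its reverse complement ATTGG, all
overlapping occurrences reported, plus-strand coordinates) within ±500 bp
of a peak center, and nearby motifs are collapsed: scanning left to right,
a hit joins the current cluster iff the intervening sequence between it
and the previous hit is at most 25 bp. "Separated by ≤ 25 bp" is read as
intervening sequence length (end-to-start, `next_start − (prev_start +
5)`); start-to-start counting is available as a sensitivity option.
Chaining is transitive, so a cluster's diameter may exceed 25 bp, and an
overlapping CCAAT/ATTGG pair always collapses to one. Hits straddling the
window edge count iff their start lies inside. A locus is classed
`high` iff more than one collapsed box remains — the two CCAAT boxes ~60 bp
apart that define the repeat promoter configuration stay distinct under
this rule.

# Co-occupancy statistics and clustering

Per-TF site sets (every site a TF contributed a summit to) are compared
as sets: exact Euler region counts by subset signature, pairwise shared
counts with percentages, and a one-sided upper-tail hypergeometric
enrichment p-value $P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, |A|,
|B|)$ over the library universe. Enrichment (not depletion) is the
question being asked, hence the one-sided test; no multiple-testing
correction is applied across pairs by default, though Bonferroni-adjusted
values are reported alongside.

TF columns of the occupancy matrix are clustered agglomeratively on
Euclidean distances under the Ward.D2 objective (minimum within-cluster
variance increase). "Ward" is ambiguous between the D and D2 variants and
partitions can differ between them, so the linkage method is exposed as a
parameter; D2 on raw distances is the default. The cut level `k` is a
user choice (default 6, the number of occupancy classes distinguished in
this system), not an inference; the pipeline's synthetic fixture uses
`k = 3` over its six simulated TFs, where six singletons would be
vacuous. An optional transform (`log1p` or row-scaling) can be applied
before clustering; the default is none.

# Strand-resolved small-RNA coverage

Reads are handled as alignment tables (one row per reported alignment;
`n_best` = number of equally best-scoring alignments of the read). The
processing chain is: size-select to 21–25 nt; either drop multi-mappers
(`n_best > 1`) or count every alignment (weight 1 per alignment by
default, `1/n_best` optionally); restrict to reads mapping uniquely
*within* a region when a single repeat copy must be isolated from its
near-identical homologs; accumulate full read bodies per base and strand
(5′-end-only counting is available); normalize to counts per 10 million
mapped reads (CP10M). The normalization denominator is the number of
distinct mapped reads after size selection and *before* unique filtering,
counting each read once regardless of `n_best`; this is exposed in the
interface because the denominator convention is not otherwise determined.

SGR output writes `chrom, 1-based position, value` with minus-strand
counts as negative values so both strands display simultaneously; by
default every position is written (a single zero record where both
strands are empty), which makes read-back exact, and zero suppression is
available for display-sized files.

# Cryptic introns

An intron model is a (donor, branch point, acceptor) triple in plus-strand
coordinates with a strand: the donor is the G of the GT dinucleotide, the
acceptor the G of AG, the branch the branch-point adenosine, all read in
transcript orientation ("top" strand = plus; "bottom" = minus — bottom is
where the TF-dependent repeat transcripts run). The scanner enumerates
donor/acceptor pairs with length within configured bounds (default
30–120 nt, the scale of cryptic introns in this genome) and requires a
branch-point consensus match 18–40 nt upstream of the acceptor. The
consensus defaults to CTRAY, the fungal branch consensus, with the branch
adenosine as its last A — the analysis names the branch point but no
consensus, so this is a configurable default. Overlapping candidates are
resolved greedily by ascending donor, preferring the shortest acceptor
satisfying all elements; an exhaustive all-candidates mode exists and is
what the planted-truth round-trip tests use, since a greedy scan of random
sequence can legitimately accept a spurious upstream candidate first.

Homology projection maps annotated introns from one repeat copy onto
another through a Needleman–Wunsch global alignment (default scoring
match +1, mismatch −1, gap open −5, extend −1; identity is
scoring-dependent and therefore documented rather than asserted). Percent
identity counts matches over *all* alignment columns, gaps included. An
intron survives projection only if the target carries an intact donor,
acceptor and branch consensus at the projected positions; otherwise it is
reported with the element it lost. Splice-site mutagenesis replaces, in
transcript orientation, donor GT→CA, acceptor AG→GC and the branch A→C —
five substitutions per intron, sequence length unchanged — after which the
scanner must recover none of the planted set.

# The synthetic-data generator

The generator emulates the statistical structure the analysis relies on,
not the sequencing process:

* **Genome and repeats.** Random chromosomes at a configurable GC
  fraction (default 0.36, the genomic GC of fission yeast). A repeat
  family is planted as `n_copies` copies of one unit; copies diverge by
  point substitutions only, at an *exact* count `round(divergence ×
  unit_length)` of positions, so that a 4% setting yields 96% identity
  deterministically and coordinates remain directly comparable between
  copies (no indels; alignment with indels is exercised separately in the
  homology tests). The first copy plays the role of the nucleation
  element (*cenH*-like), the second its centromeric homolog (*dh*-like).
* **Motif clusters.** CCAAT/ATTGG instances written at recorded positions
  with configurable per-cluster counts and gap ranges, placed outside the
  repeat copies.
* **ChIP tracks.** Per 10 bp bin, input and untagged tracks are
  Poisson(background) draws; the IP-tagged track adds a deterministic
  Gaussian bump (s.d. 50 bp) of the planted height at each site bound by
  the TF being simulated. No track magnitudes are prescribed by the
  source analysis, so the defaults are calibration choices: background
  mean 20 counts per bin with peak height 60. At much lower depth the
  pseudocount ratio becomes heavy-tailed — a handful of near-zero
  denominator bins dominate pointwise maxima — which is a property of the
  ratio statistic at low counts, not of the binding signal; the defaults
  sit where ratio noise is well-behaved, as real fragment-pileup
  enrichment tracks are.
* **Summits.** One summit per planted site with rounded Gaussian
  positional jitter, clamped to the chromosome.
* **Small RNAs.** Uniform placement in a region, lengths over 21–25 nt, a
  configurable minus-strand ("bottom") fraction, and multi-mapping
  annotation: a read drawn entirely from within a repeat copy is checked
  against the homologous offset of every other copy and reported at each
  position where the local sequence is identical over the read length.
  There is no sequencing-error or fragment-size model, and no aligner
  emulation beyond this multiplicity — which is exactly the structure the
  unique-to-region filter must handle.
* **Introns.** Canonical GT..AG introns with a planted CTAAC branch
  instance (matching CTRAY) whose branch A sits 20 nt upstream of the
  acceptor, written on the requested strand.

All randomness flows through one seeded generator per operation; seeds
are mandatory arguments, and the pipeline derives per-stage seeds from a
single master seed, so outputs are byte-identical across same-seed runs.

What passing these tests does *not* show about real data: the generator's
reads have no errors, its peaks are symmetric and isolated, repeat copies
differ only by substitutions, and planted introns always carry a perfect
branch consensus. Conclusions about aligner behaviour, peak-caller
artefacts or degenerate splice signals are outside what the synthetic
truth can support.

# The `generate_genome` / `plant_tf_sites` split

Genome generation and TF-site planting are separate operations: the
genome (with repeats and motif clusters) is generated once, and
`plant_tf_sites()` then adds bound sites for a set of TFs, drawing
centers from a spaced candidate grid (default 1.5 kb spacing, keeping
peaks separable at the default 50 bp peak s.d.) with a configurable
fraction shared between TFs so that merged libraries exercise multi-TF
sites. Keeping the steps separate lets one genome host different binding
configurations in tests without regenerating sequence.

# Numerical choices and degenerate inputs

* Pseudocounts are applied symmetrically in numerator and denominator of
  every ratio; `fe_ratio(t, t, p) ≡ 1` exactly.
* Binning conserves length-weighted signal exactly when the chromosome
  length is divisible by the bin size; otherwise the terminal-bin
  convention applies.
* Empty inputs are values, not errors: empty bedGraph files give empty
  tracks, TFs without summits give empty site sets, empty hit lists give
  zero clusters, zero planted introns leave sequences unchanged.
* Gap collapse with a negative `max_gap` disables collapsing and returns
  the raw count.
* bedGraph and SGR parsers reject malformed or overlapping records with
  the offending line number; unknown chromosomes are errors, not silent
  drops.
* CP10M normalization and its inverse round-trip to double precision;
  byte-level determinism is asserted for file outputs, value-level
  determinism for floating-point arithmetic.

# Problem sizes

The packaged synthetic runs use two chromosomes of 22–50 kb, a 2 kb
repeat unit, 3–6 TFs with 5–10 sites each, 500–3000 reads, and oracle
comparisons on chromosomes up to 50 kb with at least 100 random instances
per operation — sizes at which every brute-force oracle (per-base
expansion, transitive-closure graphs, hypergeometric pmf summation)
is exact and fast, and a full pipeline run takes seconds on one CPU.

# Known limitations

* The merged-site center is a convention; for strongly asymmetric merged
  clusters the 1 kb signal window may be off-center relative to the
  strongest summit.
* Percent identity depends on alignment scoring; the reported value for
  diverged sequences with indels is not unique.
* The hypergeometric test treats sites as exchangeable; genomic
  clustering of sites violates independence and the p-values are
  enrichment scores, not calibrated genome-wide probabilities.
* `multimap_mode = "all"` double-counts genuinely single-copy signal at
  repeat boundaries; the unique-to-region filter is the conservative
  choice for repeat-copy-specific claims.
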