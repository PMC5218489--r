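---
title: "Models and methods: dissecting PCR error sources at the single-molecule level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dissecting PCR error sources at the single-molecule level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrfidelity)
```

## The problem

PCR amplification upstream of sequencing introduces several distinct classes
of artifact: polymerase base misincorporation, small indels, non-enzymatic
DNA damage during thermal cycling (dominated by cytosine deamination, read
out as C→T), template-switching across inverted-repeat (cruciform) elements,
and PCR-mediated recombination between co-amplified homologous molecules.
Strand-specific single-molecule consensus sequencing can observe each class
directly: every read is a high-accuracy consensus over many passes of one
original molecule, so rare per-molecule events are countable.

`pcrfidelity` implements the full analysis — filtering, event
classification, rate estimation, inversion scanning, recombination
scanning — together with a simulator of the PCR process that produces
consensus-like reads with complete ground truth. Every estimator in the
package is therefore validated by parameter recovery: simulate at a known
operating point, analyze, and compare.

## Error propagation and rate normalization

Errors made early in PCR are copied by every later cycle. To first order the
observed per-base error fraction grows linearly with the number of
*doubling events* $n$:

$$ f = \frac{n\,e}{2}, \qquad n = \log_2(Y/I), $$

where $e$ is the per-base, per-doubling error rate, $Y$ the measured product
yield and $I$ the input amount. Replication is never perfectly efficient, so
$n$ is below the cycle count; normalizing by doublings rather than cycles
makes polymerases with different efficiencies comparable. The estimator
reports the inverse transform $e = 2f/n$ (`normalize_per_doubling()`), and
`per_cycle_rate()` provides the $f/\text{cycles}$ convention for comparison
with cycle-normalized studies. The linear model is first-order: the
simulator warns when $n\,e \ge 0.1$.

Raw substitution rates are composition-averaged so that template base
composition does not weight the estimate:

$$ e_{AT} = \frac{N^{A\to C,A\to G,A\to T}+N^{T\to A,T\to C,T\to G}}{N^A+N^T},
\quad
   e_{GC} = \frac{N^{G\to A,G\to C,G\to T}+N^{C\to A,C\to G,C\to T}}{N^G+N^C},
\quad
   e_{sub} = \frac{e_{AT}+e_{GC}}{2}. $$

The $GC$ numerator comprises exactly the three changes originating from C
(C→A, C→G, C→T) plus the three from G. For plasmid libraries, where no
meaningful composition correction applies, the plain estimator (total
substitutions over total bases) is used instead. Indel rates are
$N_{del}/N$ and $N_{ins}/N$ with each deleted reference base and each
inserted read base counted as one event.

## Read and event filtering

Consensus accuracy is driven by the number of sequencing passes, so the
rate analysis requires at least 15 passes per strand-specific consensus;
additionally every counted event must carry the maximum quality value of
93, the read's mapping quality must be 254 (unambiguous alignment), primer
sites are excluded, reads shorter than 80% of the expected amplicon are
dropped, and chimeric reads mapping to more than one reference region are
discarded. The switching analyses (inversions, recombination) use the
permissive preset: at least 3 passes, no further read-level criteria. Both
presets ship as `filter_policy("rates")` and `filter_policy("switching")`.

Choices the filtering criteria leave open, resolved here:

* **Length criterion** uses the read (consensus) length, not the aligned
  span; both are available from the audit.
* **Primer masking is symmetric**: events inside primer regions are
  excluded from the numerator *and* the masked reference positions from
  the denominator, which keeps the estimator unbiased.
* **Deletion quality**: a deletion has no read base; its QV is taken as the
  minimum of the two flanking read bases.
* **Audit attribution**: each removed read is attributed to the first
  failing criterion in the order passes → mapq → length → chimeric. This is
  a reporting convention only; survivorship is a conjunction and therefore
  order-independent.
* **Marker masking**: when co-amplified homolog pairs are analyzed for
  substitution rates, marker positions are masked as well — a recombinant
  read mismatches its template of origin at markers, and those mismatches
  are template-identity signal, not polymerase error.

## Mutational spectra and strand bookkeeping

Substitution events are tallied over the six complementary pairs
(A→G/T→C, G→A/C→T, A→T/T→A, A→C/T→G, G→C/C→G, G→T/C→A). Because consensus
reads are strand-specific, events from minus-strand reads are complemented
into the orientation of the synthesized strand before tallying; the pair
table is invariant to this, but directed shares (e.g. the C→T fraction of
deamination damage, which appears as G→A in reference orientation on
minus-strand reads) require it.

## Template-switching at inverted repeats

An inverted repeat (two stems that are reverse complements separated by a
loop) can extrude into a cruciform. A polymerase replicating through it may
switch strands at the loop, producing three read classes: a **double**
switch (onto the opposite strand and back) reverse-complements the loop in
place and leaves the stems unchanged, while the two **single** switches
continue on the opposite strand back toward the end they came from and
yield fold-back products whose length differs from the full amplicon — for
a switch after a prefix of length $p$ ending at the proximal stem, the
product is $2p + \ell$ nt with loop length $\ell$.

Detection classifies each read against four constructed references — the
correct local sequence and the three switch products, each covering the
element plus 30 flanking nucleotides — requiring the read to cover more
than 95% of the matched reference with **zero mismatches**; the
zero-mismatch rule matters because for small elements the correct and
double references differ by only a few bases. A read matching none, or
more than one, reference is *unassigned* (ambiguity is a value, not an
error). Exact full-reference substring matching implements this rule
directly for intact reads; reads without an exact match are re-examined by
local alignment with mismatches and indels forbidden. Percentages use the
scanned-read denominator (reads overlapping the element that meet the
3-pass requirement).

## PCR-mediated recombination

Two homologs differing only at single-base markers spaced near-regularly
across the gene are co-amplified; a chimeric product carries markers from
both. Marker calls require the read base to match one homolog's allele
*and* the two bases on either side to match the shared backbone; anything
else (including markers lost to deletions) is invalid. Switches are
transitions between consecutive *valid* calls; invalid calls are bridged,
not transition-bearing, and multiple switches per read count individually
(A,B,A is two events).

Switches between identical template copies are invisible ("cryptic"), so in
an equimolar mix the detected count is doubled:
$\text{raw} = 2 N_{re} / N_{total}$ with $N_{total}$ the total analyzed
consensus bases, then normalized per doubling as above. The factor 2 assumes
50:50 mixing; other ratios would need $1/(2 p_A p_B)$, not enabled by
default.

Two small downward biases are inherent to marker detection and documented
rather than corrected, because the assay being emulated shares them:
switches outside the outermost markers are undetectable (markers start 30
nt from each end, ≈5% of read length), and an even number of switches
between the same adjacent marker pair cancels (≈3% at the simulated event
densities). Recovery tests therefore use a band of 10% around the
configured rate. Strands with at least one *detected* event follow
$1-e^{-m}$ for per-strand detected mean $m$, which reproduces the
published ≈23% at the published event density.

## The simulator

Two modes share one validated configuration (`simulation_config()`):

* **Closed-form** (given `target_doublings`): per read, event counts for
  each class are Poisson with per-base mean $f = n e/2$ (per-cycle
  accumulation $1-(1-d)^c$ for damage), positions uniform over eligible
  bases, and identities drawn from the 12-weight directed spectrum. Event
  *type* is drawn first and the position then drawn uniformly among bases
  of the source type; the realized type distribution therefore equals the
  configured spectrum exactly in expectation even when per-source totals
  are unequal (as for the A/T-heavy Taq spectrum), which is what the
  spectrum-recovery checks require. Justified because $f \ll 1$ in every
  regime studied.
* **Lineage-explicit** (given `efficiency_per_cycle`): a branching process;
  each cycle every molecule replicates with the given probability, each
  replication draws fresh errors and may switch to a random co-amplified
  molecule or emit an inversion-class product, and damage strikes every
  molecule every cycle. Reads sample the final population. At efficiency 1
  the population mean error fraction equals $n e / 2$ exactly; at lower
  efficiency the branching mean is
  $\frac{\pi/(1+\pi)}{\log_2(1+\pi)}\, n e$, a few percent above the
  first-order model — the agreement test is run at efficiency 1.

Whether switching reads arise in one replication pass or across cycles is
not asserted: the closed-form mode draws products directly, the lineage
mode produces them during replication, and both are exposed.

Other generator conventions: substitutions and damage collapse to one
event per position (a base deaminated twice is still one mutated base);
substituted bases that are subsequently deleted vanish from the truth;
inversion-class products are emitted error-free and unmapped in SAM
(structural products have no simple CIGAR against the reference — the
scanner is sequence-based); recombination switch partners are drawn 50:50
between homolog families independent of the current source, which makes
exactly half of all switches cryptic in expectation; pass counts are
uniform on `read_pass_model`; qualities are fixed at the maximum (93)
unless a test degrades them deliberately. All coordinates are 1-based
inclusive, internally and in every file format. One master seed drives
every draw; reads are processed in index order so runs are bit-for-bit
reproducible.

Artificial templates are built with exactly balanced base composition
(shuffled equal base counts), no homopolymer longer than 5 (runs are
broken by composition-preserving swaps), markers on a near-regular grid
starting 30 nt from each end (clear of the 25-nt primer regions, keeping
edge censoring small), and marker alleles chosen so no substitution
creates a homopolymer run.

### What the generator does not emulate

Consensus-building itself (pass-level sequencing error, quality-value
miscalibration), alignment ambiguity and soft-clipping, homopolymer
length-error modes, polymerase kinetics and cruciform thermodynamics,
amplification bias between molecules, and instrument loading biases
(e.g. the length censoring that hides short single-switch products on real
instruments — the scanner classifies any product that passes the read
filters, and real-data users should expect length-dependent visibility).
Passing recovery tests therefore demonstrates correctness of the
*analysis* given idealized consensus reads, not robustness to upstream
consensus or alignment artifacts.

## Problem sizes and tolerances

The validation suite runs at desk scale, chosen so each stochastic check
holds a comfortable margin at its tolerance: module tests use hundreds to a
few thousand reads; recovery checks use 15,000–100,000 reads (≥ 100,000
substitution events for spectrum recovery within ±1 percentage point,
100,000 reads for the 1.54% inversion fraction within ±0.1 points, 3
binomial standard errors elsewhere). Stochastic assertions use fixed seeds
and pre-stated bands; classification on noise-free products is asserted
exactly.

## Known limitations

* Indel-rate background: single-pass indel errors and alignment artifacts
  dominate real-assay indel backgrounds (≈3×10⁻⁶/base); the simulator does
  not emulate them, so recovered indel rates are cleaner than real ones.
* The recombination estimator's censoring biases (above) are documented,
  not corrected.
* Lineage mode realizes whole molecule populations and is intended for
  validation at moderate scale, not for simulating full sequencing runs.
* Uncertainty reporting is limited to binomial standard errors; no
  multi-sample meta-analysis.
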