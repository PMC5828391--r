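---
title: "Profiling CCAN occupancy on alpha-satellite arrays: models and methods"
author: "satfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling CCAN occupancy on alpha-satellite arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satfrag)
```

## The problem

Functional human centromeres sit on megabase-scale tandem arrays of
alpha-satellite DNA: ~171-bp AT-rich monomers arranged, in the arrays that
actually bind the kinetochore machinery, as 340-bp or 342-bp head-to-tail
*dimeric units*, each carrying one CENP-B box — a 17-bp motif bound by the
CENP-B protein, of which the middle 15 bp (`TTCGTTGGAAACGGG`) is the
conserved ancestral core. The centromere-specific nucleosome (CENP-A) and
its constitutively associated protein network (CCAN: CENP-B/C/N/T/W/S/X)
protect characteristic DNA fragment lengths from nuclease attack, and the
stability of these particles can be probed by sequential salt extraction:
weakly bound material elutes without salt or at low salt, while intact
CENP-A/B/C particles resist and appear in the high-salt (500 mM NaCl)
supernatant or the insoluble pellet.

Sequencing such material poses two repeat-specific problems that this
package addresses computationally:

1. **Fragment length on repeats.** On near-identical tandem repeats the two
   ends of a fragment cannot be mapped independently without ambiguity, so
   fragment length is measured *directly* by merging overlapping mate pairs
   into full-length inserts.
2. **Edge effects on repeat references.** Mapping to a single repeat unit
   truncates fragments at the reference boundary. The package maps to a
   *triplicated* unit consensus and folds coverage modulo the period onto
   the middle dimer, producing an edge-free average occupancy profile.

Every analysis stage is driven by a synthetic alpha-satellite generator
with full ground truth, so the whole pipeline is testable at desk scale
without any external download.

## The synthetic generator

`build_dimer()` joins two fixed synthetic monomers (arbitrary AT-rich
sequences — deliberately *not* a real alphoid consensus, and checked to
contain no CENP-B box of their own) into a 340- or 342-nt unit and writes
the ancestral box core at offset 60. `evolve_array()` expands a founder
unit into `n_units` tandem copies with independent per-base substitutions
at rate $r \in [0, 0.25]$, uniform over the three alternative bases.
Substitution-only evolution is a deliberate restriction: it keeps the dimer
period exact, so that coordinate folding and per-unit bookkeeping stay well
defined; indel divergence and higher-order repeat structure are out of
scope. Under this model two units differ at a position with probability
$2r(1-r) + \tfrac{2}{3}r^2$, giving an expected pairwise identity of about
88.5% at $r = 0.06$ — the regime of the 88–96% identities typical of
adjacent units in homogeneous centromeric arrays.

`assign_truth_occupancy()` ties each unit's true CCAN occupancy to its box
quality through a monotone link (default $f(s) = 0.2 + s$ on the box score
$s$) times lognormal unit-level noise, and interpolates the unit's
salt-fraction weights between a dead-box endpoint
$(0.10, 0.40, 0.35, 0.15)$ and a perfect-box endpoint
$(0.02, 0.15, 0.68, 0.15)$ over (no salt, low salt, high salt, pellet).
The perfect-box endpoint was chosen so that a homogeneous array places more
than 80% of its mass in the pooled high-salt + pellet fractions, the
stable-chromatin regime expected for intact CENP-A/B/C particles. The
functional form of the link is a simulation choice, not an inference
target: only its monotone trend matters to any conclusion the package
draws.

**Noise calibration.** The lognormal log-sd defaults to 0.9. This value
was fixed once from a Monte-Carlo sweep of the generator itself: across
24 simulated contigs whose founder boxes degrade along a divergence
gradient, the per-contig Pearson correlation between best box score and
antibody/IgG fold enrichment averages ≈ 0.91 at σ = 0.5, ≈ 0.83 at 0.7,
≈ 0.75 at 0.9 and ≈ 0.66 at 1.1. σ = 0.9 centres the generator in the
r ≈ 0.66–0.83 regime reported for real centromeric contigs, and the
acceptance suite checks the recovered correlation against the
pre-registered band [0.6, 0.85] (and that r → 1 as σ → 0).

`simulate_fragments()` draws per-unit fragment counts proportional to the
truth occupancy, positions centred on the unit (with Gaussian jitter,
default sd 20 nt), and lengths from a three-regime Gaussian mixture
(`fragment_model()`): subnucleosomal ~100 bp, nucleosomal/CCAN ~172 bp
(sd 12, spanning the observed 160–185 bp major peak) and dimer-spanning
340 bp, with default weights 0.15/0.60/0.25. Lengths are truncated to
[25, 500] nt — the merge filter's minimum and the upper end of the
observed ~100–450 bp fragment range — by resampling, not clamping, so the
mixture shape is preserved. `emit_fastq()` writes truncated mate pairs
(R1 = first `read_length` nt, R2 = reverse complement of the last),
constant Phred-37 qualities lowered to 11 at simulated substitution
errors, appended `spike|`-named spike-in pairs from a synthetic exogenous
genome, and a truth TSV.

What the generator does *not* emulate — PCR duplicates, quality-score
drift, indels, chimeric fragments, higher-order repeat variation, and real
inter-array homogenisation structure — bounds what green tests mean:
they validate the *computational contracts* of the pipeline under the
stated noise model, not its behaviour on any particular real library.

## Read merging

`merge_pairs()` reconstructs inserts with the classic overlap-merge
contract: 3′ bases below Q25 are trimmed; the longest
suffix(R1)/prefix(revcomp R2) overlap of ≥ 15 nt with at most one mismatch
per 10 overlap nt is accepted; disagreements take the higher-quality base;
merged fragments shorter than 25 nt are discarded. The published merge
parameters fix the thresholds (q 25 / L 25 / o 15) but not the internal
mismatch heuristic of the original merging tool; the 1-per-10-nt rule is
therefore fixed here explicitly, and the error-free case — where any
reasonable rule agrees — anchors the tests: on error-free simulated
250 × 250 reads, 100% of merged lengths equal the true fragment length for
all fragments up to 2 × 250 − 15 = 485 nt. Unmerged pairs are retained;
in 25 × 25-bp short-read mode merging is impossible by design and only
end counts are used downstream.

## Repeat mapping and folding

`align_end_to_end()` performs an exhaustive ungapped scan of every start
position on both strands, minimising Hamming distance. This replaces an
external aligner deliberately: at desk scale (references of a few kb) the
$O(nm)$ scan is fast, has no tool dependency, and its no-clipping,
no-indel contract is exactly the end-to-end, no-mixed, no-discordant
mapping mode used for repeat references. Hits with more than
`max_mismatch_frac` (default 0.1) mismatches per base are rejected. Ties
are broken leftmost-then-plus-strand — an arbitrary but deterministic
rule. On a homogeneous triplicated reference every fragment matches all
three copies equally well; the folding step makes the reported profile
provably invariant to the tie-break (the test suite permutes the rule and
compares folded profiles exactly). The mismatch counting itself is done by
Biostrings' C-level `neditStartingAt`; the contract (best hit, tie-break,
rejection threshold) is the package's own.

`fold_to_middle_dimer()` adds coverage at position $p$ of the
$3 \times$ reference into position $p \bmod \text{period}$, conserving
total mass exactly. Folded and unfolded profiles are reported as per-base
coverage; a fragment-count view (counts per unit) is available through
`per_dimer_occupancy()` on hit tables, since mean per-base coverage and
fragment counts differ only by the mean fragment length.

## Motif scoring

`motif_score()` implements the published four-point scale directly:
identity to the 15-bp ancestral core scores 1, each mismatch subtracts
0.25, and more than three mismatches scores 0. `scan_motifs()` reports
every window on either strand within 3 mismatches — exactly the sites
with nonzero score, which makes the scanner and the score mutually
consistent by construction. This replaces a p-value-based motif search:
a probabilistic significance criterion could in principle admit rare
> 3-mismatch sites, but no such site can score above 0 on this scale, so
nothing the downstream statistics consume is lost. Overlapping same-strand
hits collapse to the best-scoring window (leftmost on ties) — a rule that
matters only for self-overlapping motifs, not for the CENP-B core, but is
fixed for determinism. `motif_density()` divides collapsed hit count by
sequence length in kb.

## Enrichment, recovery and correlation

`calibrate_counts()` scales raw counts by `scale_const / spike_count`;
the constant (default 10,000) cancels in every ratio and exists only for
readable magnitudes. `fold_enrichment()` is the calibrated
antibody-to-IgG ratio with a pseudocount of 1 calibrated unit guarding
depleted contigs (set it to 0 for exact ratios; the algebraic cancellation
of calibration when both samples share a spike count is tested
numerically). `percent_recovery()` normalises per-fraction counts to
percentages. `correlate_motif_enrichment()` computes plain Pearson
correlation on untransformed enrichment (a log10 option is reported
separately); enrichment is averaged per contig before correlating when
replicates exist.

## Per-dimer structure

`per_dimer_occupancy()` summarises a track over each unit: mean coverage,
mean over each monomer half, and the coverage centroid's signed offset
from the box start. `classify_dimers()` then labels orientation
(`centered` within 25 nt — about half a nucleosome's DNA reach — else
`upstream`/`downstream` by sign) and symmetry (`symmetric` when the
monomer ratio is below 1.5, else asymmetric toward the heavier half).
No quantitative criterion for these classes exists in the literature the
package follows; the centroid statistic is the simplest reproducible
formalisation of an orientation that is otherwise judged by eye, and both
thresholds are exposed as arguments. The 1.5 ratio was chosen so that flat
Poisson sampling noise at ~50× coverage does not trigger asymmetry calls;
the suite verifies ≥ 95% classification accuracy on truth-labelled
symmetric vs one-monomer footprints at that coverage, and exact
scale-invariance of both labels. `occupancy_fold_range()` (max/min unit
occupancy, pseudocount on zeros) quantifies within-array differential
occupancy; at a simulated 50:1 truth ratio it recovers 50 within Poisson
error at $10^4$ fragments.

## The orchestrated run

`run_pipeline()` executes simulate → merge → map → motifs → enrich →
dimers from a single validated `sat_config()` (unknown keys are rejected),
logs stage timings to `run.log`, writes every table as TSV, tracks as
bedGraph, motif hits as BED, and a `manifest.json` echoing all parameters
and output checksums. All randomness derives from the single config seed
through a pre-drawn sub-seed pool, so repeated runs are byte-identical in
their TSV outputs; `resume = TRUE` reloads the simulation stage from a
state snapshot when present. Multi-reference assignment maps each fragment
to its best array (exact-match fast path over an N-spaced concatenation,
then per-array exhaustive scan).

`make_fixtures()` freezes the walkthrough dataset: two arrays (periods
340 and 342, founder divergence 0.02 and 0.10), CENP-A and CENP-B plus
IgG, four fractions, ~19,000 read pairs plus spike-ins.

## Numerical and size choices

* Coordinates are 0-based half-open everywhere internally; bedGraph/BED
  outputs follow their standards.
* Truncated mixture draws use resampling; multinomial draws allocate
  fragment counts so totals are conserved exactly.
* Degenerate inputs have explicit contracts: all-zero occupancy, all-zero
  fraction counts, zero spike counts, < 3 correlation rows and
  zero-variance variables are errors; zero-coverage units yield `NA`
  classifications; `fold_enrichment(0, 0)` returns 1 via the pseudocount.
* Test problem sizes are chosen as the smallest that make the statistical
  assertions sharp: $10^4$ pairs for merge exactness, $10^5$ fragments for
  2%-absolute recovery of fraction weights, 12 replicates of 24 contigs at
  $5 \times 10^4$ fragments for the correlation band, $10^4$ fragments for
  the 50-fold range, 30 units at $r = 0.06$ for the identity regime.

## Limitations

The aligner is quadratic and intended for repeat consensus references, not
genomes. The generator's independence assumptions (per-base mutations,
per-fragment fraction draws conditioned only on the unit) are simpler than
real concerted evolution and real particle biochemistry. Correlations are
computed on a handful of simulated contigs, mirroring the small number of
assemblable arrays in practice — their sampling error is correspondingly
large, which is why the acceptance band is checked on replicate means.
qPCR chemistry is out of scope: percent recovery is reproduced in
count-ratio form only.
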