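# satfrag

Fragment-level occupancy profiling of centromeric alpha-satellite arrays.

Functional human centromeres are built on tandem alpha-satellite DNA:
~171-bp monomers arranged as 340-bp (or 342-bp) head-to-tail **dimeric
units**, one **CENP-B box** per dimer (ancestral 15-bp core
`TTCGTTGGAAACGGG`). Centromeric CENP-A nucleosomes and their associated
CCAN proteins (CENP-B/C/...) protect characteristic fragment lengths from
nuclease digestion, and particle stability can be read out by sequential
salt extraction (no-salt / low-salt / high-salt / pellet fractions).
`satfrag` is for computational biologists analysing such antibody-targeted,
salt-fractionated sequencing data on repeats — and for anyone who needs a
fully truth-labelled synthetic testbed for tandem-repeat chromatin methods.

The package implements, with a ground-truth simulator behind every stage:

* **Direct fragment-length inference** — overlapping 250 × 250-bp mate
  pairs are merged into full-length inserts (3′ Q25 trim, ≥ 15-nt overlap,
  ≥ 25-nt fragments), so length is measured rather than inferred from
  end-mapping, which is ambiguous on near-identical repeats.
* **Tandem-repeat-aware occupancy mapping** — exhaustive end-to-end
  ungapped alignment (best Hamming hit, ≤ 10% mismatches, deterministic
  tie-breaks) to a **triplicated** dimer consensus, then coverage folding
  `p → p mod period` onto the middle dimer, eliminating reference edge
  effects; mass is conserved exactly and the folded profile is invariant
  to alignment tie-breaking.
* **CENP-B box scoring** — score `= max(0, 1 − 0.25 × mismatches)` against
  the ancestral core (1 = perfect, 0 = more than three mismatches), motif
  scanning on both strands at ≤ 3 mismatches, and density per kb.
* **Spike-in calibrated enrichment** — counts scaled by
  `scale_const / spike_count`, fold enrichment versus an IgG control,
  percent recovery per salt fraction, and Pearson correlation of motif
  score/density with fold enrichment.
* **Per-dimer structure** — per-unit occupancy, max/min fold range,
  footprint orientation relative to the CENP-B box (coverage centroid) and
  symmetric vs one-monomer classification; pairwise percent identity of
  units.
* **A synthetic generator** — dimer construction, divergence evolution
  (substitution-only, period-preserving), box-score-linked truth occupancy
  and salt-fraction weights, a three-regime fragment-length mixture
  (~100 / ~172 / ~340 bp), paired-end FASTQ emission with spike-ins and a
  truth table.

## Worked example

Simulate a 10-unit array with 6% divergence, sequence it, and take it
through merging, mapping and per-dimer profiling:

```r
library(satfrag)

arr <- evolve_array(build_dimer(), n_units = 10, divergence_rate = 0.06,
                    seed = 1, name = "D7Z1-like")
arr
#> <satellite_array> 'D7Z1-like': 10 x 340-nt units, divergence rate 0.06
#>   box scores:  1.00 0.75 1.00 0.75 0.50 1.00 1.00 1.00 1.00 0.50

motif_density(array_sequence(arr))
#> <motif_summary> 10 hits in 3400 nt; density 2.941/kb; best score 1
```

Six percent divergence has already degraded several boxes (scores 0.75,
0.50) while the array still carries exactly one detectable box per 340-bp
dimer (2.94/kb). Now attach truth occupancy, emit reads, merge and map:

```r
arr <- assign_truth_occupancy(arr, seed = 2)
fr  <- simulate_fragments(arr, fragment_model(), 5000, seed = 3)
em  <- emit_fastq(fr, read_length = 250, seed = 4,
                  spike_in = list(genome = spike_genome, n_reads = 300),
                  out_dir = "demo", prefix = "CENPA_high_salt")

mg <- merge_pairs(em$r1, em$r2)          # merged 5300 of 5300 pairs
length_histogram(mg, bin_width = 5)      # modal bin: 170-175 nt

spike <- grepl("^spike\\|", mg$fragment_id)
hits  <- align_fragments(mg[!spike, ], array_sequence(arr),
                         ref_name = arr$name)   # 5000 fragments mapped
track <- build_track(hits, array_sequence(arr),
                     calibration_factor = 10000 / sum(spike))

prof <- classify_dimers(per_dimer_occupancy(track, unit_intervals(arr),
                                            box_starts(arr)))
head(prof, 3)
#>   occupancy monomer_a_occ monomer_b_occ centroid_offset orientation  symmetry
#> 1    2455.2        2377.5        2532.9           114.7  downstream symmetric
#> 2    5711.2        5540.8        5881.6           114.3  downstream symmetric
#> 3   24389.4       24308.2       24470.6           109.7  downstream symmetric

occupancy_fold_range(prof)               # 17.8
percent_recovery(table(fr$fraction)[SALT_FRACTIONS])
#> no_salt low_salt high_salt  pellet
#>     2.8     17.0      65.5    14.7
```

The modal merged length (170–175 nt) is the nucleosomal/CCAN protection
peak; per-unit occupancy spans an ~18-fold range driven by the
box-score-linked truth (units with perfect boxes are the heaviest); and
most material sits in the high-salt + pellet fractions, as expected for
stable CENP-A/B/C particles.

For a single-command end-to-end run (simulate → merge → map → motifs →
enrich → dimers, with a manifest and all tables):

```r
res <- run_pipeline(sat_config(seed = 1), "run_out")
```

A thin command-line interface over the same functions lives at
`inst/cli/satfrag.R` (subcommands `simulate`, `merge`, `map`, `motifs`,
`enrich`, `dimers`, `run`, `fixtures`).

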