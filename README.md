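# ctdlab

Repeat-instability analysis for the DNA that encodes the RNA polymerase II
C-terminal domain (CTD).

## The problem

The CTD of Rpb1 is a tandem array of YSPTSPS heptads — 26 in budding yeast —
each encoded by a degenerate 21-bp DNA unit. The array is essential but its
length is unstable: the repeat region expands and contracts by whole units at
rates measurable by fluctuation assay, the coding strand is extremely C-rich
(225 C vs 44 G over the 26 units) so the template strand can form
G-quadruplex structures, and unit-level indels are easily misread as clusters
of point mutations when strains are compared by nucleotide-level alignment.

`ctdlab` implements the computational stages of this analysis:

* **Repeat architecture** — `decompose_repeats()` tiles an anchored repeat
  region into 21-bp units with per-unit best matches and SNPs;
  `align_architectures()` aligns strains with whole units as alignment
  symbols (substitution = inter-unit Hamming distance, unit gap cost 4, so an
  indel is preferred over ≥ 4 coincident SNPs); `group_architectures()` and
  `count_snps()` summarize panels.
* **Signatures** — exact composition (`composition_stats()`), G−C / A−T
  sliding windows of 150 bp with 50 bp overlap (`skew_windows()`), and
  QGRS-style G-quadruplex motif calls: four G-tracts of ≥ 2 G with loops of
  1–9 bases (`find_g4_motifs()`).
* **Fluctuation analysis** — the Luria–Delbrück count distribution
  `p_0 = e^{-m}`, `p_k = (m/k) Σ_{i<k} p_i/(k−i+1)` (in C++), the
  Ma–Sandri–Sarkar maximum-likelihood estimate of `m`, Stewart 95%
  confidence intervals `exp(ln m̂ ± 1.96 · 1.225 m̂^{−0.315}/√C)`, and
  rate = `m̂ / N_t` with `N_t` from dilution-control plates
  (`estimate_rate()`).
* **Events** — amplicon-length classification into expansion / contraction /
  recombination / other (`classify_events()`), per-strain tallies with
  integer percentages (`tally_events()`), deletion-junction calls with
  microhomology and placement ambiguity (`find_deletion_junction()`), and
  viability from functional repeat count (`viability_class()`).
* **Synthetic data** — seeded generators with ground truth for every stage:
  constructs with planted stop codons, strain panels with planted unit
  gains/losses/SNPs, calibrated fluctuation assays, suppressor spectra.
* **IO / CLI** — FASTA and TSV readers/writers, a seeded end-to-end
  `pipeline_run()`, and an umbrella command line
  (`inst/scripts/ctdlab.R`) with `decompose`, `fluct`, `classify` and
  `simulate` subcommands.

Everything is tidyverse-native: tibbles in and out, `tidy()`/`glance()`
methods, `autoplot()` and `plot_*()` builders.

## Worked example

```r
library(ctdlab)
lib <- ctd_repeat_library()
lib
#> <ctd_repeat_library>
#>   unit_length: 21 bp
#>   known_units: 26 (25 distinct)
#>   heptad_consensus: YSPTSPS
#>   anchors: GATGAAGCTCAAGCTGGTTTC ... TAAGCTTCTGAAGAAGACAAC

# A 26-unit construct with stop codons in units 8-11 (the contraction
# reporter): 7 functional repeats remain, below the 8 needed for viability.
fourstop <- build_ctd_construct(26, lib, stops_at_units = 8:11)
d <- decompose_repeats(fourstop$sequence, lib, strain_id = "4stop")
d
#> <ctd_decomposition> 4stop - 26 units of 21 bp, 4 SNP(s) vs library
tc <- translate_and_check(d)
tc$functional_repeats
#> [1] 7
viability_class(tc$functional_repeats)
#> [1] "inviable"

# A fluctuation assay at true rate 26e-6 per cell per generation: note the
# culture-to-culture "jackpot" variance characteristic of Luria-Delbruck.
sim <- simulate_fluctuation_assay(C = 12, mu = 26e-6, Nt = 1e6, seed = 42)
sim$experiment$selective_counts
#>  [1]   72  139 4874 1226  100   52   56  164  121  167   66  532
tidy(estimate_rate(sim$experiment))
#> # A tibble: 1 x 8
#>   label     m_hat     Nt      rate    ci_low   ci_high     C flags
#>   <chr>     <dbl>  <dbl>     <dbl>     <dbl>     <dbl> <int> <chr>
#> 1 simulated  25.4 985000 0.0000257 0.0000200 0.0000331    12 ""

# A deletion junction: unique placement (microhomology 0) but 3 bp of
# homology visible on the two retained flanks.
find_deletion_junction("AAATTTCCCGGGTTTAAA", "AAATTTTTTAAA")
#> # A tibble: 1 x 8
#>   deletion_start deletion_end deleted_bp microhomology_len placement_min
#>            <int>        <int>      <int>             <int>         <int>
#> 1              6           12          6                 0             6
#> # i 3 more variables: placement_max <int>, flank_homology <int>, flag <chr>
```

See `vignettes/methods.Rmd` for the model assumptions, parameter defaults,
numerical choices and generator limits.

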