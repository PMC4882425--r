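---
title: "Methods: repeat decomposition, fluctuation analysis and event calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat decomposition, fluctuation analysis and event calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ctdlab)
```

# The biological setting

The C-terminal domain (CTD) of Rpb1, the largest subunit of RNA polymerase II,
is a tandem array of seven-amino-acid repeats with consensus **YSPTSPS**. In
budding yeast the array holds 26 repeats, each encoded by a 21-bp DNA unit.
The DNA units are *degenerate*: synonymous codon choices make most units
differ from each other at several positions even though nearly all translate
to the same heptad. Two consequences drive everything in this package:

* The coding strand is strongly C-rich and G-poor (225 C vs 44 G over the 26
  units), so the template strand is G-rich and can form G-quadruplex (G4)
  structures that stall replication.
* Because the units are similar but not identical, the repeat region both
  expands and contracts by whole units at measurable rates, and whole-unit
  indels can masquerade as clusters of point mutations if sequences are
  aligned at the nucleotide level.

The package provides the computational stages needed to study this
instability: unit-level decomposition and alignment of repeat architectures,
strand-composition and G4 signature scanning, Luria-Delbrück fluctuation
analysis of mutation rates, suppressor-event classification with deletion
junction calling, and seeded generators that produce ground-truth data for
every stage.

# The synthetic repeat library

Real unit-by-unit sequences for a reference strain are not bundled.
`ctd_repeat_library()` instead carries 26 hand-constructed 21-bp units that
reproduce the documented aggregate properties of the natural array:

* every unit translates to YSPTSPS in frame;
* the units are degenerate at synonymous positions, with 25 distinct
  sequences among 26 (units 1 and 17 are identical, so best-match calls
  break ties toward the lowest-numbered unit);
* the totals over the 26 units are exactly C = 225 and G = 44 on the coding
  strand, which preserves the skew and G4 asymmetry between strands.

```{r}
lib <- ctd_repeat_library()
lib
composition_stats(paste(lib$known_units, collapse = ""))
```

All downstream defaults (anchors, unit length 21) come from this library
object, and `read_repeat_library()` can load a replacement from FASTA + YAML
when real sequences are available.

# Repeat decomposition and architecture alignment

`decompose_repeats()` anchors the repeat span between fixed flanking
sequences, requires the span to be a whole number of 21-bp units (a non-zero
residue is a frame error), tiles it in frame, and assigns each observed unit
its closest library unit by Hamming distance, reporting mismatches as SNPs
with 0-based offsets. Tiling from a fixed anchor rather than searching all
frames is deliberate: the biological repeat is in frame with its flanks, and
the brute-force all-frames tiler used in the test suite confirms the anchored
tiling is always among the valid tilings.

`align_architectures()` aligns strains at the **unit level**: alignment
symbols are whole 21-bp units, substitution cost is the unit-to-unit Hamming
distance (1 per base) and a whole-unit gap costs 4. With these defaults an
indel is preferred over four or more coincident SNPs — the encoding of the
rule that repeat-length changes must not be misread as clusters of point
mutations, while one to three genuine SNPs never get turned into spurious
indel pairs. Alignment is progressive against a profile whose column
representative is the modal unit; a strain whose unit sequence is identical
to an already-aligned strain reuses that strain's gap pattern, so identical
sequences always receive identical gapped rows regardless of input order.
Events are then called per column against the column consensus
(`unit_loss`, `unit_gain`, `snp`), `group_architectures()` groups identical
gapped rows, and `count_snps()` counts SNP occurrences or unique sites.

```{r}
base <- build_ctd_construct(26, lib)
d <- decompose_repeats(base$sequence, lib)
d
translate_and_check(d)$functional_repeats
```

# Composition, skew windows and G4 motifs

`composition_stats()` counts bases exactly (with an explicit policy for
ambiguity codes: error by default, `skip` on request). `skew_windows()`
computes G−C and A−T in 150-bp windows with 50 bp of overlap (stride 100) by
default; a deep G−C trough localizes the C-rich repeat region inside a
larger genomic context.

`find_g4_motifs()` implements a QGRS-style scan: a motif is four G-tracts of
at least `min_tract = 2` guanines separated by loops of 1-9 bases
(`max_loop = 9` encodes "fewer than 10"), with total span at most
`max_span = 45`. Candidate tracts include all sub-tracts of maximal G-runs,
so a GGGG run can contribute a 2-tract when that produces a better motif.
Scoring is `sum(tract lengths) − (max loop − min loop)`, favouring long
tracts and even loops; overlapping candidates are resolved greedily by score
(ties toward the leftmost start). The minus strand is scanned as the reverse
complement with coordinates mapped back. An exhaustive 4-tuple enumerator in
the test suite verifies both motif membership and best-score equality on
random G-dense strings up to 60 bp.

```{r}
find_g4_motifs(paste(lib$known_units, collapse = ""), strand_mode = "-")[1:3, ]
```

# Fluctuation analysis

A fluctuation assay grows `C` parallel cultures from `N0 = 1` to
`Nt ≈ 1e6` cells, plates each culture selectively, and counts suppressor
colonies. Under the Luria-Delbrück model the colony counts follow the
distribution generated by Poisson-many mutation events whose clone sizes
follow `P(clone = j) = 1/(j(j+1))`. The package computes this distribution
with the standard recursion

```
p_0 = exp(-m);   p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1)
```

implemented in C++ (`ld_pmf()`), and `mss_mle()` maximizes the likelihood
of the observed counts over `log m` with `stats::optimize()` on
`[1e-6, 1e3]` at tolerance `1e-6`. Numerical choices:

* **Jackpot cap `k_cap = 1e4`:** cultures occasionally produce enormous
  "jackpot" counts; counts at or above `k_cap` are pooled into a tail class
  with probability `1 − sum(p_0..p_{k_cap−1})`, so jackpots inform the
  likelihood without forcing million-term recursions.
* **Zero-count flag:** an all-zero experiment has its maximum at the bracket
  floor; the estimate is flagged `"zero-count"` and should be read as an
  upper bound.

Confidence intervals use the closed-form Stewart approximation:
`sigma_lnm = 1.225 * m^(-0.315) / sqrt(C)` and bounds
`exp(ln m ± 1.96 sigma)`. The rate per cell per generation is `m / Nt`,
with `Nt` estimated from control plates at a `1e4`-fold dilution
(`estimate_Nt()`), and a plating-fraction correction applied when less than
the whole culture is plated. Over 500 simulated 12-culture assays the
nominal 95% intervals cover the true rate 90-99% of the time (the Stewart
approximation is slightly conservative at small `C`).

```{r}
sim <- simulate_fluctuation_assay(C = 12, mu = 26e-6, Nt = 1e6, seed = 1)
est <- estimate_rate(sim$experiment)
tidy(est)
```

# The growth simulator: model and limits

`simulate_fluctuation_assay()` draws `M ~ Poisson(mu * (Nt - N0))`
mutations per culture, places each uniformly over the `Nt - N0` cell
divisions, and expands each mutant clone deterministically to
`floor(Nt / n)` cells where `n` is the population size at occurrence. This
choice is exactly the Luria-Delbrück clone law: `P(clone >= j) = 1/j` up to
`O(N0/Nt)`, and the resulting count distribution matches `ld_pmf()` — a
chi-square goodness-of-fit over 3e5 simulated cultures confirms the
agreement in the test suite. A discrete generation-by-generation
birth process was considered and rejected: with doubling generations the
clone sizes are powers of two, which visibly distorts the per-bin
probabilities against the continuous-growth pmf the estimator assumes.

Limits of realism, by design: no mutant/wild-type fitness difference, no
cell death, no reverse mutation, deterministic clone growth, and a guard
that rejects `mu * Nt >= 1e3` (outside the regime where `m` is estimable
from 12 cultures). These match the assumptions of the MSS estimator; the
simulator exists to validate the estimator and to generate calibrated
fixtures, not to model biology beyond the estimator's scope.

# Suppressor events and deletion junctions

`classify_events()` calls colony classes from amplicon lengths with a
`tolerance_bp = 10` band (under half a unit, so calls quantize to whole
units): within tolerance of the reference is `other`; shorter is
`contraction`; longer is `recombination` when the band sits at the genomic
26-unit wild-type length *and* the reporter is the 8-unit expansion
reporter (for the 26-unit stop-codon reporter a recombination band is
indistinguishable from the reference by PCR, so it folds into `other`);
any other longer band is `expansion`. `tally_events()` recomputes totals
from class counts (warning when a supplied total disagrees) and reports
integer percentages with half-up rounding. Note one inherent degeneracy:
an expansion of exactly +18 units lands at the wild-type length and cannot
be distinguished from recombination by length alone.

`find_deletion_junction()` calls the single contiguous deletion turning a
parent sequence into a suppressor sequence, using the longest common prefix
`P` and suffix `S`:

* a single deletion exists iff `|P| + |S| >= len(suppressor)`, otherwise
  the pair is flagged `multi-segment`;
* `microhomology_len = |P| + |S| − len(suppressor)` counts the equivalent
  one-base shifts of the junction (the placement ambiguity), and the
  **leftmost** placement is reported for determinism in maximally ambiguous
  repeat substrates;
* `flank_homology` separately reports the longest identity between the end
  of the retained 5' flank and the start of the retained 3' flank — the
  homology "visible on both sides of the junction", which is non-zero even
  when the junction placement itself is unique.

The distinction matters: placement ambiguity and flanking homology are
different observables, and conflating them misstates microhomology for
junctions whose adjacent bases differ. An exhaustive deletion-pair oracle
verifies the placement range and ambiguity count on random pairs up to
500 bp.

```{r}
find_deletion_junction("AAATTTCCCGGGTTTAAA", "AAATTTTTTAAA")
```

`check_suppressor_protein()` and `viability_class()` close the loop to
phenotype: fewer than 8 functional repeats (heptads before the first stop)
cannot support growth, 8-9 grow impaired, 10 or more grow normally.

# Generators and ground truth

Every stage has a seeded generator returning data plus a truth table:
`build_ctd_construct()` (constructs with optional Tyr1→TAA stop codons, the
construction of the stop-codon reporter), `mutate_panel()` (strain panels
with planted whole-unit losses/gains and SNPs, or a fixed number of distinct
architecture templates), `simulate_fluctuation_assay()` (above) and
`simulate_suppressor_spectrum()` (amplicon-length spectra quantized to whole
units). The test suite uses these truths for exact-recovery checks and the
independent oracles for algorithmic ones.

# Problem sizes and runtime

The implementation targets the scales of the motivating experiments:
repeat regions of ≤ ~30 units, strain panels of ~36, fluctuation assays of
12 cultures with `Nt = 1e6`, suppressor screens of ≤ a few hundred
colonies, and G4 scans over kilobase-scale constructs. At these scales every
operation is sub-second except assay simulation/estimation in bulk
(hundreds of assays take tens of seconds). The oracle-based test suite and
the acceptance script (`scripts/acceptance.R`) run in a few minutes on one
CPU.
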