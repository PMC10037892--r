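---
title: "Methods: probe design and FISH-guided assembly curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe design and FISH-guided assembly curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyopaint)
```

# Overview

`karyopaint` models the full loop of Oligopaint-based chromosome-level
assembly curation: design oligo probes against draft scaffolds, observe
where they hybridize on metaphase spreads, and feed that evidence back
into the assembly as splits, orientations, an ordered AGP build and a
numbered karyotype. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic-data module
does and does not emulate.

# Oligo thermodynamics

Melting temperatures use the unified nearest-neighbor parameter set
(dinucleotide stack enthalpies/entropies plus terminal initiation
terms), with:

* **Salt**: an entropic monovalent correction,
  ΔS′ = ΔS + 0.368 (N−1) ln[Na⁺] cal mol⁻¹ K⁻¹. Default
  `salt_molarity = 0.39` (2×SSC).
* **Strand concentration**: Tm uses R ln(C_T/4) with
  `oligo_conc_M = 5e-8` (50 nM total strand), the non-self-complementary
  convention.
* **Formamide**: a linear depression of `formamide_coef = 0.72` °C per
  percent formamide, configurable; the mining default assumes a 50 %
  formamide hybridization buffer.

Hairpin stability is scored by exhaustive stem–loop enumeration: every
loop-closing pair with loop ≥ 3 nt and every fully Watson–Crick stem of
≥ 3 bp grown outward from it, scored as stack free energies at the
evaluation temperature plus a loop-size penalty. The loop penalty table
is anchored at published 37 °C hairpin-loop initiation values
(interpolated for 3–30 nt, Jacobson–Stockmayer extrapolation beyond) and
rescaled entropically to other temperatures. Dimer stability scans every
antiparallel alignment of two oligos and scores each maximal run of
complementary pairs with stacks plus terminal initiation. Both models
ignore mismatched/bulged stems and dangling ends: they are screening
filters, not folding predictions, and the corresponding tests hold the
implementation to an independent exhaustive oracle rather than to
experimental values.

# Candidate mining

`mine_candidates()` tiles 39-nt windows greedily left to right: a window
must contain no masked base (N or lowercase), fall inside the GC window
(default 20–80 %) and the Tm window (default 42–47 °C under the
formamide condition), and successive windows are separated by at least
`spacing` bases (default 0). Greedy tiling makes the candidate set a
deterministic function of the scaffold, which the brute-force oracle in
the test suite re-derives independently. Genome-wide uniqueness is an
exact k-mer filter: a candidate is rejected when any constituent 18-mer
occurs more than `max_kmer_count_allowed = 5` times in the genome,
counting both strands. This replaces aligner-based uniqueness screening
(two-mode alignment with an intersection of survivors) with a
dependency-free filter of the same intent; it is exact for the planted
exact repeats the toy genomes contain and conservative for diverged
repeats, which the generator does not model. The k-mer length and count
threshold are design choices, not published values, and are exposed as
parameters. Secondary structure is screened at the hybridization
temperature (default 42 °C) with threshold 0 kcal/mol: any
thermodynamically favourable hairpin fails. All four filters are
annotate-and-subset operations on the candidate table, so they commute —
a property the suite asserts.

# Probe-count allocation and window selection

Probe counts per scaffold follow a tiered rule: the largest scaffold
gets 5 probes, scaffolds under mis-assembly suspicion at least 4, the
rest 3/2/1 by decreasing length. The published 68-scaffold design
(1×5, 2×4, 29×3, 34×2, 2×1 = 170 probes = 255,000 oligos in three
91.5 K-oligo synthesis libraries) is reproduced by passing its tier
sizes explicitly, because the tier boundaries depend on the actual
scaffold length distribution, which is not part of this package's
inputs. Without explicit tiers, the allocator searches all tier
boundaries exhaustively and maximises the probe count under the oligo
budget, breaking ties toward larger tiers for longer scaffolds. Note
that pure budget maximisation under the published capacities yields more
probes (183) than the published design (170): the published tiering used
length thresholds, not budget saturation, which is why the explicit-tier
path exists.

Probe windows are runs of `n_oligo` consecutive candidates
(default 1500). Selection minimises, lexicographically over the summed
window criteria, (1) *centrality* — distance of each window centre from
its ideal equally-spaced position, (2) *homogeneity* — variance of
inter-oligo spacing, (3) *size* — window span; subject to a minimum
edge-to-edge gap and a minimum distance from scaffold termini (relaxed
with a warning when infeasible). These three criteria are stated
stand-ins for the published ordering keywords of the probe-query tool;
the exact published formulas are not public. The optimisation is a
dynamic program over windows sorted by start with slot-ordered
transitions; additive tuple scores compared lexicographically preserve
optimal substructure, and a small-instance exhaustive oracle pins the
implementation. Defaults of `min_gap` (7 Mb) and
`min_terminus_distance` (250 kb) reflect the smallest values observed to
work at mammalian genome scale and should be scaled down proportionally
for toy genomes (the tests use gaps of a few hundred bases).

# Orthogonal barcodes

The barcode workflow slices each 25-mer of an orthogonal pool into its
six 20-mers, then applies two filters:

* **Genome homology**: best ungapped local alignment (match +1,
  mismatch −2) against both genome strands, seeded by an exact 6-mer
  word; the best score converts to a Karlin–Altschul e-value
  (λ = ln((3+√21)/2) from the score distribution at uniform base
  composition; K = 0.333, configurable) over the two-strand search
  space. Sequences with e-value **below** 25 — i.e. with detectable
  genomic homology — are removed. The source description of this filter
  is self-contradictory (it says both "filtered out" and "isolate
  candidates with high-quality homology"); this package resolves it in
  the only direction compatible with the barcodes' purpose, which is
  orthogonality to the genome. Note the e-value scales with genome
  size: on toy genomes the same cutoff is far stricter than on a
  gigabase genome.
* **Dimers**: self- and hetero-dimer free energy at 37 °C must stay
  ≥ −9 kcal/mol. Hetero-dimer screening is greedy in pool order
  (a maximum compatible subset is NP-hard); greedy order makes the
  retained set deterministic and matches how practical pipelines screen
  primer sets.

Roles are attributed with GC-clamp preference (≥ 2 G/C among the 3
terminal bases — the clamp itself is not defined in the source and this
definition is a documented choice): 5′-clamped sequences go to reverse
primers, 3′-clamped to forward primers. Reverse primers are
scaffold-specific within a library but one reverse sequence serves the
same slot across libraries (cap 4 scaffolds); forward primers and
adapters are fluorophore-specific and shared across libraries. Final
oligos are reverse(20) + homolog(39) + forward(20) = 79 nt; the reverse
amplification primer is the 33-nt T7 extension followed by the reverse
complement of the reverse 20-mer (53 nt), the forward amplification
primer is adapter + forward (40 nt), and the detector is the adapter's
reverse complement carrying the fluorophore.

Colour schemes use 3 fluorophores and their 3 unordered pairs
(FAM+ATTO550 = green, ATTO550+ATTO647 = orange, FAM+ATTO647 = violet),
six colours total; ordered per-scaffold patterns are enumerated
deterministically and must be unique within a hybridization pool
(6^k patterns exist for k-probe scaffolds; the allocator raises an
error suggesting a pool split when a pool exceeds that). Probes with a
composite colour alternate oligos between the two fluorophores'
forward/adapter pairs.

# Curation model

Scaffold assignment is majority voting: a probe needs
`min_spreads = 2` concordant spreads (the source validated placements by
re-hybridization on additional spreads without stating a count; two
concordant spreads is the weakest defensible rule). Observations whose
colour contradicts the design invalidate the observation, not the
probe. A scaffold is *chimeric* when its placed probes vote for ≥ 2
chromosomes; otherwise *reordered* when the consensus signal order is
neither the design order nor its full reversal (a full reversal is just
the opposite orientation); chimerism takes precedence, so no scaffold is
both.

Breakpoints are localized inside the inter-probe gap flanking the
chromosome switch: alignments to a reference genome narrow the gap to
the interval between the last block consistent with the left reference
chromosome and the first consistent with the right; with no informative
alignment the full gap is reported with evidence `midpoint_fallback`.
The point estimate used for splitting is the interval midpoint, and the
interval is preserved in the output — signal resolution, not base
precision, is the honest claim of a FISH-derived breakpoint.

Orientation comes from late-metaphase observations (chromatids
separated, centromere side visible): per spread, the sign of the Kendall
correlation between design order and signal order from the centromere;
unanimous votes set "+" or "−" ("rev"), a majority sets it with the
minority discarded, an exact tie leaves orientation unset with a
warning. Single-probe parts stay "+" with a low-confidence flag — one
signal cannot orient. Part names follow the probe-range convention
`<scaffold>p<a>-<b>` (0-based design probe indices).

The AGP build (v2.1) lays parts centromere-to-telomere with U gap rows
of 100 bp, gap type "scaffold", linkage "yes", evidence "map" — FISH
placement is map evidence; the gap size is arbitrary and configurable.
Karyotype numbering orders autosomes acrocentric → submetacentric →
metacentric, by decreasing relative length within each class, with the
sex chromosome labelled X and excluded; length ties break by composition
string, reported via a message. Relative lengths divide each spread's
measurements by that spread's X length (cancelling per-spread
compaction exactly) and rescale by the grand-mean X length so values
keep the measurement unit — this treats the published "relative length
(µm)" as X-normalized micrometres, the only reading consistent with
both the unit and the normalization description.

# Synteny and rearrangements

Whole-genome alignments (PAF) chain into synteny blocks when co-linear
on the same strand with query and reference gaps ≤ `max_gap`; blocks
shorter than `min_block` on the query are dropped. At mammalian scale
100 kb / 500 kb are reasonable defaults; toy-genome tests scale both
down by three orders of magnitude. Chromosome association tables
aggregate aligned bases per chromosome pair and conserve them exactly on
unfiltered runs.

Rearrangement classification is a bounded exhaustive search over signed
block arrangements with four operations: inversion (segment reversed
with sign flip), fission (chromosome split), fusion (concatenation in
any relative orientation) and translocation (orientation-preserving
segment move). Chromosomes are flip-invariant. A breadth-first search
finds the minimal event count (bound `max_events = 4`, instances capped
at 10 blocks — raise `min_block` to get fewer, larger blocks); a
distance-to-target map then guides complete enumeration of all minimal
scenarios. When minimal scenarios disagree on event order the result
says so (`chronology_determined = FALSE`) and reports every order — the
classifier never picks one arbitrarily, which matters because the
canonical four-block ancestral-chromosome case genuinely cannot decide
whether its fission or its translocation came first. Inversions whose
segment reaches the proximal (first-drawn, centromere-bearing) end of
the chromosome are flagged pericentric; this convention models
acrocentric chromosomes drawn centromere-first and is a simplification —
the search does not track centromere inheritance through fissions.
Duplications and deletions are outside the event model.

# What the synthetic data does and does not emulate

`generate_toy_genome()` emulates a karyotype of mostly acrocentric
chromosomes (centromere within the first 5 % of the chromosome),
optionally submetacentric (25–35 %) and metacentric (45–50 %), with
exact internal repeat duplications up to a target base fraction.
`fragment_into_scaffolds()` plants the two documented mis-assembly
classes: chimeric joins between two chromosomes and internal
inversions, both recorded in a truth table that reassembles the genome
bases exactly. `simulate_hybridization()` ranks probe signals by
distance from the centromere, applies independent per-probe dropout and
a per-spread multiplicative log-normal compaction factor (chromatin
condensation varies with mitotic stage across spreads, which is why
relative lengths are X-normalized).

Deliberately not modelled: sequence divergence within repeats (the
k-mer filter sees exact copies — its easiest adversary), fluorescence
intensity and optical resolution limits, signal cross-talk between
nearby probes, diploidy and heterozygosity, and sequencing reads.
Passing the end-to-end tests therefore demonstrates the logic of the
curation calculus — not robustness to microscopy noise, which enters
real data upstream of this package's inputs.

# Problem sizes and determinism

The test suite and acceptance script run toy genomes of 5–11
chromosomes of 25–40 kb, 8–10 scaffolds with 2 planted chimeras and 1
planted inversion, 3-probe plans, 3–4 spreads, and rearrangement
instances of up to 6 blocks — sizes chosen so every brute-force oracle
(full DP alignment, exhaustive placement, quadratic contiguity checks,
breadth-first rearrangement distance) runs in seconds while still
exercising every code path. Every stochastic step takes an explicit
integer seed, uses one RNG scoped to the call (`withr::with_seed`), and
is bit-reproducible given (parameters, seed).

# Known limitations

* The Tm/ΔG models are screening-grade: no mismatch/bulge parameters,
  no dangling ends, single salt correction.
* The e-value uses a fixed K rather than the exact Karlin–Altschul K
  for the score system; relative ordering of hits is unaffected.
* Greedy dimer screening is order-dependent by design; re-ordering the
  pool can change the retained set (deterministically).
* The allocator reproduces a recorded tier structure exactly only when
  given it; length-threshold tiering from real scaffold lengths is the
  user's call.
* Rearrangement parsimony is bounded exhaustive search, not DCJ theory:
  fine at ≤ 10 blocks / ≤ 4 events, unsuitable beyond.
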