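# karyopaint

Oligopaint FISH probe design and FISH-guided chromosome assembly curation.

## The problem

Draft genome assemblies of non-model species typically stop at the
scaffold level: thousands of sequences with no chromosome assignment, and
an unknown number of assembly artifacts among them. Oligopaint
fluorescence in situ hybridization (FISH) offers an orthogonal, physical
route to chromosome level: pools of synthetic oligos — each a
genome-homologous segment flanked by shared amplification and detection
sequences — paint chosen scaffold regions in distinguishable colours on
metaphase chromosome spreads. Observing where the colours land assigns
scaffolds to chromosomes, exposes chimeric scaffolds (one scaffold
lighting up two chromosome pairs), reveals internal ordering errors,
orients scaffolds relative to the centromere, and yields a numbered
karyotype with relative chromosome lengths.

`karyopaint` implements this workflow end to end for users designing
probe libraries against a draft assembly and interpreting the resulting
hybridization evidence:

* **Oligo mining** — fixed-length (39-nt) genome-homolog candidates
  filtered on masking, GC, nearest-neighbor melting temperature,
  genome-wide k-mer abundance (uniqueness) and predicted hairpin
  structure at the hybridization temperature.
* **Probe design** — per-scaffold probe-count allocation under a
  synthesis-library budget; selection of probe windows (1500 oligos
  each by default) under spacing and terminus constraints with
  centrality/homogeneity/size criteria; fluorophore colour schemes
  (3 fluorophores, 6 colours) unique within each hybridization pool.
* **Orthogonal barcodes** — slicing a 25-mer orthogonal pool into
  20-mers, removing genome-homologous ones (ungapped local alignment +
  Karlin–Altschul e-value), screening self/hetero-dimers by
  nearest-neighbor duplex free energy (keep ΔG ≥ −9 kcal/mol),
  attributing reverse/forward/adapter/detector roles (GC-clamp aware)
  and assembling the final 79-mers plus amplification primers.
* **FISH curation** — majority-vote scaffold assignment, detection of
  chimeric and reordered scaffolds, breakpoint localization by synteny
  with a reference genome (PAF alignments), splitting and orientation of
  scaffold parts, AGP v2.1 output and karyotype numbering
  (acrocentric → submetacentric → metacentric, by decreasing relative
  length, X excluded from autosome numbering).
* **Assembly metrics** — N50, L90 (`l_fraction`), and per-chromosome
  relative lengths that cancel per-spread chromatin-compaction noise by
  normalizing to the X chromosome.
* **Synteny comparison** — chaining whole-genome alignments into synteny
  blocks, cross-genome chromosome association tables (Sankey input) and
  parsimony classification of rearrangements (fission, fusion,
  translocation, inversion) by bounded exhaustive search over signed
  block arrangements, reporting all minimal scenarios when the event
  chronology is undetermined.
* **Synthetic data** — toy genomes with planted repeats, chimeras and
  inversions, plus simulated hybridization observations and reference
  alignments with known truth, so the whole pipeline is testable without
  any external data.

## Core quantities

Melting temperature uses unified nearest-neighbor thermodynamics,

  Tm = ΔH / (ΔS + 0.368 (N−1) ln[Na⁺] + R ln(C_T/4)) − 273.15 − 0.72 f,

with ΔH, ΔS summed over dinucleotide stacks plus terminal initiation, N
the oligo length, C_T the strand concentration and f the formamide
percentage. Hairpin and dimer stabilities evaluate the same stack table
at the hybridization temperature (ΔG(T) = ΔH − TΔS), over exhaustive
stem-loop configurations and all antiparallel duplex alignments
respectively. N50 is the smallest length whose descending cumulative sum
reaches half the assembly; L90 the minimal number of largest sequences
reaching 90 %. Rearrangement classification minimises the number of
events transforming the reference block arrangement into the query
arrangement.

## Worked example

Curating a toy draft genome with one planted chimera:

```r
library(karyopaint)
g    <- generate_toy_genome(5, c(2.5e4, 4e4), seed = 7)
sc   <- fragment_into_scaffolds(g, n_scaffolds = 8,
                                chimera_spec = list(c("chr2", "chr5")),
                                seed = 8)
plan <- plan_probes(sc, n_probes = 3, span = 600)
obs  <- simulate_hybridization(plan, sc, g, n_spreads = 3, seed = 9)
a    <- assign_scaffolds(obs, plan)
an   <- detect_anomalies(a, plan)
an
#>   scaffold_id   status
#> 1          s1 chimeric
#> 2          s2    clean
#> ...
```

Scaffold s1 is flagged chimeric; synteny alignments narrow its breakpoint
to a 129 bp interval containing the true junction (10,629):

```r
paf <- simulate_reference_alignments(sc, g)
locate_breakpoints(an, plan, paf)[, c(1:4, 7)]
#>   scaffold_id left_bound right_bound midpoint evidence
#> 1          s1      10550       10679    10614  synteny
```

Splitting, orienting and building chromosomes shows the contiguity gain:

```r
parts <- split_and_orient(tapply(sc$truth$scaffold_end,
                                 sc$truth$scaffold_id, max),
                          locate_breakpoints(an, plan, paf), a, plan)
composition_strings(parts)["chr2"]
#>          chr2
#> "s1p0 s2 s7"
agp <- build_chromosomes(parts)
n50(nchar(sc$seqs))                          # scaffold N50: 9869
n50(tapply(agp$object_end, agp$object, max)) # chromosome N50: 19538
```

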