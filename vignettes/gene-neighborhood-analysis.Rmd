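---
title: "Conserved gene-neighborhood analysis with geneContext"
author: "geneContext authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved gene-neighborhood analysis with geneContext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneContext)
```

# The analysis

In prokaryotes, genes that work together tend to stay together: they sit
in operons, are co-transcribed, and keep reappearing next to each other
across distantly related genomes.  `geneContext` implements the classic
comparative-genomics workflow that exploits this -- "guilt by
association" -- to annotate uncharacterized gene families:

1. **Gene-neighborhood extraction.** Given a query gene, take the *k*
   nearest genes on each side (default *k* = 5) from a PTT protein table
   or GenBank annotation.
2. **Directon inference.** Partition each replicon into *directons*:
   maximal runs of consecutive same-strand genes in which every
   intergenic gap is at most a threshold (default 150 nt).  A directon
   is the standard coordinate-only proxy for an operon; its members
   plausibly share a promoter.  Divergently transcribed ("head-to-head")
   gene pairs within the same gap threshold are additionally treated as
   sharing a bidirectional promoter.
3. **Neighbor clustering.** Cluster the proteins found in all query
   neighborhoods into families by single-linkage over pairwise local
   alignment (BLOSUM62, affine gaps 11/1), with an edge where identity
   and bidirectional coverage pass thresholds -- the same logic
   BLASTCLUST applies.  Clusters are labeled by their majority domain
   architecture when an architecture table is supplied.
4. **Cross-genome association.** For every partner family, count the
   distinct genomes where it occurs in the query's window, and
   separately where it shares the query's (bidirectional) promoter.
   Attach an empirical p-value by shuffling gene identities over each
   replicon's fixed coordinate/strand template.
5. **Iterative homology search.** Separately, the package implements the
   search discipline used to assemble such families: an inclusion
   threshold (e ≤ 0.01), a profile built from accepted members, and
   *reciprocal validation* -- every new hit must itself retrieve an
   accepted member before it may join, which guards the profile against
   corruption by false positives.
6. **Consensus annotation.** Alignment columns are summarized with
   physicochemical class codes (h hydrophobic, p polar, s small, u tiny,
   l aliphatic, o hydroxylic = {S,T}, a aromatic, b big, c charged,
   + positively charged), and sequences can be scanned for degenerate
   class-coded motifs such as `DsoW`.

Everything can be exercised on synthetic genomes with planted ground
truth (`simulationSpec()` / `generateCohort()`), which is how the test
suite and the acceptance script validate the pipeline end to end.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `k` | 5 | genes | window half-width around the query |
| `maxGap` | 150 | nt | directon gap bound (inclusive; overlaps pass) |
| `bidirectionalGap` | 150 | nt | head-to-head promoter-sharing bound |
| `minIdentity` | 0.30 | fraction | similarity-edge identity threshold |
| `minCoverage` | 0.70 | fraction | aligned-span fraction, both sequences |
| `eCut` | 0.01 | e-value | search inclusion threshold (inclusive) |
| `minGenomes` | 3 | genomes | reporting floor for associations |
| `nPermutations` | 1000 | — | empirical-null resolution |

`k`, `maxGap` and `eCut` are the standard values for this kind of
analysis and are surfaced in the run manifest.  The clustering
thresholds are conventional family-level settings: the literature
behind BLASTCLUST-style protocols reports only "empirically determined"
cut-offs, so 30% identity with 70% bidirectional coverage was fixed
here once and made fully configurable.  Identity is computed over
aligned columns excluding gap columns; coverage is the aligned span
divided by each full sequence length, and must hold for *both*
sequences (the stricter mode, which prevents a single promiscuous
domain from stitching unrelated families together under single
linkage).

Three boundary conventions are deliberate and tested: the gap
comparison is inclusive (a 150-nt gap joins a directon), overlapping
genes always satisfy the gap rule (overlap is stronger evidence of
co-transcription than a short gap), and the search threshold is
inclusive (a hit at exactly e = 0.01 is a candidate).

## Window extension

Neighborhoods are occasionally wider than ±k when the query sits in a
long operon.  The rule is deterministic: when the query's directon
extends past the window edge, the window grows to cover the whole
directon (`extendThroughDirecton`, on by default).  This is the
narrowest reading of "extend for long neighborhoods" that is testable.

# The synthetic cohort generator

`generateCohort()` emulates exactly the structure the analysis assumes:

* genomes laid out as successive transcription units with sizes
  1 + Geometric(p) (default p = 0.5, mean two genes per unit), one
  strand per unit, intra-unit gaps uniform on [0, 150] nt and
  inter-unit gaps on [151, 1000] nt.  Because the two ranges are
  disjoint at the 150-nt boundary, `inferDirectons()` at the default
  threshold recovers the planted unit layout *exactly*, which turns the
  layout into a free oracle;
* protein families evolved from random ancestors by independent
  per-site substitution with probability *d*, replacements drawn
  uniformly from the 19 alternative residues (so ancestor-member
  identity is 1 − d in expectation, and the identity arithmetic used in
  tests stays closed-form);
* background genes as independent random sequences at uniform
  composition, so inter-family identity sits at chance level;
* planted contexts that insert a partner-family member adjacent to the
  query inside one unit (`same_directon`) or within a window offset
  otherwise.

Presence fractions are honored as **exact genome counts**
(`round(fraction × nGenomes)` over a seed-determined random subset)
rather than independent coin flips.  A planted "partner in 12 of 20
genomes" is then exactly 12, which makes ground-truth comparisons sharp
instead of binomially fuzzy.

Family ancestors in the validation cohorts are 170-520 residues long --
ordinary protein sizes (the average bacterial protein is roughly 300
residues).  Two length-related considerations shaped this choice.
First, a fixed 30% identity threshold is *length-dependent* in what it
admits by chance: Monte Carlo on random sequence pairs shows roughly
1.5 × 10⁻⁴ of 100-residue pairs reach 30% identity at 70% bidirectional
coverage through an optimal local alignment (the classic twilight
zone), while such pairs become vanishingly rare past 150 residues.
Second, distinct planted families are given lengths whose pairwise
ratio falls *below* the coverage threshold, so the bidirectional
coverage rule makes a direct inter-family edge impossible by
construction rather than merely improbable -- mirroring the common
situation where different families differ in domain composition and
hence length.  With these conditions the planted partition is recovered
with Rand index 1.0; with very short, same-length families an
occasional chance link is a property of the thresholds themselves, not
of the implementation.

What the generator does *not* emulate: indels and length variation
within families, biased substitution (a matrix-free uniform model keeps
expectations analytic), rearrangement or operon turnover, nucleotide
sequences, and real product annotations.  Passing the planted-truth
tests therefore demonstrates that the machinery is correct under the
model's assumptions, not that the default thresholds are optimal for
any particular real proteome.

# Numerical and algorithmic choices

* **Alignment kernel.** Local (Smith-Waterman) alignment with affine
  gaps, a gap of length L costing open + L·extend -- the same accounting
  as `Biostrings::pairwiseAlignment`, against which scores are
  cross-checked in the tests.  Identity and coverage are taken from the
  optimal path with deterministic tie-breaking; pairs are internally
  put in a canonical order first, so all reported metrics are exactly
  symmetric in the argument order.  Pairs whose length ratio is below
  `minCoverage` are skipped without alignment -- no such pair can
  satisfy bidirectional coverage, so the shortcut is exact.
* **Toy search engine.** E-values come from the Karlin-Altschul form
  E = K·m·n·e^(−λS) with the fixed gapped-BLOSUM62 constants λ = 0.267,
  K = 0.041 (not fitted).  Profile queries score in log₂ odds with
  pseudocount weight α: score(pos, aa) = log₂((c + αb) / ((N + α)b));
  these bit-unit scores are doubled onto the half-bit scale of BLOSUM62
  before alignment so that one gap model and one e-value calibration
  serve both sequence and profile queries.  The engine is a desk-scale
  stand-in behind a contract that external search tools can fulfill by
  importing tabular hits.
* **Permutation null.** Shuffling gene identities leaves coordinates
  and strands -- hence directons, windows and the promoter-sharing
  relation *between positions* -- untouched.  The implementation
  precomputes each position's window and promoter-sharing position sets
  once and only re-draws which positions carry query and partner genes;
  this is algebraically identical to re-extracting every neighborhood
  per permutation, at a small fraction of the cost.  The p-value uses
  the add-one convention p = (1 + #{perm ≥ obs}) / (1 + N), which
  cannot return 0.
* **Consensus tie-breaks.** A column's code is the *smallest* class
  that reaches the threshold (most specific), ties between equal-size
  classes broken by the fixed order u, o, l, a, +, s, c, h, p, b; gaps
  count in the denominator.  The hydroxylic class is exactly {S, T};
  tiny ⊂ small, aliphatic ⊂ hydrophobic, aromatic ⊂ hydrophobic and
  positive ⊂ charged are enforced by the class-table validator (the
  package's hydrophobic set therefore includes His, which sits in the
  aromatic set).
* **Determinism.** Cluster ids order by decreasing size then smallest
  member; hits order by (e-value, target id); all generator and
  permutation randomness flows through explicit seeds, and the global
  RNG state is restored afterwards.  Two runs with equal manifests
  produce byte-identical outputs.
* **Degenerate inputs.** Empty local alignments (no positive-scoring
  residue pair) report score 0 with zero identity and coverage;
  zero-depth profile columns score 0 for every residue (the formula's
  pure-background limit); a single-gene replicon is its own directon;
  ambiguous residues beyond X are collapsed to X, on which all scoring
  is defined.

# Problem sizes used in validation

The shipped test suite and `scripts/acceptance.R` run at sizes chosen
to exercise every claim while staying desk-scale: 1,000 random toy
genomes (20-100 genes) against a brute-force directon enumerator; 200
random graphs against union-find; 20 cohort seeds for planted-family
cluster recovery; 20 replicate cohorts of 20 genomes × 60 genes for the
end-to-end contextual recovery with 999 permutations; a planted family
of 10 (d = 0.3) among 200 decoys for the iterative search; 1,000 random
motif-scan cases against a sliding-window oracle.

# Known limitations

* The bundled engine's e-values are calibrated only through fixed
  Karlin-Altschul constants; absolute e-values on real databases
  require a real search tool behind the engine contract.
* Genome counting treats genomes as independent; the optional
  taxon-group table collapses counts per group, but there is no
  tree-aware correction for phylogenetic non-independence.
* PTT input cannot carry RNA genes; tRNA/rRNA context requires GenBank
  input or the supplementary RNA-feature TSV.
* Single-linkage clustering inherits BLASTCLUST's chaining behavior by
  design; with promiscuous domains, raising `minCoverage` is the
  intended remedy.
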