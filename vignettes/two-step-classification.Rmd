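---
title: "Minimizer-LCA classification with sample-tailored dynamic libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-LCA classification with sample-tailored dynamic libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynlca)
```

## The model

`dynlca` classifies shotgun metagenomic reads by exact minimizer matching
against a reference database of minimizer → LCA-taxon records, in the
style of the Kraken family of classifiers. Its distinguishing feature is a
two-step mode in which the reference library is tailored to the sample:
after a first pass against a large static library, a species-selection
heuristic determines which genomes plausibly occur in the sample, a
smaller dynamic library is rebuilt from only those genomes, and all reads
are classified a second time against it.

The reason this helps is a property of LCA databases: the record stored
for a minimizer is the lowest common ancestor over *all* library taxa
whose genomes contain it. A region conserved between two sibling species
therefore yields genus-level records, and a read covering only conserved
regions can never be classified below the genus — no matter how abundant
its species is. Removing genomes from the library can only move record
LCAs *down* the tree (the taxon set per key shrinks, so its LCA is a
descendant-or-equal of the original), never up. Restricting the library to
the taxa actually present thus converts vague (above-species) labels into
species-level ones, while the large first-pass library still protects
against false positives from missing references.

### Minimizer extraction

Every k-bp window of every maximal unambiguous (A/C/G/T-only) segment
contributes one minimizer: the ℓ-mer within the window minimizing the
scrambled ordering `(key AND NOT seed_pattern) XOR toggle_mask` over
canonical 2-bit encodings. The stored key is the *masked* canonical
encoding; the toggle affects ordering only. Windows are never formed
across ambiguous characters, so no spurious minimizers appear at the edges
of masked or ambiguous regions.

Assumptions worth stating: matching is strand-agnostic (canonical
encodings); lowercase (soft-masked) bases are uppercased rather than
treated as ambiguous, since low-complexity masking is expected to be done
upstream if desired; and keys are held in 64 bits, capping ℓ at 32 —
ample for the conventional ℓ = 31.

### Read scoring

Per read (or read pair — mates share one hit pool), each window's key is
looked up; hits accumulate per-taxon window counts. Every hit taxon is
scored by the summed counts along its root path, and the best-scoring hit
taxon becomes the candidate label. The candidate's confidence is the
fraction of the read's queried windows whose hit falls inside the
candidate's clade; while it is below the threshold the candidate is
promoted to its parent, and a read still below threshold at the root is
left unclassified.

### Two-step orchestration

Samples are classified in groups. Within a group, step-1 results are
pooled and every species-level taxon whose clade collected at least `R`
reads is selected; the dynamic library contains the genomes of the
selected species and of all their taxonomic descendants. Reads labelled
*above* species level contribute to no species total — a deliberate
property of the published rule: a genus with abundant genus-level signal
but no species passing the cutoff is dropped entirely. We implement the
rule as stated and surface the limitation here rather than invent a rescue
heuristic. Step-1 labels are unaffected by grouping; pooling only changes
the selection (and therefore step 2).

The `gold_truth` mode replaces the heuristic with the ground-truth taxon
set intersected with the library's species — the ceiling any selection
heuristic can reach.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `k` | 35 | bp | window / k-mer length |
| `ell` | 31 | bp | minimizer length; ≤ k, ≤ 32 |
| `spaces` | 7 | positions | cleared nucleotide positions in the seed mask |
| `seed_pattern` | `0x0ccccccc` | bit pairs | which positions are cleared (see below) |
| `toggle_mask` | `0x237e28c4271b5a2d` | — | ordering scrambler; never stored |
| `confidence_threshold` | 0.15 | fraction | clade-hit fraction required to keep a label |
| `cutoff_R` | 100 | reads | pooled species read total for dynamic-library inclusion |
| `detection_threshold` | 10 | reads | species counted as detected in evaluation |

The k/ℓ/s defaults are the conventional operating point of this method
family. The confidence default of 0.15 follows the threshold widely
reported as a good operating point for this method family; the classifier
is evaluated at {0, 0.05, 0.1, 0.15} in the test suite. `R` trades taxon
recall (low R) against precision and read-profile accuracy (high R); with
10× deeper sequencing a ~10× higher `R` is the comparable setting, since
the cutoff is a raw read count.

**Seed mask layout.** The published description of this method family
fixes only the *number* of spaced-seed positions, not their layout, and
does not print the XOR constant. This package therefore documents its own
defaults bit-exactly: the 7 cleared nucleotide positions are 1, 3, 5, 7,
9, 11, 13 counted 0-based from the low-order (3′) end of the encoded
minimizer (bit-pair mask hex `0ccccccc`), and the toggle is the fixed
62-bit constant `237e28c4271b5a2d`. Both are configurable; no claim of
bit-identity with other implementations is made, and databases record
their parameters so mixed-parameter lookups are impossible.

## Numerical and design choices

- **Tie-breaks.** Within a window, the leftmost minimal ℓ-mer wins.
  Between equally weighted candidate labels, the label is the LCA of the
  tied taxa — consistent with LCA semantics and deterministic.
- **Confidence denominator.** All queried windows of the read pair (hits
  and misses); windows skipped for ambiguity are excluded. A read whose
  segments are all shorter than k has zero queried windows, is
  unclassified, and renders a `0:0` hits field.
- **Rank arithmetic.** The canonical ladder is species < genus < family <
  order < class < phylum < kingdom < domain (8 ranks; "superkingdom" is
  read as domain). Non-canonical nodes (strain, subspecies, "no rank")
  count at their nearest canonical ancestor's position, so a strain is 0
  ranks from its species; nodes above every canonical rank (the root) sit
  one step above domain, making the maximal vague-positive gap 8 and the
  false-positive weight 9.
- **Index denominators.** The sample index and s-index average over *all*
  reads of the sample. A third variant restricted to classified reads
  only is coherent but its exact denominator is ambiguous in the metric's
  published uses, so it is not exposed.
- **Per-genome deduplication.** A key occurring many times in one genome
  contributes that genome's taxon once; LCAs depend on taxon sets, not
  occurrence counts. Whether duplicate window emissions are collapsed
  before or after merging is unobservable in the final database.
- **Profile log-distances.** Zero entries are floored at 1e-10 before
  log10 (configurable); fraction vectors routinely contain exact zeros.
- **Database integrity.** Databases are serialized as a sorted flat text
  table plus a JSON sidecar carrying parameters and an md5 fingerprint of
  the taxonomy; loading against a different taxonomy is a hard error
  because LCA values are taxonomy-relative.
- **Taxonomy dialect.** NCBI-style `nodes.dmp`/`names.dmp` with
  `\t|\t` field separators; only "scientific name" rows are used. Merged
  or deleted taxid remapping is not supported: unknown taxids are errors,
  which is the right behaviour for curated or synthetic inputs.

## What the synthetic generator does and does not emulate

`community_spec()` / `make_taxonomy()` / `make_genomes()` /
`simulate_reads()` produce communities with a full 8-rank ladder, genera
of sibling species whose genomes mix private sequence with conserved
blocks (one genus-wide, plus pairwise blocks between neighbouring
siblings), optional strains as lightly diverged below-species genomes, and
reads drawn multinomially from species abundances with uniform positions,
strands, and i.i.d. substitution errors.

This reproduces the *mechanism* the two-step method exploits — conserved
regions forcing genus-level records, confounder genomes in the library but
not the sample — and gives every read an unambiguous species-level truth
label. It does not emulate real sequencing error profiles (no indels, no
quality-dependent errors), real genome architecture (repeats, plasmids,
contamination), novel genomes absent from the taxonomy, or realistic
abundance distributions. Passing tests therefore demonstrate correctness
of the algorithms and the direction and mechanism of the two-step gains,
not effect magnitudes on real data: those depend on library coverage and
community composition.

Default generator conditions, chosen once as a realistic small community:
3 genera × 3 species, 4 kb genomes, 30% conserved sequence, 150 bp reads,
0.5% substitution rate (between an error-free and a noisy short-read
profile), uniform abundances. Conserved blocks must be at least k + ℓ bp
so each contributes at least one full window; the generator refuses
specifications that cannot honour this.

## Problem sizes in the test suite

Tests run on communities of 2 genera × 3 species with 0.7–3 kb genomes
and 60–150 reads, 50 random libraries for the LCA-monotonicity property,
1000 random 150 bp sequences for the minimizer oracle, and 20 seeded
confounder communities for the two-step improvement property — sizes at
which every oracle (brute-force window scans, literal path enumeration,
root-path LCA intersection) is exact and fast. The two-step improvement
check asserts a per-community inequality (step-2 species-level true
positives ≥ step-1's under R = 1 with error-free reads), which is a
theorem under genome removal rather than a statistical tendency, so small
communities lose no generality.

## Known limitations

- Single-taxonomy: classification precision is bounded by the taxonomy's
  resolution; taxa without a node cannot be named.
- The read-cutoff heuristic discards genus-level signal (see above) and
  its optimal value scales with sequencing depth.
- Multi-sample grouping makes results depend on the group composition;
  classifying a sample alone is always reproducible, at higher cost per
  sample.
- No low-complexity masking, translated search, or paired-end
  insert-size modelling during classification; protein space is out of
  scope.
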