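---
title: "Locus clustering by alignment-bin co-occurrence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus clustering by alignment-bin co-occurrence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loclust)
```

## The model

`loclust` groups transcripts into *locus clusters*: each cluster should hold
exactly the transcripts — alternative splice isoforms included, possibly from
several species — transcribed from one orthologous genomic locus. The signal
used is not sequence similarity but *where spliced alignments land* on one or
more reference genomes.

**Bins.** A bin is a genomic interval on one sequence of one genome that
records the identifiers of every transcript with an exon alignment inside it.
De novo seeding grows bins from the alignments themselves: an exon block
founds a bin or joins (and extends) any bin it overlaps, and bins merge when
extension makes them overlap. The fixpoint of this process is
order-independent: bins are exactly the connected overlap components of all
exon blocks on a sequence, which is how `seed_bins_denovo()` computes them
(via `IRanges::reduce()` at the default 1 bp overlap criterion). Pre-seeding
instead founds bins from a reference annotation's exon coordinates, freezes
them, and then assigns transcript blocks to the frozen bins; blocks touching
no frozen bin fall back to de novo seeding so unannotated loci are not lost.

**Co-occurrence.** For an ordered pair of binned transcripts,

$$\mathrm{prop}(i \to j) = \frac{|\mathrm{bins}(i) \cap \mathrm{bins}(j)|}{|\mathrm{bins}(i)|},$$

the proportion of i's bins in which j is also found. An undirected edge
\{i, j\} is formed when **either** direction reaches the threshold *t*. The
procedure is described directionally ("for each current transcript…"), and
since every node takes a turn as the current transcript, a one-directional
trigger suffices; we state this union rule explicitly because it matters for
asymmetric pairs (a fragment reaches 1 toward its parent while the parent may
stay below *t*).

**Filters.** Fragments (often single-exon truncations, hence members of a
single bin) co-occur perfectly with everything sharing that bin, without
reciprocation. An edge is *one-sided against i* when
$\mathrm{prop}(i \to j) \ge t$ but $\mathrm{prop}(j \to i) < t$; a transcript
one-sided in at least 50% of its relationships is removed — a tie at exactly
50% is removed, reading the rule's "≥" literally. Chimeras fuse two loci and
surface as articulation points of a component, nodes whose removal leaves no
edge connecting two subgraphs; all articulation points are removed in one
simultaneous pass. Detection requires the chimera to be a singleton in the
dataset: two near-identical chimeras would back each other up and neither
would be an articulation point.

**Output.** Components of the filtered graph are *binned* clusters (isolated
surviving nodes become singletons). Transcripts with no retained alignment to
any genome are *unbinned* and are clustered by sequence instead, with a
greedy incremental algorithm processing sequences longest-first: a sequence
joins the first cluster whose representative it matches at the identity
threshold with sufficient coverage of both sequences, else founds a new
cluster. This mirrors CD-HIT's `-c/-aS/-aL` semantics so the same optimised
parameter presets apply, while keeping the package free of external binaries.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `threshold` (t) | 0.66 | proportion | optimised default; clustering outcomes shift little between 0.33 and 0.66 (≤ ~6.8% cluster-count change in the worst case), with 0.5–0.66 marginally best |
| `preseed` | off | — | pre-seeding performs comparably and is therefore not the default |
| `min_identity` / `min_coverage` | 0.90 / 0.70 | fraction | GMAP path acceptance filters; no canonical values exist, so these are explicit, logged and configurable |
| `multipath` | off | — | secondary alignment paths inflate a transcript's bin denominator and dilute all of its co-occurrence proportions; only `path_rank == 1` per (transcript, genome) is kept by default |
| `stranded` | off | — | bins are strandless: de novo transcripts may have unknown strand, and a strandless space is the safest default for mixed inputs. The cost — overlapping genes on opposite strands can merge — is accepted and documented; `stranded = TRUE` gives each strand its own bin space (unknown-strand placements then form their own space) |
| `min_overlap` | 1 | bp | any overlap joins a block to a bin; no biological case for more by default |
| greedy `min_identity` | 0.98 | fraction | optimised for locus clustering of plant/animal transcripts |
| greedy coverages | 0.4 / 0.4 | fraction of short/long seq | same optimisation; `preset = "microbial"` sets both to 0.8 |

Micro-exons are retained — there is no exon length filter.

## The synthetic-data generator

`simulate_bundle()` emulates the evaluation design the method was validated
under: a deconstructed reference annotation whose transcripts must be
re-clustered into their loci. It plants `n_loci` non-overlapping loci on a
random chromosome; isoform 1 carries the full exon chain and each further
isoform skips one distinct internal exon, so siblings always share at least
two exons (the separability condition under which recovery should be exact).
Planted noise: *fragments* are single-exon truncations; *chimeras* fuse two
loci and appear exactly once; *contaminants* are random sequences with no
alignment records. Alignment GFF3s are synthesised directly rather than
computed by an aligner — exact on the home genome, coordinate-jittered on
additional genomes to emulate spliced alignment against a related species'
genome (each block shifted by up to `coordinate_jitter` bp, width preserved).

Two deliberate deviations from a naive reading of the design:

* **Chimeras are full fusions, not half fusions.** A transcript carrying only
  half of each parent locus has co-occurrence ≈ 0.5 < 0.66 in *both*
  directions against every genuine isoform, forms no edges, and is therefore
  structurally undetectable as an articulation point. Since chimeras are
  *defined* operationally as articulation points bridging two subgraphs, the
  generator plants detectable ones: the full exon sets of both loci, giving
  $\mathrm{prop}(\text{isoform} \to \text{chimera}) = 1$.
* **Related genomes reuse the home layout** (same locus coordinates) and
  model divergence purely as per-block alignment jitter. This captures what
  matters to the algorithm — coordinate drift of exon placements — without a
  sequence-evolution model.

What a green recovery test does **not** establish: robustness to real aligner
error modes (split paths, terminal soft-clips, paralog cross-mapping),
overlapping or nested genes, trans-splicing, or isoforms sharing fewer than
two exons. Defaults (exons 4–7 of 80–300 bp, introns 100–400 bp, 1–3
isoforms) are ordinary compact eukaryotic gene dimensions; they are stated
once here and not tuned per test.

## Numerical and degenerate-case choices

* **Coordinates** are GFF3-style 1-based inclusive everywhere; no half-open
  conversions are exposed (the BED-like bin dump is the one 0-based writer,
  for browser compatibility).
* **Metrics.** RI/ARI come from the contingency table; NMI and AMI are
  normalised by the *arithmetic mean* of the entropies, with the expected
  mutual information under the hypergeometric model, natural logs — stated
  because several conventions exist, and this one enables cross-checking
  against the common reference implementations (the suite pins 50 random
  cases to frozen scikit-learn values at 1e-9). ARI/AMI may be negative and
  are reported as computed, *not* clamped to \[0, 1\]. Identical trivial
  partitions give all metrics 1; other 0/0 cases resolve to 0. Items absent
  from either partition are excluded before computation, with counts
  reported.
* **Greedy clustering ties** in length are broken by identifier sort, fixing
  a deterministic processing order; identity is matches over alignment
  columns (gaps included) of a Smith–Waterman local alignment
  (`Biostrings::pairwiseAlignment`; a banded implementation was considered
  and rejected as an unnecessary hand-rolled optimisation at these sequence
  sizes). A shared 15-mer prefilter skips hopeless pairs; sequences shorter
  than 15 bp always proceed to alignment.
* **Filter order** is fragments first, then chimeras on the fragment-free
  graph, matching the order the procedure is described in. With only two
  isoforms at a locus plus a chimera, the 50% tie rule could remove genuine
  transcripts; the constructed fixtures use ≥ 3 isoforms where this matters.
  Chimera detection is single-pass: iterating detection after removal could
  cascade through legitimate hub transcripts.
* **Filtered transcripts are discarded**, not forwarded to unbinned
  clustering, unless `rescue_filtered = TRUE` — the procedure says "removed"
  without specifying a disposition, and silently re-clustering known-suspect
  sequences is the riskier default.
* **Degenerate inputs:** empty placement tables give an empty index; a graph
  with no nodes gives zero clusters; metric computation requires ≥ 2 shared
  items and errors otherwise; count aggregation refuses transcripts that are
  neither clustered nor filtered.

## Known limitations

* Bins are per-genome; cross-genome linkage happens only through transcripts
  aligning to multiple genomes. Clustering quality therefore degrades with
  evolutionary distance of the reference(s), and beyond roughly
  order-level divergence locus clustering is not expected to be reliable.
* Fragment removal uses only relationship one-sidedness (the stated rule),
  not transcript length or bin counts; a genuine short isoform nested in a
  longer one's bins can be sacrificed.
* The internal greedy clusterer is a semantic stand-in for CD-HIT/MMseqs2,
  not a bit-for-bit reproduction; the adapters parse their native outputs
  when the binaries are available.
* ARI/AMI against very fragmented truths (many singleton groups) approach 0
  and stop being informative — evaluate with several metrics, as the
  reporting functions do.
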