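---
title: "Building specific NLS/NES motif catalogues by in silico mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building specific NLS/NES motif catalogues by in silico mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsig)
library(dplyr)
```

## The model

Nuclear localization signals (NLS) and nuclear export signals (NES) are
short linear motifs recognised by karyopherins. `nucsig` treats catalogue
construction as a constrained search over literal motif strings: given a
nuclear protein set $N$, a non-nuclear set $C$, a family partition of $N$
and seed signals collected from experimental annotation, find motif
strings that

* are **specific** — match zero proteins in $C$;
* are **sensitive** — match at least one protein in $N$, and for
  machine-generated motifs at least two distinct families, so that a motif
  generalises beyond one homologous group;
* look physicochemically like their signal class.

Matching is exact substring matching throughout. The deliberate refusal
to merge motifs into regular expressions is part of the model: a regular
expression built from two observed signals admits recombined strings
nobody has ever observed functioning as a signal, and such patterns leak
matches into $C$ very quickly. The price is a larger catalogue of literal
strings; the reward is that specificity can be *verified exhaustively*
against the negative set, and holds by construction.

Refined motifs end up short (typically 3–7 residues here; the procedure
can only shorten). A match therefore marks a candidate signal site rather
than proving autonomous transport function — biologically active signals
may need flanking residues, and two adjacent matches may jointly form one
bipartite signal.

## The search procedure

Starting from seeds that pass the entry gate (≥ 1 nuclear match, 0
non-nuclear matches, length ≤ 30), the pool is initialised with all
single-residue substitution variants (20·L enumerated per seed, 19·L + 1
unique — both counts are asserted as a law in the tests). Then two steps
iterate until no new variant can be generated:

* (a) drop every candidate matching $C$ or missing $N$ entirely;
* (b) propose all single-residue deletions of the pool, skipping any
  string proposed before (global novelty tracking guarantees
  termination: the candidate space is the finite deletion closure of the
  substitution variants).

Each surviving variant records provenance: its seed, the one substitution
(if any) and how many deletions were applied. `replay_provenance()`
verifies a motif against this trail by checking that it is a subsequence
of the substituted seed shorter by exactly the recorded deletion count —
the strongest check the recorded information supports, and exact on the
string.

### The pruning-order choice

The written protocol filters before deleting: only candidates that are
already specific *and* sensitive spawn deletions. Read literally, a
candidate that matches nothing (for example an annotated signal recorded
with one spurious flanking residue) can never shed the residue that would
make it match. We regard the choice as genuinely open and expose it as
`refinement_config(prune_before_delete = )`:

* `TRUE` (default, the literal reading): deletions come only from
  survivors of filter (a).
* `FALSE` (generative): deletions come from every candidate matching no
  non-nuclear protein. Specificity still prunes the search — candidates
  matching $C$ never spawn variants in either mode, so decoys cannot
  smuggle substrings into the pool — but an insensitive candidate may
  shrink until it matches.

The default stays with the literal reading because in realistic use it is
sufficient: an experimentally annotated seed was observed *in some
nuclear protein*, so it matches at least its source protein and enters
the deletion loop from iteration one. The synthetic generator models
exactly this (below). The generative mode matters when seeds are supplied
without their source proteins; both modes are covered by tests against an
independent breadth-first oracle.

## Physicochemical and generalisation filters

Applied after the loop, to machine-generated motifs only — the seeds'
own evidence is experimental and is not second-guessed:

* **NLS**: ≥ 3 positive residues (H, K, R), relaxed to 2 when the motif
  contains a PY-NLS (`[RKH]-X{2,5}-P-Y`); and ≥ 1 *charge region* with
  net positive charge (≥ 2 for motifs of ≥ 20 residues). The region rule
  needed an operational definition of "positives not cancelled by
  adjacent negatives": we use maximal runs of charged residues
  (H/K/R/D/E), scoring +1/−1 inside a run, so a D or E directly adjacent
  to a positive cluster cancels within the run while an uncharged spacer
  breaks the run. This is the narrowest reading of adjacency; a windowed
  alternative would couple more distant residues and was rejected as
  harder to justify.
* **NES**: ≥ 3 hydrophobic residues (A, F, I, L, M, V) and a hydrophobic
  fraction of ≥ 30%. Thresholds phrased as removal conditions ("fewer
  than", "< 30%") keep their boundary: exactly 30% passes.
* **Families**: in-silico motifs must match ≥ 2 families. Families are
  computed once on the nuclear set.
* **Redundancy**: exact duplicates collapse to the strongest evidence
  (experimental > expert > potential); then whenever one motif is a
  proper substring of another, only the shorter is kept — it matches a
  superset of proteins, so sensitivity never drops. The result is the set
  of substring-minimal elements, which makes the operation idempotent and
  order-independent (property-tested over random permutations).

## Dataset preparation

* **Masking.** Low-complexity regions are masked with a two-threshold
  sliding-window Shannon-entropy segmentation in the SEG style: window
  12, trigger entropy 2.2 bits, extension entropy 2.5 bits (the canonical
  parameter triple; all three are configurable). A window below the
  trigger nucleates a segment, adjacent windows below the extension
  threshold extend it, and all covered positions become lowercase `x`.
  Windows already containing `x` are exempt, which makes masking
  idempotent. Masking informs only the dataset filter; motif matching
  always runs on the raw sequence.
* **Filters.** Proteins shorter than 50 residues (likely fragments) or
  without a 30-residue unmasked run are removed; both bounds inclusive.
* **Label policy.** Experimental nuclear evidence wins over co-occurring
  non-nuclear evidence; an experimentally non-nuclear protein carrying a
  less-reliable nuclear annotation is dropped from both sets.
* **Cross-label twins.** Non-nuclear proteins with > 80% global pairwise
  identity to any nuclear protein are removed from the negative set —
  such pairs are as likely annotation errors as true single-signal
  differences, and a wrong negative poisons every motif it contains.
  Identity is identities divided by global-alignment length (BLOSUM62,
  gap open 10, extend 0.5), a deterministic, oracle-checkable definition.
* **Families.** Single-linkage clustering (connected components of the
  pairwise-similarity graph) under a pluggable predicate: a plain
  identity threshold (> 0.30, the default used in tests because it is
  fully specified), or HVAL > 0 with the length-dependent twilight-zone
  curve $480\,L^{-0.32(1+e^{-L/1000})}$ (100 below L = 12, 19.5 above
  L = 450). Single linkage is the transitive closure a redundancy
  reduction implies.

## Coordinates

Hit tables use 1-based inclusive `start`/`end`, the universal convention
of R sequence infrastructure (Biostrings, IRanges); the invariant is
`substr(sequence, start, end) == motif`. Files exchange the same
convention.

## The synthetic benchmark

`generate_proteome()` emulates what the method needs from real data and
nothing more: family structure (members are point-mutated copies of a
founder, 5% substitution rate by default — high within-family identity,
negligible between-family identity), planted signals inserted verbatim
into every member of their carrier families, a background of
uniform-frequency sequences rejection-checked to be free of every planted
signal, and optional homopolymer insertions (rate 0.15) to exercise
masking. Defaults — 24 nuclear proteins in 6 families, 30 non-nuclear
proteins, lengths 60–120 — are small enough for thousands of end-to-end
runs in a test session while leaving every filter identifiable; the
acceptance checks use 50 independent replicates and the matcher
equivalence check 1000 random instances.

The default planted NLS (`KRKKRSA`) and NES (`LAKFLVL`) are drawn around
basic and hydrophobic cores respectively, so the plausibility filters
cannot veto recovery by design — the generator defines the study
conditions, not a difficulty dial. `generate_benchmark()` additionally
decorates each signal into a seed (one appended or substituted residue)
and plants the *decorated* string into exactly one carrier, modelling an
experimental annotation observed inside a real protein; decoy seeds cut
from non-nuclear proteins must never survive. What the generator does
*not* model: realistic phylogenetics, domain architecture, annotation
noise, or database-scale composition biases — passing tests show the
machinery is correct under the stated assumptions, not that real-data
catalogues will reach any particular size or coverage.

```{r example}
sim <- generate_benchmark(seed = 42)
cat_nls <- build_catalogue(filter(sim$seeds, signal_type == "NLS"),
                           sim$nuclear, sim$non_nuclear)
tidy(cat_nls)
glance(cat_nls)
```

```{r plot, fig.width = 5, fig.height = 3}
autoplot(cat_nls)
```

## Numerical choices and degenerate inputs

* Ambiguity codes (X, B, Z, U, O, J) are legal in proteins but match
  nothing — specificity is the hard constraint, and optimistic matching
  could only manufacture false matches. Motifs never contain them. For
  alignment scoring, U/O/J map to X (absent from BLOSUM62).
* Empty non-nuclear sets are a hard error in `seed_filter()` and
  `refine_motifs()`: the specificity constraint would be vacuously true.
* Length-1 signals produce no deletion variants; empty motif strings are
  structurally impossible.
* Duplicate-sequence tie-breaks sort by evidence rank, then source, for a
  deterministic result; refinement provenance is first-wins under a
  sorted proposal order, so output is invariant to seed input order.
* Sequences shorter than one masking window are returned unmasked;
  proteins without a populated mask are rejected by `filter_proteins()`
  with instructions rather than silently passed.
* All randomness in the generator flows from one integer seed
  (`withr::with_seed`), so fixtures are byte-identical across runs.

## Known limitations

* Specificity is relative to the build datasets; on external data the
  guarantee degrades to an empirical error rate.
* The cross-label twin removal uses global-alignment identity, not the
  word-based heuristic of clustering tools like CD-HIT; thresholds are
  comparable but not interchangeable.
* Family clustering of $n$ proteins computes $O(n^2)$ alignments; for
  genuinely large nuclear sets a pre-clustering tool is the practical
  route, with `cluster_families()` as the reference definition.
* Only single substitutions and single-residue deletions are searched;
  alignment-guided lengthening and multi-substitution variants are out of
  scope.
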