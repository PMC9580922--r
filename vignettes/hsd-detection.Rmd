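---
title: "Detecting highly similar duplicated genes: model, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting highly similar duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsdetect)
```

## The problem

Eukaryotic genomes carry groups of near-identical gene copies — highly
similar duplicated genes (HSDs) — that typically reflect recent duplication
events and often act through gene dosage (rRNA, histone, light-harvesting
and ribosomal-protein families are classic examples). `hsdetect` identifies
these groups in a single proteome from an all-vs-all protein similarity
search, annotates them with protein-signature domains, scores the
threshold choice, and aggregates HSDs under KEGG pathway categories across
species.

The tool is deliberately aimed at *highly similar* paralogs, not ancient,
diverged ones: the thresholds below define that scope.

## The detection model

Detection operates on the standard 12-column tabular alignment report
(query, subject, percent identity, alignment length, mismatches, gap opens,
coordinates, E-value, bit score) plus a 13-column InterProScan TSV that
supplies each protein's length and its Pfam/InterPro signatures.

1. **Self-hits are discarded.** A gene's alignment to itself carries no
   duplication signal.
2. **One best hit per unordered pair.** All hits between a pair of genes, in
   either direction, are reduced to the single hit with the highest bit
   score (first encountered wins ties). Similarity is treated as a
   symmetric relation; no reciprocal-best requirement is imposed.
3. **Threshold filter.** The pair qualifies when the best hit satisfies,
   inclusively: E-value ≤ `evalue_max` (default 1e-5), percent identity ≥
   `identity_min` (default 90%), and the two protein lengths differ by at
   most `length_diff_max` residues (default 10 aa). "Within 10 amino acids"
   is read as |Δlen| ≤ 10; every boundary is inclusive and unit-tested.
4. **Transitive-link clustering.** Qualifying pairs form an undirected
   graph; HSD groups are its connected components. If copy A passes the
   filter against copies B and C, then A, B, C form one group even when the
   B–C pair itself misses the thresholds. Singletons are never reported: a
   duplication needs at least two copies.

The group identifier is the lexicographically smallest member gene id —
stable across runs and input orderings, since the underlying partition is
order-invariant.

### Where protein lengths come from

The 12-column alignment format has no full-sequence lengths. We take each
protein's length from InterProScan column 3, with an optional protein FASTA
as fallback for proteins that have no signature rows at all (hypothetical
proteins are common: roughly a third of HSDs in some algal genomes carry no
Pfam domain). A pair whose lengths cannot be resolved is excluded and
counted in a reported `skipped_no_length` tally — never dropped silently.
Conflicting lengths for one protein across annotation rows raise an error
rather than a guess.

## Domain-profile classification

Each group is classified by comparing its members' domain profiles as
*sets* of distinct accessions (Pfam by default; a switch allows InterPro):

* **true** — all members carry an identical accession set. This includes
  the degenerate all-empty case.
* **space** — a flag on `true` groups in which *no* member has any domain
  (hypothetical-protein groups). Defining space as a subset of true is
  forced by the performance-score arithmetic: `candidate − space` must
  count the groups containing functional domains.
* **incomplete** — members carry differing accession sets. Such groups may
  have undergone recombination or other processes besides duplication.

Set semantics means domain order and per-domain copy counts do not matter;
the data formats provide no reliable ordering, and the classification must
be invariant to member order.

## Threshold evaluation

Two statistics summarise a threshold pair, both truncated toward zero
(floor) for reporting:

* **Capturing value** `= ⌊100 · true / (true + incomplete)⌋` — the
  percentage of candidate groups whose copies agree in domain content.
* **Performance score** `= ⌊(2·true + incomplete − space) / (incomplete + 1)⌋`
  — the numerator is true groups plus the groups carrying any functional
  domain; discordant groups inflate the denominator (the +1 avoids dividing
  by zero).

Truncation rather than rounding is deliberate: on the A. thaliana reference
grid shipped in `inst/extdata/`, 8245/8647·100 = 95.35 reports as 95 and a
score of 15308/403 = 37.98 reports as 37, where rounding would give 38. The
untruncated values remain available via `precise = TRUE`. All 40 reference
statistics (20 capturing values, 20 scores) are reproduced exactly by these
two functions in the test suite.

`threshold_sweep()` re-runs the whole pipeline at every cell of an identity
× length grid (default 60/70/80/90% × 10/30/50/70/100 aa, 20 cells).
Recomputing from scratch per cell costs little at desk scale and avoids the
correctness risks of incremental updates. On the reference grid the score
peaks at ≥90%/10 aa with ≥80%/10 aa second, which is why those are the
default and the recommended relaxed setting.

## KEGG categorization

KO accessions are assigned to genes by external annotation (BlastKOALA /
GhostKOALA two-column exports); the KO→category map is a user-supplied TSV,
never a network call, so everything runs offline. A group's KO is the
majority vote over its annotated members, ties broken to the smallest KO —
the underlying annotations are per-gene, and intra-group disagreement needs
a deterministic rule. Groups with no annotated member fall under an
`Unassigned` pseudo-category; KOs absent from the map fall under `Unmapped`
with a warning. Heatmap cells count distinct HSD *groups* per (species,
category); a KO mapping to several categories lists its group once per
category.

Neither input format carries KO descriptions, so the category map accepts
an optional fourth column (`ko_description`), empty otherwise.

## The synthetic generator

`generate_hsd_dataset()` plants families of gene copies with known fate and
writes the full input bundle (FASTA, 12-column similarity table, 13-column
signature table, KO file, category map) plus a ground-truth manifest.
Similarity rows are synthesized directly rather than computed by an
aligner: planted pairs draw identities inside their scenario's band with
E-values far below the cutoff, plus 100%-identity self-hits,
reverse-direction duplicates at lower bit score (exercising best-hit
selection) and cross-family decoys failing either the identity or the
E-value filter. Scenarios:

* `true`, `space`, `incomplete` — qualify at ≥90%/10 aa with the matching
  classification; `space` copies carry no signature rows, so their lengths
  are only recoverable through the FASTA fallback.
* `near_miss_identity` — identity in [80, 90): appears only at the relaxed
  ≥80% setting.
* `near_miss_length` — copy lengths spaced 12 aa apart: absent at both
  settings, appearing only under larger length bounds.

Generation is deterministic (same spec + seed → byte-identical bundle) and
restores the caller's RNG state. What it emulates is the *filter-relevant
structure* of real data: threshold bands, length jitter, annotation gaps,
decoys. It does not emulate sequence evolution, alignment artefacts,
assembly errors, or partial/fragmented gene models — so passing tests
demonstrate correctness of the filtering, clustering, classification and
accounting logic, not robustness to poor genome annotation quality.

An independent reference path (`brute_force_pipeline()`: naive double-loop
pair scan, iterated set-merging transitive closure) cross-checks the main
implementation, which clusters via igraph connected components. Test
problem sizes — up to 300 genes per instance, 100 random clustering
instances, 40–60 planted families — were chosen to exercise every branch
while keeping the default suite in tens of seconds.

## Numerical and design choices

* All parsing is locale-independent; E-values accept scientific notation;
  machine outputs use plain integers without thousands separators.
* The 8-column HSD output layout is: group id, member ids, member lengths,
  Pfam accessions, Pfam descriptions, InterPro accessions, InterPro
  descriptions, classification (`true`, `true;space`, `incomplete`),
  semicolon-joined within columns. Writers prepend `#` provenance comments
  (tool version, thresholds, input checksums); readers skip them, and
  `--no-header` suppresses them for byte-identical reruns.
* The classic homology cut-off of ≥150 aa aligned length used by some
  paralog surveys is *not* applied: the method's filter is defined by
  E-value, identity and length variance only.
* Edge-count monotonicity holds and is tested (raising `identity_min`
  never adds qualifying pairs; raising `length_diff_max` never removes
  them); group counts are intentionally not asserted monotone, since
  merging components can move counts either way.

## Limitations

The method cannot distinguish tandem, proximal, dispersed, whole-genome or
retro duplication mechanisms, nor estimate Ka/Ks; it detects and annotates
highly similar duplicates only. Results depend directly on assembly and
annotation quality — fragmented gene models inflate near-miss length
failures, and sparse functional annotation inflates the space count.
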