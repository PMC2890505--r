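---
title: "Motif architecture of amino-methyltransferases: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif architecture of amino-methyltransferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylarch)
```

This vignette is the package's account of the science it implements: the
models, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the design decisions taken where more
than one reasonable choice existed.

## The classification model

Bacterial N6-adenine and N4-cytosine methyltransferases carry two conserved
functional regions — the AdoMet-binding region (motif blocks X, I, II, III)
and the catalytic region (blocks IV–VIII, anchored by the \[D/N/S\]PPY
P-loop of motif IV) — separated by a variable target-recognition domain
(TRD). The α, β and γ groups are defined purely by the linear order of these
three parts; the subgroup this package flags is γ-ordered with motif IV =
DPPY (where standard γ enzymes have NPPY) plus two auxiliary blocks, IVa
(between IV and V) and Xa (at the N-terminus).

Classification proceeds in three steps, each an exported function:

1. **Scan** (`scan_motifs()`): every configured motif is matched everywhere
   on the protein. Pattern motifs use a small residue-set grammar
   (`G-x-G`, `[DNS]-P-P-Y`, `x(1,6)` spacers, `{EDQN}` group wildcards);
   motifs VII and X, described only as hydrophobic, are matched as windows
   (5 residues, ≥4 from {V,L,I,M,F,Y,W,A}; X restricted to the N-terminal
   60 residues, where it sits in every published arrangement that retains
   it near the AdoMet cluster).
2. **Select** (`choose_hits()`): at most one hit per motif label,
   maximising total match score subject to non-overlap, canonical
   left-to-right label order within each cluster, cluster contiguity, and a
   nearest-neighbour cap (`cluster_max_gap`, default 40 aa) — blocks of one
   functional region are adjacent in every known arrangement, so a
   domain-sized hole cannot be internal to a cluster. Score ties break
   toward the most compact clusters, then leftmost. The selection is exact
   (branch-and-bound, verified against exhaustive subset search in the
   tests).
3. **Assign** (`infer_trd()`, `assign_group()`): the TRD is the longest
   hit-free span among the termini and between-cluster gaps (minimum 40 aa
   — TRDs are domains, not gaps; ties resolve toward the C-terminus), and
   the group call reads off the order of AdoMet cluster, catalytic cluster
   and TRD. Group calls require ≥2 of {X,I,II,III} and motif IV plus ≥1 of
   {V,VI,VII}; with less evidence the call is `unclassified` rather than a
   guess. Every criterion that passed or failed is recorded in the
   `evidence` field.

### Why the selection rules matter

The prose consensus available for some motifs is very short — motif II is
two residues (`[DE]-[IL]`), motif I three (`G-x-G`). On a 320-aa protein a
chance `[DE][IL]` dipeptide occurs several times, and such decoys can tie
the planted cluster's total score exactly. A purely positional tie-break
then misassigns architectures at rates we measured in the tens of percent
for β-ordered proteins (whose hydrophobic motif VII block sits inside the
N-terminal window that the motif-X scan searches, creating a standing
decoy). The gap cap and compactness tie-break eliminate both failure
classes without touching the score model; with them, planted architectures
are recovered exactly (see the acceptance battery).

## Motif configurations

Three configurations ship with the package (also as TSV under
`inst/extdata/`):

- `default_motif_config()` — the prose-consensus patterns only. Motifs III
  and VIII (no consensus available as text) and IVa/Xa (consensus published
  only as figure images) are present in the vocabulary but disabled.
- `subgroup_motif_config()` — adds *synthetic stand-in* patterns for Xa and
  IVa. We refuse to invent a "real" consensus for blocks whose residues we
  cannot read from a text source; the stand-ins exist so that the subgroup
  logic (γ order + DPPY + IVa + Xa) is implementable and testable. Replace
  them with curated patterns for real data.
- `synthetic_motif_config()` — additionally gives motif III a synthetic
  pattern. This is the generator's default: with every planted block
  carrying a specific pattern, the planted architecture is the unique
  score-optimal assignment and recovery tests measure the classifier, not
  pattern-coincidence statistics. In a β layout the scanner can see neither
  X (out of its N-terminal window) nor III (disabled), leaving a two-block
  AdoMet cluster that chance dipeptides tie — so without a III pattern,
  perfect β recovery is statistically impossible for *any* selection rule.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `trd_min` | 40 aa | minimum hit-free span that counts as a TRD |
| `cluster_max_gap` | 40 aa | maximum gap to the nearest same-cluster hit |
| hydrophobic window | 5 / ≥4 | window length and hydrophobic count for motifs VII and X |
| X region | 1–60 | N-terminal region searched for motif X |
| `gap_open`, `gap_ext` | 11, 1 | affine gap penalties (BLOSUM62), the common protein database-search default |
| alignment `mode` | local (`align_pair`), global (`distance_matrix`) | local emulates database-search percentages; global suits controlled family comparisons |
| layout `k`, `t0`, `iterations` | 0.1, 0.1, 150–200 | spring constant, initial temperature, sweeps |

Identity and similarity use an explicit denominator — alignment columns
where neither sequence is gapped — because the denominator choice changes
the number and published percentages rarely state theirs. Similarity adds
columns whose residues share a conservation group: (E,D,Q,N), (V,L,I,M),
(F,Y,W), (G,P,A), (K,R), (S,T); cysteine and histidine belong to no group,
and the unknown residue X is never identical or similar to anything, so
Edman-undetermined positions cannot inflate scores.

## Degenerate primer design

Back-translation maps each residue to one IUPAC codon whose *entire*
expansion encodes that residue; this is verified exhaustively when a codon
table is loaded. The six-fold degenerate residues (L, R, S) cannot be
covered by one unambiguous IUPAC codon, so their codon choice is a design
parameter (`overrides`), exactly as real primer design treats it. The
shipped default for leucine is YTR (covering both codon families while
encoding only Leu); note that the superficially natural YTN also expands to
TTT/TTC (Phe) and is therefore rejected by the table validator. Sense
primers trim surplus bases from the 3' end of the back-translation,
antisense primers from the 5' end before reverse-complementing — the
convention that reproduces dropping an initiator base on one side and a
wobble base on the other. Binding-site search treats degenerate-vs-degenerate
positions by set-intersection emptiness: deterministic and alignment-free.

## Trees and layouts

`single_linkage()` implements minimum-linkage agglomeration directly (the
merge criterion is the minimum pairwise distance between clusters) with a
deterministic tie-break — the lexicographically smallest label pair merges
first — and is cross-checked in the tests against both a naive
agglomeration oracle and `stats::hclust(method = "single")`. The result
serialises as an unrooted `ape::phylo` with midpoint branch lengths (two
taxa at distance 0.4 get 0.2 + 0.2). Distances are `1 − identity`.

`force_layout()` is a Fruchterman–Reingold-style scheme: uniform repulsion
`k²/d`, attraction `k·s·d` proportional to pairwise similarity, and a
linearly cooling displacement cap. The spring constant defaults to a fixed
0.1 rather than the area-normalised `sqrt(area/n)` so that a similarity-free
(repulsion-only) matrix spreads further the more nodes it has, which is the
behaviour one expects of unconstrained mutual repulsion.

## The synthetic-data generators

`gen_mtase()` plants concrete motif instances (sampled from the configured
patterns) in the canonical order of the requested group, separated by 4–12
residue gaps, with a ≥40-aa TRD at the group's canonical position, in a
background drawn uniformly over the 20 residues; substitution noise touches
only non-motif positions unless asked otherwise. Protein length defaults to
320 aa — within the span of the real enzymes here (267 aa methylases) and
single-domain bacterial MTases generally, with room for every planted
block. `gen_family()` / `gen_two_clade_family()` duplicate-and-mutate along
a recorded topology with substitutions biased to stay within conservation
groups (probability 0.7), so similarity decays more slowly than identity,
as in real protein families. `gen_rm_locus()` emits a locus with exact gene
sizes, strands and intergenic gaps (the canonical two-gene divergent
geometry uses the 660-bp and 804-bp genes with a 326-bp gap; the published
description of that locus also contains a 350-bp figure for the same gap,
and we follow the more precise 326-bp value), ORF-like gene bodies
(ATG…TAA, reverse-complemented on the minus strand), an adjustable GC
fraction for high-GC genomes, and optional planted recognition-site
contexts; accidental recognition sites arising from the random background
are scrubbed so the planted site list is exhaustive truth.

What the generators deliberately do **not** emulate: insertions/deletions
(no indel noise by default), realistic substitution processes (no rate
heterogeneity), codon usage inside synthetic ORFs, and motif blocks longer
or fuzzier than their configured patterns. Passing recovery tests therefore
demonstrate that the algorithms are correct under their stated assumptions
— not that the shipped prose-consensus patterns suffice to classify
arbitrary real proteins, where curated block models (or the full published
alignment) should be supplied via the motif configuration.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive everywhere (protein and DNA); cut
  offsets are between-base positions from the recognition start (offset 3
  on TCGCGA cuts TCG↓CGA; equal top/bottom offsets mean blunt ends).
- Methylation marks are explicit per-position annotations; `dam_marks()`
  auto-marks GATC adenines. Cleavage blocking is rule-driven
  (`default_methylation_rules()`): the TCGCGATC Dam-overlap context blocks
  NruI but not Sbo13I.
- Case-insensitive sequence input, uppercase canonical storage; `-` is the
  only gap character (`.` is rejected, not translated).
- `X` back-translates to NNN with a warning; empty peptides, non-ORF
  lengths (not divisible by 3), regions outside the protein, overlapping
  requested genes and patternless enabled motifs are all errors, not
  silent fixes.
- The methylation-type call is a transparent enumerated vote (dot blots,
  Mrr restriction, Dam-overlap cleavage, homology), majority wins, ties are
  `inconclusive`, and the full vote list is returned — matching how such
  calls are argued in practice.
- Printed primer reproduction: the two reproducible published primers are
  unit-test oracles. A third published primer implies a Phe-position codon
  (TTA) that does not encode Phe under the standard code; it is documented
  here and deliberately not used as an oracle.

## Known limitations

- Circularly permuted 5mC methyltransferases are out of scope.
- The published 46%/55% (endonucleases) and 49% (methylases)
  identity/similarity figures can only be recomputed from the deposited
  GenBank records, which are not distributable as text with this package
  and whose original alignment parameters are unstated; the corresponding
  acceptance check runs only when the user supplies those sequences, and
  its tolerance is correspondingly loose.
- `run_pipeline()` problem sizes used in tests and the acceptance script
  (320-aa proteins, 100 per group, 20 family seeds, 10 layout seeds) were
  chosen as desk-scale defaults that exercise every code path with stable
  statistics.
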