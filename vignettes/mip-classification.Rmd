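---
title: "Classifying fungal MIP channels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fungal MIP channels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipscan)
```

## The problem

Major Intrinsic Proteins (MIPs; the aquaporin superfamily) are channel
proteins with a conserved "hourglass" fold: six transmembrane helices
(TM1–TM6) and two re-entrant half-helix loops, B and E, each carrying an
Asn-Pro-Ala (NPA) box that meets in the middle of the membrane. Substrate
selectivity is set largely by the aromatic/arginine (Ar/R) filter, the
narrowest pore constriction, built from four residues: one each from TM2 and
TM5 and two from loop E (LE1 and LE2). Fungal genomes encode a diverse MIP
complement — orthodox aquaporins (AQP), a large and heterogeneous
aquaglyceroporin (AQGP) branch (Fps1-like, Yfl054-like/facultative, α, β,
γ1, γ2 and the δ cluster), XIPs, and a microsporidian cluster with plant-SIP
character ("SIP-like": small proteins, hydrophobic filter without the
canonical arginine, substituted loop-E NPA box, long and highly charged loop
D).

`mipscan` re-implements the analytical pipeline behind that
characterization as reusable, testable code: sequence validation, feature
extraction, distance phylogeny and combined rule/clade subfamily
classification, plus a synthetic-data generator so each stage can be
exercised without any sequence downloads.

## Pipeline overview

1. **io_core** — FASTA input (normalized, validated), greedy CD-HIT-like
   redundancy removal (`dedup_sequences`, default identity threshold 1.0;
   the original protocol does not state its cutoff).
2. **topology** — Kyte–Doolittle hydropathy (window 19, threshold 1.6,
   TM length bounds 15/30) in `predict_topology`, or `import_topology`
   for spans computed by an external predictor such as TMHMM.
3. **anchor_align** — Needleman–Wunsch global alignment (BLOSUM62, gap
   open 10, extend 0.5) against annotated anchor sequences; all
   position-wise features are read through the alignment map
   (`choose_reference`, `map_position`).
4. **features** — NPA boxes (`locate_npa_boxes`), Ar/R filter
   (`extract_arr_filter`), pI and molecular weight, loop-D length/charge,
   loop-E motif class and intra-helical salt bridge, conservation at the 17
   helix-interface positions, and the three-criterion MIP validation.
5. **phylo** — p-distances, Saitou–Nei neighbor-joining, bootstrap over an
   anchor-projected pseudo-alignment, 50% majority-rule collapse, and
   clade labeling from anchor leaves.
6. **classify** — rule matching of the filter against the published
   per-subfamily residue sets (shipped as data in
   `inst/extdata/rules_fungal.tsv` and `rules_plant.tsv`), combined with
   the clade label (`combine_calls`); per-subfamily summaries.
7. **pipeline_cli** — `run_scan`/`run_classify` and the `mipscan` CLI
   (`simulate`, `scan`, `tree`, `classify`, `summarize`) with JSON run
   manifests.

## Validation criteria

A candidate sequence is accepted as a MIP when

* (a) both NPA boxes can be located through the anchor alignment. A box is
  located positionally, not by string search, so any triplet at the
  anchored coordinates counts as "NPA-like"; it is *substituted* wherever
  it differs from `NPA`. A sequence counts toward a subfamily's "NPA
  substitution %" when at least one box is substituted (the per-box
  convention is available from the feature table).
* (b) the topology has exactly six TM spans with loops B and E present.
* (c) at least 9 of the 17 helix-interface positions (configurable) carry a
  small/weakly polar residue (G, A, S, T, C) — "most of" the 17.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| hydropathy window | 19 residues | Kyte–Doolittle averaging window |
| TM threshold | 1.6 | windowed hydropathy cutoff |
| TM length bounds | 15–30 residues | spans outside are split/discarded |
| peak rescue threshold | 2.6 | short-run rescue (see below) |
| gap open / extend | 10 / 0.5 | BLOSUM62 affine gap penalties |
| dedup threshold | 1.0 | greedy redundancy-removal identity |
| min_conserved | 9 of 17 | interface-conservation floor |
| bootstrap replicates | 100 (`run_config`) | 1000 in the published protocol |
| support threshold | 50% | majority-rule collapse and clade use |
| pKa set | `bjellqvist` | pI computation (alternative: `emboss`) |

## Numerical and design choices

**Coordinates.** All positions are 1-based and spans inclusive, the
R/Bioconductor convention (IRanges, Biostrings), rather than 0-based
half-open; NPA box offsets are reported as 1..3.

**Topology two-cutoff rule.** Maximal hydropathy runs at or above 1.6
become TM candidates; runs longer than 30 are split near-equally. A run
slightly shorter than 15 is still accepted when its hydropathy *peak*
reaches 2.6 — the classical two-cutoff trick of hydropathy-based TM
detection. Without it, a genuinely transmembrane helix flanked by unusually
hydrophilic loop residues is occasionally trimmed below 15 positions and
dropped, which mis-fails validation criterion (b) for a fraction of a
percent of bona fide (generated) MIPs.

**Identity convention.** Pairwise identity (and similarity: positive
BLOSUM62 score) is computed over mutually non-gap columns; columns
containing `X` never count as matches. A full-alignment-length denominator
is available (`identity_denom = "columns"`) because published pairwise
statistics are sensitive to this convention.

**pI.** Bisection on pH 0–14 to 1e-4 over the Henderson–Hasselbalch net
charge with the Bjellqvist pKa set (D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98,
K 10.0, R 12.0, N-term 7.5, C-term 3.55). Loop-D "charged" counts use
D/E/K/R only; histidine is excluded as its protonation near neutral pH is
ambiguous.

**Loop-E motif precedence.** The 6-residue window after the loop-E NPA box
is classified with fixed precedence AQGP-core (RDxGPR) > AQGP-δ
(RDxG[not-P]R) > XIP-type (RCx[G/A]xx) > AQP-type (R[S/A]xG[P/A]x) > none,
which makes ambiguous windows deterministic. The intra-helical salt bridge
is reported when an acidic residue at window offset *i* co-occurs with a
basic residue at *i*+4.

**Anchors.** The experimentally determined template structures cannot be
shipped or fetched offline, so the default anchors are *synthetic*: one
canonical sequence per subfamily generated from the package's architecture,
with exactly known TM spans, NPA boxes, filter, interface positions and
motif window (`reference_set()`, `canonical_reference()`). Annotations
derived from real structures can be supplied as JSON
(`read_reference_annotations()`); every downstream function only sees the
`mip_ref` contract.

**Pseudo-alignment for the bootstrap.** A full progressive MSA is out of
scope. Each sequence is projected onto its best-scoring anchor, anchors are
projected onto a master anchor (lexicographically smallest id), and the
composed map defines common columns. Bootstrap replicates resample those
columns; supports are the fraction of replicates containing each reference
bipartition. NJ tie-breaks take the lowest index pair and negative branch
lengths are clamped to zero with a warning, so trees are deterministic.

**Clade assignment.** Clades are the descendant sets of the (NJ-rooted)
tree; a query takes the label of the smallest supported clade containing it
whose labeled anchors are unanimous. A query contained in no labeled clade
is tested against complement sides too, but is rejected when a supported
edge separates it from the side's anchors — so a stray leaf outside every
labeled clade stays unclassified, as does any tie between equally small
sides with different labels.

## The synthetic world

The generator emulates exactly the statistical structure the analysis
assumes; its defaults are the stated conditions of the characterization it
mirrors:

* six 23-residue TM blocks from a strongly hydrophobic background (I/L/V),
  loops uniform over the 20 standard residues, with charged/polar caps on
  the two loop positions flanking each TM (the positive-inside character of
  real membrane proteins; without the caps, hydropathy runs bleed across
  short loops);
* per-subfamily Ar/R filter residues drawn from the published residue sets
  (the same table the rule classifier reads, so generation and rules cannot
  drift apart);
* per-box NPA substitution rates chosen so the expected fraction of
  sequences with at least one substituted box equals the published
  per-subfamily percentage: the substitution lives on the loop-E box (the δ
  proline position for δ/α/Fps1-like/Yfl054-like, the alanine position
  otherwise), except δ which additionally substitutes loop B in 30% of
  members while its loop-E box is always substituted (100%);
* loop D longest (26 vs 14–16 residues) and most charged (fraction 0.6 vs
  0.25) in SIP-like members, which also get short termini — making them the
  smallest proteins (~27.7–28.3 kDa against ≥29.4 kDa for all others; the
  SIP-like rule-path mass ceiling of 28.8 kDa is calibrated as the midpoint
  of that gap);
* subfamily-specific loop-E motif classes consistent with the drawn LE2
  residue (an XIP member drawing K at LE2 has no motif, matching the R/K
  polymorphism of that group);
* 14 of the 17 interface positions carry the small/weakly-polar group
  residue in SIP-like members (16 elsewhere);
* background mutations at rate 0.02 by default outside planted sites; TM
  positions mutate within the hydrophobic set, loop positions over all 20
  residues — the simplest model that keeps hydropathy-based topology
  recovery meaningful.

What the generator does **not** emulate: real indel structure, correlated
evolution along a phylogeny, compositional bias beyond hydropathy, partial
sequences, or sequencing artifacts. A green round-trip test therefore
establishes internal consistency of the pipeline (extraction inverts
planting, classification inverts simulation), not accuracy on natural
sequences; on real data the alignment-based mapping and the hydropathy
predictor are the components most likely to need externally supplied
topologies (`import_topology`) and curated anchors.

For the end-to-end round trip at seven subfamilies the set
{AQP, Fps1-like, α, β, δ, XIP, SIP-like} is used: both major clusters, both
newly described subfamilies and XIP.

## Known limitations

* Neighbor-joining over p-distances is the published protocol, but
  maximum-parsimony cross-validation is out of scope here.
* The anchor-projection pseudo-alignment underweights regions absent from
  the master anchor; with the default synthetic anchors this is harmless
  (architectures are aligned), with diverse real anchors a proper MSA would
  be preferable.
* `group_identity_stats` is quadratic in the number of sequences; for
  hundreds of sequences expect minutes.
* The δ/α vs β separation (identical W-G-Y-R-compatible filters) is purely
  tree-based; the rule path reports all compatible candidates, as no
  quantitative rule separates them.
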