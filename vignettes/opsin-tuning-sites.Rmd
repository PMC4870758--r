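---
title: "Screening duplicated opsins for spectral-tuning sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening duplicated opsins for spectral-tuning sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinsites)
```

## The problem

Visual pigments are opsin proteins bound to a retinal chromophore; the
residues lining the chromophore binding pocket (CBP) — those within 4 Å of
retinal — dominate the tuning of peak sensitivity (λmax). When an insect
lineage lacks a middle-wavelength opsin class but shows behavioural or
electrophysiological evidence of short-wavelength sensitivity, a natural
hypothesis is that duplicated UVS or LWS opsin copies diverged at tuning
sites. This package implements the screening side of that analysis: given
paralog sequences, branch-site positive-selection summaries and (optionally)
a homology model with retinal, it ranks sites by combined evidence.

The screen is a deterministic rule system, not a fitted model: every output
is reproducible from the inputs with no statistical estimation beyond the
chi-square likelihood-ratio test used for the selection p-values.

## Substitution significance rules

`classify_substitution(a, b)` assigns categorical labels to an ordered
residue pair, in fixed rule order:

1. **Size** — side chains are compared by their count of non-hydrogen atoms
   (G0, A1, S2, C2, T3, V3, P3, L4, I4, M4, N4, D4, Q5, E5, K5, H6, R7, F7,
   Y8, W10); a difference of ≥ 2 atoms is an increase or decrease in size.
   We read "differs by more than one atom" as a count difference, not a
   longest-chain path difference, because the count reading reproduces the
   curated substitution rows (e.g. P→E "increase in size", S→G "decrease in
   size") with only two documented conflicts (A↔V and C↔I, both count
   difference exactly 2, flagged as exceptions in the packaged table rather
   than special-cased in code).
2. **Charge** — transitions into or out of the positive {K, R, H} and
   negative {D, E} classes; histidine is counted positive. Charge labels
   carry the partner class annotation ("from polar", "to neutral") and
   suppress plain polarity labels at the same site, matching how curated
   rows involving charged residues are labelled. A direct positive↔negative
   swap would emit both a loss and a gain label; no such row occurs in the
   packaged data, so this convention is documented rather than inferred.
3. **Polarity** — polar {S, T, C, Y, N, Q} ↔ nonpolar transitions, when no
   charge label fired.
4. **Disulfide potential** — gained or lost when exactly one side is
   cysteine; stacks with size/polarity/charge labels.
5. **Backbone rigidity/flexibility** — when exactly one side is proline.
6. Otherwise a differing pair is **most likely insignificant**; identical
   residues get no label.

The rules are antisymmetric by construction (each gain in a→b is the
matching loss in b→a), total over all 400 ordered pairs, and the
insignificant label never stacks with another. Multi-residue paralog states
("T/S" vs "Q") are expanded to all ordered pairs and a record is significant
if any pair is.

The chemistry table ships as a versioned TSV
(`extdata/residue_chemistry.tsv`) so alternate conventions can be swapped
without touching code.

### Direction and curation conventions

The source tables that the packaged evidence transcription reproduces are
not consistent about substitution direction (some rows print "gain" where
the paralog-1 → paralog-2 reading is a loss). The classifier fixes the
direction as paralog-1 → paralog-2 and the packaged table records the
printed wording verbatim; row agreement is judged modulo direction, with
classifier-found labels beyond the print tolerated as summarisation. The two
rows where the printed substance genuinely conflicts with the size rule
(A↔V printed insignificant; C↔I printed without the size change) are flagged
`exception = 1`, and the tests require exact agreement everywhere else.

## Percent similarity

`percent_similarity()` counts alignment columns whose pair is identical or
chemically conserved — BLOSUM62 score ≥ 1 (the threshold is ≥, not >; every
diagonal entry is ≥ 4, so identities always qualify) — divided by a
denominator that by default counts only columns where both rows carry a
residue. The source statistic ("identical plus conserved over total amino
acids") does not define gap treatment; the both-residue default makes
self-similarity exactly 100 and is insensitive to terminal overhangs, and a
`mean_sequence_length` mode is available for sensitivity checks. Reported
values are unrounded; round at presentation time.

Global alignment is delegated to the Biostrings Needleman–Wunsch
implementation (affine gaps, default open −10 / extend −1 in score units;
these are configuration values, not constants). Its optimality is verified
in the tests against an exhaustive enumeration oracle on short sequences,
and its tie-breaking is deterministic, which is what downstream numbering
needs.

## Reference numbering

Opsin sites are reported on a fixed reference numbering (the
bovine-rhodopsin convention). `map_to_reference()` walks the columns of a
reference–query alignment: query residues in reference columns take the
reference position; residues opposite reference gaps take insertion codes
anchored to the preceding reference position (`242^a`, `242^b`, …,
continuing `z` → `aa`), and insertions before the first reference residue
anchor to 0. Labels are monotone along the query and every query position
receives exactly one label. Insertion-coded sites are first-class sites
throughout the screen.

The packaged reference (`extdata/rhodopsin_reference_synthetic.fasta`) is a
synthetic 348-residue rhodopsin-like sequence with the canonical landmark
residues (K296, E113, C110/C187) at their usual positions; it is **not** the
deposited bovine sequence, and nothing in the analysis depends on the real
one — numbering is purely positional. Users mapping real data should supply
their own reference FASTA. The transmembrane/loop interval table
(`extdata/rhodopsin_regions.tsv`) is likewise an approximate seven-helix
topology, chosen to be consistent with every region label in the packaged
evidence; the N-terminus is classed extracellular and the C-terminus
cytoplasmic.

## Binding-pocket detection

`binding_pocket()` computes, per polymer residue, the minimum Euclidean
distance to any atom of the designated ligand (residue name `RET` by
default — selection is by residue name, not HETATM status, so waters and
ions can never masquerade as chromophore) and includes residues at or below
the cutoff. Choices that needed fixing:

* boundary at exactly 4.0 Å is **included** — ties are measure-zero on real
  coordinates but the planted-fixture tests need a deterministic convention;
* hydrogens are excluded by default (homology models are typically H-free);
  excluding them can only keep or increase a residue's minimum distance;
* distances are computed in double precision and written to 0.01 Å.

The PDB reader is a small fixed-column parser (ATOM/HETATM, first MODEL
only, altloc blank/`A`), written in-package so that malformed coordinate
fields are reported with their line number and the model/altloc policies are
exactly as stated; the test suite cross-checks it against `bio3d`. Pocket
membership is checked against a brute-force all-pairs oracle, is monotone in
the cutoff, and is invariant under rigid motions to 1e-9 Å.

## The combined-evidence screen

`load_evidence_table()` reads one row per substitution record and groups by
(gene class, site), merging branches, pairs and literature keys by union.
`screen_candidates()` applies the three clauses (positive selection;
literature; CBP + structural significance); each candidate reports which
clauses fired. "Under positive selection in one paralog" is operationalised
as: the site's record carries at least one foreground branch (the packaged
table only records selection on the lineage it was observed in;
cross-paralog exclusivity would require the full per-branch site lists,
which are out of scope). Sites whose printed labels alone would not qualify
(e.g. pocket sites with only an insignificant substitution) enter through
their literature evidence — clause 2 — rather than by special-casing.

`summarize_headline()` partitions each class's candidates into
binding-pocket sites and non-pocket sites under selection on a
**paralog-wide** branch (default {UV-C, UV-D} for UVS, {LW-C, LW-E} for
LWS — branches spanning a whole buprestid paralog clade; the set is
configuration, not hard-coded). This reproduces the published partition:
UVS 5 pocket + 5 non-pocket, LWS 3 + 3, with single-lineage branches
(UV-F, LW-F/G) and the male-specific LW-H excluded from the headline lists.

When a pocket table derived from coordinates is supplied, it overrides the
transcribed CBP flags, so a user's own homology model can re-anchor clause 3.

`lrt_pvalue()` is the one inferential step: p = upper tail of χ²(df) at
2·(lnL_alt − lnL_null), with slightly negative statistics clamped to zero
with a warning.

## Synthetic data: what it does and does not emulate

The generators give every stage a controlled truth:

* `generate_paralog_pair()` plants exactly `round((1 − f)·L)` substitutions
  drawn from pairs verified to score < 1 under BLOSUM62, so percent
  similarity equals `100·f` *exactly* — sharp tests instead of approximate
  ones. Defaults used in the tests (length 300, conserved fractions
  0.5–0.95) bracket realistic opsin paralog divergence (roughly 72–95 %
  similarity across reported insect paralog pairs).
* `generate_indel_variant()` returns the edited sequence *and* the implied
  alignment, so numbering tests check the bookkeeping, not aligner gap
  placement (which is genuinely ambiguous for repeat-adjacent insertions).
* `generate_toy_structure()` plants pocket residues at minimum distances in
  (1, cutoff] and non-pocket residues at ≥ cutoff + 1, with a two-atom
  residue whose outer atom is verified not to undercut the planted distance.
* `generate_evidence_fixture()` plants a known candidate count with a known
  clause mix.

All generators are seed-deterministic and restore the caller's RNG state.
What they do **not** emulate: real paralog pairs have conservative
substitutions (BLOSUM62 ≥ 1) that the similarity statistic counts as
conserved, alignment uncertainty, and correlated evidence across sites;
passing the synthetic tests therefore demonstrates the statistics are
computed as defined, not that the screen's biological assumptions hold.

## Problem sizes and numerical choices

The test suite runs 100-replicate batteries for the similarity, pocket and
numbering round-trips (sequences of length 300, structures of 4–12 residues
with a 10-atom ligand), the full 400-pair classifier enumeration, and a
1,000-point LRT monotonicity grid — sizes chosen so the whole suite runs in
under a minute on one core while still exercising every code path.
Tolerances: LRT quantile checks at 1e-6, the df = 1 closed form at 1e-10,
rigid-motion invariance at 1e-9 Å; everything else is exact equality by
construction.

## Known limitations

* No physics: labels are categorical, with no ΔΔG or spectral-shift
  prediction, and no handling of non-canonical residues.
* No alignment construction beyond pairwise: multiple alignments are
  consumed, not built; no codon-level alignment or tree inference.
* Branch-site model fitting and BEB posteriors are consumed as tables, not
  recomputed; both 0.95 and 0.99 posterior classes count equally as
  selection evidence.
* The structure stage reads fixed-column PDB only (no mmCIF), and pocket
  validation is on synthetic structures — the published pocket residue set
  for real buprestid models is carried as transcribed flags.
* Published similarity percentages for real paralog pairs (e.g. 72 % for
  the most divergent UVS pair) require the deposited alignments; they are
  not packaged, so the similarity statistic is validated on planted data
  only, where its value is exact by construction.
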