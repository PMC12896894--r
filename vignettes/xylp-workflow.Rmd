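---
title: "Identifying and characterizing xylogen-like proteins: methods and design"
author: "xylpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing xylogen-like proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylpscan)
```

## The biological problem

Xylogen-like proteins (XYLPs) are chimeric arabinogalactan proteins: an
AGP-type backbone rich in Pro/Ala/Ser/Thr (PAST) carrying potential
O-glycosylation dipeptides, fused to a non-specific lipid-transfer protein
(nsLTP) domain whose eight conserved cysteines form four stabilizing
disulfides. They act as mobile signals of vascular differentiation, and
genome-wide surveys of the family are a standard first step toward
functional work in a new species. This package implements such a survey as
one scripted workflow: membership classification, physicochemical
characterization, phylogeny, selection and duplication analysis, promoter
cis-element profiling, and expression summaries.

## The membership rule and its parameters

A protein is accepted as an XYLP iff it has (i) a PAST-rich region, (ii) an
AG glycomodule inside such a region, and (iii) the nsLTP cysteine motif.

**PAST-rich regions.** The field's criterion is "a region with ≥ 35% PAST
residues", which leaves *region* undefined. We make it operational and
oracle-checkable: a position belongs to a region iff it is covered by some
window of length ≥ `l_min` (default 20 residues) whose PAST fraction is
≥ `theta` (default 0.35, threshold inclusive); reported regions are the
maximal runs of covered positions, built deterministically left to right.
Every qualifying window is therefore contained in exactly one reported
region, and `find_past_regions()` is testable against a brute-force
enumeration of all windows. `l_min = 20` reflects the scale of the shortest
glycosylated AGP backbone stretches; both parameters are configurable. One
caveat is intrinsic to the union construction: a merged run is almost
always ≥ `theta` overall, but adversarial compositions can dip below it —
the actual fraction is always reported, and the union contract is the
normative one. Note also that a long dilute window can legitimately extend
a region beyond a dense planted core: with a 40%-PAST 100-mer, the full
span itself qualifies at θ = 0.35.

**Glycomodules.** All six dipeptides AP, PA, SP, PS, TP, PT are counted,
overlaps included, with no de-duplication — no merging rule exists in the
field's definition, and counts are only used as evidence of ≥ 1.

**nsLTP motif.** The consensus C1–X–C2–X–P–X–C3C4–X–C5XC6–X–C7–X–C8 fixes
the order of the eight cysteines, the C3C4 adjacency, the single inter-C5C6
residue, and a Pro between C2 and C3; the remaining spacer lengths vary
across plant nsLTPs. We treat the fixed elements as hard constraints and
the variable spacers as configurable inclusive ranges (defaults: C1–C2
5–15, C2–C3 8–20, C4–C5 5–30, C6–C7 10–30, C7–C8 3–20 residues), chosen
wide enough to span canonical plant nsLTP domains. The matcher returns the
*leftmost* assignment (smallest C1, ties by C2, then C3, …) found by
depth-first search, which is provably the first valid combination in
lexicographic order — the property the exhaustive-search oracle checks. The
inter-C5C6 residue (typically Leu) is annotated as hydrophobic or not but
never filtered on: documented family members carry I/V/A/F/M there.

Accepted candidates are named `prefix1..prefixN` in input order; without an
external homology-score ordering this is the only reproducible choice.

## Physicochemical profiling

All quantities follow the ProtParam family of tools: average (not
monoisotopic) residue masses with one water per chain, reported in kDa;
GRAVY as the mean Kyte–Doolittle value; hydropathy profiles as unweighted
sliding means (window 9, odd required); the Guruprasad instability index
`(10/L) · Σ DIWV(x_i, x_{i+1})` with the published 400-entry dipeptide
weight table bundled as data; and the aliphatic index in mole percent. The
theoretical pI uses the Bjellqvist pKa set (side chains D 4.05, E 4.45,
C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0; C-terminus 3.55; residue-dependent
N-terminus). The net charge is strictly decreasing in pH, so bisection on
[0, 14] to |charge| < 1e-4 finds the unique root; tests hold it within 0.01
of a 0.001-step grid search. The pKa set approximates the named web tool
rather than reproducing it bit-for-bit — the worked-example checks
therefore run on the *published* table columns, not on recomputed
sequences. Sequences with ambiguous `X` residues error by default rather
than silently shifting Table-style values; `X` does count in PAST-fraction
denominators, where it only dilutes.

Labels use the field's thresholds: alkaline pI > 7.0, unstable instability
index > 40, hydrophobic GRAVY > 0. External predictor outputs (signal
peptide, GPI anchor, subcellular compartment) are consumed as an annotation
sidecar and merged into reports, never computed.

## Phylogeny, selection, duplication

**Distances and trees.** Protein distances use the Poisson correction
d = −ln(1 − p) with pairwise deletion (p computed over columns where both
rows are ungapped). Saturated pairs (p ≥ 1) are capped (default 10
substitutions/site) and flagged rather than dropped, so small simulated
alignments with disjoint clades still produce trees. Neighbor joining is
the standard Saitou–Nei agglomeration; negative branch lengths are clamped
to zero and flagged. Bootstrap support resamples alignment columns with
replacement, rebuilds the NJ tree per replicate, and reports for each
internal bipartition of the full-data tree the percentage of replicates
containing it — the MEGA-equivalent procedure, deterministic under the
recorded seed. Clade labels (A–E style) are a user-supplied post-hoc
annotation, not computed.

**Ka/Ks.** `ng86_kaks()` implements Nei–Gojobori (1986) with the universal
genetic code: per-codon synonymous-site fractions averaged over both
sequences, with mutations to stop codons disregarded (removed from the
denominator — this convention is what makes the hand-workable example
S = 7/3 for GGG·GGG·AAA come out); difference counts averaged over all
mutational pathways for multi-substitution codons, pathways through stop
codons discarded (all pathways are used in the degenerate case where every
one is blocked); Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p) on both
proportions. The ratio is N/A when pS ≥ 0.75 — the published
high-divergence exclusion — and, by the same logarithmic singularity, when
pN ≥ 0.75 or Ks = 0; the reason is recorded. Codons with gaps, ambiguity,
or in-frame stops are skipped. Homolog pairs are an input (the upstream
homology search is an external step), and the codon alignment is derived
from the protein MSA by back-translation with per-residue validation.

**Duplication modes.** Tandem means same chromosome and rank distance
≤ `tandem_window` (default 2, the common collinearity-tool convention;
ranks are by gene start regardless of strand). Remaining pairs are anchors
on canonical chromosome-pair axes; maximal chains with strictly increasing
ranks on both axes (either orientation) and ≤ `max_gaps` (default 25)
intervening ranks between consecutive anchors are extracted greedily,
longest first, and pairs in chains of ≥ `match_size` (default 5) anchors
are segmental; the rest dispersed. This retains the chain-length and gap
criteria of MCScanX-style analysis while leaving its e-value and match
scoring to the external homology step. Both pair-level and chain-level
counts are reported, since "n duplication events" is ambiguous between the
two.

## Promoters and expression

Promoters are the 2000 bp upstream of the translational start (the
annotated CDS start, per the field's phrasing): for a minus-strand gene the
reverse complement of the bases after the gene end, truncated and flagged
at chromosome boundaries. Motif scanning expands each IUPAC code to its
base set — a subject `N` is matched only by the pattern code `N` — and
reports every position, overlaps included, on the requested strands;
minus-strand hits carry the original coordinate of the leftmost matched
base. A small curated cis-element dictionary (PlantCARE-style names,
categories growth/phytohormone/stress/light) ships with the package as a
default — the full upstream database is not redistributable — and user
dictionaries in the same TSV shape are accepted. TGACG-motif and
CGTCA-motif stay separate entries although they are reverse complements,
matching how such scans are conventionally reported; the default scan is
plus-strand per named motif.

Expression heatmap ordering uses average-linkage clustering on Euclidean
distances of log2(TPM + 1) rows (raw also supported; the transform is the
standard choice for TPM heatmaps, and no transform is canonical). Rows are
pre-sorted by gene name so hclust tie-breaks are deterministic.
2^−ΔΔCt quantification computes ΔCt per replicate against the
replicate-matched reference gene, ΔΔCt against the *mean* control-sample
ΔCt (replicates are biological and not paired across conditions), and
reports mean ± SD of RQ across replicates — SD on RQ, not error-propagated
from Ct, matching how such panels are reported. The control sample is a
required user parameter: which sample is the calibrator in a time-course
design is a study decision, not derivable from the data.

## What the generators emulate — and what they do not

Each generator plants known structure and emits it as machine-checkable
truth. Backgrounds are deliberately clean: proteome backgrounds are drawn
from a PAST- and Cys-free alphabet, promoter backgrounds are scrubbed of
accidental planted-pattern matches by point mutation, dispersed duplicate
pairs sit on otherwise unused chromosome pairs. This makes planted truth
unambiguous and false positives structurally impossible — which is the
point (the tests verify the *rules*, not a noise model) and also the
limitation: passing them says nothing about borderline real-world cases
such as PAST fractions hovering at θ, degenerate cysteine-rich regions with
multiple near-valid assignments, or promoter motif families that shadow
each other. Real proteomes also contain `X` residues and alternative
isoforms (structure summaries take the annotated gene's exons; isoform
choice is the user's), which the generators do not model. The amino-acid
simulator uses Poisson substitution with uniform replacement — consistent
with the Poisson distance correction, but not a realistic empirical rate
matrix; codon simulation plants fixed substitution counts rather than a
mutation process, because the quantity under test is the count recovery.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for a
routine desktop run: 200 random sequences for the region-scanner oracle, 60
sequences for the motif-assignment oracle, all 61 × 61 sense-codon pairs
for the Ka/Ks oracle, 20 seeded proteomes/layouts for recovery rates, 50
seeds × 2000 sites for NJ topology recovery, and bootstrap determinism at
B = 100 (the workflow default stays 1000). Other numerical decisions:
bisection tolerance 1e-4 on charge; saturation cap 10 substitutions/site;
negative NJ branches clamped to 0; the instability table, masses, KD scale
and pKa sets live in package constants so a different convention can be
swapped in one place.

## Known limitations

- The pI is an approximation to the named web tool's value; published-table
  checks use published columns.
- The curated cis-element dictionary covers the commonly reported element
  vocabulary, not the full upstream database; counts on real promoters
  depend on the dictionary supplied.
- Chain extraction is greedy (longest chain first); pathological anchor
  sets could admit a different chain decomposition, though pair-level
  segmental/dispersed labels are stable in all planted scenarios.
- HMM-based domain validation, signal-peptide/GPI prediction, alignment
  computation, and read quantification are out of scope by design: their
  outputs are inputs here.
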