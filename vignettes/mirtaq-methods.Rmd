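---
title: "Methods: target-site prioritization and qPCR quantification in miRtaq"
author: "miRtaq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-site prioritization and qPCR quantification in miRtaq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRtaq)
```

# Scope and model

`miRtaq` answers a practical question: given a short list of genes of
interest (for example, cancer-stem-cell-related genes differentially
expressed along the colorectal adenoma–carcinoma sequence) and a set of
database-predicted regulatory miRNAs, which miRNA–gene pairs deserve
wet-lab validation, and what do the validation qPCR data say? The
package implements the two halves separately — sequence/structure-based
prioritization and efficiency-corrected relative quantification — and a
synthetic-data generator that gives every stage a planted ground truth.

Database mining itself is out of scope: evidence (how many databases
report a pair, prior cancer/CRC/gene associations, direct validation,
miRNA annotation status) is an *input* table. Cross-species conservation
is likewise carried as an input flag, not computed.

# Seed-site model

The seed is defined as mature miRNA positions 2–7 (1-based, inclusive),
the primary determinant of target recognition. `scanSeedSites()` slides
a hexamer window over the UTR and pairs it antiparallel against the
seed. Three pair categories are distinguished: Watson–Crick, G:U wobble,
and mismatch. Wobbles have their own budget (default 1); wobbles beyond
the budget degrade to mismatches, which unifies the manual-alignment
rule ("at most one mismatch in positions 2–7") with the constrained
heteroduplex search settings ("one unpaired position, one G:U wobble").
A window is reported when mismatches ≤ 1 (default).

Site classes follow canonical nomenclature: `7mer` adds a Watson–Crick
pair opposite miRNA position 8, `8mer` additionally requires an A on the
target opposite position 1 (the A is a recognition feature, not a pair).
Coordinates are 0-based half-open throughout the machine-readable
output; the 1-based "positions 2–7" convention appears only in
documentation and rendered alignments. Overlapping sites are all
reported — no tie-breaking rule is imposed — and deduplication is left
to report consumers.

One reading decision: "one unpaired position in the seed region" is
interpreted as one unpaired *nucleotide*, not one contiguous unpaired
block. `rna22Sites()` therefore counts unpaired positions individually.

# Energies

All stacking energies come from one embedded table,
`rnaStackTable()` — the Turner 2004 RNA/RNA nearest-neighbor stacking
free energies at 37 °C, including G:U wobble stacks. The table is a
documented, swappable constant: every energy the package reports can be
reproduced by hand-summing its entries.

`duplexEnergy()` scores an ungapped antiparallel alignment as the sum of
stacking terms over consecutive paired positions plus a fixed +0.5
kcal/mol per unpaired position. The constrained search (`rna22Sites()`)
aligns the full-length miRNA over the target anchored at the seed
match, truncates at UTR ends, and filters on duplex energy at −12
kcal/mol by default (−20 kcal/mol is the other conventional setting;
both are recorded by the pipeline). Pattern-discovery significance
statistics are deliberately not implemented — the "significant" flag in
reports is the energy-cutoff test, and a tri-state (`pass` /
`near_miss` / `fail`) records seed-qualified sites whose energy misses
the cutoff.

# Folding model

`foldRNA()` is a self-contained minimum-free-energy dynamic program over
nested structures (no pseudoknots), scored by stacking only: the energy
of a structure is the sum of stack terms over directly adjacent pairs;
loops carry no penalty; the minimum hairpin loop is 3 nt. Because the
empty structure scores 0, reported energies are never positive. Ties are
broken toward fewer pairs, then the smallest pairing partner, making the
output deterministic. The recursion is O(n³) and implemented in C++;
the ~150 nt accessibility windows fold in milliseconds.

This is intentionally a simpler physical model than a full Turner
nearest-neighbor implementation (no loop penalties, dangles or
coaxial stacking). What matters for the pipeline is (i) determinism,
(ii) exact optimality under its own scoring — verified against
exhaustive enumeration of all nested structures for sequences up to
14 nt — and (iii) hand-checkable energies. The backend is pluggable:
any `function(sequence)` returning a dot-bracket and an energy can be
substituted (for example a full thermodynamic engine) without changing
any downstream contract.

# Structure elements and accessibility

`decomposeStructure()` performs the standard loop decomposition:
maximal runs of stacked pairs are stems; unpaired regions closed by one
pair are hairpin loops; by two pairs on both sides, interior loops (the
length sums both sides); on one side, bulges; by three or more pairs,
multibranch loops; and unpaired runs at the exterior level — 5′/3′ free
ends and joints between helices — are exterior segments. "Joint
sequence or free end" is mapped to exterior segments because those are
the only standard structural objects matching that phrase. Element
lengths count unpaired nucleotides (stems count base pairs); the loop
cutoffs quoted in "bp" are read as nucleotides.

Destabilising elements (DSE) are loops long enough to favor miRNA
access: hairpin ≥ 11, interior ≥ 9, bulge ≥ 7, multibranch ≥ 11,
exterior ≥ 11 nt. Stems are stabilising elements (SE). Labels are a pure
function of kind and length given the cutoffs, so lowering a cutoff can
only add DSE labels.

`assessAccessibility()` applies three criteria per site:

* **Free-energy gap (≥ 10 kcal/mol).** Three windows are folded: the
  site alone, site + 70 nt upstream, and site + 70 nt downstream. The
  criterion passes when the absolute difference between the site
  window's ΔG and either flank window's ΔG is at least 10 kcal/mol. The
  direction is reported (both signed differences), since a more stable
  flank and a less stable flank are both informative; the pass flag is
  direction-agnostic because either situation singles the site out from
  its context. Folding the site and flank jointly is the default; a
  flank-alone mode exists for sensitivity analysis.
* **DSE presence.** The site ± 30 nt window (including the site — the
  site's own pairing state is part of its accessibility) is folded,
  decomposed and labelled; the flag is whether any DSE is present.
* **Inhibitory structure (< −6 kcal/mol).** By default the rule is
  applied to the *overlapping substructure*: a stem whose attributed
  energy (the sum of its stack terms, hand-computable from the table)
  is below −6 kcal/mol and whose positions intersect the site. A
  whole-window granularity is available. The substructure default was
  chosen because a strongly folded window whose stems all avoid the
  site does not occlude it.

Windows truncated at UTR boundaries are used as-is, never padded, and
the achieved flank lengths are recorded.

# Prioritization logic

Candidates are first gated (`gateCandidates()`): the miRNA must be
annotated as a true miRNA, and the pair must have a known cancer
association or support from at least two databases. `prioritizeTargets()`
then computes four flags per pair — two-database support, folding
free-energy constraints, constrained heteroduplex hit, direct
validation — and applies two rules:

* **Inclusion** requires a DSE at the site, a previous association with
  the target gene, and a previous CRC association.
* **Selection** for the validation shortlist requires inclusion plus at
  least `min_flags` (default 2) true flags.

The folding free-energy flag defaults to "gap passed OR DSE present";
AND and gap-only variants are configurable. The 2-of-4 selection default
is a documented heuristic: the minimum-requirement marking in the
source evidence tables is not machine-recoverable, and every shortlisted
pair in the reference fixture carries exactly two positive flags. Near
misses (a seed-qualified site whose duplex energy misses the cutoff)
count toward selection only when `near_miss_counts` is set.

# qPCR model

Amplification efficiency is fitted per assay from a dilution series
(default design: 4 points, 5- to 625-fold) by regressing Cq on log10 of
relative template concentration, the standard-curve convention; the
efficiency is 10^(−1/slope), 2.0 for perfect doubling (slope −3.32).
Fits are flagged accepted for negative slopes with efficiency in
(1, 2.3].

ΔCq normalizes each target Cq to the arithmetic mean of the reference
assays' Cq values — the geometric mean of the linear reference
quantities, the standard multi-reference normalization. A literal
geometric mean of Cq values is available for sensitivity checks. The
optional efficiency correction rescales each assay's Cq to a common
log2 basis as log2(E)·Cq before differencing; this particular rescaling
is a documented package choice, since "after efficiency correction" has
no universally fixed formula. Samples missing any reference are
excluded with a logged reason; not-detected targets are never imputed.

Group contrasts use ΔΔCq = mean ΔCq(group A) − mean ΔCq(group B)
(medians available) and fold = 2^(−ΔΔCq). Folds below 1 are displayed
as x-fold down (reciprocal); the signed log2 value is kept in
machine-readable output. Dependent comparisons (lesion vs corresponding
normal mucosa) use the Wilcoxon signed-rank test; independent groups
use Mann–Whitney U; comparisons between the two carcinoma groups run on
per-case ΔΔCq values (each case normalized to its corresponding
normal first). Exact p-values are used for small samples (n ≤ 12)
without ties, otherwise the normal approximation with tie and
continuity correction. All-zero paired differences return p = 1 by
definition. No multiple-testing correction is applied by default,
matching common practice for small targeted panels; a
Benjamini–Hochberg adjustment can be applied downstream via
`p.adjust`. Spearman correlations use average ranks for ties and a
two-tailed t-approximation p; the level of malignancy is coded
ordinally (normal 0 → CRC N+ 4).

# Synthetic data: what it emulates, and what it does not

`simulationSpec()` defaults describe a five-group FFPE qPCR cohort —
normal mucosa 23, adenoma 11, adenoma with early carcinoma 13, CRC
without nodal metastases 10, with metastases 13 — with Gaussian Cq
noise of 0.25 cycles (a typical technical SD for duplicate FFPE
reactions), per-assay baselines drawn once from 18–32 cycles, reference
assays with zero group shift, and tumour samples linked to
corresponding normals. UTRs are i.i.d. background at a chosen GC
content with planted sites that are exact seed complements, optionally
carrying recorded mismatches and wobbles; planted site classes are
enforced (a planted 6mer cannot accidentally scan as a 7mer). Rank
coupling between a miRNA and a gene assay is generated through a
Gaussian copula with Pearson correlation 2·sin(πρ/6), which targets
Spearman ρ and is exact (comonotone) at |ρ| = 1.

The generator deliberately does **not** emulate FFPE RNA degradation,
amplification-curve artefacts, shared-patient correlation beyond the
paired-normal links, realistic UTR base composition, or conservation
structure. Passing tests on synthetic data therefore demonstrate
algorithmic correctness — planted signals of known size are recovered
at the expected rates — not robustness to those real-data features.

A note on noise propagation: with ΔCq referenced to the mean of two
references, each per-sample ΔCq carries variance 1.5σ²; a two-group
ΔΔCq at n = 10/group and σ = 0.25 has SD ≈ 0.14 cycles, so individual
replicate fold estimates for a planted 4-fold effect routinely land
slightly outside a ±0.2-cycle band even though the planted effect is
recovered without bias and detected at p < 0.01 essentially always.
`scripts/acceptance.R` reports both the in-band rate and the detection
rate so this behavior is visible rather than hidden.

# Numerical choices and degenerate inputs

* Energies are sums of table entries; comparisons in the folding DP use
  an absolute tolerance of 1e−9.
* Fold traceback prefers unpaired positions on ties, so zero-energy
  isolated pairs never appear.
* Empty flank windows (site at a UTR boundary, flank-alone mode) score
  ΔG = 0 without calling the folder; folding an empty sequence is an
  error.
* The scanner requires mature sequences ≥ 8 nt (seed plus position 8);
  shorter input is a validation error, as are non-ACGU/T symbols
  anywhere.
* Dilution-series fits require ≥ 3 distinct dilutions and error on zero
  Cq variance (efficiency undefined).
* Degenerate rank tests (no variance anywhere) return p = 1 rather than
  NaN.

# Problem sizes used by the test suite

The shipped tests run at desk scale, chosen to finish in minutes while
exercising every contract: 100 random miRNA–UTR pairs against a
brute-force window enumerator; 500 planted sites (250 perfect, 250 with
one mismatch); 1,000 random dot-brackets for the partition and
classifier checks; 50 sequences of length ≤ 14 for exhaustive-enumeration
folding optimality; 200 replicate Cq simulations for fold-change and
correlation recovery; and a full simulate-then-analyze pipeline run
checked for byte-identical reproducibility under a fixed seed.

# Known limitations

* The internal folder's stack-only scoring understates loop penalties;
  absolute ΔG values are not comparable to full thermodynamic engines,
  only to other energies computed by the same model. Swap in a full
  engine via the backend hook where absolute energies matter.
* MFE-only: no suboptimal ensembles or partition-function
  accessibility.
* Site scanning is seed-driven; 3′-compensatory or centered sites
  without seed pairing are not found.
* The evidence table is trusted as given; no database queries or
  literature mining are performed.
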