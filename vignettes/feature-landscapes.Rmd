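---
title: "Methods: structural feature landscapes of missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural feature landscapes of missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varscape)
```

## Overview

`varscape` turns a set of missense variants into a binary variants-by-features
matrix and compares two such matrices feature-by-feature with odds-ratio
enrichment statistics. This vignette documents the models and conventions
behind every step, the tunable parameters, the numerical choices, and what the
built-in synthetic fixtures do and do not demonstrate.

## Structure input

Models are AlphaFold-style monomeric PDB files: a single chain, heavy atoms,
and the per-residue pLDDT confidence written identically into the B-factor of
every atom of a residue. `read_structure()` therefore:

* keeps `ATOM` records only (no waters or ligands), drops hydrogens and
  alternate locations other than blank/`A`;
* rejects multi-chain files — features computed on a monomer are not
  meaningful for an arbitrary complex, and silently reading "the first chain"
  would hide that;
* reads pLDDT from the **CA atom only** (`extract_plddt()`), clipped to
  [0, 100]. AlphaFold writes identical values on all atoms of a residue, so
  any atom would do; fixing the carrier makes behaviour deterministic for
  hand-edited files whose atoms disagree. A sensitivity check against
  per-residue means is trivial to run by editing fixtures, which is why the
  CA rule is isolated in one function.

Unknown residue names are kept with code `X` (with a warning) rather than
dropped, so downstream position bookkeeping stays intact; `X` residues have
no reference maximum accessibility and therefore get `NA` burial.

## Per-residue structural features

### Order and disorder from windowed pLDDT

A position is `Order` when the mean pLDDT over a ±`window` residue window
(default 2) is at least `threshold` (default 50), else `Disorder`. Window
means at the chain termini are taken over the residues that exist
(truncation, not padding): padding with an arbitrary constant would bias
terminal calls toward that constant. `NA` values are excluded from the mean;
an all-`NA` window returns `NA`. The boundary case — a mean of exactly 50 —
is `Order`, consistent with defining order as "pLDDT ≥ 50"; the call is
monotone in every pLDDT value of the window, which the test suite checks as a
property.

### Contact density

`count_contacts()` counts distinct residues `j` with `|j − i| >
neighbor_exclusion` (default 2) having any heavy atom within `radius`
(default 5.0 Å) of any heavy atom of residue `i`. The exclusion removes
trivial bonded neighbours; 5 Å on heavy atoms is a common contact definition
in structural biology. The binary `Contacts` feature fires at
`contact_min = 8` contacts (configurable in `build_feature_matrix()`); the
cutoff is a package default chosen so that core residues of a packed fold
fire and isolated-chain residues do not, and it is deliberately exposed
rather than hidden because no single value is canonical.

### Solvent accessibility and burial

`compute_sasa()` is a Shrake–Rupley implementation: each atom's van der
Waals sphere (C 1.70, N 1.55, O 1.52, S 1.80 Å; unknown elements fall back
to 1.70 Å with a warning) is expanded by the probe radius (default 1.4 Å,
water) and sampled with a deterministic golden-spiral lattice of `n_points`
points (default 960); a point survives if it lies outside every other atom's
expanded sphere.

Two numerical choices matter:

* **Rigid-motion invariance.** The lattice is expressed in a frame built
  from the molecule's own atoms (first distinct atom pair, first
  non-collinear third atom), so rotating or translating the molecule rotates
  the quadrature with it and the computed areas are identical to rounding
  error, not merely to quadrature error.
* **Exact tangency.** A sample point lying exactly on another atom's
  expanded sphere can only arise in degenerate inputs (e.g. two coincident
  atoms). Ties are resolved by atom index — the lower-indexed atom keeps the
  surface — so two coincident identical atoms jointly expose the area of one
  sphere, matching the geometric union.

Relative accessibility is SASA divided by the residue's theoretical maximum
(Tien et al. 2013), clipped to [0, 1]; burial classes partition [0, 1] with
half-open boundaries: Core < 0.05 ≤ MediumBuried < 0.50 ≤ MediumExposed
≤ 0.75 < Exposed. Exact 0.50 and 0.75 fall in MediumExposed.

### Secondary structure

`assign_secondary_structure()` follows Kabsch–Sander: the amide H is placed
1 Å from N along the preceding residue's C=O direction (none for chain
starts, prolines, or after numbering gaps); a hydrogen bond is called when
the electrostatic dipole model `27.888·(1/d_ON + 1/d_CH − 1/d_OH − 1/d_CN)`
kcal/mol is below −0.5. Two consecutive i→i+4 turns mark residues i..i+3 as
Helix; parallel/antiparallel bridge patterns mark Strand; helix takes
precedence; everything else — including 3₁₀/π turns, bends and isolated
bridges — is Loop. This three-state reduction keeps exactly the classes the
feature registry uses (α-helix, β-ladder strand, loop). Residues with
incomplete backbones are Loop with a warning and never partners in bonds.
Turn and bridge patterns are indexed by residue *number*, so chain breaks
(used by the multi-segment fixtures) are never spanned.

## Substitution and thresholded features

The property table assigns each residue a size class (small:
G,A,S,C,T,P,N,D,V), polarity (polar: S,T,N,Q,Y,C,H,D,E,K,R), charge
(D,E,K,R,H) and hydropathy (hydrophobic: A,V,L,I,F,M,C; hydrophilic: charged
plus N,Q,S,T; the rest neutral). Charged residues are constrained to be polar
and hydrophilic, and `read_property_table()` enforces this on user-supplied
overrides. "Introduced" features fire only when the reference residue lacks
the property and the alternate has it; directional pairs (SmallToBig /
BigToSmall and PolarToNonpolar / NonpolarToPolar) are mirror images and can
never co-fire, which the suite checks over all 380 ordered residue pairs.

Thresholded features: TotalEnergy at ΔΔG ≥ +1.0 kcal/mol, LessTotalEnergy at
ΔΔG ≤ −1.0 kcal/mol (the two cutoffs must stay ordered, so the two features
cannot co-fire), VanDerWaalsClashes at a clash score ≥ 0.5. These defaults
are package choices on the usual FoldX-like scales, exposed through
`default_thresholds()`. `Conserved` has **no default cutoff**: conservation
metrics differ wildly in scale (rate-based, frequency-based, rank-based), so
the feature stays `NA` until the user supplies `cons_cutoff` for the metric
actually present in their table. Any missing input yields `NA` for the
affected features only — the pipeline never halts because one annotation
source failed, and `NA` cells are excluded from both margins of the
downstream contingency tables.

## Variant ingest and the feature matrix

The primary input is a protein-level TSV (`protein_id`, 1-based `position`,
`ref_aa`, `alt_aa`, plus optional score/annotation columns). VEP-annotated
VCF is also read: the CSQ subfield order is always taken from the VCF header
`Format:` declaration, only entries with a `missense_variant` consequence and
`CANONICAL=YES` are kept, and malformed entries are skipped with a count.
Genomic coordinates are never interpreted beyond the CSQ protein fields.

Before structural features are attached, the model residue at the variant
position must match `ref_aa`; on mismatch the structural cells become `NA`
(with a message) rather than risking silently annotating the wrong position —
isoform numbering disagreements are common enough that this is the safe
default. A missing model file likewise nulls only the structural block.

Dataset filters (`filter_dataset()`): clinical mode keeps
Pathogenic/Likely pathogenic (case-insensitive); population mode keeps
AF > 0.05 with `FILTER = PASS`; score modes keep the top/bottom 5% quantile
by default. The predicate modes are idempotent. The quantile modes are
idempotent only with an explicit `cutoff` — a quantile recomputed on its own
output selects a strictly smaller set, so a data-derived threshold cannot be
a fixed point; the function therefore accepts a fixed cutoff for workflows
that need re-runnable filtering.

## Enrichment statistics

* **Fisher p** — two-sided by the "probability ≤ observed" rule over all
  tables with the observed margins. Because two-sided definitions vary, this
  is stated explicitly; floating-point ties are included with the
  conventional 1e-7 relative tolerance (the same convention base R uses), so
  exactly tied tables always count. Tables with a zero margin return `NA` —
  there is no information to test — and the caller marks the feature
  insufficient.
* **OR and CI** — OR = ad/bc; the Haldane–Anscombe +0.5 correction is
  applied to all four cells when any is zero, for the OR and Woolf interval
  only. The p-value always uses the raw table: the correction exists to keep
  effect sizes finite, not to alter evidence. `log10(OR)` is reported for
  landscape outputs and computed in a summed-log form so that swapping the
  two datasets negates it exactly.
* **Multiplicity** — Bonferroni, q = min(p·m, 1), with m equal to the number
  of *testable* features in the comparison at hand; features excluded for
  insufficiency do not count toward m. An optional category-grouped m is a
  caller decision (pass the subset of features to compare).
* **Calls** — pathogenic-associated at OR > 1 & q < 0.05;
  benign-associated at OR < 1 & q < 0.05; otherwise not significant. The
  symmetric benign rule is used deliberately: an "OR < 1 and q > 0.05" rule
  would label noise as benign association, contradicting the significance
  framing of the rest of the analysis.
* **Insufficiency** — any zero margin, or fewer than `min_count = 5`
  feature-present variants across both groups. Heat-map outputs keep
  `insufficient` distinct from `not_significant`: absence of data is not
  absence of effect.
* **Stratification** — by protein class (both matrices restricted to the
  class: a within-class comparison) or by disease category (only the
  pathogenic matrix restricted, the full benign matrix as population
  comparator). The asymmetry mirrors how disease-stratified analyses are
  designed: there is no disease label for population variants.
* **Meta-analysis** — per feature across ≥ 2 comparisons,
  z = (log₁₀OR − mean)/sd with the population sd. Per-feature (rather than
  pooled) standardisation is used because the question is how one feature's
  strength varies across dataset pairings, not how features rank within one
  pairing. sd = 0 yields z = 0 with a `degenerate` flag; a sign change of
  log₁₀OR across comparisons sets `inverted`.
* **Proportions** — per-feature presence with Wilson score intervals, the
  standard choice near 0/1 where the Wald interval fails.

## The synthetic-data generator

`generate_backbone()` extends a chain atom-by-atom from φ/ψ torsions with
standard bond geometry (N–CA 1.458, CA–C 1.525, C–N 1.329 Å, trans peptide
ω = 180°), places O in the peptide plane and an optional CB by fixed
tetrahedral construction. Realised IUPAC dihedrals equal the requested ones
and consecutive CA–CA distances are 3.80 Å by construction, both checked as
properties. Composite fixtures build the study conditions for the end-to-end
test: a 16-residue ideal helix buried inside rings of 28-residue parallel
helices (first ring of six at 8 Å, second ring of twelve at 16 Å, poly-Ala
with CB, pLDDT 90) whose interior residues are Core/Helix/Order with ≥ 8
contacts, and a 30-residue fully extended poly-Gly coil (pLDDT 30) that is
Exposed/Loop/Disorder throughout. The antiparallel sheet fixture refines the
second strand's rigid placement numerically until the targeted O···N pairs
reach 2.9 Å hydrogen-bond register, and records which residue pairs were
planted.

`simulate_cohort()` draws every matrix cell as an independent Bernoulli with
the group's per-feature prevalence, so the true odds ratio is
[p₁/(1−p₁)]/[p₀/(1−p₀)] by construction and estimator calibration can be
measured against it. One integer seed drives all draws; the RNG state is
restored afterwards.

What the fixtures deliberately do **not** emulate: side-chain rotamers (only
CB), real packing densities, sequence-dependent pLDDT correlation along the
chain, correlated features (each cell is independent, unlike e.g. order and
burial in real proteins), and annotation noise. Passing tests therefore
demonstrate that the geometry, the statistics and the plumbing are correct
under known ground truth — not that the default thresholds are optimal for
any particular organism's proteome.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use desk-scale sizes chosen to make
every check exact or tightly bounded: all 2×2 tables with total ≤ 40
(132,470 tables) against a full enumeration oracle at 1e-9; SASA against the
isolated-sphere closed form at 1% and rigid motions at 1e-6 relative;
planted-OR recovery with 10,000 variants per group over 200 replicates;
end-to-end cohorts of 40 variants per group on a 520-residue bundle model.
Bernoulli prevalences 0.6/0.3 (OR 3.5) follow the calibration design the
recovery check is defined over.

## Known limitations

* Monomeric models only: interface residues of obligate complexes are
  scored as exposed; polyproline-II regions with low pLDDT are called
  disordered.
* PDB input only (no mmCIF); single chain per file.
* Three-state secondary structure; no 3₁₀/π/PPII subtypes.
* The Contacts binarisation (≥ 8) and the energy/clash cutoffs are package
  defaults, not universal constants; they are all exposed as parameters.
* The package quantifies feature enrichment between datasets; it does not
  score or classify individual variants.
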