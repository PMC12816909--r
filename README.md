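# varscape

Structural feature landscapes of missense variants.

## What problem this package addresses

A missense variant substitutes one amino acid for another, and whether that
substitution causes disease depends strongly on *where* it lands in the folded
protein: a buried, contact-dense core position in an ordered domain tolerates
far less change than a solvent-exposed residue in a flexible linker. Most
computational predictors compress this into a single pathogenicity score.
`varscape` instead annotates each variant with a panel of interpretable binary
features computed from AlphaFold-style monomeric models and auxiliary
annotations, and then compares the *feature landscapes* of two variant
datasets (e.g. clinically pathogenic versus high-frequency population
variants) with odds-ratio enrichment statistics. It is aimed at structural
bioinformaticians and statistical geneticists who want mechanism-level
hypotheses — "this dataset's variants are enriched at buried, ordered
positions" — rather than per-variant classifications.

## The method

For a variant at position *i* of a protein model the package computes, among
others:

* **OrderpLDDT / DisorderpLDDT** — the mean AlphaFold pLDDT over a ±2-residue
  window around *i*; mean ≥ 50 is called ordered, otherwise disordered.
* **Burial class** — Shrake–Rupley solvent-accessible surface area, normalised
  by the residue's theoretical maximum (Tien et al. 2013) into relative
  accessibility RSA, then binned: Core (RSA < 5%), MediumBuried (5–50%),
  MediumExposed (50–75%), Exposed (> 75%).
* **Contacts** — the number of residues *j* with |*i* − *j*| > 2 having any
  heavy atom within 5 Å of residue *i*; the binary feature fires at ≥ 8.
* **Helix / Strand / Loop** — Kabsch–Sander hydrogen-bond patterns (backbone
  dipole–dipole energy < −0.5 kcal/mol; two consecutive i→i+4 turns make a
  helix, bridge patterns make strands).
* **Substitution chemistry** — small→big, polar→nonpolar, charged/polar/
  hydrophilic/hydrophobic introduced, from a per-residue property table.
* **Thresholded annotations** — Conserved, TotalEnergy (ΔΔG ≥ 1 kcal/mol),
  LessTotalEnergy (ΔΔG ≤ −1), VanDerWaalsClashes, with NA propagation when a
  source is unavailable.

Feature presence in a "pathogenic" versus a "benign" matrix is summarised per
feature in a 2×2 table (a, b; c, d) with NA cells excluded. The effect size is
the odds ratio OR = ad/bc (Haldane–Anscombe +0.5 on all cells when any cell is
zero) with the Woolf interval exp(ln OR ± z₀.₉₇₅·√(1/a+1/b+1/c+1/d));
significance is a two-tailed Fisher exact test, Bonferroni-corrected as
q = min(p·m, 1) over the m testable features. A feature is pathogenic-
associated when OR > 1 and q < 0.05, benign-associated when OR < 1 and
q < 0.05, and marked *insufficient* (not merely non-significant) when a margin
is zero or fewer than 5 variants carry it. Landscapes from several dataset
pairings can be standardised per feature as z = (log₁₀OR − mean)/sd for a
meta-analysis that flags features whose association direction inverts between
datasets.

Synthetic ground truth is built in: a deterministic backbone builder
(φ/ψ torsions → N, CA, C, O, CB atoms), a PDB writer that plants pLDDT values
in the B-factor column, composite fixtures (a buried helix bundle, an exposed
coil, an antiparallel sheet), and a cohort simulator with planted per-feature
prevalences whose implied true OR is [p₁/(1−p₁)]/[p₀/(1−p₀)].

## Worked example

Variants planted in the buried, high-pLDDT central helix of a synthetic helix
bundle versus variants on a low-pLDDT exposed coil:

```r
library(varscape)
demo <- demo_structural_cohort(seed = 42)
fm_path <- build_feature_matrix(demo$pathogenic, structures = demo$structures)
fm_ben  <- build_feature_matrix(demo$benign,  structures = demo$structures)
res <- compare_feature_sets(fm_path, fm_ben)
subset(res, call != "insufficient",
       select = c(feature, a, c, or, q, log10_or, call))
```

```
                 feature  a  c       or        q log10_or                  call
1             OrderpLDDT 40  0 6.56e+03 2.42e-22    3.817 pathogenic_associated
2          DisorderpLDDT  0 40 1.52e-04 2.42e-22   -3.817     benign_associated
3                   Core 40  0 6.56e+03 2.42e-22    3.817 pathogenic_associated
6                Exposed  0 40 1.52e-04 2.42e-22   -3.817     benign_associated
7                  Helix 40  0 6.56e+03 2.42e-22    3.817 pathogenic_associated
9                   Loop  0 40 1.52e-04 2.42e-22   -3.817     benign_associated
10              Contacts 40  0 6.56e+03 2.42e-22    3.817 pathogenic_associated
16            SmallToBig 40  0 6.56e+03 2.42e-22    3.817 pathogenic_associated
19       NonpolarToPolar 33 40 5.51e-02 1.53e-01   -1.259       not_significant
20 HydrophilicIntroduced 33 31 1.37e+00 1.00e+00    0.136       not_significant
21 HydrophobicIntroduced  0  9 4.09e-02 3.07e-02   -1.388     benign_associated
22     ChargedIntroduced 33 16 7.07e+00 2.44e-03    0.850 pathogenic_associated
23       PolarIntroduced 33 40 5.51e-02 1.53e-01   -1.259       not_significant
```

All 40 helix-core variants are ordered, buried, helical and contact-dense
(a = 40, c = 0; the corrected OR of 6.56×10³ reflects the +0.5 zero-cell
rule), the coil variants are the mirror image, and features the fixture does
not separate (e.g. HydrophilicIntroduced) stay non-significant. Features
carried by neither group (catalytic sites, energy terms) are reported as
insufficient rather than tested.

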