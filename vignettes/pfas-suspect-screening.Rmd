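---
title: "PFAS suspect screening from direct-infusion UHR-MS peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PFAS suspect screening from direct-infusion UHR-MS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfscreen)
```

## The screening problem

Per- and polyfluoroalkyl substances (PFAS) occur in biota at concentrations
far below those of the biogenic matrix. Direct-infusion ultra-high-resolution
mass spectrometry (FT-ICR class instruments) measures thousands of centroid
m/z values per sample without chromatographic separation; suspect screening
then reduces those signals to a ranked shortlist of plausible PFAS by
accurate mass alone, validated by isotopologue intensities. `pfscreen`
implements that reduction as a scriptable pipeline:

1. **Suspect-list curation** — molecular formulas from a CSV are parsed,
   monoisotopic masses recomputed (input masses are never trusted), salts
   collapsed onto their free-acid anion, single-substitution isotopologues
   and elemental descriptors attached.
2. **Peak-list pre-processing** — per-window centroid lists (m/z, intensity,
   S/N) are thresholded at S/N ≥ 4, trimmed to their CASI window ± 5 Da, and
   merged with provenance; optional blank filtering removes peaks also
   present in a blank measurement.
3. **Suspect matching** — each suspect's deprotonated mass is paired with
   its 10 nearest measured m/z values and pairs within 1.5 ppm become
   candidate annotations.
4. **Isotopologue validation** — a weighted Euclidean similarity score on a
   0–100 scale.
5. **Filtering and ranking** — duplicate removal, score threshold 75,
   pKa/ionizability exclusion, in-source-fragment exclusion, composite
   normalized rank.

## Mass arithmetic

Monoisotopic masses are sums of principal-isotope exact masses from an
embedded CODATA/IUPAC table (`isotope_table()`), exportable and overridable
as CSV. Deprotonation subtracts the proton constant 1.007277 Da:

```{r masses}
monoisotopic_mass("C8HF17O3S")            # PFOS free acid
charged_mass(monoisotopic_mass("C8HF17O3S"))  # [M-H]- anion
```

Two near-isobars illustrate why sub-ppm accuracy matters — their neutral
masses differ by 0.03 ppm, and both are retained as distinct annotations of
the same measured signal:

```{r isobars}
ppm_error(monoisotopic_mass("C6H2F12O3"), monoisotopic_mass("C11H6Cl2F6N2"))
```

**Salts.** A salt such as `C8F17O3S.K` is stripped of its counter-cation
(registry: Na⁺, K⁺, Li⁺, Cs⁺, Ag⁺, NH₄⁺) and the neutral parent is
reconstructed as the anion plus one hydrogen before the standard
deprotonation is applied. This makes the salt's charged mass *bit-identical*
to the free acid's, which is what the downstream duplicate removal keys on.
Computing the bare anion mass plus the electron mass instead would differ by
~6.5 × 10⁻⁶ Da from the free-acid route and break that identity. Multivalent
salts are deliberately unsupported: rather than fabricate a charge state,
the record is kept as a neutral parent with a warning.

**Isotopologues** are single substitutions only — one ¹³C, ³⁴S, ¹⁸O, ³⁷Cl,
⁸¹Br or ²⁹Si per formula, the most abundant heavy isotope of each element
present. Combined or double substitutions (¹³C₂, ³⁷Cl₂, ¹³C¹⁸O) are orders
of magnitude less abundant and would rarely clear the detection floor, so
including them would mostly add unmatchable expectations that depress
scores. Isotopologue *shifts* are stored rather than absolute masses, and
applied to the measured monoisotopic m/z at scoring time; this makes the
stored pattern independent of the ionization mode.

**Descriptors.** DBE uses tetravalent Si, trivalent N/P and monovalent
halogens: `DBE = 1 + C + Si − (H+F+Cl+Br+I)/2 + (N+P)/2`. The mass defect is
the signed distance to the nearest integer (`m − round(m)`), so highly
fluorinated anions come out negative. The Kendrick scale defaults to CF₂
(the PFAS homolog unit; the base is configurable), under which homologs
differing by whole CF₂ units share a Kendrick mass defect.

## The similarity score

For each candidate, every isotopologue is predicted at
`measured m/z + shift` with intensity
`measured monoisotopic intensity × relative abundance`. An isotopologue is
*expected* when its predicted intensity reaches the detection floor — the
minimum intensity retained in the candidate's CASI window (detectability
varies per window, so the floor is per-window, not global). For each
expected isotopologue the nearest peak within 1.5 ppm yields the mass
deviation in ppm and the intensity deviation as a relative percentage
(denominator: predicted intensity); expressing both axes in relative units
avoids mixing Da with counts. Then

- distance: `d = sqrt(delta_ppm² + delta_rel_pct²)`
- similarity: `1 / (1 + d)` in (0, 1]
- weights: predicted intensities normalised to sum 1 over the expected
  observations (renormalised *after* dropping sub-floor isotopologues, so
  scored weight always totals 1)
- score: `sum(similarity × weight) × 100`.

An expected isotopologue with no peak in tolerance scores similarity 0 at
full weight — any deviation from the simulated pattern reduces the score.
Candidates with at least one expected isotopologue are **L-4** (scored);
candidates whose predictions all fall below the floor are **L-5** (annotated
by accurate mass only). L-5 candidates pass the score threshold, which by
construction removes only scored candidates.

The scale is deliberately sharp: a single observation with a 3 ppm / 4 %
deviation (d = 5) scores 100/6 ≈ 16.7. A score of 75 therefore implies a
near-exact pattern (total d ≤ 1/3).

## Filtering order and ranking

The funnel order is fixed: deduplication → score threshold →
pKa/ionizability → fragment exclusion → ranking. Deduplication groups
candidates by identical charged mass (window-overlap twins and
salt/free-acid twins) and keeps the highest-S/N member. The pKa stage keeps
only `acidic` candidates (an acidic pKa is present), partitioning exclusions
into `non_ionizable` (no pKa at all, e.g. perfluorohexane) and
`electropositive` (basic pKa only — ionizable in positive mode, invisible
here). The fragment stage removes candidates with `(O+S+P+N)/C = 0`, which
contain no heteroatoms besides fluorine and most plausibly are in-source
fragments of larger PFAS.

Ranking averages three normalized variables, each mapped so 0 is best:
absolute ppm error (min–max over the candidate set), QC level (1→0 … 5→1),
and acidic pKa (min–max; the most acidic candidate maps to 0). Degenerate
min = max normalizations map to 0 rather than NaN; a missing pKa among
ranked candidates (impossible after the pKa stage, but defended against)
normalizes to 1 with a warning. The absolute, not signed, ppm error is
normalized — the variable measures accuracy, not direction. Ties break on
charged mass ascending, keeping the sort stable and reruns identical.

Every filter returns a partition (`kept` plus removed rows), and the funnel
report refuses to build when any stage fails `n_in − n_removed = n_out` or
stages do not chain — bookkeeping errors surface as hard failures, not as
quietly wrong counts.

## What the synthetic generator emulates

`synthetic_suspects()` builds a 29-entry list spanning every pipeline
branch: 10 PFCA and 10 PFSA homologs as acidic spikes (QC levels cycling
1–5; pKa ≈ 0.3–0.1 for the carboxylic acids, −3.3 for the sulfonic acids),
the PFOS potassium salt as a salt/free-acid duplicate, three perfluoroalkanes
(no pKa → non-ionizable), two basic fluoroamines (electropositive), and
three heteroatom-free hydrofluorocarbons as fragment surrogates. The
fragment surrogates carry a synthetic acidic pKa so they survive the pKa
stage and are removed by the *fragment* filter — with no pKa they would be
dropped a stage earlier and the fragment rule would never be exercised.

`simulate_dataset()` spikes each non-salt suspect as its [M−H]⁻ peak plus
all isotopologues at exact theoretical relative intensity, assigns peaks to
every CASI window whose ±5 Da extended bounds contain them (reproducing the
duplicate retention of spectral stitching), and adds 200 decoy matrix peaks
rejection-sampled to lie ≥ 5 ppm from every suspect charged mass *and*
isotopologue position, plus 5 blank-overlap peaks present at equal intensity
in sample and blank. The defaults are the clean-pattern condition (ppm
jitter 0, intensity noise 0) under which every detectable spike scores
exactly 100 and the final list is exactly the 20 acidic spikes. Noise, when
enabled, is Gaussian in ppm for mass and lognormal-multiplicative for
intensity — a generic stand-in, not a physical FT-ICR model: it has no
space-charge effects, no intensity-dependent mass error, no correlated
window-level drift, and decoys are uniform rather than matrix-structured.
Passing tests on this generator demonstrate the pipeline's bookkeeping,
arithmetic and selectivity under controlled conditions; they do not
demonstrate recovery rates on real biota spectra.

## Numerical choices and degenerate inputs

- Nearest-peak ties inside the lookup tolerance resolve by smallest |ppm|,
  then higher intensity.
- Nearest-neighbour matching keeps *all* peaks tied at the k-th distance, so
  results are independent of input order; k = 10 is retained for fidelity
  although the 1.5 ppm tolerance alone determines acceptance in practice.
- Formulas without carbon return `NA` elemental ratios (flagged, not an
  error); `NA` ratios are never treated as fragments.
- Unparseable suspect rows go to a rejects report with the offending token;
  they are never silently dropped, and `accepted + rejected = input` is
  tested.
- Empty peak lists, empty blank lists and empty candidate sets propagate as
  empty results (or hard errors where a result would be meaningless, e.g. a
  peak-list CSV with no valid rows).

## Problem sizes

The bundled tests and the reproduction script run the complete pipeline on
the synthetic conditions above (29 suspects, ~270 true peaks, 200 decoys, 11
CASI windows) and verify matcher equivalence against a brute-force all-pairs
oracle at 1000 suspects × 1000 peaks, scoring closed forms on 1000 randomized
perturbations, and parameter recovery over ≥ 100 replicate spikes. These
sizes exercise every code path in seconds while keeping the arithmetic
independently checkable.

## Known limitations

- Negative-mode, singly charged screening only; `ion_form()` reserves the
  interface for adducts and positive mode but none are registered.
- No fine-structure isotope simulation and no deconvolution of overlapping
  isotope clusters from co-isolated species.
- Identifier completion (InChIKey/SMILES generation) is out of scope; SMILES
  is used only to detect dot-component salts.
- The external formula lookup (`offline_formula_hook()`) is a stub
  interface; the core contains no network code.
- pKa values are consumed from the input list, never predicted.
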