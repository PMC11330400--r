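# pfscreen

Suspect screening of per- and polyfluoroalkyl substances (PFAS) in
direct-infusion ultra-high-resolution mass spectra.

Environmental and biota samples contain PFAS at trace levels buried under
biogenic matrix signals. Direct-infusion FT-ICR-class measurements produce
tens of thousands of accurate centroid m/z values per sample; `pfscreen`
reduces them to a short, ranked list of plausible PFAS candidates without
chromatography or analytical standards. It is aimed at analytical and
environmental chemists running non-target/suspect workflows who want the
screening logic as auditable, scriptable functions rather than a GUI.

## What it computes

Given a suspect list of molecular formulas and per-window (CASI) peak
lists, the pipeline:

1. **Curates the suspect list**: recomputes monoisotopic masses from the
   formulas, strips counter-cations from salts so a salt and its free acid
   share one deprotonated mass (m\[M−H\]⁻ = M − 1.007277), and attaches
   single-substitution isotopologues (¹³C, ³⁴S, ¹⁸O, ³⁷Cl, ⁸¹Br, ²⁹Si) with
   relative abundance `count × ab_heavy / ab_light`, plus elemental
   descriptors (F/C, H/C, (O+S+P+N)/C, DBE, mass defect, Kendrick masses on
   the CF₂ scale).
2. **Pre-processes spectra**: S/N ≥ 4 threshold, CASI window trimming with
   ± 5 Da overlap, window merging with provenance, optional blank filtering
   (flag peaks within 1.5 ppm of a blank peak when sample/blank < 10).
3. **Matches suspects** to their 10 nearest measured m/z values, accepting
   pairs with |ppm error| ≤ 1.5.
4. **Validates by isotopologues** with a weighted Euclidean similarity
   score: per expected isotopologue, `d = √(Δppm² + Δrel%²)`,
   `similarity = 1/(1+d)`, weights ∝ predicted intensity (normalised to
   sum 1), `score = Σ similarity·weight × 100`. Candidates with scored
   isotopologues are L-4; accurate-mass-only annotations are L-5.
5. **Filters and ranks**: duplicate removal by identical charged mass
   (highest S/N wins), score ≥ 75, pKa/ionizability exclusion, removal of
   heteroatom-free likely in-source fragments ((O+S+P+N)/C = 0), and a
   composite rank averaging min–max-normalized |ppm error|, QC level and
   acidic pKa.

A ground-truthed synthetic-data generator (`synthetic_suspects()`,
`simulate_dataset()`) emulates spiked suspects with theoretical isotope
patterns, ppm jitter, intensity noise, decoy matrix peaks and blank
overlap, so the entire pipeline is testable offline.

## Worked example

```r
library(pfscreen)

monoisotopic_mass("C8HF17O3S")                  # 499.93749  (PFOS, neutral)
charged_mass(monoisotopic_mass("C8HF17O3S"))    # 498.93022  ([M-H]- anion)
isotopologues("C8HF17O3S")
#>   label element mass_shift relative_abundance
#> 1 13C   C             1.00            0.0865
#> 2 34S   S             2.00            0.0447
#> 3 18O   O             2.00            0.00616

sl  <- synthetic_suspects()                       # 29 suspects, all branches
sim <- simulate_dataset(simulation_config(seed = 1), sl)
res <- pfas_screen(sl, sim$spectra, blank = sim$blank)
res$funnel
#>   stage               n_in n_removed n_out reason
#> 1 matched               36         0    36 candidate annotations
#> 2 dedup                 36         8    28 duplicate charged mass
#> 3 similarity            28         0    28 score < 75
#> 4 pka_non_ionizable     28         3    25 no ionizable site
#> 5 pka_electropositive   25         2    23 positive-mode only
#> 6 fragment              23         3    20 (O+S+P+N)/C = 0
head(res$candidates[c("rank", "suspect_id", "ppm_error", "score", "level")], 3)
#>   rank suspect_id ppm_error score level
#> 1    1 PFSA-C4            0   100 L4
#> 2    2 PFSA-C9            0   100 L4
#> 3    3 PFSA-C5            0   100 L4
```

The funnel reads: 36 raw annotations (window-overlap and salt twins
included) collapse to 28 unique charged masses; none fall below the score
threshold (clean patterns); 3 non-ionizable perfluoroalkanes and 2
positive-mode-only amines are excluded by pKa class; 3 heteroatom-free
fragment surrogates are removed; the 20 spiked acids remain, ranked by
composite score (most acidic, most accurate, best-curated first).

## Command line

```sh
Rscript inst/cli/pfscreen.R simulate --seed 1 --out data/
Rscript inst/cli/pfscreen.R build-suspect-list --input data/suspects_raw.csv --out curated.csv
Rscript inst/cli/pfscreen.R screen --suspects data/suspects_raw.csv \
    --peaks data/ --blank data/blank.csv --out results/
Rscript inst/cli/pfscreen.R export-plots --candidates results/candidates.csv --out results/
```

Exit codes: 0 success, 2 schema/config error, 3 data error, 4 internal
invariant breach.

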