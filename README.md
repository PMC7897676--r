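# npsid

Computational identification of new psychoactive substances (NPS) and
their metabolites from high-resolution accurate-mass MS and
solid-deposition GC-FTIR data.

Forensic and clinical laboratories frequently face seized powders and
biofluids containing NPS for which no reference standard is at hand, and
positional isomers (2-/3-/4-methylmethcathinone; 2-/3-/4-methoxy-PCP)
that are nearly indistinguishable by chromatography and mass
spectrometry alone. `npsid` implements the complementary workflow used in
such casework:

1. **Elemental formula assignment from accurate mass.** For an observed
   protonated molecule MH⁺ at m/z *m*, all CHNO compositions with
   |Δm| ≤ tol are enumerated, where
   Δm = (accurate − exact)/exact × 10⁶ (ppm) and the exact m/z of a
   cation is Σᵢ nᵢ·Mᵢ − z·mₑ (lightest-isotope masses Mᵢ, electron mass
   mₑ), filtered by ring-and-double-bond equivalents
   RDBE = C − H/2 + N/2 + 1.
2. **Isotope-pattern simulation.** MH⁺ isotopologue patterns (M+0…M+3)
   by exact multinomial convolution; the relative isotopic abundance
   RIA = I(M+1)/I(M+0) and its error
   (RIAₑₓₚ − RIA𝒸ₐₗ𝒸)/RIA𝒸ₐₗ𝒸 × 100 support or reject an assignment.
3. **Metabolite annotation.** Candidate phase I/II metabolite formulas
   are generated from the parent by transformation rules
   (O-demethylation −CH₂, hydroxylation +O, dehydrogenation −H₂, oxo
   +O−H₂, carboxylation +O₂, terminal glucuronidation +C₆H₈O₆) and
   scored against a centroided peak table by five criteria: earlier
   retention than the parent, MH⁺ mass accuracy, isotopic-pattern
   agreement, product-ion matches, and literature concordance. The most
   abundant identified analytes form a targeted screening panel.
4. **IR library search.** Spectra on a common 650–4000 cm⁻¹ / 4 cm⁻¹
   grid are compared by a quality match factor
   QMF = 100·max(r, 0), with r the Pearson correlation of
   Savitzky–Golay first derivatives (9-point window, order 2) — the
   derivative weighting makes the sharp fingerprint-region bands
   decisive, which is what discriminates positional isomers. Repeated
   solid depositions co-add analyte signal linearly against a fixed
   readout noise, so the QMF climbs with depositions; the limit of
   identification (LOI) is the smallest deposition count whose median
   QMF reaches the search threshold.

Because raw casework data are withheld for legal reasons, the package
ships seeded generators (`simulate_peak_table()`,
`simulate_ir_library()`) that plant ground truth for every stage.

## Worked example

```r
library(npsid)

# powder with an MH+ ion observed at m/z 178.1226
search_compositions(178.1226, composition_space())
#>  rank  formula    mh_mz     dm_ppm rdbe ria_error_pct
#>     1 C11H15NO 178.1226 -0.2276926    5            NA

isotope_pattern(mh_ion("C18H27NO"))
#>  label       mz   abundance
#>    M+0 274.2165 1.000000000
#>    M+1 275.2199 0.201937703
#>    M+2 276.2233 0.021384661
#>    M+3 277.2266 0.001580266
```

The single composition within ±3 ppm of 178.1226 is C₁₁H₁₅NO
(methylmethcathinone; Δm = −0.23 ppm, RDBE 5). The pattern shows the
theoretical MH⁺ isotopologue ladder of 3-MeO-PCP: m/z 274.2165 with an
M+1 at 275.2199 carrying 20.2% of the M+0 abundance (the calculated RIA
against which an experimental RIA is judged).

The full workflow — powder identification, urine metabolite screening
with a 7-analyte panel, IR isomer discrimination, and the
deposition-ladder LOI — is run by the numbered scripts in `analysis/`,
which write their tables under `results/`:

```sh
Rscript analysis/01_powder_identification.R
Rscript analysis/02_metabolite_screening.R
Rscript analysis/03_ir_isomer_discrimination.R
Rscript analysis/04_limit_of_identification.R
```

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the
theoretical m/z values of the two protonated molecules that anchor the
workflow (ion compositions C18H28NO⁺ and C11H16NO⁺, electron-corrected,
rounded to 4 decimals) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — formulas, isotopes, composition search, transformation rules,
  annotation, IR matching, simulators, I/O
- `inst/extdata/` — atomic-mass constants; published reference data for
  3-MeO-PCP and its metabolites
- `analysis/` — the four narrative workflow drivers
- `vignettes/nps-identification.Rmd` — methods and design notes
- `tests/testthat/` — unit, property and acceptance tests with
  independent oracles
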