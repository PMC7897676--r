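---
title: "Identifying NPS by accurate mass and IR library search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying NPS by accurate mass and IR library search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npsid)
```

`npsid` implements the two complementary identification routes used when
a new psychoactive substance (NPS) must be characterised without a
reference standard: high-resolution accurate-mass MS (elemental formula
assignment, isotope patterns, metabolite annotation) and solid-deposition
GC-FTIR library search (positional-isomer discrimination). This vignette
explains the models, the tunable parameters, the synthetic-data world the
tests run in, and the design decisions taken where the underlying methods
are not fully published.

## Exact mass and the electron correction

All mass computation reduces to an element→count map and a bundled
isotopic constants table (`inst/extdata/atomic_masses.tsv`,
IUPAC/CODATA-derived), so results never depend on an external library's
tables. The exact (monoisotopic) m/z of an ion is

$$ m/z = \frac{\sum_i n_i M_i - z\, m_e}{|z|} $$

with $M_i$ the lightest-isotope masses and $m_e$ the electron mass.
Whether published "exact mass" values include the electron term is rarely
stated; here the correction is **on** by default because it is what
reproduces the reference MH⁺ values to four decimals — C18H28NO⁺ gives
274.2165 with the correction and 274.2171 without, and only the former
matches the published value for the 3-MeO-PCP protonated molecule. The
flag is per-ion (`ion_species(..., electron_correction =)`) for users who
need the other convention. Display rounding is R's round-half-even at 4
decimals (m/z) and 2 decimals (ppm, RIA error); internal computation is
always full precision.

The parser restricts element symbols to an allowed set (default C, H, N,
O — sufficient for the methoxy-PCP/methcathinone chemistry) to catch
typos such as a digit zero for an O; the set is an argument, and the
constants table additionally carries P, S, Cl, Br for generic use.

## Isotope patterns: binning and the reported m/z

Patterns are computed by exact multinomial convolution over elements:
for each element, all isotope-substitution vectors with nominal shift
≤ 3 are enumerated with their multinomial weights; cross-element
combinations are pruned at shift 3 (patterns are truncated at M+3, the
deepest isotopologue worth measuring for CHNO ions at these abundances).
Two conventions matter:

* **Abundances** are summed per unit nominal-mass bin and normalised to
  M+0 ≡ 1. The implementation is checked against two independent
  oracles: exhaustive per-atom enumeration (small ions, agreement 1e-9)
  and sequential atom-by-atom convolution (real ions, 1e-6).
* **The m/z reported for M+k is that of the bin's most abundant
  isotopologue**, not an abundance-weighted centroid. For CHNO ions the
  M+1 and M+2 bins are always dominated by pure ¹³C substitution
  (M+k = M+0 + k·1.00336), but for oxygen-rich ions the M+3 bin flips to
  the ¹³C+¹⁸O isotopologue (+3.00761): e.g. for C17H26NO3⁺ the most
  abundant M+3 species is ¹³C¹⁸O, and the reported ladder ends at
  295.1983 rather than 295.2008. This convention reproduces every
  published M+1/M+2/M+3 value in the bundled reference table and is what
  a centroiding algorithm reports for the most intense peak of each
  cluster.

The relative isotopic abundance RIA = I(M+1)/I(M+0) and its error
(experimental − calculated)/calculated × 100 are the scalar pattern
summaries. Pattern comparison uses per-label ppm tolerances of
5/5/5/7.5 ppm (M+0..M+3) — enveloping the sub-4.2 ppm label accuracies
observed on externally calibrated Orbitrap data, with the loosest bound
on the weakest peak — and a ±20% relative RIA tolerance. Labels missing
from an experimental envelope (truncated for low-abundance species) are
recorded as *absent*, never as failures; a pattern with no M+1 at all,
however, cannot support identification (criterion 3 below requires it).

## Composition search

`search_compositions()` enumerates the full per-element count lattice,
computes every neutral candidate's MH⁺ m/z in one vectorised pass, and
keeps candidates with |Δm| ≤ tol and RDBE = C − H/2 + N/2 + 1 within
bounds (default 0–25, integer and half-integer alike; the two case
drugs have RDBE 5 and 6). Ranking is by |Δm|, with ties broken by RIA
fit (when an experimental pattern is supplied) and then formula text, so
hit ranks are reproducible. Default bounds (C ≤ 20/25, H ≤ 40/50,
N ≤ 2, O ≤ 4, ±3 ppm) are engineering choices — the original software's
settings are unpublished — and the implementation is tested to agree
exactly with a brute-force nested-loop oracle on every lattice tried.

## Metabolite annotation: rules, depth, five criteria

The default rule set is the transformation vocabulary established for
PCP-type drugs: O-demethylation (−CH₂, once), hydroxylation (+O, up to
three sites), dehydrogenation (−H₂), oxidation to an oxo group (+O−H₂),
carboxylation after ring opening (+O₂), methyl-ester formation (+CH₂,
flagged as an analytical artifact) and glucuronidation (+C₆H₈O₆,
phase II). Rules without a chemically forced maximum default to two
applications; two oxo steps are genuinely needed (the
demethyl-dehydro-oxo metabolite is −CH₂ +2(O−H₂) from the parent).

**Depth counts phase I applications only.** Phase II conjugation is
applied at most once and only terminally — glucuronides of oxidised
aglycones exist, but oxidation *of* a glucuronide is implausible — and
it does not consume depth: each conjugate corresponds one-to-one with
its aglycone, so a depth-3 enumeration covers the glucuronide of every
depth-3 aglycone. This is the reading under which the full published
metabolite composition set (including the triply transformed
aglycone-glucuronides) is reachable at depth 3; counting the conjugation
against depth would arbitrarily exclude exactly those conjugates whose
aglycones the same run generates.

Annotation scores each candidate against five criteria: (1) retention
time below the parent's minus a guard band (default 0.1 min — the
direction is established, the margin is ours); (2) an MH⁺ match within
±5 ppm (enveloping the ≤1.37 ppm published accuracies with margin for
jitter); (3) isotopic-pattern agreement as above, requiring at least an
M+1; (4) at least one observed product ion within 10 ppm of the
reference fragment list for that composition (fragment *prediction* is
out of scope; the lists are configuration); (5) membership of the
composition in a literature list (default: the bundled reference table).
A candidate is **identified** iff 2 and 3 pass together with at least
one of 1, 4, 5. Multiple peaks within tolerance at one retention time
are resolved deterministically (smallest |Δm|, then larger intensity)
with an ambiguity flag; peaks at distinct retention times are isomeric
features sharing one composition, each scored separately with the most
abundant flagged primary.

Panel selection pins the parent and fills the remaining k−1 slots with
identified, non-artifact features by descending intensity (ties:
formula text, then retention time). Artifact-rule candidates (methyl
esters) are excluded by default. The report generator emits
reference-style rows — per-isotopologue exact/accurate/Δm triplets and
product ions — with Δm recomputed from the *stored rounded* masses so
the published table is internally consistent, and absent measurements
rendered "-".

## The synthetic MS world

`simulate_peak_table()` plants the bundled reference analytes as
M+0..M+3 peaks with: Gaussian mass jitter of σ = 0.5 ppm (published
|Δm| ≤ 1.37 ppm implies sub-ppm scatter) plus an optional bias; 2%
relative envelope noise; log-normal abundances (meanlog = log(10⁶),
sdlog = 1.5 — the 2–3 decades of dynamic range typical of urinary
metabolite profiles) unless explicit abundances are given; metabolite
retention times uniform in (0.4, 0.98)·parent tR, strictly below the
parent (metabolites are more polar and elute earlier); and 50 decoy
peaks. Planted features sharing one composition are kept ≥ 0.15 min
apart — two co-eluting "features" would not be distinct ground truth,
and the zero-noise recovery guarantee (exactly 100%, non-increasing in
jitter) is stated over distinct features. The
`urine_screening_abundances()` profile encodes the published urinary
ordering: parent plus M1a, M1b, M1g, M1h, M2a, M2c dominant, elevated
metabolite-to-parent ratios for M1g/M1h/M2a, all others minor. What the
generator does **not** emulate: chromatographic peak shapes, profile
(non-centroided) spectra, fragment-ion formation, ion suppression. A
green recovery test therefore establishes the bookkeeping and tolerance
logic, not instrument behaviour.

## IR matching: QMF, co-addition, LOI

The vendor's "first derivative correlation" algorithm is unpublished, so
the score is defined here as QMF = 100·max(r, 0) with r the Pearson
correlation of Savitzky–Golay first derivatives (window 9 points ≙
32 cm⁻¹ at the 4 cm⁻¹ grid, polynomial order 2; both configurable; the
filter is implemented directly, ~15 lines of least squares, since no
installed package provides it). Choices and their consequences:

* r (not r²) preserves sign information; anti-correlated input clamps
  to 0 rather than scoring 100.
* The score is symmetric and invariant to positive affine rescaling —
  differentiation removes offsets, correlation removes gain — so
  absolute absorbance scale never matters.
* Edge samples lost to the filter window are dropped from both vectors
  symmetrically; zero-variance derivatives yield QMF 0 with a
  degenerate flag.

Spectra are linearly interpolated onto the 650–4000 cm⁻¹ / 4 cm⁻¹
acquisition grid and min-max normalised; a spectrum must overlap ≥ 90%
of the grid. Library ranking is by descending QMF with alphabetical
tie-breaks. Absolute QMF values from real instruments are **not**
reproducible from first principles (the vendor algorithm, spectral
weighting and library contents are unknown); the package's claims are
therefore order and gap properties on its own synthetic benchmark.

The synthetic IR world builds compounds as sums of Gaussian bands. An
isomer family shares 80% of its bands; the distinguishing 20% sit below
1500 cm⁻¹ and are sharper (6–14 vs 15–45 cm⁻¹) and stronger (0.6–1.0 vs
0.2–0.8) than the shared skeleton bands — the defining observation of
solid-phase spectra is precisely that fingerprint-region bands are
sharp, intense and structure-specific. Because differentiation weights
band amplitude/width, those unique bands carry a large share of
derivative energy, and wrong-isomer QMFs fall well below the correct
match (the fixed-seed benchmark requires a gap > 30 points at
SNR ≥ 50). With the shared fraction forced to 1.0 the gap collapses to
zero — the degenerate control.

**Co-addition** is a pointwise sum (deposition accumulates analyte on
the disc; averaging would model repeated *scans*, not repeated
*deposits*). The LOI simulation models a trace analyte: per-deposition
signal amplitude 0.018 (in units of the normalised reference), signal
growing as n, per-deposition noise growing as √n (sd 5·10⁻⁴), one
readout noise per co-added measurement (sd 0.02, the dominant term) and
random slow baseline drift (amplitude 0.005, mostly removed by
differentiation). Median QMF over 30 seeded replicates is tracked on a
14-step deposition ladder; the LOI is the first step at or above the
threshold (default 80). The amplitude was fixed analytically from the
correlation–SNR relation median QMF ≈ 100/√(1+q²), with q the
derivative noise-to-signal ratio ∝ 1/n: 0.018 puts a single deposition
just below QMF 20 (not library-searchable) and the 80 crossing within
nine depositions. Under *any* linear-accumulation/additive-noise model
those two constraints force the >90 regime beyond the ninth deposition;
published trajectories that rise faster presumably reflect detector
nonlinearities at the noise floor that this model deliberately omits.
The package asserts the qualitative shape — monotone median, <20 at one
deposition, threshold crossing within nine, >90 within the ladder — and
no absolute QMF values.

## Known limitations

* Adducts other than protonation, multiply charged species and negative
  mode are supported by the mass algebra but untested against published
  values; average (chemical) masses are out of scope.
* Fine isotope structure within a nominal-mass bin is aggregated; the
  reported bin m/z convention is validated for CHNO only.
* Criterion 4 matches fragment m/z lists; it neither predicts nor
  verifies fragment formulas.
* Quantitation is out of scope throughout (the motivating casework
  explicitly performed none).
* JCAMP-DX support covers the plain XYDATA=(X++(Y..Y)) dialect only; no
  compression schemes.
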