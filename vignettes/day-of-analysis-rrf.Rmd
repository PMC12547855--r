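---
title: "Day-of-analysis relative response factors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Day-of-analysis relative response factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrfkit)
```

## The problem

Nontargeted chemical characterization of medical-device extractables reports
every compound found above an analytical evaluation threshold (AET). The AET
starts from a dose-based toxicological threshold (DBT, µg/day), is converted
to a solution concentration by the extraction parameters, and is then divided
by an uncertainty factor (UF) that absorbs the variability of the analytical
method. Compounds without authentic standards (nontarget extractables, NTEs)
are semiquantitated through a surrogate standard's relative response factor
(RRF). Every step therefore leans on the RRF:

$$\mathrm{RRF} = \frac{A_{\text{analyte}} / C_{\text{analyte}}}
                      {A_{\text{ISTD}} / C_{\text{ISTD}}}$$

where $A$ are integrated responses and $C$ concentrations, with the internal
standard (ISTD) correcting run-level signal drift. RRFs are not constants:
they depend on the quantitation model used to integrate the ion current, on
the concentration range used to estimate them, and on the day the instrument
was calibrated. This package implements the full day-of-analysis workflow —
quantitation models, qualified-range RRF slopes with acceptance filters,
population statistics across calibrations, UF and AET derivation, and
surrogate semiquantitation — together with a calibration-campaign simulator
rich enough to exercise each failure mode.

## Quantitation models and ion-ensemble arithmetic

A compound in ESI rarely appears as one ion: protonated, ammoniated, and
sodiated species, solvent clusters, dimers, and multiple charge states share
its ion current, and each species spreads over an isotope envelope. Under
electron ionization a compound fragments to a varying extent. The five
models in `quant_model()` differ only in which of these peaks they sum:

* **TIC** — everything in the sample (background included);
* **BPC** — the single most intense peak;
* **EIC_single** — one selected (species, isotope) peak;
* **EIC_multi** — the monoisotopic peak of every species of the compound;
* **ECC** — all peaks attributed to the compound (the deconvoluted compound
  chromatogram).

Because the EIC-family models discard real signal, their RRFs are biased low
by exactly the discarded share. Two closed-form consequences anchor the test
suite:

* the monoisotopic fraction of a formula is
  $\prod_e a_e^{n_e}$ over its elements' lightest-isotope abundances — for
  the eight-silicon siloxane `C16H48O8Si8` this falls below one half, so a
  monoisotopic EIC loses the majority of the envelope
  (`monoisotopic_fraction("C16H48O8Si8")`);
* a base-peak EIC of a compound whose 40 EI fragments follow a
  rank$^{-0.7}$ intensity profile captures only
  $1/\sum_{i=1}^{40} i^{-0.7} \approx 0.14$ of the ion current.

Isotope envelopes are computed by exact convolution of per-element isotope
distributions (`isotopologue_distribution()`), aggregated by integer nominal
mass shift. Fine structure (distinct exact masses at the same nominal shift)
is deliberately not resolved: the bias arithmetic concerns envelope
*fractions*, which only need nominal aggregation. Abundances are the
IUPAC/CIAAW 2021 representative values shipped as a plain-text table
(`isotope_table()`); m/z arithmetic includes the electron mass, appropriate
for high-resolution accurate-mass work. The convolution is validated in the
tests against an independent oracle that exhaustively enumerates multinomial
isotope assignments for small formulas (≤ 12 atoms), with per-peak agreement
to 1e-12.

## The campaign simulator

`simulate_campaign()` emulates the statistical structure of a multi-day
calibration campaign so that every downstream stage is testable without
instrument data. Its latent model, per run $r$ and compound $c$:

* a run-level response multiplier $\exp(z_{rc})$ with
  $z_{rc} = \sigma_c(\sqrt{\rho}\, u_r + \sqrt{1-\rho}\,\varepsilon_{rc})$ —
  a lognormal day effect with a fraction $\rho$ shared through a common run
  factor $u_r$, so ISTD correction helps but cannot remove compound-specific
  drift;
* day-level ESI adduct ratios drawn from a Dirichlet distribution centred on
  the compound's propensities with concentration `adduct_drift` (the
  predominant adduct can change between days, as observed in practice; the
  Dirichlet is the simplest simplex-valued family with a tunable
  concentration);
* a concentration–response shape $g(C)$: `linear` ($C$), `saturating`
  ($C/(1+kC)$, electrospray droplet saturation and competitive ionization),
  or `overload_enhancing` ($C(1+kC)$, capped — GC inlet/detector overload),
  with per-compound curvature $k$;
* multiplicative lognormal injection noise with a configurable CV, the
  heteroscedasticity that motivates $1/x$ and $1/x^2$ calibration weighting.

The injection total is distributed over species by the (possibly drifted)
species fractions and over isotope peaks by the formula's envelope, so model
biases emerge mechanically rather than being painted on. EI fragment ratios
are held stable across runs, and each fragment carries the neutral
molecule's isotope envelope — fragment elemental compositions are not
modelled, an approximation that leaves envelope arithmetic exact at the
compound level. Internal standards are generated in every sample at the
fixed mid-range spike concentration.

Defaults were chosen once, as representative of routine practice, and are
simulator parameters rather than estimates from any instrument: day-to-day
dispersion $\sigma = 0.15$ for analytes and $0.05$ for isotopically labeled
internal standards, $\rho = 0.7$, injection CV 5 %, adduct-drift
concentration 50, six calibration levels from 0.025 to 1 µg/mL with three
injections each. What the simulator does **not** contain: chromatographic
peak shapes, coeluting interferences, carryover, retention-time drift, and
matrix effects. Passing tests therefore demonstrate the estimators' behavior
under the stated statistical structure, not performance on real extracts.

## RRF estimation over qualified ranges

`rrf_from_slope()` averages replicate injections per level (keeping the
per-level injection RSD as a diagnostic), fits corrected response against
concentration by weighted least squares with a free intercept, and scales
the slope by $C_{\mathrm{ISTD}}$ so that slope-based and single-point RRFs
coincide for a line through the origin. Acceptance mirrors routine system
suitability: worst per-level injection RSD strictly below 20 %, and weighted
$R^2$ strictly above 0.95 for GC-MS (with $1/x^2$ weighting) or 0.97 for
LC-MS (with $1/x$), evaluated under the required weighting; failures carry
machine-readable reasons. The weighted $R^2$ is computed from weighted
residuals about the weighted mean — the definition is stated here because
several are in circulation.

Two properties of the estimator are worth spelling out, because both are
verified in the tests:

* **Weighting and recovery.** Under multiplicative noise the response
  variance grows as $C^2$, so $1/x^2$ is the variance-optimal (GLS)
  weighting; with it, the slope RRF recovers the simulator's true
  coefficient ratio within 5 % in ≥ 95 % of seeded replicates at the default
  campaign design.
* **Range dependence under curvature.** For a saturating (concave,
  through-origin) response, the single-point RRF at the top concentration is
  the chord from the origin, which always exceeds any free-intercept
  $1/x$-weighted slope fitted inside a high range — a consequence of
  concavity, not an instrument artifact. Under $1/x^2$ weighting the fit
  localizes at the low end of the range and the practically important
  ordering emerges: low-range slope > high-range slope > single point at the
  maximum. The overload shape gives the mirror image (high-range slope >
  low-range slope). This is why RRFs should be reported as slopes of the
  qualified range rather than single high-concentration measurements, and
  why the package evaluates the range-ordering demonstrations under
  $1/x^2$.

## Population statistics

`summarize_population()` reports sample ($n-1$) moments — conservative for
an ongoing process — and percentiles by linear interpolation of order
statistics (`type = 7`), including the 16th/84th percentiles as the
$\pm 1\sigma$ analogues. Mean differences between compounds are tested with
Welch's unequal-variance $t$ (`welch_test()`, Welch–Satterthwaite degrees of
freedom); spread differences with the Brown–Forsythe variant of Levene's
test (`levene_test()`), which is robust to the lognormal-like shape of RRF
populations. `variance_inequality_report()` reports all pairs with raw
p-values, flagged as unadjusted; multiplicity correction across pairs is
left to the analyst because the pair set is usually small and exploratory.
Populations default to accepted-only RRFs (a flag includes rejected runs),
since rejected calibrations would not have been used for reporting either.

## UF, AET, and semiquantitation

`compute_uf()` converts RRF variability into a threshold divisor. The
default strategy is the reciprocal form $\mathrm{UF} = 1/(1-\mathrm{RSD})$
with the RSD capped (default 0.9) so a degenerate population cannot send the
threshold to zero; a mean/p16 percentile-ratio strategy is provided as a
labeled alternative, and both are clamped to $\mathrm{UF} \ge 1$. The AET
follows the extraction-parameter arithmetic

$$\mathrm{AET}_{\text{initial}} =
  \frac{\mathrm{DBT}}{\text{devices/day}} \times
  \frac{\text{devices extracted}}{\text{extraction volume}},
  \qquad
  \mathrm{AET}_{\text{final}} = \mathrm{AET}_{\text{initial}}/\mathrm{UF}$$

in µg/mL throughout; each configuration field accepts exactly one unit, so a
litre/millilitre confusion is unrepresentable. The reportable comparison is
inclusive (`conc >= aet_final`), the protective reading of the boundary.
In `run_pipeline()` the UF is computed per run from the RSD of that run's
accepted standard RRFs and applied only to that run — the day-of-analysis
scope; applying RRFs across runs requires deliberately re-wiring the tables.

`semiquantitate()` converts an unknown's corrected response through a
surrogate RRF *of the same quantitation model* (a mismatch is an error, not
a warning). In the noiseless linear limit the single-ion EIC bias against an
NTE whose monoisotopic fraction is $m_n$ under a surrogate with $m_s$ is
exactly $m_n/m_s - 1$, generalizing to $(f_n m_n)/(f_s m_s) - 1$ when the
base-peak fragment shares $f$ differ as well; the ECC model is unbiased in
that limit. Under realistic noise, the ECC bias magnitude beats the
single-ion EIC on the packaged heavily-fragmenting-alkane / stable-aromatic
pair in ≥ 90 % of seeded replicates. Both statements are verified in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Envelope pruning keeps peaks at or above the threshold (default 1e-10)
  without renormalizing, so the reported abundances remain true fractions;
  the simulator renormalizes its envelopes instead, so feature intensities
  always sum to the latent compound total.
* Convolution is direct (no FFT): envelope vectors are short, and direct
  summation avoids negative round-off.
* Weighted fits run through `stats::lm(weights=)`; the tests compare every
  fit against the closed-form normal equations at 1e-10.
* Zero-variance populations yield UF 1; an RSD ≥ 1 without a cap below 1 is
  an error rather than a negative divisor.
* `compute_response()` returns a flagged 0 for empty TIC-family input but
  errors for EIC selections, which reference peaks that should exist.
* Replicate averaging precedes fitting; a single injection per level yields
  an injection RSD of 0 by convention and relies on the $R^2$ filter.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use deliberately small designs:
single-analyte campaigns of 1–6 runs for unit checks, 50 runs for the
variance-inequality demonstrations, 200 seeded replicates for the recovery
and semiquantitation-ordering rates, 100 random designs for the
least-squares oracle, and formulas of ≤ 12 atoms for the exhaustive isotope
oracle. These sizes give stable rates while keeping the whole suite fast;
they are the package's own choices, stated here so they can be scaled up.

## Known limitations

* Feature-to-compound attribution is taken from the feature table; vendor
  deconvolution of raw chromatograms is out of scope, so attribution errors
  upstream propagate untouched.
* EI fragments share the neutral molecule's envelope; fragment-specific
  envelopes would require fragment formulas.
* The three response shapes are smooth idealizations; real calibration
  curves can mix regimes within one range.
* No LOD/LOQ estimation, no nonlinear calibration models, and no
  multiple-testing correction across population pairs.
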