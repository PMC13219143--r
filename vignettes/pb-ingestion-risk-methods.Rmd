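---
title: "Methods: soil–vegetable Pb ingestion risk in urban agrisystems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil–vegetable Pb ingestion risk in urban agrisystems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbagrisk)
```

## The problem

Urban greenspaces repurposed for food growing often carry legacy lead (Pb)
contamination. The health-relevant question is not the total soil Pb but how
much Pb an adult who both tends the plot (incidental soil ingestion) and
eats its produce (vegetable consumption) actually ingests in bioavailable
form, and whether a soil amendment such as digestate biochar changes that
intake. `pbagrisk` implements this assessment as a tested pipeline over a
2 Pb-condition × 2 amendment × 4 agrisystem (no-crop, lettuce, carrot,
garlic) pot-experiment design with 3 replicates per cell.

## Exposure model

For each replicate the average daily intake (ADI, mg Pb per kg body weight
per day) is computed per pathway:

$$\mathrm{ADI}_{soil} = \frac{C_{soil}\,(\mathrm{BAF}\times 0.8)\,
  \mathrm{EF}\,\mathrm{ED}\,\mathrm{IR}_{soil}}{\mathrm{BW}\,\mathrm{AT}}
  \times 10^{-6}, \qquad
\mathrm{ADI}_{veg} = \frac{C_{veg}\,C\,
  \mathrm{EF}\,\mathrm{ED}\,\mathrm{IR}_{veg}}{\mathrm{BW}\,\mathrm{AT}}
  \times 10^{-3}$$

where BAF is the gastric-phase bioaccessible fraction entering as a
*fraction* (percent/100) — the printed forms of such equations are often
loose about the percent symbol, so the unit handling is made explicit and
unit-tested through the $10^{-6}$ (mg→kg soil) and $10^{-3}$ (g→kg crop)
factors. The 0.8 multiplier is a published regression conversion of in
vitro bioaccessibility to relative bioavailability; it is taken as given,
not refitted. The hazard indices are $\mathrm{THQ} = \mathrm{ADI}/\mathrm{RfD}$
(threshold 1) and $\mathrm{CR} = \mathrm{ADI}\times\mathrm{CSF}$ (bands:
negligible < 10⁻⁶ ≤ moderate acceptable < 10⁻⁴ ≤ unacceptable). The
combined pathway sums the per-replicate soil and vegetable ADIs and
recomputes THQ/CR from the sum, so the identities
$\mathrm{THQ}\times\mathrm{RfD}=\mathrm{ADI}$ and
$\mathrm{CR}=\mathrm{ADI}\times\mathrm{CSF}$ hold exactly for every stored
result.

### Parameters

| symbol | meaning | default | unit |
|---|---|---|---|
| EF | exposure frequency | 365 | days/year |
| ED | exposure duration | 75 | years |
| IR_soil | soil ingestion rate (grower) | 50 | mg/day |
| IR_veg | crop consumption rate | 161 | g fresh wt/day |
| BW | adult body weight | 70 | kg |
| AT | averaging time | EF × ED | days |
| C | dry→fresh conversion | 0.096 lettuce; 0.103 carrot, garlic | – |
| RBA | BAF→bioavailability factor | 0.8 | – |
| RfD | oral reference dose (Pb) | 0.0035 | mg/kg/day |
| CSF | oral cancer slope factor (Pb) | 0.0085 | (mg/kg/day)⁻¹ |

With the derived AT = EF × ED, EF and ED cancel: the indices are invariant
to jointly rescaling them (property-tested), and the non-carcinogenic and
carcinogenic indices share a single ADI. An explicit `AT` argument is
exposed for the USEPA-style variant that averages carcinogenic exposure
over a fixed 70-year window, but it defaults off: the headline tables are
only internally consistent with the cancelling convention, and a 75-year ED
alongside a 70-year cancer-averaging window would otherwise reintroduce a
5/70 discrepancy that the deterministic results never show.

### Aggregation order

Risk indices are computed **per replicate and then averaged within each
treatment cell** (mean of per-replicate ADIs), not evaluated at the cell's
mean concentration. The two orders agree only when BAF (soil) or C (veg) is
constant across replicates — an algebraic fact asserted as a property test —
and the per-replicate-first order is both the statistically standard choice
and the one consistent with published cells that do not match the ADI of
their quoted mean concentration. Percent change control→biochar is
$(A - B)/B \times 100$ on cell means, reported signed; a missing biochar
cell yields a missing change, never 0.

## Bioaccessibility accounting

`compute_baf()` returns BAC/total × 100 and **flags** values above 100 %
(assay recovered more than the total digest) rather than clipping them:
clipping would silently hide assay error, while the flag preserves the
audit trail. The gastric phase is the default phase for risk (worst case —
it solubilises more Pb than the gastrointestinal phase); the
gastrointestinal alternative is selectable by policy. Batch QC follows
routine assay practice: certified-reference recovery, duplicate relative SD
computed per pair then averaged (pooling across pairs was the plausible
alternative; per-pair averaging was chosen and is documented here), and
mean blank as a percentage of mean sample. Missing roles report as
*missing*, never zero. The 0.4 g/40 mL assay adaptation is treated as
metadata: concentrations are assumed already normalised to soil mass, so no
dilution correction is applied.

## Transfer and screening

BCF = vegetable/soil total Pb is homogeneous of degree zero (scale-free),
with a strict BCF > 1 hyperaccumulator flag. Guideline exceedance is also
strict (> limit): equality passes, a convention we fixed because the
sources never adjudicate the boundary. Food limits are compared against
**dry-weight** concentrations by default, matching how the headline
comparisons are made; because the international food limits are
conventionally fresh-weight values, a `basis = "fresh"` switch converts
with the crop's C factor first — the scientifically arguable alternative,
available but not the default.

## Synthetic cohort generator

The generator emulates the pot experiment's statistical structure, not its
chemistry: per-cell normal distributions truncated at 0 for concentrations
(and to (0, 100] for BAF), no soil-process or plant-uptake model, no
correlation between soil and vegetable Pb (the measured data showed only a
weak link). Truncated normals were chosen because only means and SDs are
reported; the truncation bias this introduces is accepted and the
moment-recovery tests compare against the truncated-distribution moments at
the generated scale. Defaults are condition-level moments (high-Pb soil
557.2 ± 60.22 mg/kg, BAF 47.80 ± 6.79 %; low-Pb 250.2 ± 61.29 mg/kg,
43.16 ± 10.62 %) applied uniformly across agrisystems, with cell-level
vegetable means where measured ones exist (all four lettuce cells, the two
low-Pb garlic cells) and crop-level means elsewhere — *interpolated
synthetic defaults*, clearly not per-cell measurements. Biochar effects are
multiplicative factors on cell means (default 1 = no effect), since only
directions/magnitudes per cell are reported, not a generative mechanism.

Two deliberate consistency modes exist: the default derives BAC as
total × BAF/100, so recomputing the fraction from a generated table
round-trips exactly (this is what makes the generator a fixture-grade
oracle for the bioaccessibility module); `consistent_bac = FALSE` samples
BAC independently to exercise the QC and >100 %-flag failure paths. The
gastrointestinal-phase column is filled as gastric × 0.5, a synthetic
placeholder ratio (no gastrointestinal values are published for this
design). Passing tests on this generator demonstrate the pipeline's
arithmetic and invariants — they do not validate distributional assumptions
against real field data, which show features (spatially sparse
anthropogenic Pb, skewness, soil–plant correlation structure) the generator
does not emulate.

## Monte Carlo layer

Each simulation set draws all varied parameters **independently and
uniformly** over their ranges — the minimal-assumption reading of
"continuous values within each parameter range", with the distribution tag
left extensible — and evaluates the same vectorised intake kernels as the
deterministic pipeline, so degenerate ranges reproduce deterministic
results bitwise (the module's primary oracle). Default 10,000 iterations
per treatment × pathway combination (16 soil + 12 vegetable = 280,000
draws), site-specific concentration/BAF ranges taken as the per-cell
min–max of the measurements, and adult EF/IR/BW ranges shipped as clearly
labelled placeholders (EF 180–365 d/y; IR 10–100 mg soil/d or 50–250 g
crop/d; BW 50–95 kg) because the survey-derived ranges are not in the main
published text — replace them for any real assessment.

Sensitivity uses the **swing** method as the tornado default (each
parameter evaluated at its range endpoints with the others at midpoints;
contribution = |THQ_max − THQ_min|, the tornado bar width) and offers
**rank correlation** (Spearman) because spreadsheet risk add-ins compute
correlation-based importance; both are reported by the analysis driver.
Rankings sort by influence — the absolute value, for correlations, since
body weight's influence is large and negative — descending, with ties
broken by the fixed parameter order and flagged. A degenerate range
contributes exactly 0. Note that with AT = EF × ED the swing of EF is 0 by
cancellation: EF genuinely does not move THQ under this convention, which
matches its consistently low published influence.

## Numerical choices and degenerate inputs

* Truncated-normal draws use the inverse-CDF construction
  (`qnorm(runif())`), which keeps the RNG stream consumption fixed per cell
  so a degenerate SD does not desynchronise seeds.
* Exceedance probability is the strict tail fraction
  (draws > threshold); monotone non-increasing in the threshold.
* Histograms use equal-width bins over the draw range; an all-equal draw
  set gets a single token-width bin so probabilities still sum to 1.
* Tables render in 3-significant-figure scientific notation (`1.87E-03`);
  test comparisons against published cells use relative tolerance 5 × 10⁻³
  to absorb the rounding of the printed concentration inputs.
* Sub-seeds for the per-cell grid are derived as
  `(seed × 1000 + cell index) mod (2³¹ − 1)` to stay in integer range.
* Empty treatment cells are omitted with a warning; a single replicate
  reports SD 0; percent change with a zero baseline is a domain error.

## Problem sizes

The test suite and the analysis drivers use the study-scale design (3
replicates per cell; 10,000 Monte Carlo iterations per combination) except
where a statistical property needs volume, where n = 10,000 replicates per
cell are generated; the standard-error scaling check repeats 30 small
simulations at two draw counts (500 and 8,000).

## Known limitations

* Adult receptor only; no child (pica) scenario, no dermal or inhalation
  pathways, no multi-element hazard index.
* No IVBA→RBA regression refit: the 0.8 factor is fixed.
* Uniform, independent sampling — no copulas, no Latin hypercube.
* The generator's normality and independence are conveniences, not claims
  about field data.
* Guideline values are consumed, not derived; no Pb speciation modelling.
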