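---
title: "Methods: projecting forest carbon with growth models and habitat suitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting forest carbon with growth models and habitat suitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcarbon)
```

## The model

The package projects per-pixel forest aboveground biomass (AGB, Mg/ha) as an
additive decomposition

$$C \;=\; C^{age} + C^{climate} + C^{co_2},$$

under the assumptions that (i) stand aging, climate change and CO₂
fertilization act additively on biomass density, (ii) no further
disturbances (fire, harvest, pests) occur, and (iii) forest presence and
composition are governed by habitat suitability alone.

**Age and climate.** The biomass–age relationship of each forest type is one
of three saturating curves with asymptote $\mu$ (Mg/ha):
Michaelis–Menten $f(t) = \mu t/(k+t)$, where $k$ (years) is the age at half
the asymptote; monomolecular $f(t) = \mu(1 - c e^{-\alpha t})$; and logistic
$f(t) = \mu/(1 + c e^{-\alpha t})$, with rate $\alpha$ (1/yr) and shape
$c \ge 1$ (so the curve starts at or below its midpoint and growth is
non-decreasing). A linear climate term extends the curve to

$$C_t^{age+climate} = f(t) + a\,\mathrm{MAT} + b\,\mathrm{MAP} + d,$$

with MAT in °C and MAP in mm, so $a$ and $b$ are Mg/ha per °C and per mm.
The *age component* evaluates this model at the future stand age but with
baseline-year (2020) climate; the *climate component* is the difference when
future climate is substituted, and can be negative. Because the linear term
can drive predictions below zero at young ages, predictions are clipped at 0
(the clipped count is attached to the prediction as an attribute).

**CO₂ fertilization.** The ratio
$F = \mathrm{cVeg}(\mathrm{ppm}_t)/\mathrm{cVeg}(371.8\,\mathrm{ppm})$ is
read off tabulated vegetation-carbon responses to CO₂ concentration (the
kind of curve produced by idealised 1-percent-per-year CO₂ experiments),
using linear interpolation between tabulated points; requests outside the
tabulated range are refused rather than extrapolated, because silent
extrapolation of a saturating response is an invisible bias. With an
ensemble of curves the per-model ratios are averaged — not the ratio of mean
cVeg — so each model stays self-normalised. Period ratios average the yearly
$F$ over the inclusive 20-year windows 2021–2040, 2041–2060 and 2061–2080.
The CO₂ component is $(F-1)\,C^{age}$; for replaced and planted pixels it
uses the new type's age component, since the ratio method is generic in the
underlying biomass. The baseline ppm of 371.8 is the 1978–2020 mean
concentration.

## Fitting and model selection

All free parameters — the curve parameters and $(a, b, d)$ — are estimated
jointly by constrained nonlinear least squares (the model is written as one
equation, so a two-stage fit would bias the curve parameters). Positivity of
$\mu, k, \alpha$ and the constraint $c \ge 1$ are enforced by optimising
$\log \mu$, $\log k$, $\log \alpha$ and $\log c \ge 0$ with box constraints
(L-BFGS-B). Because saturating curves have well-known local minima, the
optimiser is started from a fixed grid: $\mu_0 \in \{0.5, 1, 2\} \times
\max(\mathrm{AGB})$, $k_0 \in \{15, 50, 150, 450\}$ years, $\alpha_0 \in
\{0.01, 0.03, 0.1, 0.3\}$/yr, $c_0 \in \{1, 20\}$; at each start the linear
coefficients are initialised by regressing the residual from the starting
curve on MAT and MAP. The best start is polished with a tight convergence
tolerance. The grid is fixed, so fits are deterministic.

Fit quality is reported as RMSE $=\sqrt{RSS/n}$, $R^2 = 1 - RSS/TSS$, and
the Gaussian least-squares AIC $= n\log(RSS/n) + 2p$ with $p$ counting all
free parameters including the intercept $d$ (5 for MM, 6 for MO/L). The
constant terms of the Gaussian likelihood are dropped; only AIC differences
on the same records matter. Among the three families the lowest AIC wins;
exact ties fall back to lower RMSE, then to the fixed order MM, L, MO — AIC
is the primary criterion because it balances accuracy against the extra
shape parameter of the MO/L families. Degenerate inputs (constant AGB,
constant age, fewer records than parameters plus one) are refused with a fit
error naming the family and type.

## Map fusion

Three cover products, ranked by reliability, are fused per pixel by
sequential criteria: (1) if at least two products agree on a *forest* type,
that type is adopted; (2) otherwise the rank-1 code if it is forest; (3)
otherwise the rank-2 code if forest; (4) otherwise the rank-3 code.
Agreement is deliberately restricted to forest codes: a pixel on which the
two most reliable products say non-forest but the third reports a forest
type is classified by the third product (criterion 4), not by the non-forest
majority. This is the reading under which all four criteria are reachable;
treating a non-forest majority as binding would make criteria (3) and (4)
dead letters. The package's forest definition is a tree-cover fraction of at
least 20% (inclusive).

Stand ages are filled by priority: the rank-1 product where non-null, else
rank-2, else rank-3 plus its epoch offset (default +10 years, for a product
mapped a decade before the baseline). Pixels null in all three products —
a case the priority rule does not reach — are filled with the median fused
age of same-type pixels and reported via a warning, keeping the age map
complete inside the forest mask without inventing spatial structure.

The fusion operations require inputs on a shared grid; a nearest-neighbour
regridding utility is provided for convenience because nearest-neighbour is
the only resampling that cannot invent categorical codes.

## Scenarios

Both scenarios are projected from the 2020 baseline with horizon $N$ =
period midpoint − 2020 (10, 30, 50 years for the 2030s, 2050s, 2070s);
the evaluation year inside a 20-year window is not dictated by the data, so
the midpoint is used and is configurable. Half-ages $N/2$ for replaced and
planted stands are rounded to whole years by default (the curves themselves
are continuous in age, and real-valued ages are supported). Chained stepping
(projecting the 2050s from the 2030s state) is deliberately not the default:
the age component is defined against 2020 climate, so each period is
projected from the baseline.

**Nature.** A forest pixel whose own type's future suitability strictly
exceeds that type's MTSS threshold ("exceeds", hence strict inequality)
remains and ages by $N$. Otherwise every *other* type on the pixel is
considered, and the qualifying type with the highest suitability replaces
the incumbent at age $N/2$; exact ties break to the lowest type code so
results are deterministic. If no type qualifies the pixel is lost. The
scenario never creates forest.

**Afforestation.** Area targets (Mha per year) are near-linear policy
series; an OLS line is fitted and evaluated at the period's representative
year. The demand is the target minus the remaining nature-scenario forest
area, clipped at zero. Candidate pixels are non-forest pixels with at least
one qualifying type; they are drawn uniformly at random (the data give no
basis for weighting) without replacement until the cumulative spherical
pixel area meets the demand, each planted with its most suitable qualifying
type at age $N/2$. If candidates run out the shortfall is a warning, not an
error. The draw is repeated over explicit replicate seeds (default 10) and
the summaries report the replicate mean and between-replicate standard
deviation.

Pixel areas use the spherical formula
$R^2\,\Delta\lambda\,(\sin\phi_{top}-\sin\phi_{bottom})$, so Mha accounting
is latitude-correct.

## Suitability inputs

Suitability probabilities and MTSS thresholds are *inputs*: they are the
outputs of an external species-distribution model, which is not
re-implemented here. The package provides the standard pre-modelling
collinearity screen — greedy removal of environmental variables until all
pairwise Pearson $|r| \le 0.8$, dropping first the variable with the most
above-threshold partners (ties: larger mean $|r|$, then name order) —
and the threshold decisions themselves. Pearson correlation is used, as is
conventional for bioclimatic screens.

## The synthetic world

`generate_world()` fabricates every input with known truth, emulating the
statistical structure of the real data sources:

- **Climate**: smooth north–south gradients (MAT −4…16 °C, MAP 600…1600 mm)
  with low-amplitude sinusoidal east–west texture, defined on normalised
  grid position so any grid size samples the full range; futures add uniform
  per-period/per-scenario deltas (defaults ΔMAT 1.0–4.3 °C, ΔMAP 20–90 mm,
  typical of mid-latitude ensemble projections).
- **Tree cover** rises with MAP and is centred so roughly a quarter of the
  domain clears the 20% forest threshold, a realistic forested fraction for
  a national territory.
- **Suitability** is logistic in standardised climate distance from
  type-specific optima placed on the climate quantiles of *forested* cells
  (niche models infer optima from occurrences). MTSS is set to the
  probability quantile at which a configured fraction of grid cells
  qualifies (default 0.25); a median-based threshold would be far too
  permissive once niches concentrate in the forest zone.
- **Survey records** (default 600) draw ages uniformly on 1–150 years —
  spanning curve saturation — with climate read from random cells and AGB
  from per-type generating laws (families cycling MM/L/MO, asymptotes
  105–205 Mg/ha, MM half-saturation 120 yr, $a = 2$, $b = 0.05$, $d = 5$)
  plus Gaussian noise (default sd 10 Mg/ha, the scale of field-plot
  scatter).
- **Cover products**: to make every product pair disagree at the configured
  rate $r$, a cell is perturbed in exactly one product (chosen uniformly)
  with probability $3r/2$; a given pair is then affected with probability
  $r$. This requires $r \le 2/3$.
- **Age products** null out configured fractions of forest cells; the
  rank-3 product stores ages a decade younger so the +10 adjustment is
  exercised.
- **CO₂**: concentration trajectories are quadratic in year (about 560 ppm
  by 2080 under the moderate pathway, 780 ppm under the high-emission one);
  the cVeg response is a saturating Michaelis form in ppm, perturbed across
  a 12-member synthetic ensemble.
- **Area targets** grow linearly at 1.2%/yr of the baseline forest area with
  small noise, matching the near-linear character of published national
  afforestation target series.

What the generator does *not* emulate: real geography and the real climatic
zones, spatially correlated product errors (disagreement is independent
across cells), disturbance history in the age maps, non-climatic suitability
drivers (soil, topography), and sub-type to primary-type aggregation (the
typology is a configuration input). Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline's logic under
controlled conditions, not the accuracy of any national-scale estimate.

## Numerical and engineering choices

- Rasters are plain matrices with a lightweight geometry record; files are
  plain-text ESRI ASCII grids, CSV and JSON, avoiding GIS system
  dependencies entirely.
- All randomness flows through explicit seeds (the generator's config seed;
  the allocation replicate seeds); reruns are byte-identical, and pipeline
  runs write a manifest with the config hash and seeds.
- `carbon_fraction` defaults to 1.0 — input densities are treated as already
  in carbon units, since survey AGB tables and carbon totals are frequently
  reported in the same unit system without an explicit conversion; set 0.5
  for the conventional biomass-to-carbon factor if the survey densities are
  dry biomass. This choice scales totals but no rate or share.
- The spread reported next to a total is the area-weighted spatial standard
  deviation of pixel density scaled to the forest area, so the total's ±
  and the density's ± are consistent; for afforestation ensembles the
  between-replicate sd of the total is reported separately.

## Problem sizes in the test suite

The suite exercises: exhaustive truth tables over all 64 cover-code triples
and all age null patterns; parameter recovery on 50 replicate surveys of
n = 200 at noise sd 10 Mg/ha and family selection at sd 5; pixel-by-pixel
oracle equivalence of both scenario engines on one hundred random 8×8
worlds; conservation audits (additive decomposition to 1e−9 relative,
exact remained/replaced/lost partition, planting within one pixel-area of
demand) on a full 50×50 world; and an end-to-end 50×50 demonstration over
3 periods × 2 scenarios × 2 pathways with a 10-replicate planting ensemble,
run twice to confirm determinism. These sizes were chosen so the whole suite
gives thorough coverage in a few minutes on a single CPU.

## Limitations

Inherited from the model: additivity of the three components is an
assumption, not a result; no disturbance, mortality-within-type, management,
land-competition or socio-economic constraints; suitability is taken at face
value from its producer; the climate term is linear, so strong
extrapolations beyond the survey's climate range are untrustworthy; the
fertilization ratio applies one curve (or ensemble) to all pixels of a
class. Inherited from the data model: products must share a grid (regridding
is nearest-neighbour only); no reprojection between coordinate systems.
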