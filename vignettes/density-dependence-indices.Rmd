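---
title: "Spatial density-dependence indices: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial density-dependence indices: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seascapeDD)
```

## The question the package addresses

When a pelagic fish population grows, does crowding degrade the body
condition of individuals *where* the fish concentrate? seascapeDD computes
the descriptive spatial statistics used to answer this on gridded acoustic
survey data — yearly maps of density (fish per squared nautical mile) and
body condition per ICES statistical rectangle (0.5° latitude x 1°
longitude) — and tests their temporal co-variation. The diagnostic
fingerprint of spatial density-dependence is threefold: the centres of
gravity of density and of maximum condition drift apart over time; the
within-year spatial correlation between density and condition grows more
negative as mean density rises; and the patchiness of the density field
(spatial autocorrelation) rises with mean density.

## Body condition

Condition is Fulton's factor

$$K = \mathrm{TW} / \mathrm{TL}^{b},$$

with total weight TW in g, total length TL in cm, and $b$ the slope of the
*pooled* ordinary-least-squares regression of $\ln \mathrm{TW}$ on
$\ln \mathrm{TL}$ across all years and rectangles (one overall allometry,
not a per-year fit). Before any computation the survey measurement protocol
is applied: weights to the nearest gram, lengths *down* to the nearest
0.5 cm. Two conventions are deliberately fixed and documented rather than
configurable:

* **Units.** TL enters both the ln–ln fit and $K$ in cm. Any fixed unit
  gives the same $b$; only the scale of $K$ changes, and every downstream
  comparison is rank-based (Spearman), so the choice is cosmetic. No x100
  multiplier is applied to $K$.
* **Rounding ties.** An exact .5 g rounds up. Survey protocols say only
  "nearest gram"; half-up is the common field convention and makes the
  operation idempotent.

Rectangle-level condition is the mean $K$ of the fish in the 120–130 mm
reference class (inclusive at both ends), the modal size class present
throughout a long survey series; restricting to one class removes the
length-structure signal from the spatial comparison. A cell with no
in-window fish is *absent* from the table — never recorded as condition 0.

## Centres of gravity

The centre of gravity (COG) of a yearly map is the weighted mean position

$$\left(\frac{\sum_i w_i \,\mathrm{lat}_i}{\sum_i w_i},\;
       \frac{\sum_i w_i \,\mathrm{lon}_i}{\sum_i w_i}\right),$$

with weights $w_i$ the density (or condition) of rectangle $i$ and
coordinates the cell centres (no within-cell positioning). To track the
centre of *maximum* density and *maximum* condition, each map is first
restricted to cells strictly above the within-year median of the weight
variable. Strictness is a deliberate tie-break: "above the median" reads
literally, so ties at the median drop out, and a map where every cell is
equal has no "above" — such a year is flagged degenerate rather than
silently centred.

Uncertainty comes from an exact leave-one-out enumeration: the COG is
recomputed with each of the $n$ retained cells deleted in turn, the point
estimate is the coordinate-wise median of the $n$ results and the 95%
interval their 2.5th–97.5th percentile range. Enumeration (rather than a
randomised resample) makes the whole pipeline deterministic — identical
inputs give byte-identical outputs. Years whose above-median subset holds
fewer than `min_cells` cells (default 10; surveys give no canonical number,
and 10 cells on a 0.5°x1° grid is the least we would call a spatial
pattern) are excluded from COG and separation series but retained in yearly
means, where a thin year still carries information.

Separation between the density and condition trajectories is reported per
year as signed and absolute differences per coordinate, and as the total
distance $\sqrt{\Delta\mathrm{lat}^2 + \Delta\mathrm{lon}^2}$ for the
single separation-versus-time test.

## Patchiness: Moran's I

For each yearly map and variable,

$$I = \frac{n}{S_0} \,
  \frac{\sum_{i}\sum_{j} w_{ij}(x_i-\bar x)(x_j-\bar x)}
       {\sum_i (x_i-\bar x)^2},
  \qquad w_{ij} = 1 - \frac{d_{ij}}{d_{\max}},$$

with $d_{ij}$ the Euclidean distance between cell centres in (lat, lon)
degree space, $d_{\max}$ the largest distance on that year's map (weights
are built per map, not across years), $w_{ii}=0$, and $S_0=\sum_{ij}w_{ij}$.
Values toward 1 mean clustering into large patches, toward −1 dispersion;
the null expectation is $-1/(n-1)$. Distances in raw degrees (not
great-circle km) match how these indices are conventionally computed on
survey grids of this extent; at 55–60°N a longitude degree is ~0.55 of a
latitude degree, so the metric stretches east–west — an accepted distortion
at this scale, and irrelevant to the temporal *comparisons* the pipeline
makes. Note that some reference implementations (e.g. `ape::Moran.I`)
row-standardise the weight matrix before applying the same formula; the
package keeps the raw $1-d/d_{\max}$ weights and its tests show equality
with `ape` once the same standardisation is applied. $I$ is computed on all
cells of a map, not only the above-median subset: patchiness is a property
of the whole field.

Degenerate inputs are refused loudly: fewer than 3 cells, a constant field
(zero variance), or fully coincident coordinates ($d_{\max}=0$) raise
errors rather than returning NaN.

## Correlations and adjusted significance

The within-year spatial density–condition relationship is Spearman's rank
correlation across rectangles with both values (pairwise-complete; years
with fewer than 4 complete cells are omitted). Rank correlation makes every
result invariant to the unit and scale conventions above.

Associations between yearly time series (e.g. Moran's I of density vs mean
density) are Spearman correlations whose significance is corrected for
serial autocorrelation through an effective sample size, the modified
Chelton estimator

$$\frac{1}{n_{\mathrm{eff}}} = \frac{1}{n} + \frac{2}{n}
  \sum_{j=1}^{\lfloor n/5 \rfloor} r_{xx}(j)\, r_{yy}(j),$$

with $r_{xx}, r_{yy}$ the lag-$j$ sample autocorrelations of the two
series, computed here on the *ranks* for consistency with the rank
correlation being tested. The estimator's source literature offers several
lag truncations; $\lfloor n/5 \rfloor$ keeps only lags estimated with
reasonable precision at the 20–30-year series lengths this pipeline
targets, and is configurable. $n_{\mathrm{eff}}$ is clipped to $[2, n]$ —
the adjustment may only *reduce* significance. P-values use the
t-approximation $t = \rho\sqrt{(n_{\mathrm{eff}}-2)/(1-\rho^2)}$ with
$n_{\mathrm{eff}}-2$ (possibly fractional) degrees of freedom; a
permutation alternative exists for unadjusted small-n checks. Simulation in
the test suite shows the adjusted test holds its nominal size on white
noise and loses significance, as it should, on strongly autocorrelated
AR(1) pairs.

## The synthetic seascape generator

Rectangle-resolution acoustic survey databases are not public, so the
package ships a generator that emulates the statistical structure the
analysis assumes, on a Baltic-Proper-like domain (default 10 x 10 cells of
0.5° x 1° starting at 54.5°N, 14°E; 25 years from 1985):

* **Density.** $d_{it} = A(t)\,\exp(\kappa(t)\,g_t(i))\,\varepsilon_{it}$,
  where $A(t)$ ramps 100→1000 fish/nmi² (an order-of-magnitude increase
  over the series, the kind of rise seen in a boom of a small pelagic),
  $g_t$ is a unit gradient toward a hotspot drifting linearly from the grid
  centre to the north-east corner, $\kappa(t)$ ramps 0→3 (from no gradient
  to a ~20-fold expected density contrast), and
  $\varepsilon \sim \mathrm{lognormal}(0, 0.3)$ — lognormal because
  acoustic densities are positive and right-skewed.
* **Condition.** $K_{it} = K_0\,(1 - \beta\,\nu(d_{it})) + \eta_{it}$ with
  $K_0 = 0.007$ (the magnitude of $\mathrm{TW}/\mathrm{TL}_{cm}^3$ for a
  ~13 g, 12.5 cm clupeid), suppression strength $\beta = 0.6$, Gaussian
  noise $\eta$ with sd $2\times10^{-4}$ (~3% of $K_0$), and
  $\nu(d) = 1 - e^{-d/d_{\mathrm{ref}}}$ where $d_{\mathrm{ref}}$ is the
  run-wide maximum of the noise-free expected density surface. Two
  properties of $\nu$ matter and drove its selection: it is *strictly*
  increasing (so noise-free coupling gives a within-year rank correlation
  of exactly −1), and it is anchored to a run-wide carrying-capacity scale
  rather than renormalised within each year. Within-year renormalisation
  would make every year's mean condition blind to abundance and cannot
  produce the joint temporal decline of condition with rising density; the
  absolute scale makes low-abundance years uniformly well-conditioned and
  crowded years suppressed exactly where the fish are.
* **Fish records.** Per cell, individual fish with lengths uniform on the
  0.5 cm grid in 120–130 mm and weights $K_{\mathrm{cell}}\,
  \mathrm{TL}_{cm}^3$ under lognormal individual variation, emitted
  *unrounded* so the measurement protocol is exercised downstream. This
  closes the loop: the condition module run on emitted records recovers
  each cell's $K$ up to the 1 g rounding bound.

A homogeneous null configuration ($\kappa = 0$, $\beta = 0$, flat abundance
— the early-era regime has no trend of any kind) provides the negative
control: there the pipeline should find nothing, and its Moran's I should
average the null expectation $-1/(n-1)$.

What the generator does *not* emulate — and what passing tests therefore do
not certify about real surveys: unsurveyed cells and year-varying coverage,
coastline geometry, measurement error in the acoustic-to-density
conversion, length/age structure beyond the reference class, immigration
and recruitment dynamics, and any mechanistic movement rule (the regime
shift is imposed, not emergent). The generator validates the *statistical
machinery*, not the ecology.

## Reproducibility and problem sizes

All randomness lives in the generator and is governed by a single seed
(derived streams for density, condition and fish records); everything
downstream is deterministic, and rerunning the pipeline on the same inputs
produces byte-identical output trees. The test suite exercises Moran's I
against a brute-force double-sum oracle on 200 random maps of up to 12
cells (agreement to 1e-12), the COG closed forms exactly, the condition
round-trip at n = 200 fish, the divergent-regime fingerprint on the default
10 x 10 x 25-year seascape, and the null calibration on twenty 25-year null
replicates — sizes chosen so the whole suite runs in well under a minute
while leaving the estimators in their intended regime.

## Known limitations

* Degree-space distances stretch zonally at high latitude (see above); a
  great-circle option is a natural extension but is not the convention this
  pipeline reproduces.
* The percentile leave-one-out interval is a coverage heuristic, not an
  exact confidence procedure; with spatially clustered weights it can be
  narrow. It is used comparatively, never inferentially.
* The effective-df adjustment is an approximation whose behaviour at
  $n < 10$ overlapping years is poorly characterised; the pipeline refuses
  association tests below 5 overlapping years rather than pretending
  precision.
* Moran's I is reported without per-year significance tests; the pipeline's
  claims rest on its temporal association with density, which is tested.
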