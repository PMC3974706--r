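# seascapeDD

Spatio-temporal density-dependence indices for gridded fish surveys.

When a pelagic population grows, crowding can depress individual body
condition exactly where the fish concentrate. seascapeDD computes the
descriptive spatial statistics used to diagnose this on survey data resolved
to ICES statistical rectangles (0.5° latitude x 1° longitude), and is aimed
at fisheries ecologists working with acoustic or trawl survey grids:

* **Body condition** — Fulton's K = TW/TL^b per fish, with b the slope of
  the pooled ln(TW)–ln(TL) regression, averaged per (year, rectangle) over a
  reference length class (default 120–130 mm), after applying the survey
  measurement protocol (weights to 1 g, lengths floored to 0.5 cm).
* **Centres of gravity** — the density- (or condition-) weighted mean
  position of each yearly map, restricted to cells above the within-year
  median, with a deterministic leave-one-out 95% interval; plus the per-year
  separation between the density and condition centre trajectories.
* **Patchiness** — Moran's I per yearly map with distance-decay weights
  w_ij = 1 − d_ij/d_max (Euclidean, degree space); null expectation
  −1/(n−1).
* **Associations** — per-year spatial Spearman correlation between density
  and condition, and Spearman tests between the resulting yearly series with
  significance adjusted for serial autocorrelation via an effective sample
  size (modified Chelton estimator, lags up to ⌊n/5⌋).
* **A synthetic seascape generator** — emulates a Baltic-Proper-like grid
  shifting from a homogeneous low-abundance regime to a concentrated
  high-abundance regime with condition suppressed where density is high, so
  the full pipeline is testable without access to restricted survey
  databases.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_condition.R
Rscript analysis/03_spatial_indices.R
Rscript analysis/04_correlations.R
```

simulates the default 10 x 10-rectangle, 25-year seascape (seed 42), derives
condition from 50,000 individual fish records, computes every index, and
writes the tables under `results/`. The run prints:

```
seascape: 100 rectangles x 25 years, 50000 fish records
mean density rises 106 -> 5059 per nmi^2 over the period
Length-weight fit: b = 3.0014, ln-intercept = -5.0167, n = 50000, R^2 = 0.6465
condition for 2500 (year, rectangle) cells; yearly mean K falls 0.0070 -> 0.0061
excluded years (coverage): 0
COG separation grows 0.45 -> 3.77 degrees (first -> last year)
Moran's I of density: -0.012 (first year) -> 0.102 (last year)
headline associations (Spearman, autocorrelation-adjusted p):
                            pair    rho  n n_eff    p_raw p_adjusted
1 mean_density_vs_mean_condition -0.993 25  4.65 6.72e-23    0.00153
2   cog_lat_density_vs_condition -0.874 25  5.85 1.17e-08    0.02584
3   cog_lon_density_vs_condition -0.921 25  5.78 7.02e-11    0.01158
4    spatial_rho_vs_mean_density -0.965 25  4.73 8.22e-15    0.01186
5  moran_density_vs_mean_density  0.936 25  4.77 6.33e-12    0.02521
6         cog_separation_vs_year  0.948 25  4.76 5.73e-13    0.01892
7     cog_separation_lat_vs_year  0.955 25  4.75 1.37e-13    0.01613
8     cog_separation_lon_vs_year  0.932 25  4.86 1.38e-11    0.02494
```

Reading the table: the allometric slope recovers the generative cube law
(b ≈ 3); mean condition falls as mean density rises (rho = −0.99); the
density and condition centres of gravity move in opposite directions in both
coordinates (rows 2–3) and drift apart over time (rows 6–8); the within-year
density–condition correlation deepens with mean density (row 4); and density
patchiness (Moran's I) rises with mean density (row 5). This is the full
qualitative fingerprint of spatial density-dependence in body condition.
With few effective degrees of freedom (n_eff ≈ 5 for these strongly trending
series) every association nevertheless remains significant at the 5% level.

The same functions run on real data: `run_analysis("observations.csv",
fish_records = "fish_records.csv", outdir = "out")` accepts
`year,rect,density[,condition]` (rectangle codes are georeferenced
automatically) or `year,lat,lon,density[,condition]`, plus individual
records `year,rect,length_mm,weight_g`, and writes the same tables plus a
run manifest. `validate_inputs()` reports row-level schema problems first.

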