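---
title: "Methods: ecosystem-service trade-off mapping and driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecosystem-service trade-off mapping and driver attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrade)
```

`estrade` quantifies four ecosystem services on annual raster stacks,
classifies their pairwise relationships, maps trade-off intensity and
attributes it to landscape drivers. This vignette is the package's account
of the science behind each stage: the models and their assumptions, the
parameters that matter, the numerical choices, and what the synthetic data
can and cannot tell you about real landscapes.

## The raster container

All stages operate on `raster_grid` objects: a numeric matrix on a regular
north-up grid (row 1 = northern edge), a lower-left origin, a square cell
size in metres, and `NA` as the nodata mask. Every multi-raster operation
requires identical shape, transform and mask; `quantify_all()` additionally
unions the four service masks so downstream statistics always see the same
pixel set. Interchange uses the Arc/Info ASCII grid format — plain text,
readable by any GIS — with categorical rasters (land use, soil, landform)
written as integers and resampled only by nearest neighbour
(`align_rasters()` refuses bilinear interpolation of class codes).

## The four service models

**Water yield** follows the Budyko-curve annual partition:
$Y = (1 - \mathrm{AET}/P)\,P$ with
$\mathrm{AET}/P = (1 + wR)/(1 + wR + 1/R)$, dryness ratio
$R = k\,\mathrm{ET}_0/P$ and $w = Z\,\mathrm{AWC}/P$,
$\mathrm{AWC} = \min(\mathrm{MSD}, \mathrm{RD})\cdot\mathrm{PAWC}$. The
seasonality parameter defaults to $Z = 3.6$; the per-class
evapotranspiration coefficient $k$ and rooting depth come from the
land-class table. The construction guarantees $0 \le Y \le P$ and $Y = 0$
where $P = 0$. Glacier and snow-melt contributions are explicitly *not*
modelled; in mountainous arid basins this understates yield.

PAWC comes from a quadratic pedotransfer polynomial in sand, silt, clay and
organic-matter percentages. Two coefficient presets exist because published
transcriptions of this polynomial disagree: the default (`"plausible"`,
quadratic terms 0.003/0.055/0.006) stays positive for ordinary soils, while
the `"printed"` variant (0.03/0.55/0.06) goes negative for common textures
and is clipped to zero with a warning. The default is the variant that
produces physically meaningful water capacities.

**Soil conservation** is RUSLE's retained potential erosion,
$SC = R\,K\,LS\,(1 - C\,P)$, in t·hm⁻²·yr⁻¹ (regional reporting multiplies
the mean by 100 for t/km²). The package deliberately accepts $R$, $K$ and
$LS$ as *inputs*: their derivation is site-specific and no single formula is
canonical. For synthetic data it supplies flagged convenience estimators — a
precipitation power law $R = aP^b$ (defaults $a=0.3$, $b=1.5$), the EPIC
texture nomograph for $K$, and a slope-length/steepness $LS$ with the
standard piecewise length exponent — none of which should be mistaken for
calibrated formulations.

**Windbreak and sand fixation** uses the RWEQ transport-capacity closure.
With factor product $FP = WF\cdot EF\cdot SCF\cdot K'\cdot COG$:
$Q_{\max} = 109.8\,FP$, critical field length $s = 150.71\,FP^{-0.3711}$,
and soil loss at plot length $x$ (default 50 m)
$SL = (2x/s^2)\,Q_{\max}\,e^{-(x/s)^2}$. A frequently printed variant of the
transport equation, $Q(x) = Q_{\max}[1 - e^{(x/s)^2}]/x$, is non-physical
(negative and divergent in $x$); this package implements the standard forms
above. The service is the vegetation's protective effect,
$SR = SL_q - SL$, where $SL_q$ recomputes $SL$ with the vegetation factor
reset to its bare-soil value (1), leaving soil moisture and snow factors
unchanged. $SR \ge 0$ holds throughout the realistic factor range; at
extremely large factor products ($FP \gtrsim 60$ at $x = 50$ m) $SL$ is no
longer monotone in $FP$ — far outside the magnitudes the generator or any
plausible county produces, but worth knowing if you feed measured inputs.
A zero factor product (no erosive wind) leaves $s$ undefined; the package
returns $SL = 0$ there with a warning, which is the physically sensible
limit.

The climate factor sums erosive wind records:
$WF = [\sum WS_2(WS_2 - WS_t)^2]\,N_d\,\rho/(N g)\cdot SW\cdot SD$ over
records above the threshold speed, where $g$ is gravitational acceleration
in m/s². The erodible fraction $EF$ again has two presets: the default
standard regression
$(29.09 + 0.31S_a + 0.17S_i + 0.33 S_a/C_i - 2.59\,OM - 0.95\,CaCO_3)/100$
and a `"printed"` variant ($0.33 S_iC_i/100$, $-2.95\,OM$, $+0.95\,CaCO_3$)
that tolerates zero clay, matching an alternative transcription. The crust
factor is $SCF = 1/(1 + 0.0066C_i^2 + 0.021\,OM^2)$. The surface roughness
factor $K'$ has no canonical derivation and is taken from the land-class
table; the vegetation factor is $COG = e^{-0.0438\cdot(100\,F_c)}$ with
fractional cover $F_c$ from the dimidiate NDVI model (5th/95th percentile
endmembers, clipped to [0, 1]; a constant NDVI field is a hard error since
the endmembers coincide).

**Habitat quality** is a threat-decay half-saturation model. Degradation at
pixel $x$ with land class $j$ sums, over stressors $r$, the
weight-normalized ($W_r/\sum W_r$) mean distance-decayed impact of the
stressor's source pixels, scaled by accessibility $\beta_x$ and sensitivity
$S_{jr}$. Two conventional kernels are supported: linear $1 - d/d_{\max}$
and exponential $e^{-2.99\,d/d_{\max}}$ (the default), both zero beyond
$d_{\max}$. Impacts are averaged over source pixels (not summed): without
that normalization degradation scales with stressor area and saturates
quality to zero for any realistic mosaic. Quality is then
$Q = H_j\,(1 - D^z/(D^z + k^z))$ with defaults $k = 0.5$, $z = 2.5$ — so
$Q = H_j$ at no degradation and exactly $H_j/2$ at $D = k$. Impact fields
are computed by FFT convolution with zero padding of one kernel radius,
which is exact for these compactly supported kernels.

## Trade-off classification and intensity

Services are compared in two modes, because "correlation between services"
is ambiguous on a raster time series. **Temporal mode** correlates the two
services *across years at each pixel*, controlling for the remaining
services — a second-order partial correlation when all four are present —
and produces r/p/category maps plus category pixel fractions. **Spatial
mode** correlates them *across pixels within each year* and produces one
classified coefficient per year. Both are first-class; outputs record the
mode.

The partial correlation uses the standard recursion (implemented for any
order); its p-value is $t = r\sqrt{(n-2-g)/(1-r^2)}$ on $n-2-g$ degrees of
freedom. Temporal mode refuses to run unless $n_\mathrm{years} - 2 - g \ge
1$: with only four annual snapshots a second-order partial correlation has
zero degrees of freedom, which is why the synthetic fixtures default to 20
years — statistical validity over literal mimicry of a four-date study
design. Classification is synergy/trade-off by the sign of significant
coefficients at $\alpha = 0.05$; raw p-values are always reported, and no
multiple-testing correction is applied across pixels (an FDR switch would be
easy to add, but the default mirrors common practice in this literature — a
known weakness, not a feature). A star-notation formatter
(`significance_stars()`) reproduces the nonstandard reporting convention
some studies use (`*` p > 0.1, `**` 0.05–0.1, `***` ≤ 0.05) but plays no
role in classification. Pixels where any service is constant across years
(e.g. zero sand fixation at permanently calm or barren cells) have undefined
correlation and are reported as nodata rather than silently dropped into a
category.

Trade-off intensity is the RMSD of min–max standardized services,
$\sqrt{\sum_i (v_i - \bar v)^2/(n-1)}$. Pairwise maps use $n = 2$, for which
the closed form $|v_1 - v_2|/\sqrt 2$ holds exactly and the maximum is
$\sqrt{0.5} \approx 0.7071$; a multi-service intensity over all four
services is available by passing more names to `rmsd_map()`. The
standardization domain is, by default, each service's valid pixels within
the analysed year; a pooled all-years domain is a switch
(`domain = "all_years"`) since either convention is defensible and the
choice changes the maps. Because standardization absorbs affine rescaling,
category and intensity maps are invariant to the services' raw units — a
property the tests check explicitly.

## Driver attribution

The response is the pairwise RMSD intensity for a chosen year (default: the
most recent — pooling years would mix land-use states) against the ten
drivers, sampled at all pixels valid in every layer. The model is a
gradient-boosted ensemble of regression trees minimizing squared error with
second-order (Newton) leaf updates and L1/L2 leaf regularization, trained
via the xgboost library. Hyperparameter defaults — 500 rounds, depth 6,
learning rate 0.05, $\lambda = 1$, $\gamma = 0$, no subsampling, one
thread — are conventional for tabular responses of this size and are logged
with every fit; single-threading makes training bitwise reproducible. Fit
quality (RMSE, R²) is evaluated on a seeded 80/20 held-out split and stored
with the model; training uses all rows, since the attribution explains the
fitted surface rather than claiming out-of-sample skill.

Attributions are tree-structured Shapley values (conditional expectations by
cover-weighted tree traversal), with the training table as background, so
the base value is the ensemble's expected prediction. Local accuracy —
prediction = base + row contributions — is checked on every call and the
maximum residual stored. It holds to single-precision round-off: roughly
2 × 10⁻⁷ per unit of prediction for small ensembles, growing with ensemble
size (about 10⁻⁶–10⁻⁵ at the 500-round default). The test suite additionally
verifies exact agreement (10⁻⁶) with a brute-force Shapley computation that
enumerates all feature coalitions on small ensembles.

Categorical drivers (land use, soil, landform) are integer-coded and split
ordinally by the trees; their attributions are summarized *per category*
(mean contribution and sign) rather than through thresholds, which matches
how per-class effects are discussed in this literature and avoids one-hot
inflation of the feature space.

Driver importance is the mean absolute contribution. The "promote/inhibit"
direction is an operationalized beeswarm reading: the sign of the mean
signed contribution among rows where the driver exceeds its median. It is an
interpretation, and it is documented as such — a driver with a U-shaped
effect gets a direction that only describes its upper half.

**Thresholds.** For continuous drivers, `detect_thresholds()` bins the
driver by quantiles (default 50 bins), averages contributions per bin,
smooths with a centred 3-bin moving average, and reports sign changes that
persist for at least 2 bins, locating each crossing by linear interpolation
between bin centres. Quantile binning keeps per-bin sample sizes equal;
persistence filtering suppresses sign flips from bin noise; the smoothing
window trades bias for variance and matters little beyond 3–5 bins. One
subtlety deserves emphasis: a Shapley attribution is centred on the model's
*mean* prediction, so for a one-sided effect such as a hinge
$(x - c)\,\mathbf{1}\{x > c\}$ the attribution crosses zero not at the hinge
$c$ but at $c + \mathrm{E}[(x - c)_+]$ — where the effect overtakes its own
average. Sign-change thresholds are therefore statements about *relative*
(above-average vs below-average) influence, which is exactly how dependence
plots are read, but they should not be conflated with structural breakpoints
of the underlying response. The tests recover planted crossings at their
analytically derived locations within one bin width.

## The synthetic county

The generator emulates the statistical structure the analysis assumes, not
any real geography: a 64 × 64 grid of 1-km cells (cell size is free — real
studies harmonize sources of 30 m–1 km resolution to a working grid, and
nothing in the pipeline depends on the choice), with elevation 1050–4000 m
falling from a northern mountain belt to southern plains, temperature
following a 6.5 °C/km lapse rate, and precipitation around 40–80 mm/yr with
orographic enhancement — an arid county of the kind this methodology is
designed for. All random fields are Gaussian with a squared-exponential
kernel (default correlation length 8 pixels), synthesized by FFT-filtering
white noise on the torus: fast, exactly seedable, and with spectral
truncation at zero the only numerical guard. Determinism is per
(seed, field, year) substream, so any single year can be regenerated
bitwise without simulating its predecessors' rasters.

Climate, NDVI and soil-moisture anomalies evolve as AR(1) processes with
persistence 0.9 and unit marginal variance, so the lag-1 autocorrelation of
any pixel's series equals the persistence parameter (the *sample*
autocorrelation at 20 years is biased low by the short-series demeaning, by
roughly $(1+\rho)/n$; the tests compare against a simulated AR(1) oracle
under the identical estimator rather than against 0.9 itself). Land use is
a quantile-thresholded latent field — class areas match the requested
proportions *exactly*, ties broken by raster order — biased by elevation so
forest sits high and construction low. One transition process operates:
each year a configurable fraction (default 1%) of cropland pixels nearest
existing construction converts to construction, emulating the urban
expansion narrative that drives habitat decline in such counties. Wind
speeds are per-pixel Weibull draws (shape 2, scale ≈ 4.5 m/s, 60
observations/year) with a spatially varying scale; soil texture sums to
exactly 100%; a smooth boundary blob masks ~5% of the grid so every stage
exercises nodata handling.

What the generator does *not* emulate: seasonal structure (everything is
annual), cross-variable feedbacks (NDVI responds to precipitation but
precipitation not to land use), measurement error, registration error
between sources, or the fat-tailed extremes of real climate. Passing tests
on synthetic data therefore demonstrates that the *pipeline* is correct —
formulas, statistics, determinism — not that any particular ecological
conclusion transfers to a real county.

## Numerical choices and degenerate inputs

* Grids are row-major with pixel-centre registration and 0-based year
  indices; all distances derive from the cell size in metres.
* FFT convolutions pad by one kernel radius, making circular wrap-around
  unreachable; negative round-off in kernels is clamped at zero.
* `minmax_standardize()` and `fractional_vegetation_cover()` treat a
  degenerate domain (max = min) as a hard error, not a silent zero.
* Zero-variance series give `NA` correlations with a warning; |r| = 1 gives
  p = 0 with a warning.
* Quantile bin edges are deduplicated before cutting, so heavily tied
  drivers cannot produce empty bins.
* Ensemble training is single-threaded; all stochastic steps (sampling,
  train/validation split, simulation substreams) derive from explicit seeds,
  and the pipeline manifest records MD5 checksums so a rerun is verifiable
  file by file.

## Problem sizes

The shipped tests run the scalar formula suite and closed-form checks at
trivial size; statistical calibration on 2 000-pixel null fields over 20
years; planted-signal recovery on 800–6 000-row tables over 10–20 seeds;
and the end-to-end determinism check on the default 64 × 64, 20-year
county — the configuration the package treats as its reference study size,
large enough for stable second-order partial correlations (18 residual
degrees of freedom) and several thousand attribution samples, small enough
to iterate comfortably on a laptop.

## Limitations

Beyond the generator's simplifications: the four service models are annual
and uncalibrated (no discharge or erosion-plot validation is attempted);
pixel-wise significance is uncorrected for multiplicity; the attribution
explains a fitted surface and inherits the usual caveats of interpreting
Shapley values on correlated drivers (importance can be shared or shifted
among collinear features); and threshold locations are attribution-relative
as discussed above. These are properties of the methodology itself, faithfully
implemented.
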