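---
title: "Methods: persistence, patch size and leverage from synoptic surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: persistence, patch size and leverage from synoptic surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synoptic)
```

## The problem

National water-quality monitoring programmes sample thousands of stream and
lake sites, but each site only once or a handful of times per multi-year
campaign. Such *synoptic* designs trade temporal frequency for spatial
extent, so the usual time-series toolkit does not apply. This package
implements the set of analyses that synoptic designs do support:

1. **Temporal change** between campaigns, restricted to repeat sites so that
   shifts in site selection between campaigns cannot masquerade as trends.
2. **Spatial persistence** — whether the *rank* pattern of concentrations
   across sites is conserved between campaigns. High persistence means a
   single campaign is representative of the long-term spatial pattern.
3. **Patch size** — the catchment-area scale at which site-to-site
   variability of standardized concentration collapses toward the regional
   mean, interpreted as the characteristic size of nutrient source and sink
   patches.
4. **Subcatchment leverage** — each subcatchment's influence on the nutrient
   flux at the regional outlet, identifying critical source areas and giving
   a first-order network mass balance.

Concentrations are analysed in mg/L; catchment areas in km². Analytes are
arbitrary labels — the conventional panel is dissolved organic carbon (DOC),
nitrate (NO3), total nitrogen (TN) and total phosphorus (TP), but ions and
physiochemical parameters pass through unchanged.

## Data model and normalization

The exchange format is a long CSV, one measurement per row (campaigns
measure different analyte panels, so a wide layout would be mostly empty).
Sites are matched across campaigns by `site_id` string equality only;
monitoring programmes reuse site identifiers, and coordinate-based fuzzy
matching would introduce silent mismatches.

Two normalization steps precede every analysis:

* **Nondetects.** Values below the analytical detection limit are recorded
  as zero in source data. Zeroes break log transforms and percent
  normalizations, so they are replaced by half the detection limit, the
  standard substitution. A zero with no recorded limit cannot be
  substituted; it is excluded and flagged rather than guessed at.
* **Revisit averaging.** Sites sampled repeatedly within one campaign are
  collapsed to their arithmetic mean concentration per analyte. Site
  metadata must be identical across a site's records within a campaign;
  conflicts are a hard error listing the sites, because there is no
  defensible automatic resolution.

Records with missing catchment area are retained for the temporal and
persistence analyses (which do not use area) and excluded from patch-size
and leverage analyses (which do) — national surveys commonly lack area for a
large minority of sites, and discarding those records everywhere would waste
most of the repeat-site panel.

## Temporal change

For each consecutive campaign pair, group and analyte, the repeat-site panel
is tested with a two-sided paired t-test. Right-skewed panels are
log-transformed first; the conventional visual normality check is replaced
by a deterministic rule — transform when either campaign's values have
|sample skewness| > 1 — because a reproducible pipeline cannot depend on
eyeballing Q-Q plots, and water chemistry is near-universally
log-transformed anyway. The reported percent change is always computed on
raw means, `100 (mean_b − mean_a) / mean_a`, so magnitudes are in familiar
concentration terms regardless of the test scale.

Decisions use a per-test α of 0.05 (configurable). No multiple-testing
correction drives the `significant` flag — the per-test convention is how
survey programmes report — but a Benjamini–Hochberg adjusted column is
emitted alongside so readers can apply a stricter standard. Degenerate
panels (zero variance of paired differences) are reported with p = 1 and a
flag instead of an error, since exact ties arise in rounded data.

## Spatial persistence

Persistence is the Spearman rank correlation of repeat-site concentrations
between two campaigns: Pearson correlation of average-ranked values, robust
to the extreme values common in aquatic chemistry. For every campaign pair
with at least `min_n` shared sites (default 10 — rank correlations of a
handful of sites are noise; the cutoff is configurable) the correlation is
computed, and the per-cell summary is the arithmetic mean over retained
pairs. The qualitative threshold is √0.5 ≈ 0.71, applied to the mean: above
it, more than half of the spatial pattern persists. Cells with no retained
pair report an explicit "insufficient data" status.

Lake and stream persistence are compared across ecoregion × analyte cells by
ordinary least squares of lake on stream mean correlation; under the
no-difference expectation the fit approaches slope 1, intercept 0, R² ≈ 1.

## Patch size by variance collapse

Within a group, concentrations are standardized (subtract the group mean,
divide by the group *population* standard deviation — the divide-by-n
convention makes "variance of z = 1" exact, and at survey sample sizes the
distinction is immaterial) and ordered by catchment area, ties broken by
`site_id`. Variance changepoints of the ordered series are then located and
the area at which variance *decreases* is read off as the patch size.

**Cost model.** Because the series is standardized, segments are modelled as
zero-mean Gaussian with segment-specific variance; the cost of a segment is
twice its negative log-likelihood at the ML variance,
`n (log 2π + log σ̂² + 1)` with `σ̂² = mean(z²)` floored at 1e-12 so
constant segments stay finite. Modelling the mean as well would spend
parameters on a quantity the standardization has already removed.

**Search.** The penalized optimum (`Σ segment costs + penalty × number of
changepoints`) is found exactly by a PELT dynamic programme. Splitting a
segment never increases its total ML cost, so the pruning constant is 0. One
subtlety: with a minimum segment length, a candidate dominated at time *t*
is only provably useless once the dominating position itself is usable
(i.e. for times ≥ *t* + `min_seg_len`); pruned candidates therefore survive
for that grace period. Without it, pruning can miss the optimum — the test
suite checks exact agreement with exhaustive enumeration on hundreds of
random series.

**Parameters.** The default penalty is BIC-scale, `2 log n` per changepoint;
`min_seg_len` defaults to 10 (a patch claimed from fewer than ten sites is
not interpretable, and longer segments also blunt single-point triggers).
Groups with fewer than `2 × min_seg_len` sites report "not determinable"
rather than failing — small ecoregions genuinely cannot support the
analysis.

**Screening.** Single extreme sites can still trigger spurious breaks. Each
changepoint is re-examined after deleting the single largest |z| from either
adjacent segment; if any deletion (or the undeleted segments themselves)
drops the between-segment variance ratio below `retention_ratio` (default
2), the changepoint is rejected with a recorded reason. This is a
deterministic replacement for the manual review such analyses traditionally
require.

**Threshold extraction.** At each retained changepoint where downstream
(larger-area) variance is lower than upstream, the area of the first
downstream site is a collapse threshold. Heavy-tailed data can yield several
small-scale decreases where clusters of extreme sites are carved out; the
*primary* threshold — the patch size proper — is defined as the largest-area
retained decreasing changepoint, the scale above which the series stays
collapsed toward the regional mean. Variance *increases* are reported but
never counted as collapse thresholds.

## Subcatchment leverage

With discharge unmeasured at survey sites, specific discharge (runoff per
unit area) is assumed constant within a group, so catchment area proxies
discharge. The outlet is the largest measured catchment in the group (ties
broken by smallest `site_id`); each other site's raw leverage is

> (C_i − C_out) × (a_i / a_out)   [mg/L]

and percent leverage normalizes by the outlet concentration,
`100 × raw / C_out` — the only normalization consistent with interpreting
leverage as a share of outlet flux under the constant-discharge assumption.
Positive leverage marks a source, negative a sink; values far above 100% are
legitimate and mark critical source areas whose inputs must be removed or
diluted in transit.

The group mean percent leverage estimates the network mass balance: positive
means in-network removal, negative means production. Means within ±0.5
percentage points (configurable) are called neutral — a dead-band is needed
because means of order 1% are indistinguishable from conservative mixing
given the method's assumptions. The critical-source fraction sorts positive
raw leverages descending and reports the smallest fraction of *all*
subcatchments whose cumulative source leverage reaches `flux_share`
(default 75%) of the total positive leverage. Total positive leverage (not
net, not outlet flux) is the denominator because the quantity of interest is
the share of source flux; this is configurable and documented rather than
hidden. The outlet is excluded from its own summary. Every leverage output
carries the constant-specific-discharge caveat.

## The synthetic survey generator

Real national survey data require downloads and licensing gymnastics; the
generator produces tables with exactly the statistical structure the
analyses assume, so the whole pipeline is testable offline:

* **Lognormal concentrations** (right-skewed, like real chemistry), with
  per-analyte baseline `mu_log`/`sigma_log`. Defaults are typical stream
  values (DOC ≈ 5, NO3 ≈ 0.2, TN ≈ 0.8, TP ≈ 0.05 mg/L, log-sd 0.6–1.1).
* **Persistence** from a permanent per-site effect carrying a fraction
  `persistence_share` of the log-variance. Two campaigns' log values at a
  shared site are then bivariate normal with Pearson correlation equal to
  the share, so the recovery target for the Spearman analysis is the closed
  form `(6/π) asin(share/2)` (`expected_rank_persistence()`).
* **Patch structure**: sites with area below `patch_area_km2` have both
  variance components inflated by `patch_variance_ratio` (default 250 km²
  and 4; ratio 1 disables it), reproducing small-catchment variance
  inflation at a known scale.
* **Critical sources**: a `source_fraction` (default 5%) of small-catchment
  sites have concentrations multiplied by `source_multiplier` (default 10).
* **Areas** log10-uniform on `area_log10_range` (default 0.1–10,000 km²),
  with one designated largest-area outlet per ecoregion × waterbody cell.
* **Nondetects**: values below `detection_limit_mgL` written as zero with
  the limit recorded; **trends** as per-campaign multiplicative shifts;
  **repeat sites** as a configured fraction of consecutive campaigns' panels.
* A **conservative-network mode** sets the outlet's area to the sum of the
  subcatchment areas and its concentration to their area-weighted mean, so
  the leverage zero-sum identity holds exactly; nondetect zeroing is skipped
  in this mode so rounding does not perturb the identity.

Site-level draws flow from the configured seed; each campaign's sampling
noise uses a sub-stream keyed by campaign index, so identical configurations
are byte-reproducible and adding a campaign does not disturb earlier ones.

What the generator does *not* emulate: hydrological routing and nested
catchments, seasonality, spatial autocorrelation beyond the patch term, and
any calibration to a real survey's concentration distributions. Passing
recovery tests therefore demonstrates that the estimators recover known
structure under the stated model — not that real data satisfy that model.

## Validation sizes and numerical choices

The test and acceptance suites run, on one CPU in a few minutes: oracle
equivalence of the rank correlation on 200 random vectors (tolerance 1e-12);
exact PELT–exhaustive agreement on 200 random series of n ≤ 30; persistence
recovery at shares 0.3/0.6/0.9 with 500 sites × 3 seeds (within ±0.05 of the
closed form); patch recovery of a 100 km² patch at 9:1 variance ratio with
800 sites (within a factor of 3 in ≥ 4 of 5 seeds); the leverage zero-sum
identity to 1e-9 on 20 random conservative networks; paired-test type-I
error on 200 null panels of 50 pairs (within [0.02, 0.09] at α = 0.05) and
recovery of a 0.7× trend with 200 repeat sites; and a ≤ 5% screened
changepoint rate on 100 null series of length 200. These sizes were chosen
as the smallest at which the sampling error of each check is comfortably
below its tolerance.

Numerical conventions collected in one place: variance floor 1e-12
everywhere a variance is a divisor or log argument; population (divide-by-n)
variance in standardization and rank computations; area ties broken by
`site_id`; outlet ties broken by smallest `site_id`; skewness of constant
samples defined as 0; degenerate paired tests report p = 1 with a flag;
empty panels warn rather than error.

## Known limitations

* Leverage inherits the constant-specific-discharge assumption wholesale;
  in regions where specific discharge varies strongly between sites the
  source/sink attribution can be biased, and no discharge correction is
  attempted.
* Grouping by ecoregion violates the nested-subcatchment assumption of the
  leverage formula; results are comparative within a group, not a routed
  mass balance.
* The patch-size penalty and minimum segment length are conventions, not
  estimates; different choices shift thresholds, which is why they are
  explicit configuration.
* Percent changes are raw-mean based; median- or geometric-mean-based
  percentages from the same data will differ.
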