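---
title: "Methods: callosal developmental morphometry with ccmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: callosal developmental morphometry with ccmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

ccmorph studies how the midsagittal cross-section of the corpus callosum —
the largest inter-hemispheric commissure — grows from infancy to early
adulthood, and whether that growth differs between the sexes. A binary
midsagittal mask is partitioned geometrically into the seven Witelson
subregions (rostrum, genu, rostral body, anterior midbody, posterior
midbody, isthmus, splenium) and the subregion areas, together with
whole-brain volume, form one record per subject. Per sex and per measure,
a robust locally weighted regression (lowess) of area against age yields a
smooth developmental trajectory; its month-to-month percentage change (the
growth-change rate) localises the ages at which each subregion attains a
local maximum. Cohort-level contrasts use a mixed-design repeated-measures
ANOVA (region within subjects, sex and age group between subjects) with
Tukey–Kramer post hoc comparisons, and Mann–Whitney U tests on
brain-normalised area ratios for sex differences.

```{r}
library(ccmorph)
cohort <- generate_cohort(seed = 1)
dplyr::count(cohort, sex)
```

## Witelson parcellation of a raster mask

The parcellation is purely geometric. The principal axis joins the centres
of the most anterior and most posterior foreground pixels; when several
pixels tie in the extreme column, the median row of the tied run is used at
both ends so that an axis-aligned bar gets a horizontal axis rather than a
corner-to-corner diagonal. Every foreground pixel centre is projected onto
the axis, giving a position $u \in [0, L]$ along the total length $L$, and
the classical length fractions define half-open primary slabs: the anterior
third $[0, L/3)$, anterior midbody $[L/3, L/2)$, posterior midbody
$[L/2, 2L/3)$, isthmus $[2L/3, 4L/5)$ and splenium $[4L/5, L]$ (closed at
$L$ so no pixel escapes). Projections are clipped to $[0, L]$, which keeps
pixels beyond the extreme columns (possible on curved shapes) inside the
end slabs.

The anterior third must be split into genu, rostrum and rostral body, and
this is the one place where a published-diagram convention has to be
operationalised for rasters. ccmorph uses the ventral notch under the genu:
a column of the anterior third whose foreground splits into two or more
vertically disjoint runs is a *notch column*, and pixels in lower runs are
the rostral spur (rostrum, label 1). The genu/rostral-body boundary is then
placed at $u_Q$, the projection of the most anterior rostrum pixel — the
spur's origin. An earlier draft used the smallest projection within the
first notch column instead; that definition is unstable under resolution
changes because a column's vertical extremes move with the axis tilt,
whereas the spur origin converges at the pixel scale. Convex masks have no
notch: the rostrum is then empty and the anterior third is split at its
midpoint ($L/6$ of the total length, configurable via `fallback_split`).
This notch rule is one defensible reading of the classical diagram, not the
only one, and it is deliberately isolated behind `partition_witelson()`.

On a 90 mm by 20 mm rectangle at 1 mm/pixel the slabs are exact: areas
0, 300, 300, 300, 300, 240 and 360 mm², i.e. fractions 1/3 (anterior
third), 1/6, 1/6, 2/15 and 1/5 of the 1800 mm² total:

```{r}
partition_witelson(generate_cc_mask("rectangle", 90, 20, spacing = 1))$areas
```

Masks must be nonempty, single 8-connected components with positive pixel
spacing; components are counted on an igraph pixel-adjacency graph. Masks
are assumed already midsagittally oriented (rows superior to inferior,
columns anterior to posterior); reorienting 3-D acquisitions is out of
scope.

## Robust lowess trajectories

The smoother is Cleveland's robust locally weighted regression, written out
in full because its details are the contract of the trajectory stage. At
each evaluation age $x_0$ the $q = \lceil \alpha n \rceil$ nearest
observations by age distance form the neighbourhood (distance ties all
enter); weights are tricube $w(z) = (1 - |z|^3)^3$ in the scaled distance
$z$; a weighted degree-1 polynomial is evaluated at $x_0$. Robustness
iterations compute residuals $r$ at the observed ages, set
$m = \mathrm{median}|r|$, reweight by the bisquare
$B(r) = (1 - (r/6m)^2)^2$ for $|r| < 6m$ and zero otherwise, and refit;
the defaults are $\alpha = 0.75$ and four iterations, the settings used
throughout the developmental analysis this package operationalises. When
$m$ collapses to zero mid-iteration — the bulk of the data fitted exactly,
as happens with noise-free fixtures plus an outlier — points with
essentially zero residual keep weight one and the rest are rejected
outright, which is the limiting behaviour of the bisquare. Degree 0 and 2
local fits and the iteration count are configurable; the local solve uses
`lm.wfit`, whose pivoting also handles degenerate neighbourhoods (a single
distinct age collapses to a weighted mean). Neighbourhoods with zero age
spread raise an error, as do strata with fewer than five points. The fit is
evaluated at every integer month between the youngest and oldest observed
age, because the downstream statistic is monthly. Agreement with
`stats::lowess` is at the $10^{-9}$ level on shared evaluation points
(tested), but the implementation here is independent, evaluates on an
arbitrary grid, and reports its configuration.

One caveat surfaced by the validation suite: local linear fits may
overshoot the data range by a sliver (about 1% of the range on a concave
monotone fixture), so "fitted values stay within the data range" holds only
up to that tolerance.

## Growth-change rate and growth peaks

The monthly growth-change rate at month $t$ is
$100 \, (v_t - v_{t-1}) / v_t$, the change expressed as a percentage of the
*present* month's smoothed value — note the denominator; the statistic is
therefore scale-invariant but not symmetric in time. Months with a zero
smoothed value are flagged undefined rather than dropped. A growth peak (a
local maximum of the trajectory) is a month with strictly positive rate
followed by a zero-or-negative rate — the positive-to-nonpositive zero
crossing — excluding grid endpoints. `fit_all()` applies the chain to all
16 strata (2 sexes × 7 subregions + total), skipping strata with fewer
than five subjects with a warning.

## The synthetic cohort generator

No subject-level data are distributable for this kind of study, so the
generator is a first-class module, not a test fixture. Each (region, sex)
stratum follows a saturating-exponential rise with an optional quadratic
post-peak decline,
$$m(t) = A\,(1 - e^{-t/\tau}) - d\,\max(0, t - t_{peak})^2,$$
multiplied by unit-mean lognormal noise with coefficient of variation `cv`
(areas are positive and their spread grows with size, which is what the
published group SDs look like). The total callosal area is the exact sum of
the seven subregions. Whole-brain volume rises exponentially from a
neonatal volume (~450–480 mL) to a sex-specific plateau (males higher),
which reproduces the observation that callosal/brain *ratios* run slightly
higher in females even when raw areas are similar. The parametric form is a
stand-in chosen so that a unique interior local maximum exists; the
published analysis fits no parametric model, and nothing downstream depends
on this form.

The default design reproduces the published recruitment cells — males
19/18/17/7 and females 10/21/15/7 across infants (≤ 24 months), children
(25–120), adolescents (121–215) and adults (216–300); 114 subjects — with
ages drawn uniformly within each cell's month range (no attempt to model
recruitment density inside a cell). Default asymptotes (18–172 mm² per
region), time constants (~20 months, giving the marked rise over the first
two years), late-adolescent peak ages and `cv = 0.15` are loose
calibrations to the magnitude and dispersion of the published group means;
they are synthetic stand-ins, not estimates. One master seed drives
everything; each subject's draws come from a stream derived from the seed
and the subject's position, so a subset of the design regenerates
identically (tested).

What the generator does *not* emulate: recruitment density within cells,
measurement error from tracing real MRI, rater effects, left-right or
handedness structure, and any covariance between regions beyond the shared
age trend. Tests passing on synthetic cohorts therefore validate the
*machinery* (geometry, smoothing, statistics), not claims about real
callosal development.

## Growth-peak recovery: design and an honest limitation

`peak_recovery_study()` is the package's built-in parameter-recovery check:
20 replicate cohorts (200 subjects/sex, ages uniform on 1–300 months,
`cv = 0.05`) with a generative peak at `t_peak = 210` months, scored as
recovered when a detected peak lies within ±12 months. The recovery model
(`flat_growth_model()`: every region $A = 70$, $\tau = 60$, $d = 0.004$)
gives the total curve a single well-defined interior maximum near 213
months; a plateau-by-age-3 model ($\tau \approx 15$) would leave
essentially no rising slope near the peak and no smoother could localise
it — a recovery benchmark must contain the signal it tests for.

The recovery fits use span 0.4, not the cohort-analysis default 0.75, and
this is a deliberate, documented choice: with $\alpha = 0.75$ the
neighbourhood spans roughly half the 300-month age range, the post-peak
decline is averaged into the plateau, and the detected crossing is
displaced about 30 months early in *every* replicate — a bias of the
bandwidth, not of the implementation. At span 0.4 (neighbourhood roughly
±60 months) the peak is recovered in 20/20 replicates, and spans 0.3 and
0.5 behave the same, so the result is not knife-edge. The flip side is a
genuine limitation worth stating: wide-span lowess (as used for the
published developmental figures) localises late-adolescent growth peaks
poorly, and printed peak ages from such fits carry a bandwidth-dependent
uncertainty of months to a few years. Detected peaks also jitter: near the
maximum the rate hovers around zero and noise can produce several
crossings within a decade; the study counts a replicate as recovered when
*any* crossing falls in the window, and reports the crossing nearest the
target.

## Cohort statistics

Age groups follow the published year boundaries converted at 12
months/year, with the printed inequalities honoured exactly: infant ≤ 24,
child (24, 120], adolescent (120, 216), adult [216, 300].

The mixed-design ANOVA treats region as a 7-level within-subject factor
and sex and age group as between-subject factors, computed via
`car::Anova` on a multivariate linear model with sum-to-zero contrasts and
read from its univariate repeated-measures table. Between-subject effects
are tested against subjects-within-cells (denominator df $n - 8$ for the
full 2 × 4 design; 106 at $n = 114$) and region terms against the
region-by-subject error (df $6(n-8)$; 636), with no sphericity correction
— the published dfs are the uncorrected univariate ones. The design is
unbalanced, and the publication does not state its sum-of-squares type;
marginal (Type III) sums of squares are the default and Type II is a flag.
An explicit cell-means sums-of-squares oracle in the test suite pins the
balanced case, where the types coincide. Empty or single-subject
sex-by-age cells raise errors naming the cell; unused age-group levels are
dropped so partial-range cohorts remain analysable.

Post hoc comparisons are Tukey–Kramer (studentized range with unequal-n
standard errors $\sqrt{MS_e/2\,(1/n_i + 1/n_j)}$), flagged significant at
$p < 0.001$ — the Bonferroni gate for seven subregions — while the omnibus
level stays 0.05. At $k = 2$ the Tukey $p$ equals the pooled two-sample
$t$ $p$ ($q = t\sqrt{2}$), which the tests exploit as a closed-form
cross-check. The pooled two-sample $t$ from summary statistics exists
because cohort age comparisons are published only as mean ± SD; applied to
the printed age summaries it returns $t = -1.227$, df 112. Mann–Whitney U
uses midranks, the tie-corrected normal approximation for $Z$, and no
continuity correction by default (the publication reports $Z$ values
without method details; continuity correction is a flag). Identical-value
degenerate samples are flagged rather than divided by zero. Ratios are
area (mm²) over whole-brain volume (mL), unitless as printed (~0.42 for
the total), and each record's subregion ratios sum exactly to its total
ratio.

`summarize_groups()` reproduces the published tables' layout (mean ± SD by
region × sex × age group, and ratios by region × sex), reporting SD = 0
for single-subject cells. `flag_total_mismatch()` checks the linearity
identity — a cell's total mean must equal the sum of its seven region
means — and flags violations instead of reproducing them; on the shipped
reference summaries it isolates exactly one printed cell (male adults)
whose total is inconsistent with its own region means, an apparent
transcription slip in the source table.

## Numerical and design choices

- Pixel centres, not corners, are projected; areas are pixel counts times
  the pixel footprint. Halving the spacing on a converged rasterisation
  moves every subregion area by under 2% (tested at 0.1 → 0.05 mm on a
  fixture with generic, non-grid-aligned parameters; coarser grids or
  edges lying exactly on pixel-centre lines can double that for the small
  rostrum).
- Growth-model validation rejects parameter sets whose mean area would go
  nonpositive anywhere on 1–300 months (the quadratic decline makes this
  easy to do by accident).
- Problem sizes in the test and acceptance runs — 114-subject default
  cohorts, 200/sex recovery cohorts, 20 replicates, masks at 0.1–1
  mm/pixel — keep the full suite in the minutes range on one core while
  leaving every statistic in its asymptotic regime.
- CSV I/O is comma-separated, UTF-8, dot-decimal with a mandatory header;
  doubles survive a round trip to ~1e-15 relative (text formatting), which
  is treated as identity everywhere it matters.
- The pipeline manifest records the seed, a configuration hash, package
  and R versions, stage warnings and every output file; rerunning the same
  configuration reproduces the outputs byte for byte.

## Known limitations

Masks are parcellated as given: no segmentation from grey-scale images, no
midsagittal plane estimation, no thickness or shape analysis. The
rostrum/genu notch rule is a convention; alternative readings of the
classical scheme would move a few percent of the anterior area between
labels 1–3. Lowess confidence bands are not provided, and, as above,
wide-span fits localise late peaks poorly. The synthetic generator's
parametric growth form is convenient, not mechanistic; published group
means, F, Z and peak ages from the source cohort derive from raw scans
that are not available, so the package reproduces their *structure*
(degrees of freedom, table identities, formula values) and validates
recovery on synthetic data rather than asserting those numbers.
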