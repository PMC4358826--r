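---
title: "Models and methods behind objdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind objdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(objdens)
```

## The environmental model

The package is built around one empirical regularity: for everyday
liftable, man-made objects, density is a decreasing power function of
volume,

$$ d = c\,V^{\gamma}, \qquad \gamma < 0, $$

with $d$ in g/cm³ and $V$ in cm³. Weight is treated as functionally
equivalent to mass throughout (gravitational acceleration is constant
across objects, so it cancels from every ratio the package computes).
After a natural log transform the relationship is linear,
$\ln d = \ln c + \gamma \ln V$, so the analysis stack is: log-transform,
Pearson correlation (`log_log_correlation()`), ordinary least squares
(`fit_power_law()`). Natural logs are used everywhere; correlations are
therefore invariant to unit changes, and $\gamma$ is dimensionless.

p-values for $r$ use the exact transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, two-sided. For a noiseless
power-law population $|r| = 1$ and the transform degenerates; the p-value
is clamped to the smallest positive double rather than erroring, so
perfect-fit fixtures remain usable.

### Pair ratios

For a pair with $V_S < V_L$, define $VR = \ln(V_S/V_L) < 0$,
$WR = \ln(w_S/w_L)$, $DR = \ln(d_S/d_L)$. Since $d = w/V$,

$$ DR = WR - VR $$

holds *identically*, not statistically. Two consequences the package
asserts to machine precision: the OLS density line over any pair set
equals the weight line with slope reduced by exactly 1 and the same
intercept; and predictions satisfy
$\widehat{d_S/d_L} = \widehat{w_S/w_L} \cdot (V_L/V_S)$ at every volume
ratio. Pairs are the full factorial half with $V_1 < V_2$
($n(n-1)/2$ of them); equal-volume pairs have no small/large orientation
and are dropped with a warning. The pair set is deliberately not
deduplicated or reweighted — the statistical non-independence of factorial
pairs is a property of the original analysis that the package reproduces,
not corrects.

### Canonical ratio convention

All ratios are small/large (values in $(0,1]$, logs $\le 0$). "Smaller is
denser" then reads $d_S/d_L > 1$, and a density prior *raises* log weight
ratios toward zero. The ratio views (`predict_ratio()`,
`density_ratio_from_weight()`) exponentiate at the edges; everything
internal stays in log space.

## Object tables

Volumes from survey-style sources are bounding-box products of
length × width × height (`volume_from_dims()`), flagged
`volume_method = "box_dims"` so analyses can stratify by measurement
coarseness; precomputed volumes from ruler-and-geometry decomposition are
accepted as-is (the decomposition itself is not reconstructable from
published tables). Units are normalized at parse time to cm³ and g (m³,
mm³, L, in³; kg, mg, oz, lb; m, mm, in). Rows with missing or
non-positive volume/weight are dropped and logged, never imputed.
Dataset labels D1–D3 (artificial, liftable), D4 (natural, liftable) and
D5 (artificial, unliftable) enforce their class labels at construction.

## Mesh volumes

The scanned route to volume ends in a triangle mesh; the package computes
its enclosed volume by the divergence theorem as the sum of signed
tetrahedron volumes $\mathbf{v}_0 \cdot (\mathbf{v}_1 \times
\mathbf{v}_2)/6$ per face. Preconditions are checked, not patched:
every undirected edge must be shared by exactly two faces traversing it in
opposite directions (watertight + consistently oriented). Repairable
orientation inconsistencies are fixed by flood fill over shared edges at
load time; holes are refused — how non-watertight scans should be closed
is a scanning-pipeline question the package deliberately does not answer.
A globally inward-oriented mesh yields $|V|$ with a warning. Validation is
analytic: boxes are exact, icospheres (vertices exactly on the sphere)
converge to $\tfrac43\pi r^3$ monotonically from below, and volume is
invariant under rigid motion and additive over disjoint components.
Internal cavities are invisible to a viewer, which is the measurement's
rationale; nested shells are not specially detected beyond the outer-hull
orientation pass.

## Perceptual analysis

Reports arrive in reference-10 units: the left object is worth 10, the
subject prices the right one. Normalization maps both presentation orders
onto the canonical log small/large ratio — `ln(10/report)` when the small
object is on the left, `ln(report/10)` otherwise — so "20" (S-L) and "5"
(L-S) both mean "the larger is twice the smaller". Per-subject cell means
collapse the two orders (20 trials per subject × set × pair).

Statistical machinery, all hand-rolled and oracle-tested:

- **Lilliefors test**: $D = \sup|F_n - \Phi_{\hat\mu,\hat\sigma}|$ with
  parameters estimated from the sample. The null distribution is built by
  seeded Monte Carlo on standard-normal samples of the same $n$ (location
  and scale cancel, so this null is exact), default 10⁴ replicates. This
  was chosen over closed-form approximations for transparency: the null is
  literally the definition, and the test suite checks the simulated 95th
  percentile at $n = 20$ against the tabulated 0.19.
- **Split-plot ANOVA** (`mixed_anova()`): one between-subjects factor
  (condition), one or two within-subjects factors (object set, pair).
  Classical balanced sums-of-squares decomposition: the condition effect is
  tested against subjects-within-groups; each within effect and its
  condition interaction against the matching subject × factor stratum; the
  three-way terms against the subject × set × pair stratum. Degrees of
  freedom are the classical uncorrected ones — no sphericity correction,
  matching the analysis being reproduced. Unbalanced or incomplete designs
  are refused outright rather than approximated; the test suite verifies
  every F and p against `aov()` with explicit `Error()` strata.
- **FDR**: Benjamini–Hochberg step-up, $q_{(i)} = \min_{j \ge i} m\,
  p_{(j)}/j$. The published per-pair table's "FDR" column (values around
  0.0013–0.0019) is *not* what BH step-up produces from the printed
  p-values (BH gives 0.036–0.042); the exact variant behind those numbers
  is ambiguous, so the package implements the standard method and does not
  chase the printed column.
- **Effect sizes**: Cohen's d with the pooled $n-1$ standard deviation.
- **Perceptual lines**: for the Expected-Weight group, OLS of the
  across-subject mean log ratio (one point per pair, six points) on the
  true log volume ratio, per object set; pooled-mean OLS was chosen over
  per-subject fits because only the pooled coefficients are published and
  the two differ only in weighting. Density lines are derived (slope − 1,
  same intercept), never refitted.
- **Volume-underestimation t-tests** use per-subject mean log errors
  (report minus true) per object set — the per-subject-mean reading of
  "t-tests against 0", since trial-level tests would have inflated df.

## Synthetic data: the stated world

The generators exist so that every analysis stage is testable without the
original deposited data. Their defaults are fixed once:

- **Objects** (`env_gen_config()`): $n = 195$ (the pooled liftable
  man-made sample size); volumes log-uniform on $[\ln 10, \ln 4000]$ cm³
  so factorial pairs cover the experimental volume-ratio range down to
  $1/27$ with margin; $\gamma = -0.387$ (the pooled density-line slope);
  $c = 2$ g/cm³ at 1 cm³ (small everyday objects near water's density,
  large ones far below it); log-scatter sd 0.95, which with this volume
  spread puts the population's log-log correlation near the observed
  pooled $r \approx -0.57$ (sd of $\ln V$ is $\ln(400)/\sqrt{12} \approx
  1.73$, so $r = \gamma\sigma_{\ln V} / \sqrt{\gamma^2\sigma_{\ln V}^2 +
  \sigma^2} \approx -0.57$ at $\sigma = 0.95$).
- **Observers** (`observer_gen_config()`): 10 per group, the complete
  3 set × 6 pair × 2 order × 10 trial design. Per trial the perceived log
  volume ratio is $L_p = \beta \cdot VR + b_s + \varepsilon$ with
  compression $\beta = 0.85$ (consistent volume underestimation; the
  power-law form of the compression is a modeling choice, the literature
  gives no functional form), a per-subject bias $b_s \sim N(0, 0.6^2)$
  (ratio-scaling idiosyncrasy — the dominant error stratum in real
  magnitude-estimation data; 0.6 puts the planted overall condition effect
  size near the observed $d \approx 1.2$, i.e. $F(1,18) \approx 7.5$), and
  trial noise $\varepsilon \sim N(0, 0.25^2)$. PV observers report $L_p$;
  EW observers report $L_p + \text{prior}(L_p)$ where the prior is the
  environmental density line $(-0.387, 0.114)$. The prior is evaluated at
  the *perceived* (compressed) log ratio by default — observers have no
  access to true volume — with a `prior_on = "true"` toggle for
  plant-and-recover tests. Optional integer rounding of reports is off by
  default.
- All generators are bit-reproducible given (config, seed), and generated
  populations satisfy $d = w/V$ identically by construction.

What a green synthetic test establishes: that the estimators recover
planted parameters, that the exact identities hold on arbitrary data, and
that null worlds produce nominal false-positive rates. What it does not
establish: that the real deposited datasets yield the published numbers —
the generator's populations are lognormal-scatter power laws and its
observers are linear-in-log reporters, while real object tables have
heavy-tailed, category-structured scatter and real subjects quantize,
drift and anchor. The two acceptance tests that need the deposited data
fail explicitly when the converted CSVs are absent rather than being
silently skipped.

## Numerical choices and edge cases

- OLS is computed from centered sums (numerically adequate at these sizes;
  no QR needed for simple regression).
- `residual_sd` of the power-law fit uses divisor $n$, so it is exactly 0
  for noiseless inputs.
- Correlation p-values are clamped to the open interval; ANOVA F on a
  zero-variance error stratum yields `NaN`/`NA` rather than an error, so
  noiseless plant-and-recover worlds still run end to end.
- Equal-volume pairs: dropped (a $VR = 0$ pair has no orientation).
- Ratio-line prediction refuses volume ratios outside $(0, 1]$: the
  convention is one-sided by construction.
- Seeds: every stochastic entry point takes an explicit seed; internal
  derived seeds stay below $2^{31}$.

## Known limitations

- The mixed ANOVA handles exactly one between-subjects factor and at most
  two within factors, balanced only — the design it exists for.
- No errors-in-variables treatment of volume measurement noise; the
  bounding-box volumes of survey rows are coarse by construction and only
  flagged, not corrected.
- The observer model is forward-only; fitting it to real trial data is
  future work.
- Mesh repair is limited to orientation; holes and non-manifold edges are
  refused.
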