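---
title: "Global clustering tests with weight-adjusted Moran statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global clustering tests with weight-adjusted Moran statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranmod)
```

## The problem

Given case counts $y_i$ and populations at risk $n_i$ over $N$ geographic
units (census tracts, counties, lattice cells), a *global* clustering test
asks whether the map as a whole shows spatial structure — a broad trend or a
diffuse correlation — as opposed to pinpointing a single hot spot. moranmod
implements three such statistics and a Monte Carlo testing procedure for
them, together with the simulation machinery needed to study their power.

## The statistics

**Classic Moran's I.** With spatial weights $w_{ij}$ ($i \ne j$) and
$\bar y = y_+/N$,

$$I = \frac{N}{S_0}\,
      \frac{\sum_{i \ne j} w_{ij}(y_i-\bar y)(y_j-\bar y)}
           {\sum_i (y_i-\bar y)^2},
  \qquad S_0 = \sum_{i \ne j} w_{ij}.$$

$I$ usually lies in $[-1, 1]$ (its exact range depends on the weight
function; we do not clamp it), positive under spatial clustering and near
$-1/(N-1)$ under complete spatial randomness.

**Modified Moran's I.** In $I$ the weights enter the cross-product but not
the variance. Pairs that contribute more to the differences should also
contribute more to their variation, so the modified statistic carries the
weights into the denominator:

$$I_w = \frac{N}{S_0}\,\frac{\sum_{i \ne j} w_{ij}(y_i-\bar y)(y_j-\bar y)}
        {s^2_{y,w}},
  \qquad
  s^2_{y,w} = \frac{N}{S_0}\sum_{i \ne j} w_{ij}\,
      \frac{(y_i-\bar y)^2 + (y_j-\bar y)^2}{2}.$$

This symmetric-average form is adopted because it makes the defining
property provable rather than merely plausible: when all off-diagonal
weights are equal and positive, $s^2_{y,w}$ reduces algebraically to
$\sum_i (y_i-\bar y)^2$ and $I_w = I$ exactly (a property the test suite
asserts to $10^{-10}$), and by the AM–GM inequality it keeps $|I_w| \le 1$
whenever the weights are nonnegative. The component `iw_le_i` reports
whether $s^2_{y,w} \ge s^2_y$, the condition under which the weighting
shrinks the statistic. The sampling distribution of $I_w$ depends on the
weight function and is not tractable, hence the Monte Carlo inference below.

**Oden's I_pop.** Count-based Moran statistics confound spatial structure in
the *cases* with spatial structure in the *populations*. I_pop adjusts for
population heterogeneity; it is what one obtains by applying Moran's I to
the $n_+$ individual case indicators rather than to the $N$ regional counts.
Writing $v_i = n_i/n_+$, $e_i = y_i/y_+$, $\hat b = y_+/n_+$ and
$A_i = y_i - \hat b\,n_i = y_+(e_i - v_i)$,

$$I_{pop} =
  \frac{\sum_{i \ne j} w_{ij} A_i A_j
        + \sum_i w_{ii}\!\left[A_i^2 - y_i(1-\hat b)^2 - (n_i-y_i)\hat b^2\right]}
       {\hat b (1-\hat b)\left[\sum_{i \ne j} w_{ij} n_i n_j
        + \sum_i w_{ii}\, n_i(n_i-1)\right]}.$$

The off-diagonal part is the spatial cross-product of the rate deviations
(it vanishes exactly when every region has the same rate, $e_i = v_i$); the
$w_{ii}$ part is a chi-square-like heterogeneity term analogous to the
conventional chi-squared test for heterogeneity of rates. Symmetry of the
weights is not required, and the diagonal may be kept or masked
(`wii_policy`): the package keeps it when the weight scheme defines one (PD)
and masks it for adjacency weights, whose diagonal is structurally zero.
This individual-level derivation was chosen because every documented
property of the statistic — the proportions it uses, the role of $w_{ii}$,
its behaviour under uniform rates, scale invariance — follows from it
rather than having to be imposed; the unit tests verify it against a
hand-written term-by-term transcription on a three-region toy and against
naive double-loop oracles on random instances.

## Weight schemes

**Adjacency (Adj).** $w_{ij} = 1$ if units $i$ and $j$ share a border, else
0; symmetric, zero diagonal. On a lattice this is rook contiguity. Only
bordering pairs are evaluated, which limits sensitivity to map-wide
patterns.

**Population-density-adjusted exponential (PD).**

$$w_{ij} = \exp(-d_{ij}/k_i),$$

where $d_{ij}$ is the inter-centroid distance (great-circle with a
spherical-Earth radius of 6371 km for lon/lat input, Euclidean for planar)
and the bandwidth $k_i$ is the distance from $i$ to its $m_i$-th nearest
neighbor, with

$$m_i = \max\{j : u_j(i) \le \lambda\},$$

$u_j(i)$ the population of the larger region formed by unit $i$ and its $j$
nearest neighbors. The threshold $\lambda$ is a population fraction chosen
by the user (`lambda_fraction`, default 0.5, i.e. half the total population,
which draws a large share of the map into every neighborhood and makes the
scheme sensitive to large-scale patterns; smaller values tune it to smaller
patterns). $k_i$ is therefore large in sparsely populated areas and small in
dense ones — the spatial scale adapts to population density. The matrix is
generally asymmetric ($k_i \ne k_j$); this is meaningful and is never
corrected silently (`symmetrize = FALSE` by default). The diagonal is stored
as $\exp(0) = 1$; Moran-type sums always mask it, I_pop may keep it.

Three deliberate edge-case rules: (i) if even the nearest neighbor pushes
$u_1(i)$ past $\lambda$, $m_i$ is floored at one neighbor with a warning —
a zero bandwidth would make the exponential degenerate; (ii) $m_i$ is capped
at $N-1$ when $\lambda$ exceeds the reachable population; (iii) nearest-
neighbor ties are broken by the region order of the geography, so $k_i$ and
everything downstream is reproducible. A constant in the exponent
(`exponent_scale`, default 1) rescales the effective range for users whose
weight convention includes one.

## Monte Carlo inference

Under the constant-risk null hypothesis the $y_+$ observed cases fall on
regions as a multinomial with $p_i = n_i/n_+$. `null_distribution()` draws
$M$ such data sets (the reference size is $M = 10{,}000$), evaluates the
statistic on each, and the critical value is the empirical 95th percentile —
implemented as the order statistic of rank $\lceil (1-\alpha) M \rceil$, no
interpolation, which at $\alpha = 0.05$, $M = 10{,}000$ is exactly the
9,500th. The p-value uses the add-one convention
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(M+1)$, one-sided in the
upper tail since positive autocorrelation is the alternative of interest;
add-one guarantees a valid test and $p \ge 1/(M+1)$. The simulated total is
always the observed $y_+$, so null and alternative are compared at the same
case load.

Replicates on which a statistic is undefined (a constant count vector makes
the variance zero; these raise typed errors, never NaN) are redrawn; if more
than 1% of replicates degenerate the run aborts, because that signals a
$y_+$ far too small for the number of regions rather than bad luck.
Everything is seeded and bit-reproducible; seeds derived internally stay
below $2^{31}$.

```{r example}
lat <- make_lattice(10, 10, population_per_cell = 5000)
risks <- local_cluster_risks(lat$geography, center_id = "r5c5",
                             population_fraction = 0.2, rr = 2)
y <- simulate_alternative(risks, lat$geography, y_plus = 500, R = 1,
                          seed = 11)[, 1]
counts <- data.frame(id = lat$geography$id, cases = y)
run_test(counts, lat$geography, statistic = "I_w", weights = "adj",
         adjacency = lat$adjacency, M = 2000, seed = 12)
```

## The simulation machinery

The generator reproduces the homogeneous-population study design: a map of
equally populated units (the reference configuration is 3,109 county-like
units of 5,000 people each; the desk-scale analogue is a rook-adjacency
lattice, e.g. 30x30 cells of 5,000) and three alternative risk patterns, all
with maximum relative risk 1.5 unless overridden:

* **local** — regions are sorted by distance from a chosen center and
  accumulated until a target fraction of the total population (5–30% in the
  reference grid) is first reached; the crossing region is included, which
  on homogeneous maps matches the target to within one unit. Cluster
  members get $r = 1.5$, the rest 1.
* **spiral** — a central cluster holding 2% of the population at $r = 1.5$,
  then 100 equal decrements of risk with distance rank until the outermost
  group sits at exactly 1. The decrement groups are equal in *region count*,
  not in distance width: equal-count groups are well defined on any
  geography, including irregular ones where equal-width annuli can be empty.
* **linear** — a west-to-east trend: the longitude range (default the
  continental U.S. span, $-124.161$ to $-67.623$) is cut into 100 equal
  sub-intervals indexed $a = 0, \dots, 99$ and $r = 1 + 0.5\,a/99$, so the
  endpoints are exactly 1 and 1.5. The denominator is $\text{bins}-1$
  precisely so the last bin attains the stated maximum.

Counts under an alternative are multinomial with
$p_i = r_i n_i / \sum_j r_j n_j$. The simulated case total is not dictated
by the design, and power is sensitive to it; the package's convention is an
expected one case per 1,000 at risk ($y_+ = \text{round}(n_+/1000)$, e.g.
4,500 cases on the 30x30 lattice), exposed as `total_cases` in the power
configuration and recorded in every result.

`estimate_power()` rejects when the alternative statistic exceeds the null
critical value and reports the rejection percentage over $R$ replicates
(reference $R = 1{,}000$); `power_study()` crosses patterns, statistics and
weight schemes into a tidy table, caches completed cells as JSON so long
studies are resumable, and serializes to a wide TSV (rows = pattern,
columns = statistic x scheme).

## Problem sizes and what the tests show

The test suite runs everything at desk scale: type-I calibration on a 20x20
lattice with $M = 2{,}000$ null replicates and 1,000 test data sets, power
curves on a 30x30 lattice with $M = 2{,}000$ and $R = 500$, and oracle
comparisons at $N \le 30$. These sizes were chosen so the whole suite
completes in minutes while leaving Monte Carlo error small relative to the
assertions made (a rejection-rate band of $0.05 \pm 3$ binomial standard
errors; strict power increase only across the full 5% to 30% range, with
adjacent fractions compared up to 3 binomial SEs). Full-scale runs —
thousands of regions, $M = 10{,}000$, $R = 1{,}000$ — use the same code
paths via `power_study()` with a user-supplied county geography CSV and GAL
file.

The lattice generator is deliberately idealized: homogeneous populations
(chosen to isolate the spatial signal from population confounding), regular
geometry, no islands or edge corrections. Passing tests therefore
demonstrate correctness of the statistics and calibration of the Monte
Carlo machinery under those conditions, not performance on irregular
real-world maps with heterogeneous populations — on such data I_pop's
population adjustment and the PD bandwidths genuinely matter, and count
statistics can reflect population structure. Edge effects (clusters
touching the map boundary) are not studied.

## Known limitations

* No polygon ingestion: contiguity must arrive as a GAL file or a lattice;
  no choropleth mapping or rate smoothing.
* One-sided testing only; regular-pattern (negative autocorrelation)
  alternatives would need the lower tail.
* Counts only; rate and normalized variants of the statistics would accept
  the same plumbing (the statistics already accept nonnegative reals) but
  are untested extensions.
* Normal-approximation moments for $I$ are intentionally absent — inference
  here is exclusively Monte Carlo.
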