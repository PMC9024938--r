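---
title: "Methods: dietary exposure and health risk of toxic elements in rice-crayfish systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary exposure and health risk of toxic elements in rice-crayfish systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalrisk)
library(dplyr)
```

## The problem

Rice-crayfish co-culture (RCS) grows *Oryza sativa* and the freshwater
crayfish *Procambarus clarkii* in the same flooded paddies. The system is
economically attractive, but heavy feeding and long flooding change how
toxic elements (As, Cd, Cr, Cu, Hg, Ni, Pb, Zn) move from paddy soil into
the two foods people actually eat — rice grain and crayfish tail muscle.
`metalrisk` implements the full quantitative chain used to assess that
hazard for an RCS area and a conventional rice culture (CRC) comparison:
descriptive screening of soil concentrations, soil-to-grain transfer
factors, deterministic dietary exposure and risk scores, Monte Carlo
uncertainty propagation, and multivariate source apportionment. All
concentrations are mg/kg dry weight throughout.

## Deterministic exposure and risk model

The estimated daily intake of element *i* through food *f* is

$$EDI_{i,f} = \frac{EF \times ED \times VI_f \times MC_{i,f}}{BW \times AT} \times 1000
\quad [\mu g\, kg^{-1}\, day^{-1}]$$

with exposure frequency $EF$ (365 days/year), exposure duration $ED$
(77 years for adults, 9 for children), ingestion rate $VI_f$ (rice:
0.337/0.24 kg/day adult/child; crayfish: 0.0555/0.02 kg/day), body weight
$BW$ (70/25 kg) and averaging time $AT = ED \times 365$ days. The factor
1000 converts mg to µg and is applied in exactly one place
(`compute_edi()`), fixing the unit contract for the whole package. Because
$AT = ED \times 365$ and $EF = 365$, the time factor cancels; we keep the
full formula and validate the convention at scenario construction instead
of simplifying, so non-default scenarios (e.g. lifetime averaging for
carcinogens) stay correct.

Non-carcinogenic risk uses the target hazard quotient
$THQ_i = EDI_i / RfD_i$ (reference doses in µg/kg/day: As 0.3, Hg 0.16,
Cr 1500, Cu 40, Ni 20, Zn 300, Cd 1, Pb 3.5) and the hazard index
$HI = \sum_i THQ_i$; $HI > 1$ flags potential risk. Carcinogenic risk uses
$CR_i = (EDI_i/1000) \times SF_i$ with slope factors in kg·day/mg (Cd 15,
As 1.5, Cr 0.5, Ni 0.84, Pb 0.0085) — the division by 1000 bridges the
µg-based EDI to the mg-based slope factor — and
$TCR = \sum CR_i$ over the five carcinogens. Risks below $10^{-6}$ are
negligible and above $10^{-4}$ unacceptable; the benchmarks themselves are
classified as *acceptable* (the literature uses strict inequalities that
leave the boundary undefined; we close the interval on both ends and
document it here).

Tables of EDI/THQ/HI/CR/TCR are computed from **group mean**
concentrations, matching how such tables are conventionally reported; the
Monte Carlo engine works at whatever granularity its distribution specs
describe. The transfer factor $TF = MC_{grain}/MC_{soil}$ is likewise a
ratio of group means.

A deliberate boundary convention in screening: a soil mean exactly equal
to a background value or regulatory limit is *not* an exceedance (strict
`>`). The coefficient of variation is always reported in percent
(CV = SD/mean × 100); published summary tables for the comparison system
print it inconsistently as a fraction in some rows, which this package
does not imitate. The sample SD uses the n − 1 denominator.

## Worked deterministic example

```{r}
res <- risk_assessment(study_means())
res$hi |> select(system, food, population, hi, tolerable)
```

Rice consumption exceeds the HI = 1 benchmark for every population in both
systems (driven by As, then Cu and Zn), crayfish does not — and the RCS HI
for rice is lower than the CRC one.

## Monte Carlo engine

`run_mc()` re-evaluates the deterministic formulas once per iteration
(default 10,000) with each uncertain quantity drawn from its
`dist_spec()`: a small distribution-specification language covering point
masses, normal, lognormal (parameterized either on the log scale or
moment-matched to an arithmetic mean/SD), triangular and uniform families,
with optional truncation enforced by inverse-CDF restriction (no
resampling loops, no out-of-bound draws). Defaults we recommend — and use
in examples — are lognormal concentrations moment-matched to the group
mean/SD, body weight normal truncated at zero, and point-mass ingestion
rates; all are configurable because the underlying per-parameter
distribution choices of any particular study are rarely published.

Design choices that matter for reproducibility:

* **Seed substreams.** Each quantity draws from a seed derived from the
  global seed plus a stable hash of its id (`mc_<element>`, `vi`, `bw`),
  so adding one more element to an HI simulation does not perturb the
  draws of the others.
* **Percentiles** (1, 5, 25, 50, 75, 95, 99) use linear interpolation
  between order statistics (R's type-7 quantile), always computed from the
  full draw vector.
* **Point-mass collapse.** With all specs degenerate, every summary equals
  the deterministic pipeline output *exactly* — this identity is an
  acceptance-tested invariant, not an approximation.
* Exceedance probabilities are fractions of draws strictly above the
  threshold (default 1 for THQ/HI; $10^{-6}$ and $10^{-4}$ for CR/TCR).

## Source apportionment

`correlations()` gives Pearson matrices with two-tailed p-values from the
t transform; `kmo()` implements the Kaiser-Meyer-Olkin adequacy statistic
from anti-image partial correlations (computed from the inverse
correlation matrix, with an optional ridge for near-singular inputs);
`bartlett_sphericity()` is the chi-square identity test
$\chi^2 = -(n - 1 - (2p+5)/6)\ln\det R$. `pca_varimax()`
eigendecomposes the correlation matrix, retains components by the strict
Kaiser rule (eigenvalue > 1; exactly 1 is dropped, matching the usual
wording of the rule), forms loadings as eigenvector × √eigenvalue and
applies varimax rotation with Kaiser normalization. Loading columns are
sign-flipped so the largest-magnitude entry is positive — published
loading signs are otherwise irreproducible conventions of particular
software. Rotation preserves per-variable communalities to numerical
precision, which the tests check at $10^{-8}$.

The raw 158-site soil dataset behind the published correlation and PCA
tables is not available, so those exact values are treated as generator
targets and qualitative references; the quantitative tests are
*recovery* tests — planted factor structures must be recovered with
congruence ≥ 0.95, Bartlett must hold its nominal 5% type-I error on
identity-correlation simulations, and KMO is checked against brute-force
partial-correlation oracles.

## The synthetic generator

`generate_concentrations()` draws latent standard normals with a target
correlation matrix (Gaussian copula, via `MASS::mvrnorm`) and pushes each
margin through a moment-matched transform — lognormal by default, since
concentrations are positive and right-skewed. Targets that are not
positive semi-definite are repaired by nearest-PSD projection
(`Matrix::nearPD`) with a warning. Two properties deserve emphasis:

* After a monotone non-linear marginal transform the *Pearson* correlation
  of the output is close to, but not exactly, the latent target; tests
  therefore compare empirical correlations with a ±0.05 band rather than a
  standard-error bound.
* Normal margins can produce negative concentrations; the generator does
  **not** silently clip. Truncation must be requested explicitly, which
  keeps the moment contract honest.

Preset targets mirror the published summary tables: soil presets per
farming system use the published means/SDs and inter-element correlation
matrices with n = 79 (the study reports 158 topsoil sites without a
per-system breakdown; an even split is this package's choice). The food
presets carry only published means — per-sample dispersions for rice
(n = 3) and crayfish muscle (n = 16) were never published — so they assume
a 20% CV, an explicit assumption (`cv` argument), not a reported fact.
What passing generator-based tests show is therefore that the *pipeline*
is correct under the published moment/correlation structure, not that real
paddy data are lognormal or that food CVs are 20%.

## Problem sizes and numerical choices

Simulation-based tests use n = 10,000 draws for moment/correlation
recovery (3-standard-error bands), n = 2,000 samples for factor-structure
recovery, and 500 replicates for the Bartlett type-I check — sizes chosen
so sampling error is far below the assertion bands while a full test run
stays fast on a laptop. Degenerate inputs fail fast with classed errors:
empty TCR aggregation is an error (a total risk over no carcinogens is
undefined, not zero), a constant column stops correlation analysis naming
the variable, a near-identity correlation matrix makes KMO undefined, and
every Monte Carlo spec is validated before any sampling starts.

## Known limitations

* Exposure is ingestion-only (rice and crayfish); dermal and inhalation
  routes, other foods, and fresh-weight conversions are out of scope.
* Below-detection values are substituted (LOD/2 by default; 0 or LOD
  configurable) rather than modelled by censored-likelihood methods.
* Published probabilistic results from proprietary tooling depend on
  per-parameter distribution choices that were not published; the engine
  here reproduces any such analysis only once those specs are supplied.
* The PCA layer stops at rotated loadings and diagnostics; it assigns no
  source labels ("agricultural", "traffic") — that interpretation is the
  analyst's.
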