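---
title: "Cosolvency analysis of solubility grids: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosolvency analysis of solubility grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolvr)
```

`cosolvr` analyzes the mole-fraction solubility of a crystalline solute
measured on a grid of absolute temperatures and binary solvent
compositions (a water-miscible cosolvent blended with water, indexed by the
cosolvent mass fraction $m_1$, with $m_2 = 1 - m_1$). The bundled fixture
is 6-phenylpyridazin-3(2H)-one (PPD) in DMSO + water: 11 compositions
$\times$ 5 temperatures (298.2–318.2 K) at 0.1 MPa. This vignette explains
the models, the conventions the package commits to where the field leaves
room, and what the synthetic-data generator does and does not emulate.

## The pipeline

```{r pipeline}
d <- ppd_dataset()
f <- ppd_fusion()
report <- suppressWarnings(run_full_analysis(d, f))
report
```

## Ideal solubility and activity coefficients

The ideal solubility of a crystalline solute below its melting point
$T_{fus}$ follows from its fusion enthalpy $\Delta H_{fus}$ and the
solid–liquid heat-capacity difference $\Delta C_p$:

$$\ln x^{idl} = -\frac{\Delta H_{fus}\,(T_{fus}-T)}{R\,T_{fus}\,T}
  + \frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T}
  + \ln\frac{T}{T_{fus}}\right].$$

Both bracketed terms vanish at $T = T_{fus}$, so `ideal_solubility()`
returns exactly 1 there and refuses temperatures above the melting point.
With $\Delta C_p = 0$ the classic van't Hoff ideal form is recovered; the
test suite asserts this reduction.

The activity coefficient $\gamma_i = x^{idl}/x_e$ is computed from the
*unrounded* ideal solubility, never from a displayed 3-significant-figure
value: for the fixture's neat-water cell this reproduces the published
$\gamma \approx 9460$, where the rounded route would give 9450.

The gas constant defaults to the CODATA value $R = 8.3145$ J mol$^{-1}$
K$^{-1}$ and is overridable in every function that uses it; at the
precision of printed solubility tables the choice among common $R$
conventions is immaterial.

## Apparent dissolution thermodynamics

Per composition, ordinary least squares of $\ln x_e$ on
$(1/T - 1/T_{hm})$ gives the apparent standard dissolution enthalpy and
Gibbs energy,

$$\Delta_{sol}H^0 = -R \cdot \text{slope}, \qquad
  \Delta_{sol}G^0 = -R\,T_{hm} \cdot \text{intercept}, \qquad
  \Delta_{sol}S^0 = \frac{\Delta_{sol}H^0 - \Delta_{sol}G^0}{T_{hm}},$$

with $T_{hm} = n / \sum_i 1/T_i$ the harmonic-mean study temperature
(308.0 K for the fixture grid). The enthalpy is invariant to the choice of
$T_{hm}$ — shifting the abscissa only moves the intercept — and the Gibbs
identity above holds to machine precision by construction; both are
property-tested. $R^2$ is the squared Pearson correlation of fitted versus
observed $\ln x_e$, identical to the with-intercept OLS $R^2$.

Values are SI (J mol$^{-1}$) internally and kJ mol$^{-1}$ in displays and
written tables.

### Enthalpy–entropy compensation

`compensation_analysis()` regresses $\Delta_{sol}H^0$ on
$\Delta_{sol}G^0$ across compositions (unweighted: no defensible weights
exist for derived quantities whose uncertainties are unpublished). The
orientation of this regression is a recurring ambiguity in the
compensation literature, and it matters: on the fixture the enthalpy spans
slightly *less* than the Gibbs energy (25.3 vs 27.8 kJ mol$^{-1}$), so
the $\Delta H$-on-$\Delta G$ slope is necessarily below 1 (about 0.92)
while the reversed regression is above 1 (about 1.09), even though both
directions share $R^2 > 0.99$. Rather than silently pick the orientation
that flatters an "enthalpy-driven" reading, the result carries the primary
slope and `slope_reversed`, and users should report which convention they
used. Note this is a qualitative-interpretation knife edge, not a numerical
instability: a slope this close to 1 says the enthalpy and Gibbs energy
track each other almost one-to-one across the composition range.

## The five cosolvency models

All fitting happens in log space — residuals in $\ln x$, not $x$ — which
is what makes a plain regression of $\ln x_e$ reproduce the conventional
van't Hoff parameter tables, and which weights the five-orders-of-magnitude
solubility range sensibly.

* **van't Hoff** (per composition): $\ln x = a + b/T$, OLS on $1/T$.
* **Apelblat** (per composition): $\ln x = A + B/T + C\ln T$, solved as a
  *linear* least-squares problem on the design $(1, 1/T, \ln T)$. This is
  mathematically the optimum of the log-space objective that iterative
  "nonlinear multivariate regression" seeks, without an optimizer. Over a
  20 K window, $1/T$ and $\ln T$ are almost perfectly collinear, so the
  parameter triplet is weakly identified — tiny input perturbations move
  $(A, B, C)$ by tens of units while barely moving the fitted curve. The
  package warns about this and treats predictions and RMSD, not parameter
  values, as the comparable quantities.
* **Yalkowsky–Roseman**: the fit-free decadic log-linear blend
  $\log_{10} x = m_1 \log_{10} x_1 + m_2 \log_{10} x_2$ of the
  experimental neat-solvent solubilities $x_1$ (cosolvent) and $x_2$
  (water). Evaluated on mixture compositions only; the neat ends are its
  inputs, not predictions.
* **Jouyban–Acree**:
  $\ln x_{m,T} = m_1 \ln x_1 + m_2 \ln x_2 +
  \frac{m_1 m_2}{T}\sum_{i=0}^{2} J_i\,(m_1-m_2)^i$, fitted by
  no-intercept least squares of the excess
  $\ln x_e - m_1\ln x_1 - m_2\ln x_2$ on the interaction terms, mixture
  rows only. With all $J_i = 0$ it collapses to the Yalkowsky blend
  (natural vs decadic logs reconcile exactly); the suite asserts this.
* **Jouyban–Acree–van't Hoff**: the same interaction structure with the
  experimental neat terms replaced by their van't Hoff smooths
  $(A_1 + B_1/T)$ and $(A_2 + B_2/T)$. The package uses the two-stage
  construction — neat parameters frozen from the per-composition van't
  Hoff fits, then $J$ regressed — so its $(A_1,B_1,A_2,B_2)$ equal the
  neat-series fits by definition, and its prediction grid is the full
  surface including the neat ends.

### Interaction-term count

Published applications sometimes retain a single $J_0$ and sometimes the
full three-term polynomial. The default here fits three terms and then
prunes trailing terms whose removal worsens the pooled RMSD by at most
0.01 percentage points; on the fixture all three terms survive (dropping
$J_2$ costs 0.13 points). `n_terms = 1` is available for the single-term
convention, and `drop_tol = -Inf` pins the count exactly.

### Goodness of fit

The field's RMSD for solubility correlations is relative:

$$\%RMSD = 100\sqrt{\frac{1}{N}\sum_{i=1}^{N}
  \left(\frac{x_e^{(i)} - x_{calc}^{(i)}}{x_e^{(i)}}\right)^2}.$$

Two aggregations across compositions coexist in the literature. The
package computes both: `overall_rmsd` is the arithmetic mean of the
per-composition RMSDs — the convention under which the published
per-composition tables for this system are internally consistent with
their own overall values — and `overall_rmsd_pooled` pools all residuals.
The mean aggregation is the default for summaries and pass/fail flags; the
conventional adequacy bound is an overall RMSD below 2%.

```{r rmsd}
vapply(report$evaluation, `[[`, numeric(1), "overall_rmsd")
```

### What printed inputs can and cannot reproduce

The bundled grid stores solubilities to 3 significant figures, as
published. Quantities dominated by first-order structure — ideal
solubility, activity coefficients, $\Delta_{sol}H^0$, $\Delta_{sol}G^0$,
van't Hoff parameters, Yalkowsky predictions, the sub-2% adequacy of all
five models — are insensitive to that rounding and reproduce published
values to well under 1%. Three kinds of quantity are not recoverable from
rounded inputs, and the package makes no attempt to force them:
small *differences* of large quantities ($\Delta_{sol}S^0$ moves ~3% when
its parents move 0.15%); weakly identified parameter triplets (Apelblat);
and residual-scale statistics of an already-good fit, where rounding to 3
significant figures smooths genuine measurement scatter and therefore
*shrinks* recomputed RMSDs (the Apelblat and Jouyban–Acree–van't Hoff
overall RMSDs land below their published counterparts for this reason).
The test suite pins each quantity at the tolerance its class supports.

## The synthetic-data generator

`synthetic_spec()` / `generate_surface()` produce grids from the
Jouyban–Acree–van't Hoff mean surface with multiplicative log-normal
noise: $x_e = \exp(\mu_{m,T})\,\varepsilon$,
$\ln\varepsilon \sim N(0, \sigma^2)$ with
$\sigma = \sqrt{\log(1 + CV^2)}$, the exact log-normal relation (for small
CV, $\sigma \approx CV$). Noise is placed on the log scale because that is
where fitting happens and because solubility measurement uncertainty is
naturally relative. Defaults are the fixture's study conditions: the
published neat-solvent van't Hoff parameters, a single interaction term
$J_0 = 25.32$ K, the 11 $\times$ 5 grid, and a 1.38% coefficient of
variation matching the fixture's stated relative measurement uncertainty.

```{r synthetic}
spec <- synthetic_spec(noise_cv = 0, seed = 1)
d0 <- generate_surface(spec)
fit_ja_vant_hoff(d0, n_terms = 1, drop_tol = -Inf)$params
```

Generation is bit-reproducible for a fixed spec, leaves the caller's RNG
stream untouched, and refuses any cell outside $(0,1)$, naming the
offending cell. `recovery_report()` runs the replicate-fit study (replicate
$r$ uses seed `seed + r`); the suite uses 100 replicates of the 55-point
grid, which completes in seconds and gives standard errors small enough to
detect percent-level bias in $J_0$.

What the generator does *not* emulate: equilibration kinetics, assay error
structure, temperature-dependent error variance, or any deviation of the
true surface from the Jouyban–Acree–van't Hoff family. Passing recovery
tests therefore demonstrate correctness of the estimation machinery under
the model's own assumptions, not robustness to misspecified surfaces.

## Degenerate inputs and numerical choices

* Grid construction rejects duplicates, incomplete grids, and fewer than
  two temperatures or compositions; monotonicity violations on user data
  warn rather than error (real measurements may cross), but the bundled
  fixture is held to strict monotonicity in tests.
* Regressions with rank-deficient designs (zero temperature variance,
  fewer points than parameters) raise errors rather than returning NaN.
* All least-squares solutions go through QR; the suite cross-checks them
  against closed-form normal equations.
* Mixture models require both neat series and at least one mixture
  composition, and fail with a precondition error otherwise;
  `run_full_analysis()` records such failures per model and continues the
  remaining stages.
* CSV serialization writes 17 significant digits so read–write round-trips
  are exact at double precision.

## Limitations

* Pressure is metadata only; no pressure dependence is modeled.
* No conversion from mass-based concentration units to mole fraction; the
  input grid must already be mole fraction.
* No uncertainty intervals on fitted parameters: the published
  per-parameter uncertainty summaries for this system have no stated
  computation to reproduce.
* Models beyond the five above (higher-order CNIBS/R–K, Wilson/NRTL,
  Buchowski λh) are out of scope.
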