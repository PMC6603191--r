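---
title: "Methods: the integrated microdosimetric-kinetic model in imkfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the integrated microdosimetric-kinetic model in imkfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imkfit)
```

## The model

`imkfit` implements an integrated microdosimetric-kinetic (IMK) description
of clonogenic survival under (possibly) intensity modulated radiation
fields. Lethal lesions per cell are Poisson, so `S = exp(-w)` with
`w = w_T + w_NT` — the survival of a population factorizes exactly into a
targeted (DNA damage along tracks, "TE") and a non-targeted (intercellular
signalling, "NTE") component.

**Targeted effects.** Potentially lethal lesions are produced in micron-scale
domains in proportion to dose, and disappear at a first-order rate `(a+c)`
(h⁻¹) by conversion to lethal lesions or repair. For a delivery split into
sub-sections of dose $d_n$ and width $\Delta T$,

$$-\ln S_T = \sum_n \left[(\alpha_0+\gamma\beta_0) d_n + \beta_0 d_n^2\right]
  + 2\beta_0 \sum_{n<m} d_n d_m\, e^{-(m-n)(a+c)\Delta T},$$

where the cross terms carry the decay of pairwise lesion interaction with
the time separating the two dose increments. The exponential weight is a
plain deterministic factor: for a fixed grid the expectation over lesion
histories collapses, and no stochastic averaging is performed. In the
constant-rate limit this becomes the familiar linear-quadratic form
$-\ln S_T = (\alpha_0+\gamma\beta_0)D + F\beta_0 D^2$ with the Lea-Catcheside
factor $F(x) = 2(x + e^{-x} - 1)/x^2$, $x = (a+c)T$. The microdosimetric
constant $\gamma = y_D/(\rho \pi r_d^2)$ converts the dose-mean lineal
energy $y_D$ (keV/µm) of the radiation field into the dose-squared
correction of the linear term; defaults are $y_D = 4.393$ keV/µm in-field
and $4.769$ keV/µm out-of-field (225 kVp X-rays), $\rho = 1$ g/cm³,
$r_d = 0.5$ µm, giving $\gamma_{IF} = 0.896$ Gy and $\gamma_{OF} = 0.973$ Gy.

**Non-targeted effects.** Hit cells (those with at least one activated
signal-releasing target, probability
$f_h(D) = 1-\exp[-((\alpha_b+\gamma\beta_b)D + \beta_b D^2)]$) emit
signals that kill non-hit cells anywhere in the flask — the signal range is
assumed to cover the whole flask for both half-field and uniform exposures.
The signal-mediated lethal-lesion load is
$w_{NT} = \delta\, f_h(D)_{IF} f_b(D)_{region}$, bounded by $\delta$.
By assumption $f_h$ depends on *cumulative* dose only, never on the temporal
structure of delivery; out-of-field survival is therefore
fractionation-independent in the model. Setting $\delta = 0$ reproduces
signalling-inhibited (e.g. nitric-oxide inhibitor) conditions.

**Field geometry.** `field_config()` carries the irradiated area fraction
`a_if`, the two gamma constants and `scatter_fraction`, the direct dose
under the shield as a fraction of the in-field dose. The default is 0 — all
out-of-field killing is signalling — because scattered low-energy photons
were found to have no significant impact on out-of-field survival in the
experiments this model targets; the parameter is exposed for users whose
shielding leaks more dose. A related open choice is the x-axis of
out-of-field curves: the package treats the delivered in-field dose as the
abscissa everywhere.

## Parameters

| Parameter | Unit | Meaning | Typical range |
|---|---|---|---|
| `alpha0` | Gy⁻¹ | linear TE coefficient | 0.02–0.4 |
| `beta0` | Gy⁻² | quadratic TE coefficient | 0.01–0.08 |
| `a_plus_c` | h⁻¹ | SLDR (lesion conversion + repair) rate | 0–2.5 |
| `alpha_b`, `beta_b` | Gy⁻¹, Gy⁻² | signal-target activation coefficients | 0.02–0.4 |
| `delta` | — | lethal-lesion yield per signal interaction | 0.4–0.7 |

`imk_presets()` ships estimates for a normal human fibroblast line
(AGO1522) and a prostate cancer line (DU145), each under modulated
(half-field) and uniform exposure. The AGO1522 modulated-field repair rate
was estimated at 0.034 ± 0.062 h⁻¹ — statistically indistinguishable from
zero — so the default (`idealized = TRUE`) preset sets it to exactly 0,
making schedule-independence an exact property; `idealized = FALSE` keeps
the literal estimate. The same numbers are shipped as a plain-text fixture
(`inst/extdata/cell_line_parameters.yaml`) for the file-based interface.

## Split-dose estimators

From a recovery curve $S(\tau)$ after fractions $D_1 + D_2$,

$$(a+c) = \frac{\lim_{\tau\to 0} (1/S)\,dS/d\tau}{\ln(S(\infty)/S(0))},
\qquad \beta_0 = \frac{\ln(S(\infty)/S(0))}{2 D_1 D_2}.$$

Conventions, all configurable:

- The initial slope is a forward finite difference over `step`, normalized
  by $S(0)$ (not a mid-point survival — an assumption the package makes
  explicit). The conventional `step = 0.25` h — the first measured
  inter-fraction time — systematically *underestimates* the rate; on a
  noiseless curve the estimator equals
  $(e^{B(1-e^{-(a+c)s})}-1)/(sB)$ with $B = 2\beta_0 D_1 D_2$, about −13%
  at $(a+c) = 2.5$ h⁻¹ with $\beta_0 = 0.081$ Gy⁻². A "fine" mode
  (`step = 1e-4` h on model curves) approaches the true limit and recovers
  generating rates to better than 0.1%. Both behaviours are asserted in the
  test suite.
- $S(\infty)$ is the mean survival over the plateau `window`, default 6–48 h
  inclusive. For the sampled grid {0, 0.25, 0.5, 1, 2, 4, 24, 48} h this
  averages the 24 h and 48 h points (the 4 h point falls outside). For slow
  repair ($a+c \lesssim 0.1$ h⁻¹) the 6–48 h window is nowhere near the
  plateau ($e^{-0.034\cdot 24} = 0.44$) and the literal convention would be
  tens of percent off; tests of estimator self-consistency for such sets
  therefore extend the tau grid (to hundreds of hours) and the window with
  it. This is a property of the estimator, not of the implementation.
- Both estimators are invariant to rescaling all survivals (plating
  efficiency cancels). A flat curve makes the rate unidentifiable and raises
  an error; inverse recovery ($S(\infty) < S(0)$, seen out-of-field) yields
  a negative $\beta_0$ reported as-is with a warning, never clamped.

## MCMC inference

With $\gamma$, $\beta_0$ and $(a+c)$ fixed at their split-dose estimates,
$\theta = (\alpha_0, \alpha_b, \beta_b, \delta)$ is sampled by
component-wise Gaussian random-walk Metropolis with reflection at zero,
under independent normal priors truncated at zero (default: mean = an
initial guess, sd = 10× that guess) and a Gaussian error model on
$-\ln S$. The upstream description of this fitting step leaves the sampler
internals unspecified, so the scheme here is the simplest one consistent
with "normal priors, normal error on $-\ln S$": defaults of 20 000 draws
with 5 000 burn-in, proposal scales adapted in blocks of 100 iterations
during burn-in toward 20–50% acceptance and then frozen, which keeps the
chain a deterministic function of the seed. Datasets from several regions
are fitted jointly with a single shared $\alpha_0$ and shared NTE
parameters; fitting modulated and uniform conditions with their own TE
parameters is done as two runs, mirroring how the preset tables are
structured. The 95.4% predictive band (the ±2σ convention) is the pointwise
2.3%/97.7% quantile of survival curves over retained draws. $R^2$ and the
reduced $\chi^2$ are computed on the survival scale (configurable to
$-\ln S$ for $R^2$); the survival-scale $\sigma$ is obtained from the
$-\ln S$ sd by the delta method ($\sigma_S = S\,\sigma_{\ln}$).

The migration-versus-damage-yield comparison of in-field radio-resistance
is exposed as two model variants scored with the same statistics:
`migration_adjusted_survival()` mixes in a surviving migrant fraction
(`f_move`, with plateau $f_{move} s_m$ at high dose), and
`scale_by_damage_yield()` rescales $(\alpha_0, \beta_0)$ by $(k, k^2)$ for a
damage-yield ratio $k$, since $\alpha_0 = ak/c$ and $\beta_0 = bk^2/2c$ in
the kinetic derivation. The rate constants $a$, $b$, $c$ are not
individually identifiable from survival data and the package deliberately
exposes only the combinations $(a+c)$ and $k$-ratio scaling.

## Synthetic data

The generator emulates the three experiment families the analysis expects:
single-dose dose-response curves (default grid 0–10 Gy), split-dose
recovery (2 + 2 Gy over the tau grid above), and four pulsed regimens
delivering 4 Gy at average rates of 0.59, 0.2, 0.1 and 0.05 Gy/min. The
regimen presets pulse the beam at its native 0.59 Gy/min output with equal
beam-off gaps sized to meet each average rate — machine delivery logs are
not available, so the pulse structure is an explicit approximation and is
data (a schedule object), not code.

Noise is additive Gaussian on $-\ln S$, truncated below at zero so recorded
survival never exceeds the unirradiated control, with zero-dose controls
fixed at exactly 1. `noise_sd` (default 0.1) is the standard deviation of
the *recorded point* — i.e. of the mean over `n_replicates` flasks — and is
stored in the `sd` column, which makes generator, likelihood and $\chi^2$
mutually consistent and makes "empirical sd of $-\ln S$ equals the
configured sd" literally testable. True replicate-level scatter in such
assays is only visible as figure error bars; 0.1 is a stand-in of the right
magnitude, not a measured value. A Poisson colony-count mode was considered
and rejected: it would break conjugacy with the fitted likelihood while
adding a parameter (plating cell number) the analysis never uses.

What passing tests show — and what they do not: parameter-recovery and
coverage tests demonstrate that the estimators and sampler invert the
model's own data-generating process at realistic noise. They cannot show
that the error model matches real clonogenic scatter (which is closer to
beta/colony-count), that plating efficiency is stable, or that signal
saturation holds in flasks of other sizes.

## Numerical choices

- **Exact gap handling.** The production evaluator `w_te()` refines each
  beam-on segment into $2^k$ midpoint impulses (doubling $k$ until
  successive $w_T$ values agree to `rel_tol`, default 1e-6, cap $2^{20}$)
  and carries the exponential decay across beam-off gaps *exactly* instead
  of binning them. A uniform global grid capped at $2^{20}$ steps cannot
  resolve acute pulses separated by tens of hours better than ~1e-6 in
  $w_T$; per-segment refinement reaches the algebraic two-impulse closed
  form to 1e-9 and is orders of magnitude cheaper. The uniform-grid route
  (`discretize()` + `w_te_schedule()`, with the same adaptive doubling in
  `w_te_uniform()`) is retained and verified against the continuous closed
  form to 0.1%.
- **Within-segment sums** use `expm1`-based geometric forms, with a series
  for the cancellation-prone difference $n - \sum_k q^k$ when
  $n(a+c)\Delta T < 10^{-4}$.
- **Acute exposures** are finite segments of 1e-6 h so every code path goes
  through one schedule representation; tests needing the impulse limit to
  1e-9 shrink epsilon to 1e-10.
- **Lea-Catcheside branch.** The direct form of $F$ loses ~$4.4\times
  10^{-16}/x$ relative precision to cancellation, so the series
  $1 - x/3 + x^2/12 - x^3/60$ is used for $x < 10^{-3}$; at that switch
  point series truncation (~$x^4/360$) and direct-form noise are both below
  1e-12, which a test asserts.
- **Overflow guards.** Exponents are clipped at ±700 before
  exponentiation; survival is returned as `exp(-w)` without flooring.
- **Degenerate inputs** fail loudly: flat recovery curves, zero-variance
  observations, all-zero sigmas, empty plateau windows and all-rejected
  chains raise errors naming the problem rather than returning NaN.

Test-suite problem sizes (dose grids of 21–41 points over three regions,
chains of 2 000–6 000 draws, 10–200 replicate seeds) are chosen so the whole
suite exercises every recovery property at comfortable statistical margins
while completing in well under a minute; they are package choices, and all
scale up without code changes.

## Limitations

- No track-structure or DSB-induction simulation: $y_D$ values are consumed
  as constants from microdosimetric transport calculations done elsewhere.
- No spatial dose profiles or signal-diffusion gradients; geometry enters
  only through `a_if`, the two gammas and `scatter_fraction`.
- No cell-cycle or tissue-level (TCP/NTCP) modelling.
- The sampler is fixed-form Metropolis; no HMC/NUTS, and model comparison
  is limited to $R^2$/$\chi^2$ of explicitly constructed variants.
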